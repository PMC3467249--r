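# End-to-end orchestration: simulate (or load) -> preprocess -> differential
# expression -> six-criterion selection -> LOOCV with re-selection -> final
# signature -> ddCt quantification and cross-platform transfer -> evaluation.
# A single seeded config drives every stage; the run report is one JSON
# document carrying all tables and metrics.

#' Pipeline configuration
#'
#' @param simulate Generate a synthetic cohort instead of reading inputs.
#' @param sim A [simulation_config()] (when simulating).
#' @param arrays_dir,sheet_path,ct_path Input paths (when not simulating).
#' @param span Loess span.
#' @param thresholds A [filter_thresholds()].
#' @param cost SVM cost.
#' @param k Signature size.
#' @param run_tlda Run the qRT-PCR branch.
#' @param permutation_test Replace parametric p-values by permutation
#'   p-values (>= 1000 label permutations).
#' @param seed Integer master seed.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A `pipeline_config` list with its own config hash attached.
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            arrays_dir = NULL, sheet_path = NULL,
                            ct_path = NULL, span = 0.5,
                            thresholds = filter_thresholds(), cost = 1.0,
                            k = 10L, run_tlda = TRUE,
                            permutation_test = FALSE, seed = 1L,
                            out_dir = NULL) {
  cfg <- list(simulate = simulate, sim = sim, arrays_dir = arrays_dir,
              sheet_path = sheet_path, ct_path = ct_path, span = span,
              thresholds = thresholds, cost = cost, k = as.integer(k),
              run_tlda = run_tlda, permutation_test = permutation_test,
              seed = as.integer(seed), out_dir = out_dir)
  cfg$hash <- cs_config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim` and
#' `thresholds` are nested maps passed to [simulation_config()] and
#' [filter_thresholds()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$sim)) args$sim <- do.call(simulation_config, y$sim)
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(filter_thresholds, y$thresholds)
  }
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report` list: config hash, stage timings, differential
#'   expression table, selected genes with audit, CV report, signature,
#'   confusion metrics (microarray and, when run, qRT-PCR), AUC, MDS stress
#'   and variance fraction, covariate baseline. Written to
#'   `<out_dir>/run_report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    cs_log(sprintf("stage %-12s done at %7.2fs", stage, timings[[stage]]))
  }

  if (cfg$simulate) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    coh <- generate_cohort(sim)
    arrays <- coh$arrays; sheet <- coh$sheet
  } else {
    if (is.null(cfg$sheet_path) || !file.exists(cfg$sheet_path)) {
      cs_stop("sample sheet not found: %s", cfg$sheet_path %||% "<missing>",
              class = "chemosig_io_error")
    }
    sheet <- read_sample_sheet(cfg$sheet_path)
    files <- list.files(cfg$arrays_dir, pattern = "\\.tsv$", full.names = TRUE)
    files <- files[!grepl("sample_sheet|ct_table", files)]
    arrays <- lapply(files, read_spot_table)
    names(arrays) <- vapply(arrays, `[[`, "", "array_id")
    coh <- NULL
  }
  tick("input")

  expr <- preprocess_arrays(arrays, sheet, span = cfg$span)
  tick("preprocess")

  de <- if (cfg$permutation_test) {
    out <- permutation_p_values(expr, sheet, seed = cfg$seed)
    out$q <- bh_adjust(out$p)
    class(out) <- c("de_result", "data.frame")
    out
  } else run_diffexp(expr, sheet)
  tick("diffexp")

  sel <- apply_selection_criteria(de, cfg$thresholds)
  tick("select")

  cv <- loocv_with_reselection(expr, sheet, cfg$thresholds, cost = cfg$cost,
                               fallback_k = cfg$k)
  k_eff <- min(cfg$k, length(cv$selection_frequency))
  model <- derive_final_signature(cv, expr, sheet, k = k_eff, cost = cfg$cost)
  tick("classify")

  cm_ma <- confusion_metrics(cv$samples$true, cv$samples$predicted)
  roc_ma <- roc_auc(cv$samples$score, cv$samples$true)
  Xsig <- t(expr$M[model$genes, , drop = FALSE])
  mds <- mds_smacof(Xsig, dims = min(3L, nrow(Xsig) - 1L))
  baseline <- tryCatch(covariate_baseline(sheet), error = function(e) NULL)
  tick("evaluate")

  tlda <- NULL
  if (cfg$run_tlda) {
    ct <- if (cfg$simulate) {
      generate_ct_table(coh$expr_true, model$genes, sim)
    } else if (!is.null(cfg$ct_path)) {
      read_ct_table(cfg$ct_path)
    }
    if (!is.null(ct)) {
      rq <- compute_rq(ct)
      tr <- transfer_signature(model, rq, sheet, retrain = TRUE,
                               cost = cfg$cost)
      tlda <- list(
        fold_change = tlda_fold_change(rq, sheet),
        confusion = confusion_metrics(tr$predictions$true,
                                      tr$predictions$predicted),
        accuracy = tr$cv$accuracy)
    }
    tick("tlda")
  }

  report <- list(
    config_hash = cfg$hash,
    seed = cfg$seed,
    timings = timings,
    n_samples = ncol(expr$M),
    n_genes = nrow(expr$M),
    selected_genes = sel$selected,
    signature = list(genes = model$genes,
                     weights = as.list(model$weights),
                     intercept = model$intercept),
    loocv = list(accuracy = cv$accuracy,
                 samples = cv$samples,
                 confusion = unclass(cm_ma),
                 auc = roc_ma$auc),
    mds = list(stress = mds$stress,
               variance_fraction = mds$variance_fraction),
    covariate_baseline = if (!is.null(baseline)) baseline$accuracy,
    tlda = if (!is.null(tlda)) list(confusion = unclass(tlda$confusion),
                                    accuracy = tlda$accuracy),
    de_table = de[, intersect(c("gene", "m_nr", "m_ccr", "s_nr", "s_ccr",
                                "a_mean", "fc_signed", "t_mod", "p", "q"),
                              names(de))])
  class(report) <- "run_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(report$de_table,
                       file.path(cfg$out_dir, "diffexp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0("<run_report %s: %d genes x %d samples | LOOCV accuracy ",
                     "%.1f%% (AUC %.3f) | %d genes selected | MDS stress %.4f>\n"),
              x$config_hash, x$n_genes, x$n_samples,
              100 * x$loocv$accuracy, x$loocv$auc,
              length(x$selected_genes), x$mds$stress))
  invisible(x)
}
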