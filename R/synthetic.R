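# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: two-channel arrays measuring log2(sample/universal-reference)
# ratios with an intensity-dependent dye bias, planted differential genes
# between non-responders (NR) and complete clinical responders (CCR),
# matched qRT-PCR Ct tables concordant with the planted fold changes, and a
# clinical sample sheet. The default design mirrors the modeled study:
# 23 samples (13 CCR + 10 NR) on ~41,000-probe arrays with 2,615 control
# probes; gene counts are scaled down in tests for speed.

#' Simulation configuration
#'
#' Defaults state the emulated world: 13 CCR + 10 NR patients, 2,000 probes
#' of which 100 controls (a scaled-down array; pass `n_genes = 41000`,
#' `n_controls = 2615` for the full-size design), 10 planted differential
#' genes at one log2 unit (2-fold), per-gene biological SD 0.3 log2 units
#' (consistent with the downstream SD < 0.5 selection criterion), dye-bias
#' amplitude 0.5 log2 units, spot-level technical SD 0.1, Ct slope 1 cycle
#' per log2 unit and Ct replicate SD 0.1 cycles.
#'
#' @param n_nr,n_ccr Cohort sizes.
#' @param n_genes Total probe count (including controls).
#' @param n_controls Control-probe count.
#' @param n_de Number of planted differential genes.
#' @param delta Planted log2 group difference (NR minus CCR).
#' @param sigma_gene Per-gene biological SD, log2 units.
#' @param sigma_spot Spot-level technical SD, log2 units.
#' @param bias_amplitude Dye-bias amplitude, log2 units.
#' @param flag_rate Fraction of spots randomly flagged bad.
#' @param ct_slope Cycles per log2-expression unit.
#' @param ct_noise_sd Ct replicate SD, cycles.
#' @param seed Integer seed; one global seed drives per-array substreams.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_nr = 10L, n_ccr = 13L,
                              n_genes = 2000L, n_controls = 100L,
                              n_de = 10L, delta = 1.0,
                              sigma_gene = 0.3, sigma_spot = 0.1,
                              bias_amplitude = 0.5, flag_rate = 0.01,
                              ct_slope = 1.0, ct_noise_sd = 0.1,
                              seed = 1L) {
  cfg <- list(n_nr = as.integer(n_nr), n_ccr = as.integer(n_ccr),
              n_genes = as.integer(n_genes), n_controls = as.integer(n_controls),
              n_de = as.integer(n_de), delta = delta,
              sigma_gene = sigma_gene, sigma_spot = sigma_spot,
              bias_amplitude = bias_amplitude, flag_rate = flag_rate,
              ct_slope = ct_slope, ct_noise_sd = ct_noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_nr > 0, n_ccr > 0, n_genes > 0, n_controls >= 0,
              n_de >= 0, n_de <= n_genes - n_controls,
              sigma_gene > 0, flag_rate >= 0, flag_rate < 1)
  })
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic two-channel cohort
#'
#' Per gene and sample the true log2(sample/reference) ratio is
#' `0 + effect + N(0, sigma_gene)`, with `effect = +/- delta` in NR samples
#' for planted genes (half up-, half down-regulated in NR) and 0 otherwise.
#' Spot intensities are back-computed so that log2(Cy5/Cy3) equals the true
#' ratio plus the dye bias `bias_amplitude * sin(A*pi/8)` plus N(0, sigma_spot)
#' spot noise, with A ~ Uniform(6, 14). About `flag_rate` of spots are
#' randomly flagged (-50/-75/-100) and control probes carry M_true = 0.
#' Array substreams are split from the global seed, so adding arrays never
#' perturbs earlier ones.
#'
#' @param cfg A [simulation_config()].
#' @return List with `arrays` (named list of `spot_table`), `sheet`
#'   (`sample_sheet`), `truth` (planted genes with signed fold changes and
#'   true classes) and `expr_true` (noise-free per-sample expected M, as a
#'   matrix gene x sample).
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  n <- cfg$n_nr + cfg$n_ccr
  ids <- sprintf("P%03d", seq_len(n))
  classes <- rep(c("NR", "CCR"), c(cfg$n_nr, cfg$n_ccr))
  n_target <- cfg$n_genes - cfg$n_controls
  genes <- sprintf("G%05d", seq_len(n_target))
  controls <- if (cfg$n_controls > 0) sprintf("CTRL%04d", seq_len(cfg$n_controls))
              else character()

  set.seed(cfg$seed)
  de_idx <- sort(sample.int(n_target, cfg$n_de))
  de_sign <- rep_len(c(1, -1), cfg$n_de)
  effect <- numeric(n_target)
  effect[de_idx] <- de_sign * cfg$delta

  # per-sample biological expression (gene-level, shared by spot replicates)
  expr_true <- matrix(0, n_target, n, dimnames = list(genes, ids))
  expr_true[de_idx, classes == "NR"] <- effect[de_idx]

  arrays <- vector("list", n)
  names(arrays) <- ids
  n_probes <- cfg$n_genes
  flag_pool <- c(-50L, -75L, -100L)
  for (i in seq_len(n)) {
    set.seed(cs_subseed(cfg$seed, i))
    m_bio <- expr_true[, i] + stats::rnorm(n_target, 0, cfg$sigma_gene)
    m_true <- c(m_bio, numeric(cfg$n_controls))          # controls at 0
    A <- stats::runif(n_probes, 6, 14)
    bias <- cfg$bias_amplitude * sin(A * pi / 8)
    M <- m_true + bias + stats::rnorm(n_probes, 0, cfg$sigma_spot)
    cy5 <- 2 ^ (A + M / 2)
    cy3 <- 2 ^ (A - M / 2)
    flag <- rep(0L, n_probes)
    nbad <- round(cfg$flag_rate * n_probes)
    if (nbad > 0) {
      bad <- sample.int(n_probes, nbad)
      flag[bad] <- sample(flag_pool, nbad, replace = TRUE)
    }
    sym <- c(genes, controls)
    df <- data.frame(probe_id = sprintf("%s_p1", sym), gene_symbol = sym,
                     cy5_fg = cy5, cy3_fg = cy3, flag = flag,
                     is_control = c(rep(FALSE, n_target),
                                    rep(TRUE, cfg$n_controls)),
                     stringsAsFactors = FALSE)
    arrays[[i]] <- new_spot_table(ids[i], df)
  }

  set.seed(cs_subseed(cfg$seed, n + 1L))
  sheet <- data.frame(
    patient_id = ids,
    response = classes,
    regimen = "PF",
    hpv = sample(c("positive", "negative"), n, replace = TRUE),
    cigarettes_per_day = stats::rpois(n, 25),
    alcohol_l_per_day = round(stats::rexp(n, 1), 1),
    hemoglobin = round(stats::rnorm(n, 12.5, 1.0), 1),
    age = round(stats::rnorm(n, 57, 8)),
    stringsAsFactors = FALSE)
  sheet <- structure(sheet, class = c("sample_sheet", "data.frame"))

  fc <- ifelse(de_sign >= 0, 2 ^ (cfg$delta), -(2 ^ (cfg$delta)))
  truth <- list(de_genes = data.frame(gene = genes[de_idx],
                                      fc_signed = fc,
                                      stringsAsFactors = FALSE),
                true_class = stats::setNames(classes, ids))
  list(arrays = arrays, sheet = sheet, truth = truth, expr_true = expr_true)
}

#' Generate a matched qRT-PCR Ct table from an expression matrix
#'
#' Emulates TaqMan low-density array output for the signature genes:
#' `Ct(sample, gene) = 25 - ct_slope * M(gene, sample) + N(0, ct_noise_sd)`,
#' two replicates per well. The reference gene is generated with M = 0 in
#' every sample, and a calibrator sample (the universal reference run against
#' itself) is generated with M = 0 for every gene, so its relative quantity
#' is 1 by construction.
#'
#' @param expr An `expression_matrix` or plain gene x sample matrix of M.
#' @param genes Genes to carry on the card (subset of rownames).
#' @param cfg A [simulation_config()] (uses ct_slope, ct_noise_sd, seed).
#' @param reference_gene,calibrator_id Names used in the output table.
#' @return A `ct_table`.
#' @export
generate_ct_table <- function(expr, genes, cfg = simulation_config(),
                              reference_gene = "GAPDH",
                              calibrator_id = "calibrator") {
  M <- if (inherits(expr, "expression_matrix")) expr$M else expr
  absent <- setdiff(genes, rownames(M))
  if (length(absent)) cs_stop("gene(s) absent from expression matrix: %s",
                              paste(absent, collapse = ", "),
                              class = "chemosig_key_error")
  stopifnot(cfg$ct_slope > 0)
  set.seed(cs_subseed(cfg$seed, 999983L))
  samples <- c(colnames(M), calibrator_id)
  all_genes <- c(genes, reference_gene)
  grid <- expand.grid(replicate = 1:2, gene = all_genes, sample = samples,
                      stringsAsFactors = FALSE)
  m_of <- function(s, g) {
    if (s == calibrator_id || g == reference_gene) 0 else M[g, s]
  }
  mu <- mapply(m_of, grid$sample, grid$gene)
  ct <- 25 - cfg$ct_slope * mu + stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd)
  out <- data.frame(sample_id = grid$sample, gene = grid$gene,
                    replicate = grid$replicate, ct = ct,
                    undetermined = FALSE, stringsAsFactors = FALSE)
  structure(out, reference_gene = reference_gene,
            calibrator_id = calibrator_id,
            class = c("ct_table", "data.frame"))
}

#' Classify a clinical response
#'
#' Complete clinical response (CCR) is a decrease of tumor size of more than
#' 90%; non-response (NR) is a decrease of less than 50% or progression of
#' disease. Both inequalities are strict: exactly 90% or 50% falls in
#' neither extreme group and is excluded (the modeled study enrolled only
#' the two extreme groups).
#'
#' @param percent_decrease Tumor size decrease in percent, in \[0, 100\].
#' @param progressed Logical; disease progressed under therapy.
#' @return One of "CCR", "NR", "excluded".
#' @export
classify_response <- function(percent_decrease, progressed = FALSE) {
  if (progressed) return("NR")
  if (!is.finite(percent_decrease) || percent_decrease < 0 ||
      percent_decrease > 100) {
    cs_stop("percent_decrease must lie in [0, 100] (got %s) unless progressed",
            format(percent_decrease), class = "chemosig_domain_error")
  }
  if (percent_decrease > 90) "CCR"
  else if (percent_decrease < 50) "NR"
  else "excluded"
}

#' Write a full synthetic cohort to disk
#'
#' Spot tables (one TSV per array), sample sheet, Ct table for the planted
#' genes, and ground-truth JSON.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list from [generate_cohort()].
#' @export
simulate_to_dir <- function(cfg = simulation_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(cfg)
  hash <- cs_config_hash(cfg)
  for (s in names(coh$arrays)) {
    write_spot_table(coh$arrays[[s]], file.path(dir, paste0(s, ".tsv")),
                     config_hash = hash)
  }
  write_sample_sheet(coh$sheet, file.path(dir, "sample_sheet.tsv"),
                     config_hash = hash)
  ct <- generate_ct_table(coh$expr_true, coh$truth$de_genes$gene, cfg)
  write_ct_table(ct, file.path(dir, "ct_table.tsv"), config_hash = hash)
  jsonlite::write_json(coh$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(coh)
}
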