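# Relative quantification of qRT-PCR (TaqMan low-density array) data by the
# threshold-cycle method: replicate Ct values are averaged per well, each
# gene is normalized to the reference gene within its sample
# (dCt = Ct_gene - Ct_ref), then to the calibrator sample
# (ddCt = dCt_sample - dCt_calibrator), and the relative quantity is
# RQ = 2^-ddCt, so the calibrator has RQ = 1 for every gene by construction.
# Undetermined Ct (no amplification by cycle 40) is treated as missing,
# never imputed as 40.

#' Compute relative quantities from a Ct table
#'
#' @param ct A `ct_table` (see [read_ct_table()] / [generate_ct_table()]).
#' @return An `rq_matrix`: `rq` (gene x sample, calibrator column dropped),
#'   `ddct`, `n_rep` and `ct_sd` (replicate count and SD per well),
#'   `reference_gene`, `calibrator_id`. Wells whose replicates are all
#'   undetermined are `NA` and flagged in `missing_wells`.
#' @export
compute_rq <- function(ct) {
  ref <- attr(ct, "reference_gene")
  cal <- attr(ct, "calibrator_id")
  if (is.null(ref) || is.null(cal)) {
    cs_stop("ct table lacks reference_gene/calibrator_id attributes",
            class = "chemosig_parameter_error")
  }
  if (!cal %in% ct$sample_id) cs_stop("calibrator sample '%s' absent", cal,
                                      class = "chemosig_parameter_error")
  if (!ref %in% ct$gene) cs_stop("reference gene '%s' absent", ref,
                                 class = "chemosig_parameter_error")
  key <- interaction(ct$gene, ct$sample_id, drop = TRUE, lex.order = TRUE)
  agg <- function(v, f) tapply(v, key, f)
  mean_ct <- agg(ct$ct, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  n_rep <- agg(ct$ct, function(v) sum(!is.na(v)))
  ct_sd <- agg(ct$ct, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  parts <- strsplit(names(mean_ct), ".", fixed = TRUE)
  genes <- sort(unique(ct$gene)); samples <- sort(unique(ct$sample_id))
  to_mat <- function(v) {
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))] <- v
    m
  }
  CT <- to_mat(mean_ct)
  if (is.na(CT[ref, cal])) cs_stop("reference gene undetermined in calibrator",
                                   class = "chemosig_validation_error")
  dct <- sweep(CT, 2, CT[ref, ])              # Ct_gene - Ct_ref per sample
  ddct <- dct - dct[, cal]
  rq <- 2 ^ (-ddct)
  target <- setdiff(genes, ref)
  keep_s <- setdiff(samples, cal)
  partial <- names(n_rep)[n_rep == 1]
  if (length(partial)) cs_log(sprintf(
    "%d well(s) with a single usable replicate", length(partial)), level = 2L)
  miss <- which(is.na(rq[target, keep_s, drop = FALSE]), arr.ind = TRUE)
  structure(list(rq = rq[target, keep_s, drop = FALSE],
                 ddct = ddct[target, keep_s, drop = FALSE],
                 n_rep = to_mat(n_rep)[target, keep_s, drop = FALSE],
                 ct_sd = to_mat(ct_sd)[target, keep_s, drop = FALSE],
                 rq_full = rq[target, , drop = FALSE],
                 missing_wells = miss,
                 reference_gene = ref, calibrator_id = cal),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("<rq_matrix: %d genes x %d samples (ref %s, calibrator %s), %d missing wells>\n",
              nrow(x$rq), ncol(x$rq), x$reference_gene, x$calibrator_id,
              nrow(x$missing_wells)))
  invisible(x)
}

#' Per-gene signed fold change NR vs CCR on the qRT-PCR scale
#'
#' Group means of log2(RQ) per gene, signed fold change under the same
#' NR-over-responder convention as the microarray table, plus a two-sided
#' Welch t p-value on log2(RQ).
#'
#' @param rq An `rq_matrix`.
#' @param sheet A `sample_sheet`.
#' @return Data frame: gene, m_nr, m_ccr, fc_signed, p.
#' @export
tlda_fold_change <- function(rq, sheet) {
  L <- log2(rq$rq)
  cls <- sheet$response[match(colnames(L), sheet$patient_id)]
  if (length(unique(stats::na.omit(cls))) < 2) {
    cs_stop("both classes must be present", class = "chemosig_domain_error")
  }
  res <- lapply(rownames(L), function(g) {
    a <- L[g, cls == "NR" & !is.na(cls)]; a <- a[!is.na(a)]
    b <- L[g, cls == "CCR" & !is.na(cls)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      return(data.frame(gene = g, m_nr = NA_real_, m_ccr = NA_real_,
                        fc_signed = NA_real_, p = NA_real_))
    }
    p <- if (length(a) > 1 && length(b) > 1) {
      group_compare(a, b, method = "welch_t")
    } else NA_real_
    data.frame(gene = g, m_nr = mean(a), m_ccr = mean(b),
               fc_signed = signed_fold_change(mean(a) - mean(b)), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Transfer a gene signature to the qRT-PCR platform
#'
#' The signature's gene set is kept fixed; its weights are re-learned on the
#' qRT-PCR scale because the two platforms' feature scales differ. With
#' `retrain = TRUE` (labeled cohort) the transferred model is evaluated by
#' LOOCV with the gene set fixed (no re-selection - the signature is given)
#' and a model trained on the full cohort is returned. With
#' `retrain = FALSE`, `model` must already be a TLDA-scale fit, and it is
#' applied frozen to the new samples.
#'
#' @param model A `signature_model` (microarray-derived gene set, or a
#'   TLDA-scale fit when `retrain = FALSE`).
#' @param rq An `rq_matrix` containing every signature gene.
#' @param sheet A `sample_sheet` with labels (required when `retrain = TRUE`).
#' @param retrain Refit weights on the labeled qRT-PCR cohort?
#' @param cost SVM cost for retraining.
#' @param extra_features Optional sample x covariate matrix (see
#'   [augment_with_covariates()]).
#' @return List: `predictions` data frame (sample, predicted, score, true if
#'   known), `model` (TLDA-scale), `cv` (LOOCV report when retrain).
#' @export
transfer_signature <- function(model, rq, sheet = NULL, retrain = TRUE,
                               cost = 1.0, extra_features = NULL) {
  missing <- setdiff(model$genes, rownames(rq$rq))
  if (length(missing)) cs_stop("signature gene(s) absent from RQ matrix: %s",
                               paste(missing, collapse = ", "),
                               class = "chemosig_key_error")
  X <- t(log2(rq$rq[model$genes, , drop = FALSE]))
  if (anyNA(X)) cs_stop("missing RQ values for signature genes",
                        class = "chemosig_domain_error")
  if (!is.null(extra_features)) {
    keep <- intersect(rownames(X), rownames(extra_features))
    X <- cbind(X[keep, , drop = FALSE], extra_features[keep, , drop = FALSE])
  }
  if (retrain) {
    if (is.null(sheet)) cs_stop("retrain = TRUE requires a labeled sheet",
                                class = "chemosig_state_error")
    cls <- sheet$response[match(rownames(X), sheet$patient_id)]
    if (anyNA(cls)) cs_stop("unlabeled sample(s): %s",
                            paste(rownames(X)[is.na(cls)], collapse = ", "),
                            class = "chemosig_join_error")
    n <- nrow(X)
    pred <- character(n); score <- numeric(n)
    for (i in seq_len(n)) {
      m <- train_linear_svm(X[-i, , drop = FALSE], cls[-i], cost = cost)
      score[i] <- decision_score(m, X[i, , drop = FALSE])
      pred[i] <- if (score[i] > 0) "NR" else "CCR"
    }
    final <- train_linear_svm(X, cls, cost = cost)
    final$platform <- "tlda"
    cv <- list(samples = data.frame(sample = rownames(X), true = cls,
                                    predicted = pred, score = score,
                                    stringsAsFactors = FALSE),
               accuracy = mean(pred == cls))
    list(predictions = cv$samples, model = final, cv = cv)
  } else {
    if (!identical(model$platform, "tlda")) {
      cs_stop("retrain = FALSE requires a model previously fitted on the qRT-PCR scale",
              class = "chemosig_state_error")
    }
    s <- decision_score(model, X)
    preds <- data.frame(sample = rownames(X),
                        predicted = ifelse(s > 0, "NR", "CCR"),
                        score = s, stringsAsFactors = FALSE)
    if (!is.null(sheet)) {
      preds$true <- sheet$response[match(preds$sample, sheet$patient_id)]
    }
    list(predictions = preds, model = model, cv = NULL)
  }
}
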