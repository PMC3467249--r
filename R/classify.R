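# Leave-one-out cross-validation with per-fold feature re-selection, final
# signature derivation, covariate augmentation, and the clinical-covariate
# discriminant baseline. The LOOCV contract is leakage-free: differential
# expression and the six-criterion filter are recomputed on the n-1 training
# samples of every fold, so nothing from the held-out sample informs either
# gene selection or the SVM fit.

# complete-case feature matrix (samples x genes) from an expression matrix
.complete_feature_matrix <- function(expr) {
  M <- expr$M
  keep <- rowSums(is.na(M)) == 0
  t(M[keep, , drop = FALSE])
}

#' Leave-one-out cross-validation with per-fold gene re-selection
#'
#' For each fold: recompute [run_diffexp()] + [apply_selection_criteria()] on
#' the training samples only, train a linear SVM on the fold-selected genes,
#' score the held-out sample. A fold selecting zero genes falls back to the
#' top `fallback_k` genes by |moderated t| (logged).
#'
#' @param expr An `expression_matrix` (genes with missing values are excluded
#'   from classification, not from DE reporting).
#' @param sheet A `sample_sheet`.
#' @param thr A [filter_thresholds()].
#' @param cost SVM cost.
#' @param fallback_k Fallback signature size for empty-selection folds.
#' @param extra_features Optional sample x covariate matrix appended to every
#'   fold's feature matrix (see [augment_with_covariates()]).
#' @return A `cv_report`: per-sample truth/prediction/score, per-gene
#'   selection frequency, per-fold gene lists and standardized weights.
#' @export
loocv_with_reselection <- function(expr, sheet, thr = filter_thresholds(),
                                   cost = 1.0, fallback_k = 10L,
                                   extra_features = NULL) {
  X_all <- .complete_feature_matrix(expr)
  samples <- rownames(X_all)
  cls <- sheet$response[match(samples, sheet$patient_id)]
  if (min(table(cls)) < 3L) cs_stop("need >= 3 samples per class for LOOCV",
                                    class = "chemosig_domain_error")
  n <- length(samples)
  pred <- character(n); score <- numeric(n)
  fold_genes <- vector("list", n)
  fold_weights <- vector("list", n)
  for (i in seq_len(n)) {
    train <- samples[-i]
    sub <- new_expression_matrix(expr$M[, train, drop = FALSE],
                                 if (!is.null(expr$A)) expr$A[, train, drop = FALSE])
    # recompute the cross-sample mean intensity on training samples only,
    # so the held-out sample cannot influence the A > a_min criterion
    sub$a_mean <- if (!is.null(sub$A)) rowMeans(sub$A, na.rm = TRUE)
                  else expr$a_mean
    de <- run_diffexp(sub, sheet)
    sel <- apply_selection_criteria(de, thr)$selected
    sel <- intersect(sel, colnames(X_all))
    if (length(sel) == 0L) {
      cs_log(sprintf("fold %s: empty selection, falling back to top %d by |t|",
                     samples[i], fallback_k))
      de_ok <- de[de$gene %in% colnames(X_all) & !is.na(de$t_mod), ]
      sel <- de_ok$gene[order(-abs(de_ok$t_mod))][seq_len(min(fallback_k,
                                                              nrow(de_ok)))]
    }
    Xtr <- X_all[train, sel, drop = FALSE]
    Xte <- X_all[i, sel, drop = FALSE]
    if (!is.null(extra_features)) {
      Xtr <- cbind(Xtr, extra_features[train, , drop = FALSE])
      Xte <- cbind(Xte, extra_features[samples[i], , drop = FALSE])
    }
    model <- train_linear_svm(Xtr, cls[-i], cost = cost)
    score[i] <- decision_score(model, Xte)
    pred[i] <- if (score[i] > 0) "NR" else "CCR"
    fold_genes[[i]] <- sel
    fold_weights[[i]] <- model$weights[sel]
  }
  all_sel <- unlist(fold_genes)
  freq <- table(factor(all_sel, levels = sort(unique(all_sel)))) / n
  structure(list(
    samples = data.frame(sample = samples, true = cls, predicted = pred,
                         score = score, stringsAsFactors = FALSE),
    selection_frequency = stats::setNames(as.numeric(freq), names(freq)),
    fold_genes = stats::setNames(fold_genes, samples),
    fold_weights = stats::setNames(fold_weights, samples),
    accuracy = mean(pred == cls)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d folds, accuracy %.1f%%, %d genes ever selected>\n",
              nrow(x$samples), 100 * x$accuracy,
              length(x$selection_frequency)))
  invisible(x)
}

#' Derive the final gene signature from a cross-validation report
#'
#' Genes are ranked by cross-fold selection frequency, then by mean absolute
#' standardized SVM weight across the folds that selected them; ties at the
#' k-th rank break lexicographically by gene ID (logged). The final model is
#' trained on all samples restricted to the top-k genes. An explicit
#' `override` gene list bypasses the ranking (used to reproduce a published
#' panel on real data).
#'
#' @param report A `cv_report` (ignored when `override` is given).
#' @param expr An `expression_matrix`.
#' @param sheet A `sample_sheet`.
#' @param k Signature size (default 10).
#' @param cost SVM cost.
#' @param override Optional explicit gene list.
#' @return A `signature_model` with `provenance` (selection ranking, k, seed
#'   inputs) attached.
#' @export
derive_final_signature <- function(report, expr, sheet, k = 10L, cost = 1.0,
                                   override = NULL) {
  X_all <- .complete_feature_matrix(expr)
  if (!is.null(override)) {
    missing <- setdiff(override, colnames(X_all))
    if (length(missing)) cs_stop("override gene(s) not available: %s",
                                 paste(missing, collapse = ", "),
                                 class = "chemosig_key_error")
    genes <- override
  } else {
    freq <- report$selection_frequency
    if (k > length(freq)) {
      cs_stop("k = %d exceeds the %d genes ever selected", k, length(freq),
              class = "chemosig_size_error")
    }
    wmag <- sapply(names(freq), function(g) {
      w <- unlist(lapply(report$fold_weights, function(fw) fw[g]))
      mean(abs(w), na.rm = TRUE)
    })
    ord <- order(-freq, -wmag, names(freq))
    genes <- names(freq)[ord][seq_len(k)]
    kth <- names(freq)[ord][k]
    tied <- setdiff(names(freq)[freq == freq[kth] & abs(wmag - wmag[kth]) < 1e-12],
                    genes)
    if (length(tied)) cs_log(sprintf(
      "tie at rank %d broken lexicographically (%s kept over %s)", k, kth,
      paste(tied, collapse = ", ")))
  }
  cls <- sheet$response[match(rownames(X_all), sheet$patient_id)]
  model <- train_linear_svm(X_all[, genes, drop = FALSE], cls, cost = cost)
  model$provenance <- list(k = k, override = !is.null(override),
                           config_hash = cs_config_hash(list(genes, cost)))
  model
}

#' Append clinical covariates to a feature matrix
#'
#' Binary covariates become 0/1 columns (HPV positive = 1); samples whose
#' covariate is unknown are dropped (and their count logged), mirroring
#' cohorts where a status cannot be ascertained for some individuals.
#'
#' @param X Sample x gene matrix (rownames = patient IDs).
#' @param sheet A `sample_sheet`.
#' @param covariates Character vector of sheet column names. `"hpv"` has a
#'   built-in 0/1 encoding; other columns must already be numeric.
#' @return List: `X` (augmented, possibly fewer rows), `dropped` (IDs).
#' @export
augment_with_covariates <- function(X, sheet, covariates) {
  X <- as.matrix(X)
  if (length(covariates) == 0L) return(list(X = X, dropped = character()))
  missing <- setdiff(covariates, names(sheet))
  if (length(missing)) cs_stop("covariate(s) not in sheet: %s",
                               paste(missing, collapse = ", "),
                               class = "chemosig_key_error")
  idx <- match(rownames(X), sheet$patient_id)
  add <- matrix(NA_real_, nrow(X), length(covariates),
                dimnames = list(rownames(X), covariates))
  for (cv in covariates) {
    v <- sheet[[cv]][idx]
    if (cv == "hpv") {
      add[, cv] <- ifelse(v == "positive", 1,
                          ifelse(v == "negative", 0, NA_real_))
    } else if (is.numeric(v)) {
      add[, cv] <- v
    } else {
      cs_stop("covariate %s is non-binary/non-numeric and has no encoding", cv,
              class = "chemosig_encoding_error")
    }
  }
  keep <- rowSums(is.na(add)) == 0
  if (any(!keep)) cs_log(sprintf("%d sample(s) dropped for unknown covariate: %s",
                                 sum(!keep),
                                 paste(rownames(X)[!keep], collapse = ", ")))
  list(X = cbind(X[keep, , drop = FALSE], add[keep, , drop = FALSE]),
       dropped = rownames(X)[!keep])
}

# Fisher linear discriminant with pooled covariance; ridge jitter on
# singularity. Returns a scoring closure.
.fisher_lda <- function(X, y) {
  pos <- X[y == "NR", , drop = FALSE]
  neg <- X[y == "CCR", , drop = FALSE]
  mu1 <- colMeans(pos); mu0 <- colMeans(neg)
  S <- ((nrow(pos) - 1) * stats::cov(pos) + (nrow(neg) - 1) * stats::cov(neg)) /
    (nrow(pos) + nrow(neg) - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
    cs_log("singular pooled covariance: adding ridge 1e-6")
    solve(S + diag(1e-6, ncol(S)), mu1 - mu0)
  })
  # threshold at the midpoint of projected class means, equal priors
  thresh <- sum(w * (mu1 + mu0)) / 2
  function(newX) drop(as.matrix(newX) %*% w) - thresh
}

#' Clinical-covariate discriminant baseline
#'
#' Leave-one-out accuracy of a Fisher linear discriminant on clinical
#' covariates only (default: age, cigarettes/day, alcohol, hemoglobin),
#' the no-expression baseline the signature has to beat.
#'
#' @param sheet A `sample_sheet` with numeric covariate columns.
#' @param covariates Covariate columns to use.
#' @return List: `accuracy`, per-sample `predictions` data frame.
#' @export
covariate_baseline <- function(sheet,
                               covariates = c("age", "cigarettes_per_day",
                                              "alcohol_l_per_day",
                                              "hemoglobin")) {
  missing <- setdiff(covariates, names(sheet))
  if (length(missing)) cs_stop("covariate(s) missing from sheet: %s",
                               paste(missing, collapse = ", "),
                               class = "chemosig_key_error")
  X <- as.matrix(sheet[, covariates])
  if (anyNA(X)) cs_stop("missing covariate values",
                        class = "chemosig_domain_error")
  y <- sheet$response
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    scorer <- .fisher_lda(X[-i, , drop = FALSE], y[-i])
    pred[i] <- if (scorer(X[i, , drop = FALSE]) > 0) "NR" else "CCR"
  }
  list(accuracy = mean(pred == y),
       predictions = data.frame(sample = sheet$patient_id, true = y,
                                predicted = pred, stringsAsFactors = FALSE))
}
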