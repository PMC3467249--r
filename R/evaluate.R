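# Evaluation machinery: confusion-matrix rates with non-responder (NR) as
# the positive condition, ROC/AUC via midranks, metric multidimensional
# scaling by SMACOF majorization with Kruskal stress-1, the two-sided Fisher
# exact test (probability-mass rule), and two-group cohort comparisons
# (Welch t, pooled t, Mann-Whitney with midranks and tie correction).

#' Confusion-matrix summary (positive class = NR)
#'
#' All eight rates are percentages; a rate whose denominator is zero is
#' reported as `NA`, never as 0.
#'
#' @param truth,predicted Equal-length vectors over \{"NR", "CCR"\}; or pass
#'   counts directly via `tp`, `fn`, `tn`, `fp`.
#' @param tp,fn,tn,fp Optional explicit counts (override the vectors).
#' @return A `confusion_summary` list: tp, fn, tn, fp, sensitivity,
#'   specificity, ppv, npv, fpr, fnr, accuracy, fdr.
#' @export
confusion_metrics <- function(truth = NULL, predicted = NULL,
                              tp = NULL, fn = NULL, tn = NULL, fp = NULL) {
  if (is.null(tp)) {
    if (length(truth) == 0L || length(truth) != length(predicted)) {
      cs_stop("truth and predicted must be non-empty and equal length",
              class = "chemosig_domain_error")
    }
    stopifnot(all(truth %in% c("NR", "CCR")), all(predicted %in% c("NR", "CCR")))
    tp <- sum(truth == "NR" & predicted == "NR")
    fn <- sum(truth == "NR" & predicted == "CCR")
    tn <- sum(truth == "CCR" & predicted == "CCR")
    fp <- sum(truth == "CCR" & predicted == "NR")
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn),
    fpr = pct(fp, fp + tn),
    fnr = pct(fn, fn + tp),
    accuracy = pct(tp + tn, tp + tn + fp + fn),
    fdr = pct(fp, tp + fp)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "True condition = Non-responder\n",
    "  tp %d  fn %d  tn %d  fp %d\n",
    "  sensitivity %.1f%%  specificity %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
    "  FPR %.1f%%  FNR %.1f%%  accuracy %.1f%%  FDR %.1f%%\n"),
    x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity, x$ppv, x$npv,
    x$fpr, x$fnr, x$accuracy, x$fdr))
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' AUC is computed from midranks, i.e. it equals the Mann-Whitney U statistic
#' normalized by `n_pos * n_neg` (the probability that a random positive
#' outscores a random negative, ties counting one half).
#'
#' @param scores Numeric decision scores (higher = more NR-like).
#' @param truth Class vector over \{"NR", "CCR"\}; NR is positive.
#' @return List: `auc`, `roc` (data frame threshold/fpr/tpr).
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == "NR"
  if (!any(pos) || all(pos)) cs_stop("both classes must be present",
                                     class = "chemosig_domain_error")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC degenerate at 0.5")
    auc <- 0.5
  } else {
    r <- rank(scores)                          # midranks
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(threshold = thr,
                    fpr = vapply(thr, function(t) mean(scores[!pos] >= t),
                                 numeric(1)),
                    tpr = vapply(thr, function(t) mean(scores[pos] >= t),
                                 numeric(1)))
  list(auc = auc, roc = roc)
}

#' Metric multidimensional scaling by SMACOF majorization
#'
#' Euclidean distances between samples are embedded in `dims` dimensions.
#' Starts from the classical-scaling (principal coordinates) configuration
#' and iterates the Guttman transform until the drop in normalized stress is
#' below `tol` or `max_iter` iterations. Per-iteration stress (reported in
#' `trace`) is normalized by the fixed input dissimilarities, so majorization
#' guarantees it is non-increasing; the final `stress` field is Kruskal
#' stress-1, `sqrt(sum((delta - d)^2) / sum(d^2))` with `d` the configuration
#' distances.
#'
#' @param X Sample x feature matrix (distances on rows), or a `dist` object.
#' @param dims Embedding dimension (default 3).
#' @param max_iter,tol Iteration controls.
#' @return An `embedding_result`: `coordinates` (sample x dims), `stress`
#'   (Kruskal stress-1), `variance_fraction` (share of positive classical-
#'   scaling eigenvalue mass in the first `dims` components), `trace`
#'   (normalized stress per iteration), `n_iter`.
#' @export
mds_smacof <- function(X, dims = 3L, max_iter = 300L, tol = 1e-6) {
  D <- if (inherits(X, "dist")) X else stats::dist(as.matrix(X))
  n <- attr(D, "Size")
  if (dims >= n) cs_stop("dims (%d) must be < number of samples (%d)", dims, n,
                         class = "chemosig_dimension_error")
  delta <- as.matrix(D)
  labels <- rownames(delta) %||% paste0("s", seq_len(n))
  # classical scaling start + eigenvalue variance fractions
  cmd <- stats::cmdscale(D, k = min(n - 1L, max(dims, 2L)), eig = TRUE)
  eig_pos <- pmax(cmd$eig, 0)
  variance_fraction <- if (sum(eig_pos) > 0) {
    sum(eig_pos[seq_len(min(dims, length(eig_pos)))]) / sum(eig_pos)
  } else NA_real_
  Z <- cmd$points[, seq_len(dims), drop = FALSE]
  if (ncol(Z) < dims) {  # degenerate rank: pad with zeros
    Z <- cbind(Z, matrix(0, n, dims - ncol(Z)))
  }
  eta2 <- sum(delta ^ 2) / 2                       # sum over i<j
  cfg_dist <- function(Z) as.matrix(stats::dist(Z))
  raw_stress <- function(d) sum((delta - d) ^ 2) / 2
  d <- cfg_dist(Z)
  s_norm <- sqrt(raw_stress(d) / eta2)
  trace <- s_norm
  for (it in seq_len(max_iter)) {
    B <- ifelse(d > 0, -delta / d, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Z <- B %*% Z / n                               # Guttman transform
    d <- cfg_dist(Z)
    s_new <- sqrt(raw_stress(d) / eta2)
    trace <- c(trace, s_new)
    if (s_norm - s_new < tol) { s_norm <- s_new; break }
    s_norm <- s_new
  }
  dsum <- sum(d ^ 2) / 2
  stress1 <- if (dsum > 0) sqrt(raw_stress(d) / dsum) else 0
  rownames(Z) <- labels
  structure(list(coordinates = Z, stress = stress1,
                 variance_fraction = variance_fraction,
                 trace = trace, n_iter = length(trace) - 1L),
            class = "embedding_result")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass rule: the p-value sums the hypergeometric probabilities,
#' over all tables with the observed margins, of every table whose
#' probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  tb <- as.matrix(table)
  stopifnot(identical(dim(tb), c(2L, 2L)), all(tb >= 0), all(tb == round(tb)))
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    warning("zero margin: p = 1")
    return(1)
  }
  m <- sum(tb[1, ])          # row-1 total ~ white balls
  n_ <- sum(tb[2, ])         # row-2 total
  k <- sum(tb[, 1])          # column-1 total drawn
  x <- tb[1, 1]
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  obs <- stats::dhyper(x, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Two-group comparison of a continuous or ordinal covariate
#'
#' `welch_t`: unequal-variance t with Welch-Satterthwaite df (the default
#' for continuous covariates); `pooled_t`: equal-variance two-sample t;
#' `mann_whitney`: midrank U with normal approximation and tie correction,
#' no continuity correction (the convention for ordinal/skewed covariates).
#'
#' @param x,y Numeric vectors (the two groups), >= 2 values each.
#' @param method One of "welch_t", "pooled_t", "mann_whitney".
#' @return Two-sided p-value; for `mann_whitney`, attribute `U` carries the
#'   midrank U statistic of the first group.
#' @export
group_compare <- function(x, y, method = c("welch_t", "pooled_t",
                                           "mann_whitney")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) cs_stop("need >= 2 values per group",
                                              class = "chemosig_domain_error")
  n1 <- length(x); n2 <- length(y)
  if (method == "mann_whitney") {
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    N <- n1 + n2
    ties <- table(c(x, y))
    tie_corr <- sum(ties ^ 3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * (N + 1 - tie_corr)
    if (v <= 0) return(structure(1, U = U))
    z <- (U - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    return(structure(min(p, 1), U = U))
  }
  d <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) return(1)
    warning("zero variance in both groups with unequal means: p = 0")
    return(0)
  }
  if (method == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2 ^ 2 / ((v1 / n1) ^ 2 / (n1 - 1) + (v2 / n2) ^ 2 / (n2 - 1))
    tstat <- d / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    tstat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
}

#' Exact/Monte-Carlo independence test for an r x 2 contingency table
#'
#' Generalizes the probability-mass Fisher rule to r x 2 tables (ordinal
#' covariates binned into categories). Exact enumeration over fixed-margin
#' tables when the total count is <= `exact_limit`; otherwise a seeded
#' Monte-Carlo estimate (`r2dtable`).
#'
#' @param table r x 2 matrix of counts.
#' @param exact_limit Largest total for exact enumeration (default 50).
#' @param n_mc Monte-Carlo tables when beyond the limit.
#' @param seed Seed for the Monte-Carlo path.
#' @return Two-sided p-value.
#' @export
fisher_rx2 <- function(table, exact_limit = 50L, n_mc = 20000L, seed = 1L) {
  tb <- as.matrix(table)
  stopifnot(ncol(tb) == 2L, all(tb >= 0), all(tb == round(tb)))
  rs <- rowSums(tb); cs <- colSums(tb); N <- sum(tb)
  if (any(rs == 0) || any(cs == 0)) { warning("zero margin: p = 1"); return(1) }
  log_prob <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1) -
      sum(lgamma(m + 1))
  }
  obs <- log_prob(tb)
  if (N <= exact_limit) {
    # enumerate first-column entries per row subject to the column margin
    total <- 0; hit <- 0
    rec <- function(i, remaining, acc) {
      if (i == length(rs)) {
        if (remaining >= 0 && remaining <= rs[i]) {
          m <- cbind(c(acc, remaining), rs - c(acc, remaining))
          lp <- log_prob(m)
          total <<- total + exp(lp)
          if (lp <= obs + 1e-10) hit <<- hit + exp(lp)
        }
        return(invisible())
      }
      for (v in 0:min(rs[i], remaining)) rec(i + 1L, remaining - v, c(acc, v))
    }
    rec(1L, cs[1], integer())
    return(hit / total)
  }
  set.seed(seed)
  sims <- stats::r2dtable(n_mc, rs, cs)
  mean(vapply(sims, log_prob, numeric(1)) <= obs + 1e-10)
}
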