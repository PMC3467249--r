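# Differential expression between non-responders (NR) and complete clinical
# responders (CCR): per-class summaries of M = log2(sample/reference), a
# moderated two-sample t-statistic with empirical-Bayes variance shrinkage
# (per-gene pooled variance shrunk toward a scaled inverse-chi-square prior
# whose hyperparameters d0, s0^2 are moment-matched on log s^2 across genes),
# Benjamini-Hochberg adjustment, and the signed fold-change convention
# (ratio r >= 1 reported as +r, r < 1 as -1/r, oriented NR over responder).

#' Signed fold change from a difference of log2 group means
#'
#' @param dlog2 `m_nr - m_ccr`, log2 units.
#' @return `+2^dlog2` when the ratio is >= 1, `-2^-dlog2` otherwise, so
#'   `|fc| >= 1` always and the sign matches `sign(m_nr - m_ccr)`.
#' @export
signed_fold_change <- function(dlog2) {
  ifelse(dlog2 >= 0, 2 ^ dlog2, -(2 ^ (-dlog2)))
}

#' Per-gene group summaries
#'
#' Means and SDs of M per class on available (non-missing) values, the mean
#' intensity A, and the signed fold change NR/CCR.
#'
#' @param expr An `expression_matrix` (or list with `M` and optional `a_mean`).
#' @param sheet A `sample_sheet` with `patient_id` and `response`.
#' @return Data frame: gene, m_nr, m_ccr, s_nr, s_ccr, n_nr, n_ccr, a_mean,
#'   fc_signed. Genes with < 2 non-missing values in a class carry `NA`
#'   summaries for that class.
#' @export
summarize_groups <- function(expr, sheet) {
  M <- expr$M
  samples <- colnames(M)
  cls <- sheet$response[match(samples, sheet$patient_id)]
  if (anyNA(cls)) cs_stop("samples missing from sheet: %s",
                          paste(samples[is.na(cls)], collapse = ", "),
                          class = "chemosig_join_error")
  for (lv in c("NR", "CCR")) {
    if (sum(cls == lv) < 2) cs_stop("need >= 2 samples per class, %s has %d",
                                    lv, sum(cls == lv),
                                    class = "chemosig_domain_error")
  }
  stat <- function(sub, f) apply(sub, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else f(v)
  })
  nr <- M[, cls == "NR", drop = FALSE]
  ccr <- M[, cls == "CCR", drop = FALSE]
  out <- data.frame(
    gene = rownames(M),
    m_nr = stat(nr, mean), m_ccr = stat(ccr, mean),
    s_nr = stat(nr, stats::sd), s_ccr = stat(ccr, stats::sd),
    n_nr = rowSums(!is.na(nr)), n_ccr = rowSums(!is.na(ccr)),
    a_mean = if (!is.null(expr$a_mean)) expr$a_mean[rownames(M)] else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  out$fc_signed <- signed_fold_change(out$m_nr - out$m_ccr)
  out
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (it in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate the variance-shrinkage prior (d0, s0^2)
#'
#' Moment-matching of log pooled variances to a scaled inverse-chi-square
#' prior: with z = log s^2 and residual df d, E(z) and Var(z) follow
#' digamma/trigamma identities; Var(z) in excess of trigamma(d/2) identifies
#' the prior df d0, then the mean identifies s0^2.
#'
#' @param s2 Per-gene pooled variances (positive; zeros dropped with warning).
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0
  if (sum(keep) < 10L) {
    warning("fewer than 10 usable variances: no shrinkage (d0 = 0)")
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  s2 <- s2[keep]
  df <- rep_len(df, length(s2))[keep] ## tolerate per-gene df
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e)
  excess <- evar - mean(trigamma(df / 2))
  if (excess <= 0) {
    # variances more concentrated than chi-square sampling alone: infinite
    # prior df, all shrunk to the common value
    s0_sq <- exp(ebar)
    return(list(d0 = Inf, s0_sq = s0_sq))
  }
  d0 <- 2 * .trigamma_inverse(excess)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-test
#'
#' Pooled equal-variance per-gene variances are shrunk toward the prior:
#' `s_tilde^2 = (d0*s0^2 + d*s^2) / (d0 + d)`;
#' `t = (m_nr - m_ccr) / (s_tilde * sqrt(1/n_nr + 1/n_ccr))` with
#' `d0 + d` degrees of freedom. `d0 = 0` (forced or estimated) reduces to
#' the ordinary pooled t-test; `d0 = Inf` fixes every variance at `s0^2`.
#'
#' @param summaries Output of [summarize_groups()].
#' @param d0,s0_sq Optional forced hyperparameters; estimated from the data
#'   via [estimate_variance_prior()] when `NULL`.
#' @return `summaries` with columns s2_pooled, s2_shrunk, t_mod, df_total, p
#'   appended, and attributes `d0`, `s0_sq`.
#' @export
moderated_t_test <- function(summaries, d0 = NULL, s0_sq = NULL) {
  n1 <- summaries$n_nr; n2 <- summaries$n_ccr
  d <- n1 + n2 - 2
  ok <- !is.na(summaries$s_nr) & !is.na(summaries$s_ccr) & d >= 1
  s2 <- ((n1 - 1) * summaries$s_nr ^ 2 + (n2 - 1) * summaries$s_ccr ^ 2) / d
  s2[!ok] <- NA_real_
  if (is.null(d0)) {
    pri <- estimate_variance_prior(s2[ok], d[ok])
    d0 <- pri$d0; s0_sq <- pri$s0_sq
  } else if (is.null(s0_sq) && d0 > 0) {
    cs_stop("s0_sq must accompany a forced d0 > 0",
            class = "chemosig_parameter_error")
  }
  if (d0 == 0) {
    s2_shrunk <- s2
  } else if (is.infinite(d0)) {
    s2_shrunk <- ifelse(is.na(s2), NA_real_, s0_sq)
  } else {
    s2_shrunk <- (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  diff <- summaries$m_nr - summaries$m_ccr
  t_mod <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  df_total <- if (is.infinite(d0)) rep(Inf, length(d)) else d + d0
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[which(t_mod == 0)] <- 1
  out <- summaries
  out$s2_pooled <- s2
  out$s2_shrunk <- s2_shrunk
  out$t_mod <- t_mod
  out$df_total <- df_total
  out$p <- p
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    cs_stop("p-values outside [0, 1]", class = "chemosig_domain_error")
  }
  m <- sum(!is.na(p))
  q <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  o <- idx[order(p[idx], decreasing = TRUE)]
  q[o] <- pmin(1, cummin(m / (m:1) * p[o]))
  q
}

#' Permutation-null p-values for the moderated t
#'
#' Gene-wise two-sided p-values from the pooled permutation distribution of
#' the moderated t-statistic under class-label permutation (hyperparameters
#' re-estimated per permutation), as an alternative to the parametric tail.
#'
#' @param expr An `expression_matrix`.
#' @param sheet A `sample_sheet`.
#' @param n_perm Number of label permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @return The [moderated_t_test()] table with `p` replaced by permutation
#'   p-values (attribute `p_parametric` keeps the parametric ones).
#' @export
permutation_p_values <- function(expr, sheet, n_perm = 1000L, seed = 1L) {
  base <- moderated_t_test(summarize_groups(expr, sheet))
  obs <- abs(base$t_mod)
  set.seed(seed)
  exceed <- numeric(length(obs))
  total <- 0L
  sheet_p <- sheet
  for (b in seq_len(n_perm)) {
    sheet_p$response <- sample(sheet$response)
    tb <- moderated_t_test(summarize_groups(expr, sheet_p))$t_mod
    tb <- abs(tb[is.finite(tb)])
    # pooled null across genes
    exceed <- exceed + vapply(obs, function(o) sum(tb >= o), numeric(1))
    total <- total + length(tb)
  }
  out <- base
  attr(out, "p_parametric") <- base$p
  out$p <- (exceed + 1) / (total + 1)
  out
}

#' Full differential-expression table
#'
#' [summarize_groups()] + [moderated_t_test()] + [bh_adjust()].
#'
#' @param expr An `expression_matrix`.
#' @param sheet A `sample_sheet`.
#' @param d0,s0_sq Optional forced shrinkage hyperparameters.
#' @return A `de_result` data frame with column `q` appended.
#' @export
run_diffexp <- function(expr, sheet, d0 = NULL, s0_sq = NULL) {
  out <- moderated_t_test(summarize_groups(expr, sheet), d0 = d0, s0_sq = s0_sq)
  out$q <- bh_adjust(out$p)
  class(out) <- c("de_result", "data.frame")
  out
}
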