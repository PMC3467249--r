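# The six-criterion composite gene-selection filter. A gene is called
# differentially expressed between non-responders and responders only if ALL
# of the following strict inequalities hold:
#   1. adjusted p < 0.025
#   2. |signed fold change| > 1.3  (evaluated on the log2 scale)
#   3. mean intensity A > 7
#   4. max(|m_nr|, |m_ccr|) > 0.4      (at least one group clearly off zero)
#   5. min(s_nr, s_ccr) < 0.5          (at least one group tight)
#   6. separation score |m_nr - m_ccr| - (s_nr + s_ccr) > -0.55
#      ("minimal recovery", i.e. limited overlap, between the groups)

#' Filter thresholds
#'
#' Defaults are the published selection thresholds.
#'
#' @param p_max Adjusted-p threshold (default 0.025).
#' @param fc_min Absolute fold-change threshold (default 1.3).
#' @param a_min Mean-intensity threshold, log2 units (default 7).
#' @param mean_min Group-mean threshold, log2 units (default 0.4).
#' @param sd_max Group-SD threshold, log2 units (default 0.5).
#' @param sep_min Separation-score threshold (default -0.55).
#' @param use_raw_p Apply criterion 1 to raw p instead of adjusted p.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(p_max = 0.025, fc_min = 1.3, a_min = 7,
                              mean_min = 0.4, sd_max = 0.5, sep_min = -0.55,
                              use_raw_p = FALSE) {
  thr <- list(p_max = p_max, fc_min = fc_min, a_min = a_min,
              mean_min = mean_min, sd_max = sd_max, sep_min = sep_min,
              use_raw_p = isTRUE(use_raw_p))
  stopifnot(vapply(thr[1:6], function(v) is.finite(v), logical(1)))
  structure(thr, class = "filter_thresholds")
}

#' Group-separation score
#'
#' `|m_nr - m_ccr| - (s_nr + s_ccr)`: positive when the group means are more
#' than one summed SD apart (no overlap of the 1-SD bands), negative when the
#' bands overlap ("recovery" between the groups).
#'
#' @param m_nr,m_ccr Group means of log2(sample/reference).
#' @param s_nr,s_ccr Group SDs (>= 0).
#' @return The score, same shape as the inputs.
#' @export
separation_score <- function(m_nr, m_ccr, s_nr, s_ccr) {
  if (any(s_nr < 0 | s_ccr < 0, na.rm = TRUE)) {
    cs_stop("standard deviations must be >= 0", class = "chemosig_domain_error")
  }
  abs(m_nr - m_ccr) - (s_nr + s_ccr)
}

#' Apply the six selection criteria
#'
#' All six strict inequalities must hold. The fold-change criterion is
#' evaluated on the log2 scale (`|m_nr - m_ccr| > log2(fc_min)`), equivalent
#' to `|fc_signed| > fc_min` under the signed convention. Genes with missing
#' summaries are skipped and logged, never passed.
#'
#' @param de A `de_result` from [run_diffexp()].
#' @param thr A [filter_thresholds()].
#' @return List with `selected` (character vector of gene IDs, in `de` order)
#'   and `audit` (gene x criterion logical table, columns p, fc, a, mean, sd,
#'   sep, pass).
#' @export
apply_selection_criteria <- function(de, thr = filter_thresholds()) {
  pval <- if (thr$use_raw_p) de$p else de$q
  dlog2 <- de$m_nr - de$m_ccr
  sep <- separation_score(de$m_nr, de$m_ccr, de$s_nr, de$s_ccr)
  audit <- data.frame(
    gene = de$gene,
    p    = pval < thr$p_max,
    fc   = abs(dlog2) > log2(thr$fc_min),
    a    = de$a_mean > thr$a_min,
    mean = pmax(abs(de$m_nr), abs(de$m_ccr)) > thr$mean_min,
    sd   = pmin(de$s_nr, de$s_ccr) < thr$sd_max,
    sep  = sep > thr$sep_min,
    stringsAsFactors = FALSE)
  complete <- stats::complete.cases(audit[, -1])
  if (any(!complete)) {
    cs_log(sprintf("filter: %d gene(s) with missing summaries skipped",
                   sum(!complete)), level = 2L)
  }
  audit$pass <- complete &
    audit$p & audit$fc & audit$a & audit$mean & audit$sd & audit$sep
  audit$pass[is.na(audit$pass)] <- FALSE
  list(selected = de$gene[audit$pass], audit = audit)
}
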