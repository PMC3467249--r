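# Shared fixture builders. Everything is generated in code; nothing binary.

cs_verbosity(0L)

# minimal spot table data frame
make_spots <- function(n = 100, n_flagged = 0, n_control = 0, seed = 1,
                       array_id = "A1", m_fun = function(A) rep(0, length(A))) {
  set.seed(seed)
  A <- runif(n, 6, 14)
  M <- m_fun(A)
  flag <- rep(0L, n)
  if (n_flagged > 0) flag[seq_len(n_flagged)] <- -100L
  ctrl <- rep(FALSE, n)
  if (n_control > 0) ctrl[n_flagged + seq_len(n_control)] <- TRUE
  df <- data.frame(probe_id = sprintf("p%04d", seq_len(n)),
                   gene_symbol = sprintf("g%04d", seq_len(n)),
                   cy5_fg = 2 ^ (A + M / 2), cy3_fg = 2 ^ (A - M / 2),
                   flag = flag, is_control = ctrl, stringsAsFactors = FALSE)
  chemosig:::new_spot_table(array_id, df)
}

# tiny labeled expression matrix: g genes x (n_nr + n_ccr) samples
make_expr <- function(g = 50, n_nr = 5, n_ccr = 6, delta_genes = NULL,
                      delta = 1, sigma = 0.3, seed = 1, a_mean = 10) {
  set.seed(seed)
  n <- n_nr + n_ccr
  ids <- sprintf("S%02d", seq_len(n))
  cls <- rep(c("NR", "CCR"), c(n_nr, n_ccr))
  M <- matrix(rnorm(g * n, 0, sigma), g, n,
              dimnames = list(sprintf("g%03d", seq_len(g)), ids))
  if (!is.null(delta_genes)) M[delta_genes, cls == "NR"] <-
    M[delta_genes, cls == "NR"] + delta
  expr <- chemosig:::new_expression_matrix(M)
  expr$a_mean <- setNames(rep(a_mean, g), rownames(M))
  sheet <- structure(data.frame(patient_id = ids, response = cls,
                                regimen = "PF", stringsAsFactors = FALSE),
                     class = c("sample_sheet", "data.frame"))
  list(expr = expr, sheet = sheet, cls = cls)
}

# random DEResult-shaped table for filter oracle tests
random_de <- function(m, seed = 1) {
  set.seed(seed)
  de <- data.frame(
    gene = sprintf("g%05d", seq_len(m)),
    m_nr = rnorm(m, 0, 0.8), m_ccr = rnorm(m, 0, 0.8),
    s_nr = runif(m, 0, 1), s_ccr = runif(m, 0, 1),
    a_mean = runif(m, 5, 12),
    p = runif(m), q = runif(m),
    stringsAsFactors = FALSE)
  de$fc_signed <- signed_fold_change(de$m_nr - de$m_ccr)
  de
}

# brute-force re-evaluation of the six inequalities, gene by gene
filter_oracle <- function(de, thr) {
  vapply(seq_len(nrow(de)), function(i) {
    with(de[i, ], {
      pv <- if (thr$use_raw_p) p else q
      isTRUE(pv < thr$p_max) &&
        isTRUE(abs(signed_fold_change(m_nr - m_ccr)) > thr$fc_min) &&
        isTRUE(a_mean > thr$a_min) &&
        isTRUE(max(abs(m_nr), abs(m_ccr)) > thr$mean_min) &&
        isTRUE(min(s_nr, s_ccr) < thr$sd_max) &&
        isTRUE(abs(m_nr - m_ccr) - (s_nr + s_ccr) > thr$sep_min)
    })
  }, logical(1))
}

cohort_sheet_path <- system.file("extdata", "pf_cohort_clinical.tsv",
                                 package = "chemosig")
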