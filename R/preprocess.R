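# Spot filtering and intra-array loess normalization. Two-channel arrays
# co-hybridize a Cy5-labeled tumor sample against a Cy3-labeled universal
# reference; expression is M = log2(Cy5/Cy3) with mean spot intensity
# A = log2(Cy5*Cy3)/2. Backgrounds are never subtracted. Normalization is
# intra-array only: the intensity-dependent dye bias is removed by
# subtracting a loess fit of M on A (degree 1, span 0.5 by default).

new_expression_matrix <- function(M, A = NULL) {
  stopifnot(is.matrix(M))
  if (!is.null(A)) stopifnot(identical(dim(M), dim(A)))
  structure(list(M = M, A = A,
                 genes = rownames(M), samples = colnames(M)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d samples, %d missing cells>\n",
              nrow(x$M), ncol(x$M), sum(is.na(x$M))))
  invisible(x)
}

#' Discard flagged and control spots
#'
#' Removes spots whose quality flag is non-zero (not found / bad / saturated)
#' and control probes, so that neither enters normalization statistics or the
#' expression matrix. No background subtraction is performed anywhere in the
#' pipeline.
#'
#' @param spots A `spot_table`.
#' @return A filtered `spot_table`; removal counts are logged and attached as
#'   attributes `n_flagged` and `n_control`.
#' @export
filter_spots <- function(spots) {
  df <- spots$spots
  flagged <- df$flag != 0L
  ctrl <- df$is_control & !flagged
  keep <- !flagged & !df$is_control
  if (!any(keep)) cs_stop("array %s: no analysable spots after filtering",
                          spots$array_id, class = "chemosig_empty_array_error")
  cs_log(sprintf("array %s: removed %d flagged + %d control spots, %d remain",
                 spots$array_id, sum(flagged), sum(ctrl), sum(keep)),
         level = 2L)
  out <- new_spot_table(spots$array_id, df[keep, , drop = FALSE])
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "n_control") <- sum(ctrl)
  out
}

# M/A from foreground intensities
spot_ma <- function(df) {
  list(M = log2(df$cy5_fg) - log2(df$cy3_fg),
       A = (log2(df$cy5_fg) + log2(df$cy3_fg)) / 2)
}

#' Intra-array loess normalization of log-ratios
#'
#' Fits a locally weighted linear regression of M on A (tricube weights,
#' `stats::loess`, degree 1) on non-control spots and subtracts the fitted
#' trend from all retained spots, removing the intensity-dependent dye bias.
#'
#' @param spots A `spot_table` (typically after [filter_spots()]).
#' @param span Loess span in (0, 1]; default 0.5.
#' @return A data frame with probe_id, gene_symbol, M (normalized), A.
#' @export
loess_normalize <- function(spots, span = 0.5) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    cs_stop("span must lie in (0, 1], got %s", format(span),
            class = "chemosig_parameter_error")
  }
  df <- spots$spots
  ma <- spot_ma(df)
  fit_idx <- which(!df$is_control & df$flag == 0L)
  if (length(fit_idx) < 50L) {
    cs_stop("array %s: %d unflagged non-control spots (< 50) - too few to fit",
            spots$array_id, length(fit_idx), class = "chemosig_parameter_error")
  }
  fd <- data.frame(M = ma$M[fit_idx], A = ma$A[fit_idx])
  if (stats::sd(fd$M) == 0) {
    # constant M is absorbed entirely by the trend
    trend <- rep(fd$M[1], length(ma$M))
  } else {
    # robust (Tukey-biweight) fitting so differential genes cannot drag the
    # dye-bias trend toward themselves; degenerate (exact-fit) data breaks
    # the robustness iterations, where a plain fit is identical anyway
    fit <- tryCatch(
      stats::loess(M ~ A, data = fd, span = span, degree = 1,
                   family = "symmetric"),
      error = function(e) stats::loess(M ~ A, data = fd, span = span,
                                       degree = 1, family = "gaussian"))
    trend <- stats::predict(fit, newdata = data.frame(A = ma$A))
  }
  data.frame(probe_id = df$probe_id, gene_symbol = df$gene_symbol,
             M = ma$M - trend, A = ma$A, stringsAsFactors = FALSE)
}

#' Assemble the gene x sample expression matrix
#'
#' Collapses replicate probes of a gene by the median of their normalized M
#' (and mean A); genes absent (all spots discarded) in a sample carry explicit
#' `NA`, never an imputed value.
#'
#' @param arrays Named list of normalized per-array data frames from
#'   [loess_normalize()]; names (or `array_id`s) must match `patient_id`s.
#' @param sheet A `sample_sheet`.
#' @return An `expression_matrix` with `M`, per-gene/sample `A`, and
#'   `a_mean` (per-gene cross-sample mean A) attached.
#' @export
build_expression_matrix <- function(arrays, sheet) {
  ids <- names(arrays)
  if (is.null(ids) || any(ids == "")) {
    cs_stop("arrays must be a named list keyed by patient_id",
            class = "chemosig_join_error")
  }
  missing <- setdiff(ids, sheet$patient_id)
  if (length(missing)) {
    cs_stop("array(s) without sample-sheet entry: %s",
            paste(missing, collapse = ", "), class = "chemosig_join_error")
  }
  genes <- sort(unique(unlist(lapply(arrays, function(a) a$gene_symbol))))
  M <- matrix(NA_real_, length(genes), length(ids),
              dimnames = list(genes, ids))
  A <- M
  for (s in ids) {
    a <- arrays[[s]]
    mm <- vapply(split(a$M, a$gene_symbol), stats::median, numeric(1))
    aa <- vapply(split(a$A, a$gene_symbol), mean, numeric(1))
    M[names(mm), s] <- mm
    A[names(aa), s] <- aa
  }
  out <- new_expression_matrix(M, A)
  out$a_mean <- rowMeans(A, na.rm = TRUE)
  out
}

#' One-call preprocessing of a set of spot tables
#'
#' [filter_spots()] then [loess_normalize()] per array, then
#' [build_expression_matrix()].
#'
#' @param spot_tables Named list of `spot_table`s keyed by patient_id.
#' @param sheet A `sample_sheet`.
#' @param span Loess span, default 0.5.
#' @return An `expression_matrix`.
#' @export
preprocess_arrays <- function(spot_tables, sheet, span = 0.5) {
  norm <- lapply(spot_tables, function(st) loess_normalize(filter_spots(st),
                                                           span = span))
  build_expression_matrix(norm, sheet)
}
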