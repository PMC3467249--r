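# Readers and writers for the on-disk formats the pipeline touches:
# GPR-like spot tables (TSV), long-format Ct tables (TSV), sample sheets
# (CSV/TSV) and gene x sample expression matrices (TSV). All plain text,
# UTF-8, "." decimal; every writer prepends a provenance comment line.

#' Default spot-table dialect
#'
#' Column names and flag vocabulary of a GenePix-style per-spot export.
#' Flags: 0 good, -50 not found, -75 bad, -100 saturated.
#'
#' @param probe,symbol,cy5,cy3,flag,control Column names in the file.
#' @param flag_good Value of `flag` marking an analysable spot.
#' @param flag_values Full flag vocabulary accepted by the reader.
#' @return A named list describing the dialect.
#' @export
spot_dialect <- function(probe = "ProbeID", symbol = "GeneSymbol",
                         cy5 = "F635", cy3 = "F532", flag = "Flags",
                         control = "ControlType",
                         flag_good = 0L,
                         flag_values = c(0L, -50L, -75L, -100L)) {
  list(probe = probe, symbol = symbol, cy5 = cy5, cy3 = cy3,
       flag = flag, control = control,
       flag_good = as.integer(flag_good),
       flag_values = as.integer(flag_values))
}

new_spot_table <- function(array_id, df) {
  stopifnot(all(c("probe_id", "gene_symbol", "cy5_fg", "cy3_fg",
                  "flag", "is_control") %in% names(df)))
  structure(list(array_id = array_id, spots = df),
            class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("<spot_table '%s': %d spots, %d flagged, %d control>\n",
              x$array_id, nrow(x$spots), sum(x$spots$flag != 0L),
              sum(x$spots$is_control)))
  invisible(x)
}

# skip "ATF"/block header lines that GPR exports carry before the column header
.find_header_line <- function(path, required) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "#")) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- gsub('^"|"$', "", fields)
    if (all(required %in% fields)) return(i)
  }
  NA_integer_
}

#' Read a per-array spot-level two-channel table
#'
#' Flags are preserved verbatim; nothing is filtered at read time.
#'
#' @param path Path to a tab-separated spot table.
#' @param dialect Column mapping, see [spot_dialect()].
#' @param array_id Array identifier; defaults to the file name sans extension.
#' @return A `spot_table` with columns probe_id, gene_symbol, cy5_fg, cy3_fg,
#'   flag, is_control. The number of spots read is logged.
#' @export
read_spot_table <- function(path, dialect = spot_dialect(),
                            array_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) cs_stop("spot table not found: %s", path,
                                  class = "chemosig_io_error")
  need <- c(dialect$probe, dialect$cy5, dialect$cy3, dialect$flag)
  hl <- .find_header_line(path, need)
  if (is.na(hl)) {
    # identify which required column is absent for the error message
    first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
    missing <- setdiff(need, gsub('^"|"$', "", first))
    cs_stop("spot table %s: missing column(s) %s", path,
            paste(missing, collapse = ", "), class = "chemosig_format_error")
  }
  df <- utils::read.delim(path, skip = hl - 1L, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (nrow(df) == 0L) {
    warning(sprintf("spot table %s has a header but no spots", path))
    empty <- data.frame(probe_id = character(), gene_symbol = character(),
                        cy5_fg = numeric(), cy3_fg = numeric(),
                        flag = integer(), is_control = logical())
    return(new_spot_table(array_id, empty))
  }
  for (col in c(dialect$cy5, dialect$cy3)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      cs_stop("spot table %s: non-numeric intensity in column %s at line %d",
              path, col, hl + bad[1], class = "chemosig_parse_error")
    }
    df[[col]] <- v
  }
  ctrl <- if (dialect$control %in% names(df)) {
    df[[dialect$control]] %in% c(1, "1", TRUE, "TRUE", "control", "Control")
  } else rep(FALSE, nrow(df))
  sym <- if (dialect$symbol %in% names(df)) as.character(df[[dialect$symbol]])
         else as.character(df[[dialect$probe]])
  out <- data.frame(probe_id = as.character(df[[dialect$probe]]),
                    gene_symbol = sym,
                    cy5_fg = df[[dialect$cy5]],
                    cy3_fg = df[[dialect$cy3]],
                    flag = as.integer(df[[dialect$flag]]),
                    is_control = ctrl,
                    stringsAsFactors = FALSE)
  if (any(out$probe_id == "")) cs_stop("spot table %s: empty probe_id", path,
                                       class = "chemosig_format_error")
  unknown <- setdiff(unique(out$flag), dialect$flag_values)
  if (length(unknown)) {
    warning(sprintf("spot table %s: flag codes outside dialect: %s",
                    path, paste(unknown, collapse = ", ")))
  }
  ok <- out$flag == dialect$flag_good
  if (any(!is.finite(out$cy5_fg[ok])) || any(!is.finite(out$cy3_fg[ok])) ||
      any(out$cy5_fg[ok] <= 0) || any(out$cy3_fg[ok] <= 0)) {
    cs_stop("spot table %s: non-positive or non-finite intensity on unflagged spots",
            path, class = "chemosig_format_error")
  }
  cs_log(sprintf("read %d spots from %s", nrow(out), path), level = 2L)
  new_spot_table(array_id, out)
}

#' Write a spot table in the default dialect
#'
#' @param x A `spot_table`.
#' @param path Output path.
#' @param dialect Column mapping, see [spot_dialect()].
#' @param config_hash Provenance string for the header comment.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(x, path, dialect = spot_dialect(),
                             config_hash = "unversioned") {
  df <- data.frame(x$spots$probe_id, x$spots$gene_symbol,
                   x$spots$cy5_fg, x$spots$cy3_fg,
                   x$spots$flag, as.integer(x$spots$is_control))
  names(df) <- c(dialect$probe, dialect$symbol, dialect$cy5, dialect$cy3,
                 dialect$flag, dialect$control)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(cs_header_comment(config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format Ct table
#'
#' Columns sample, gene, replicate, ct. "Undetermined" (any capitalisation,
#' also "NA"/"") is mapped to `NA` and flagged; the undetermined policy is
#' applied downstream by [compute_rq()], never at parse time.
#'
#' @param path TSV path.
#' @param reference_gene Reference (housekeeping) gene, default "GAPDH".
#' @param calibrator_id Calibrator sample identifier.
#' @return A `ct_table`: data frame plus `reference_gene`/`calibrator_id`
#'   attributes; per-(sample, gene) replicate counts are logged.
#' @export
read_ct_table <- function(path, reference_gene = "GAPDH",
                          calibrator_id = "calibrator") {
  if (!file.exists(path)) cs_stop("ct table not found: %s", path,
                                  class = "chemosig_io_error")
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    cs_stop("ct table %s: missing column(s) %s", path,
            paste(missing, collapse = ", "), class = "chemosig_integrity_error")
  }
  ct_raw <- as.character(df$ct)
  undet <- tolower(ct_raw) %in% c("undetermined", "undet", "na", "") |
    is.na(ct_raw)
  ct <- suppressWarnings(as.numeric(ct_raw))
  ct[undet] <- NA_real_
  bad <- which(!undet & is.na(ct))
  if (length(bad)) cs_stop("ct table %s: non-numeric ct at row %d", path,
                           bad[1], class = "chemosig_parse_error")
  if (any(ct > 40, na.rm = TRUE) || any(ct <= 0, na.rm = TRUE)) {
    cs_stop("ct table %s: determined ct outside (0, 40]", path,
            class = "chemosig_validation_error")
  }
  key <- paste(df$sample, df$gene, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    cs_stop("ct table %s: duplicate (sample, gene, replicate) triple: %s",
            path, gsub("\r", "/", key[duplicated(key)][1]),
            class = "chemosig_integrity_error")
  }
  out <- data.frame(sample_id = as.character(df$sample),
                    gene = as.character(df$gene),
                    replicate = as.integer(df$replicate),
                    ct = ct, undetermined = undet,
                    stringsAsFactors = FALSE)
  structure(out, reference_gene = reference_gene,
            calibrator_id = calibrator_id, class = c("ct_table", "data.frame"))
}

#' Write a Ct table
#'
#' @param ct A `ct_table` (or compatible data frame).
#' @param path Output path.
#' @param config_hash Provenance string for the header comment.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, config_hash = "unversioned") {
  out <- data.frame(sample = ct$sample_id, gene = ct$gene,
                    replicate = ct$replicate,
                    ct = ifelse(ct$undetermined, "Undetermined",
                                format(ct$ct, digits = 10, trim = TRUE)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(cs_header_comment(config_hash), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.response_levels <- c("NR", "CCR")
.regimen_levels <- c("PF", "T1PF", "T2PF")
.hpv_levels <- c("positive", "negative", "unknown")

#' Read a patient sample sheet
#'
#' Tab- or comma-separated, sniffed from the header line. Closed vocabularies
#' (response NR/CCR, regimen PF/T1PF/T2PF, hpv positive/negative/unknown) are
#' enforced; optional covariates may be empty (stored as `NA`).
#'
#' @param path Path to the sheet.
#' @return A `sample_sheet` data frame with one row per patient.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) cs_stop("sample sheet not found: %s", path,
                                  class = "chemosig_io_error")
  first <- readLines(path, n = 20L, warn = FALSE)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, na.strings = c("", "NA"))
  if (!"patient_id" %in% names(df)) {
    cs_stop("sample sheet %s: missing column patient_id", path,
            class = "chemosig_format_error")
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    cs_stop("sample sheet %s: duplicate patient_id", path,
            class = "chemosig_integrity_error")
  }
  for (spec in list(c("response", paste(.response_levels, collapse = "|")),
                    c("regimen", paste(.regimen_levels, collapse = "|")))) {
    col <- spec[1]
    if (!col %in% names(df)) {
      cs_stop("sample sheet %s: missing column %s", path, col,
              class = "chemosig_format_error")
    }
    allowed <- strsplit(spec[2], "|", fixed = TRUE)[[1]]
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad)) {
      cs_stop("sample sheet %s: %s value(s) outside {%s}: %s", path, col,
              paste(allowed, collapse = ", "), paste(bad, collapse = ", "),
              class = "chemosig_vocabulary_error")
    }
  }
  if ("hpv" %in% names(df)) {
    df$hpv[is.na(df$hpv)] <- "unknown"
    bad <- setdiff(unique(df$hpv), .hpv_levels)
    if (length(bad)) cs_stop("sample sheet %s: hpv value(s) %s", path,
                             paste(bad, collapse = ", "),
                             class = "chemosig_vocabulary_error")
  } else df$hpv <- "unknown"
  if ("hemoglobin" %in% names(df)) {
    hb <- df$hemoglobin[!is.na(df$hemoglobin)]
    if (any(hb <= 5 | hb >= 25)) {
      cs_stop("sample sheet %s: hemoglobin outside (5, 25) g/dL", path,
              class = "chemosig_validation_error")
    }
  }
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Write a sample sheet
#' @param sheet A `sample_sheet` or data frame.
#' @param path Output path (TSV).
#' @param config_hash Provenance string for the header comment.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path, config_hash = "unversioned") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(cs_header_comment(config_hash), con)
  utils::write.table(as.data.frame(sheet), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Parse an ordinal alcohol-consumption label to liters/day
#'
#' Clinical sheets record alcohol as "0", "<1", "1", ">1", ">1<=2", ... ;
#' thresholded labels are mapped to interval midpoints ("<1" -> 0.5,
#' ">2" -> 2.5, ...). Plain numbers pass through.
#'
#' @param x Character vector of labels.
#' @return Numeric liters/day.
#' @export
parse_alcohol <- function(x) {
  x <- gsub("[[:space:]]", "", as.character(x))
  out <- suppressWarnings(as.numeric(x))
  idx <- which(is.na(out) & !is.na(x) & x != "")
  for (i in idx) {
    v <- x[i]
    num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", v)))
    if (is.na(num)) next
    out[i] <- if (startsWith(v, "<")) num - 0.5 else
      if (startsWith(v, ">")) num + 0.5 else num
  }
  out
}

#' Write a gene x sample expression matrix (TSV)
#'
#' Genes as rows, samples as columns, first column `gene`. The companion
#' A-value matrix, when present, is written alongside as `<path>.avalues`.
#'
#' @param expr An `expression_matrix`, see [build_expression_matrix()].
#' @param path Output path.
#' @param config_hash Provenance string for the header comment.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, config_hash = "unversioned") {
  write_one <- function(mat, p) {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    con <- file(p, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(cs_header_comment(config_hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(expr$M, path)
  if (!is.null(expr$A)) write_one(expr$A, paste0(path, ".avalues"))
  invisible(path)
}

#' Read a gene x sample expression matrix written by [write_expression_matrix()]
#'
#' @param path TSV path (first column `gene`).
#' @return An `expression_matrix` (A-values reloaded if `<path>.avalues` exists).
#' @export
read_expression_matrix <- function(path) {
  read_one <- function(p) {
    df <- utils::read.delim(p, header = TRUE, comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  M <- read_one(path)
  A <- if (file.exists(paste0(path, ".avalues"))) read_one(paste0(path, ".avalues"))
  new_expression_matrix(M, A)
}
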