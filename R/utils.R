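#' @keywords internal
"_PACKAGE"

# Internal logging: everything goes to stderr so stdout stays machine-readable.
.chemosig_env <- new.env(parent = emptyenv())
.chemosig_env$verbosity <- 1L  # 0 quiet, 1 info, 2 debug

#' Set pipeline logging verbosity
#'
#' @param level 0 (quiet), 1 (info, default) or 2 (debug).
#' @return The previous level, invisibly.
#' @export
cs_verbosity <- function(level = 1L) {
  old <- .chemosig_env$verbosity
  .chemosig_env$verbosity <- as.integer(level)
  invisible(old)
}

cs_log <- function(..., level = 1L) {
  if (.chemosig_env$verbosity >= level) {
    message(sprintf("[chemosig %s] ", format(Sys.time(), "%H:%M:%S")), ...)
  }
  invisible(NULL)
}

cs_stop <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "chemosig_error")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Header comment written at the top of every output table.
cs_header_comment <- function(config_hash = "unversioned") {
  sprintf("# chemosig %s | config=%s | written=%s",
          as.character(utils::packageVersion("chemosig")),
          config_hash, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

# Short stable hash of an R object (for provenance fields). Not cryptographic.
cs_config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, vec.len = 1e6, digits.d = 15)),
             collapse = "\n")
  raw <- utils::head(charToRaw(s), 1e6)
  # polynomial rolling hash mod a Mersenne prime (provenance only)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive a substream seed from a base seed; kept below 2^31.
cs_subseed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647
}
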