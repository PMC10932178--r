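#' @importFrom stats cor pnorm qnorm rnorm rbinom rpois runif sd var
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline table to TSV
#'
#' Full-precision TSV writer used by every stage so that a write/read round
#' trip reproduces real values to better than 1e-12 relative error and keeps
#' `NA` entries intact.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a pipeline table from TSV
#'
#' @param path file to read.
#' @param required_cols character vector of columns that must be present;
#'   a missing column raises an error naming it.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, required_cols = NULL) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(x))
    if (length(miss) > 0L) {
      stop("table ", path, " lacks required column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  x
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Stable file checksum for manifests.
file_md5 <- function(path) unname(tools::md5sum(path))

## assert helper for argument checking with a readable message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}
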