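## TPM normalisation and the expression filter.

#' Convert a count matrix to TPM
#'
#' Standard length-normalised transcripts-per-million:
#' `TPM_gs = (c_gs / len_g) / sum_g (c_gs / len_g) * 1e6`. A sample column
#' with no counts stays all-zero with a warning.
#'
#' @param counts genes x samples non-negative count matrix.
#' @param lengths per-gene effective length in bp (> 0); defaults to the
#'   `length` attribute of `counts` when present.
#' @return genes x samples TPM matrix.
#' @export
compute_tpm <- function(counts, lengths = attr(counts, "length")) {
  counts <- as.matrix(counts)
  check_that(!is.null(lengths), "gene lengths are required")
  check_that(length(lengths) == nrow(counts), "one length per gene required")
  check_that(all(lengths > 0), "gene lengths must be > 0")
  check_that(all(counts >= 0), "counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample column(s) left at zero TPM")
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Filter genes on an expression threshold
#'
#' A gene is kept iff it reaches `TPM >= tpm_min` in at least
#' `ceil(frac_samples * n_samples)` samples (both comparisons inclusive).
#'
#' @param tpm genes x samples TPM matrix.
#' @param tpm_min expression threshold (default 0.1).
#' @param frac_samples minimum fraction of samples (default 0.20).
#' @return list: `tpm` filtered matrix, `kept` logical per input gene,
#'   `n_kept` kept-gene count.
#' @export
filter_expressed <- function(tpm, tpm_min = 0.1, frac_samples = 0.20) {
  tpm <- as.matrix(tpm)
  need <- ceiling(frac_samples * ncol(tpm))
  kept <- rowSums(tpm >= tpm_min) >= need
  list(tpm = tpm[kept, , drop = FALSE], kept = kept, n_kept = sum(kept))
}
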