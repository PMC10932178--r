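## Genotype quality control and population-structure covariates.
##
## Filters follow the conventional whole-genome resequencing QC chain:
## individual call rate, SNP call rate, minor allele frequency, and an exact
## two-sided Hardy-Weinberg test (the exact test rather than the chi-square
## approximation, because cohorts of ~100 animals make asymptotics
## unreliable). Remaining missing dosages are mean-imputed per SNP, so the
## post-QC matrix is complete.

#' QC thresholds
#'
#' Defaults mirror common practice for dense resequencing panels:
#' call rates > 0.99 (strictly greater), MAF > 0.05, HWE exact p > 1e-6.
#'
#' @param snp_call_rate,ind_call_rate,maf_min,hwe_p_min fractions in [0, 1].
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate = 0.99, ind_call_rate = 0.99,
                          maf_min = 0.05, hwe_p_min = 1e-6) {
  v <- c(snp_call_rate, ind_call_rate, maf_min, hwe_p_min)
  check_that(all(v >= 0 & v <= 1), "thresholds must lie in [0, 1]")
  structure(list(snp_call_rate = snp_call_rate, ind_call_rate = ind_call_rate,
                 maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Exact two-sided Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (the Wigginton-style two-sided exact test). The
#' heterozygote probabilities are evaluated by a multiplicative recurrence.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return exact p-value in (0, 1]; 1 for a monomorphic site.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  check_that(n_AA >= 0 && n_Aa >= 0 && n_aa >= 0, "counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  check_that(n > 0, "total genotype count must be > 0")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa      # minor allele copies
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  ## possible het counts share the parity of n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(hets))
  ## start at the smallest het count, recurse upward:
  ## P(h+2)/P(h) = [ (nr-h)(2n-nr-h) ] / [ (h+2)(h+1)/4 * 4 ] ... derived from
  ## P(h) = C(n, h) C(n-h, (nr-h)/2) 2^h / C(2n, nr) (homozygote split)
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in 2:length(hets)) {
      h <- hets[k - 1]
      probs[k] <- probs[k - 1] *
        ((n_rare - h) * (2 * n - n_rare - h)) / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("inconsistent genotype counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Apply SNP/individual quality control
#'
#' Filter order: individual call rate, then SNP call rate, then minor allele
#' frequency, then HWE. "Greater than" thresholds are strict. Missing
#' dosages surviving QC are mean-imputed per SNP.
#'
#' @param G [geno_matrix()] (missing dosages allowed).
#' @param th [qc_thresholds()].
#' @return list: `G` filtered complete [geno_matrix()], `report` data.frame
#'   of per-step removal counts, `kept_snps`, `kept_samples`.
#' @export
apply_qc <- function(G, th = qc_thresholds()) {
  dos <- G$dosage
  report <- data.frame(step = character(0), removed = integer(0),
                       remaining = integer(0))
  log_step <- function(step, removed, remaining) {
    rbind(report, data.frame(step = step, removed = removed,
                             remaining = remaining))
  }
  ## 1. individual call rate
  icr <- rowMeans(!is.na(dos))
  keep_i <- icr > th$ind_call_rate
  report <- log_step("individual_call_rate", sum(!keep_i), sum(keep_i))
  dos <- dos[keep_i, , drop = FALSE]
  ## 2. SNP call rate
  scr <- colMeans(!is.na(dos))
  keep_s <- scr > th$snp_call_rate
  report <- log_step("snp_call_rate", sum(!keep_s), sum(keep_s))
  dos <- dos[, keep_s, drop = FALSE]
  ## 3. minor allele frequency (minor = rarer allele at this stage)
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf > th$maf_min
  report <- log_step("maf", sum(!keep_m), sum(keep_m))
  dos <- dos[, keep_m, drop = FALSE]
  ## 4. exact HWE
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    d <- dos[, j]
    hwe_exact_test(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 0, na.rm = TRUE))
  }, numeric(1))
  keep_h <- hwe_p > th$hwe_p_min
  report <- log_step("hwe", sum(!keep_h), sum(keep_h))
  dos <- dos[, keep_h, drop = FALSE]
  if (ncol(dos) == 0L) stop("all SNPs removed by quality control")
  ## mean-impute residual missingness per SNP
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  kept_ids <- colnames(dos)
  Gq <- geno_matrix(dos, G$map[match(kept_ids, G$map$snp_id), , drop = FALSE])
  list(G = Gq, report = report, kept_snps = kept_ids,
       kept_samples = rownames(dos))
}

#' VanRaden genomic kinship matrix
#'
#' Method 1: `K = M M' / (2 sum_j p_j (1 - p_j))` with `M` the
#' column-centered dosage matrix and `p_j` the observed counted-allele
#' frequency.
#'
#' @param G post-QC [geno_matrix()] (complete, >= 2 SNPs).
#' @return symmetric animals x animals matrix.
#' @export
compute_kinship <- function(G) {
  dos <- G$dosage
  check_that(ncol(dos) >= 2, "need >= 2 SNPs for kinship")
  check_that(!anyNA(dos), "kinship requires a complete (post-QC) matrix")
  p <- colMeans(dos) / 2
  denom <- 2 * sum(p * (1 - p))
  check_that(denom > 0, "zero-variance denominator: all SNPs monomorphic")
  M <- sweep(dos, 2, 2 * p)
  tcrossprod(M) / denom
}

#' Principal components of the genotype matrix
#'
#' Scores are the top eigenvectors of the covariance of column-standardised
#' dosages, centered at zero, with a fixed sign convention (the
#' largest-magnitude loading of each PC is positive) so results are
#' reproducible across runs.
#'
#' @param G post-QC [geno_matrix()].
#' @param n_pcs number of components (default 3).
#' @return animals x `n_pcs` score matrix (columns `PC1..`).
#' @export
compute_pcs <- function(G, n_pcs = 3L) {
  dos <- G$dosage
  check_that(!anyNA(dos), "PCA requires a complete (post-QC) matrix")
  sds <- apply(dos, 2, sd)
  keep <- sds > 0
  Z <- scale(dos[, keep, drop = FALSE])
  check_that(n_pcs <= min(nrow(Z) - 1L, ncol(Z)),
             "n_pcs must be below the matrix rank")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = n_pcs)
  sc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(ncol(sc))) {
    load <- pc$rotation[, k]
    if (load[which.max(abs(load))] < 0) sc[, k] <- -sc[, k]
  }
  sc <- sweep(sc, 2, colMeans(sc))
  colnames(sc) <- paste0("PC", seq_len(n_pcs))
  rownames(sc) <- rownames(dos)
  sc
}
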