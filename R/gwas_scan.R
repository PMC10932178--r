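## Stage II input: per-SNP association summary statistics on EBV phenotypes.
##
## The scan is ordinary least squares of the phenotype on [intercept,
## covariates, dosage] per SNP, vectorised by projecting phenotype and
## dosages off the nuisance design once. p-values use the standard normal
## reference so that z and p round-trip exactly through the burden
## statistics (with ~100 animals the normal and t references differ
## slightly in the far tail; documented choice).

#' Covariate-adjusted single-SNP association scan
#'
#' @param y per-animal phenotype (EBV) vector, names optional.
#' @param G [geno_matrix()] (post-QC, complete), rows aligned with `y`.
#' @param covariates optional numeric matrix of covariates (e.g. PC scores),
#'   full column rank after adding the intercept.
#' @param kinship_whiten optional kinship matrix; when supplied, the
#'   phenotype and design are pre-whitened with the inverse Cholesky factor
#'   of `h2 * K + (1 - h2) * I` before the scan.
#' @param h2_whiten heritability used by the whitening transform (default 0.5).
#' @return data.frame (`snp_id`, `chr`, `pos`, `a1`, `beta`, `se`, `z`, `p`,
#'   `n`, `reason`): `a1` is the counted (minor) allele; monomorphic SNPs
#'   after covariate projection get `NA` statistics with a reason code;
#'   p-values are floored at 1e-300.
#' @export
single_snp_scan <- function(y, G, covariates = NULL, kinship_whiten = NULL,
                            h2_whiten = 0.5) {
  dos <- G$dosage
  n <- length(y)
  check_that(nrow(dos) == n, "phenotype and genotype sample counts differ")
  check_that(!anyNA(dos), "scan requires a complete (post-QC) dosage matrix")
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (!is.null(kinship_whiten)) {
    V <- h2_whiten * kinship_whiten + (1 - h2_whiten) * diag(n)
    Li <- solve(t(chol(V)))
    y <- as.vector(Li %*% y)
    X0 <- Li %*% X0
    dos <- Li %*% dos
  }
  qr0 <- qr(X0)
  check_that(qr0$rank == ncol(X0), "covariate design is rank deficient")
  yt <- qr.resid(qr0, y)
  Gt <- qr.resid(qr0, dos)
  sxx <- colSums(Gt^2)
  sxy <- as.vector(crossprod(Gt, yt))
  ok <- sxx > 1e-12
  beta <- se <- z <- p <- rep(NA_real_, ncol(dos))
  df <- n - ncol(X0) - 1L
  check_that(df > 0, "not enough samples for the scan design")
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- sum(yt^2) - beta[ok]^2 * sxx[ok]
  sigma2 <- pmax(rss, 0) / df
  se[ok] <- sqrt(sigma2 / sxx[ok])
  z[ok] <- ifelse(se[ok] > 0, beta[ok] / se[ok], sign(beta[ok]) * Inf)
  p[ok] <- pmax(2 * pnorm(-abs(z[ok])), 1e-300)
  data.frame(snp_id = G$map$snp_id, chr = G$map$chr, pos = G$map$pos,
             a1 = G$map$minor, beta = beta, se = se, z = z, p = p, n = n,
             reason = ifelse(ok, NA_character_, "monomorphic"),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  check_that(length(n_tests) == 1 && n_tests >= 1, "n_tests must be >= 1")
  alpha / n_tests
}
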