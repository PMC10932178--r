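## Stage II: gene-based burden association from GWAS summary statistics.
##
## With per-SNP GWAS z-scores z_l, trained cis-eQTL weights w_l and a
## reference genotype panel G0, the two burden statistics are
##
##   Z_FUSION     = sum_l w_l z_l / sqrt(w' V w),        V = Corr(G0)
##   Z_SPrediXcan = sum_l w_l sigma_l z_l / sqrt(w' V w), V = Cov(G0),
##                  sigma_l^2 = Var(G0_l)
##
## which coincide when all reference dosage variances equal one. Both test
## the association of genetically regulated expression (GReX = G_new w)
## with the trait without individual-level data.

#' Impute genetically regulated expression
#'
#' @param G_new [geno_matrix()] (or dosage matrix with SNP-id columns).
#' @param w `eqtl_weights` fit or named weight vector. SNPs missing from
#'   `G_new` are dropped with a warning.
#' @return per-sample GReX vector (centered dosages are not used here; the
#'   raw product `G_new w` over the aligned SNP set, as in stage II usage).
#' @export
impute_grex <- function(G_new, w) {
  dos <- if (inherits(G_new, "geno_matrix")) G_new$dosage else as.matrix(G_new)
  wv <- if (inherits(w, "eqtl_weights")) w$w else w
  check_that(!is.null(names(wv)), "weights must be named by SNP id")
  hit <- names(wv) %in% colnames(dos)
  if (!all(hit)) {
    warning(sum(!hit), " weight SNP(s) absent from the genotype matrix; dropped")
    wv <- wv[hit]
  }
  check_that(length(wv) > 0, "zero aligned SNPs between weights and genotypes")
  as.vector(dos[, names(wv), drop = FALSE] %*% wv)
}

#' Build an LD reference from a genotype panel
#'
#' Per gene: covariance and correlation matrices of the cis dosages named in
#' the weights, and the per-SNP dosage variances. Covariance matrices that
#' are not numerically PSD are repaired by clipping eigenvalues at 1e-8
#' (recorded in `psd_repaired`).
#'
#' @param G0 post-QC [geno_matrix()] reference panel.
#' @param weights list of `eqtl_weights` (each with `gene_id`, `snp_ids`).
#' @return list of class `ld_reference`: per gene a list with `snp_ids`,
#'   `corr`, `cov`, `var`, `psd_repaired`; SNPs absent from the panel are
#'   dropped with a warning.
#' @export
build_ld_reference <- function(G0, weights) {
  out <- list()
  for (w in weights) {
    ids <- w$snp_ids
    hit <- ids %in% colnames(G0$dosage)
    if (!all(hit)) {
      warning(sum(!hit), " SNP(s) of gene ", w$gene_id,
              " absent from the LD reference; dropped")
      ids <- ids[hit]
    }
    if (length(ids) == 0L) next
    D <- G0$dosage[, ids, drop = FALSE]
    cv <- stats::cov(D)
    repaired <- FALSE
    ev <- eigen(cv, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      cv <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
      dimnames(cv) <- list(ids, ids)
      repaired <- TRUE
    }
    v <- diag(cv)
    cr <- cv / sqrt(outer(v, v))
    out[[w$gene_id]] <- list(snp_ids = ids, corr = cr, cov = cv, var = v,
                             psd_repaired = repaired)
  }
  structure(out, class = "ld_reference")
}

#' FUSION-style burden Z statistic
#'
#' `Z = sum_l w_l z_l / sqrt(w' R w)` with `R` the reference SNP correlation
#' matrix. Returns `NA` when the denominator is numerically zero.
#'
#' @param w weight vector.
#' @param z GWAS z-score vector (same SNP order).
#' @param R correlation matrix.
#' @return Z statistic (scalar, possibly `NA`).
#' @export
fusion_z <- function(w, z, R) {
  check_that(length(w) == length(z) && all(dim(R) == length(w)),
             "dimension mismatch between weights, z-scores and LD matrix")
  denom2 <- as.numeric(t(w) %*% R %*% w)
  if (!is.finite(denom2) || denom2 < 1e-12) return(NA_real_)
  sum(w * z) / sqrt(denom2)
}

#' SPrediXcan-style burden Z statistic
#'
#' `Z = sum_l w_l sigma_l z_l / sqrt(w' V w)` with `V` the reference dosage
#' covariance and `sigma_l^2` its diagonal. Returns `NA` when the
#' denominator is numerically zero.
#'
#' @param w weight vector.
#' @param z GWAS z-score vector.
#' @param cov_mat covariance matrix.
#' @param var_vec per-SNP dosage variances (must match `diag(cov_mat)`).
#' @return Z statistic (scalar, possibly `NA`).
#' @export
spredixcan_z <- function(w, z, cov_mat, var_vec = diag(cov_mat)) {
  check_that(length(w) == length(z) && all(dim(cov_mat) == length(w)),
             "dimension mismatch between weights, z-scores and LD matrix")
  check_that(all(var_vec >= 0), "negative reference dosage variance")
  check_that(max(abs(diag(cov_mat) - var_vec)) <= 1e-8 * (1 + max(var_vec)),
             "diag(cov) and variance vector disagree")
  denom2 <- as.numeric(t(w) %*% cov_mat %*% w)
  if (!is.finite(denom2) || denom2 < 1e-12) return(NA_real_)
  sum(w * sqrt(var_vec) * z) / sqrt(denom2)
}

#' Gene-based burden tests for all genes
#'
#' @param sumstats GWAS summary data.frame from [single_snp_scan()].
#' @param weights list of `eqtl_weights`.
#' @param ld [build_ld_reference()] output.
#' @return data.frame per gene: `gene_id`, `n_snps_used`, `z_fusion`,
#'   `p_fusion`, `z_spredixcan`, `p_spredixcan` (two-sided normal p-values
#'   floored at 1e-300; `NA` statistics stay `NA`).
#' @export
twas_burden <- function(sumstats, weights, ld) {
  rows <- lapply(weights, function(w) {
    ref <- ld[[w$gene_id]]
    if (is.null(ref)) return(NULL)
    ids <- intersect(ref$snp_ids, sumstats$snp_id[!is.na(sumstats$z)])
    if (length(ids) == 0L) {
      return(data.frame(gene_id = w$gene_id, n_snps_used = 0L,
                        z_fusion = NA_real_, p_fusion = NA_real_,
                        z_spredixcan = NA_real_, p_spredixcan = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wv <- w$w[ids]
    zv <- sumstats$z[match(ids, sumstats$snp_id)]
    R <- ref$corr[ids, ids, drop = FALSE]
    V <- ref$cov[ids, ids, drop = FALSE]
    zf <- fusion_z(wv, zv, R)
    zs <- spredixcan_z(wv, zv, V, diag(V))
    two_p <- function(z) if (is.na(z)) NA_real_ else pmax(2 * pnorm(-abs(z)), 1e-300)
    data.frame(gene_id = w$gene_id, n_snps_used = length(ids),
               z_fusion = zf, p_fusion = two_p(zf),
               z_spredixcan = zs, p_spredixcan = two_p(zs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag significant TWAS genes at a Bonferroni threshold
#'
#' The per-trait threshold is `alpha / n_effective`; `n_effective` defaults
#' to the count of genes with a non-`NA` statistic for the method, and can
#' be supplied explicitly to reproduce printed thresholds.
#'
#' @param results data.frame from [twas_burden()].
#' @param alpha family-wise level (default 0.05).
#' @param n_effective effective test count; `NULL` = per-method non-`NA`
#'   gene count.
#' @return list: `results` with `significant_fusion` / `significant_spredixcan`
#'   flags, `sig_fusion` / `sig_spredixcan` sorted gene-id sets, and the
#'   thresholds used.
#' @export
call_significant <- function(results, alpha = 0.05, n_effective = NULL) {
  n_f <- n_effective %||% sum(!is.na(results$z_fusion))
  n_s <- n_effective %||% sum(!is.na(results$z_spredixcan))
  check_that(length(results$gene_id) == 0 || (n_f >= 1 && n_s >= 1),
             "n_effective must be >= 1")
  if (nrow(results) == 0L) {
    results$significant_fusion <- logical(0)
    results$significant_spredixcan <- logical(0)
    return(list(results = results, sig_fusion = character(0),
                sig_spredixcan = character(0),
                threshold_fusion = NA_real_, threshold_spredixcan = NA_real_))
  }
  th_f <- bonferroni_threshold(alpha, n_f)
  th_s <- bonferroni_threshold(alpha, n_s)
  results$significant_fusion <- !is.na(results$p_fusion) & results$p_fusion < th_f
  results$significant_spredixcan <-
    !is.na(results$p_spredixcan) & results$p_spredixcan < th_s
  list(results = results,
       sig_fusion = sort(results$gene_id[results$significant_fusion]),
       sig_spredixcan = sort(results$gene_id[results$significant_spredixcan]),
       threshold_fusion = th_f, threshold_spredixcan = th_s)
}

#' Intersect the significant gene sets of the two burden methods
#'
#' @param set_fusion,set_spredixcan character vectors of gene ids.
#' @return sorted intersection.
#' @export
overlap_genes <- function(set_fusion, set_spredixcan) {
  sort(intersect(set_fusion, set_spredixcan))
}

#' Annotate TWAS signals with nearby genes
#'
#' Reports every gene whose span intersects the closed interval
#' `[signal_start - window, signal_end + window]`; when none does, the
#' single nearest gene on the chromosome is reported with its distance.
#'
#' @param signals data.frame with `signal_id`, `chr`, `start`, `end`
#'   (point signals use `start == end`), 1-based coordinates.
#' @param genes gene annotation data.frame (`gene_id`, `chr`, `start`,
#'   `end`).
#' @param window half-width in bp (default 25 kb).
#' @return data.frame (`signal_id`, `gene_id`, `distance`): distance 0 for
#'   an overlap with the widened interval, otherwise the gap to the nearest
#'   gene; `NA` gene if the chromosome has no annotated gene.
#' @export
annotate_signals <- function(signals, genes, window = 25000) {
  check_that(nrow(genes) > 0, "empty gene annotation")
  rows <- lapply(seq_len(nrow(signals)), function(i) {
    lo <- signals$start[i] - window
    hi <- signals$end[i] + window
    on_chr <- genes[genes$chr == signals$chr[i], , drop = FALSE]
    if (nrow(on_chr) == 0L) {
      return(data.frame(signal_id = signals$signal_id[i], gene_id = NA_character_,
                        distance = NA_real_, stringsAsFactors = FALSE))
    }
    hit <- on_chr$end >= lo & on_chr$start <= hi
    if (any(hit)) {
      data.frame(signal_id = signals$signal_id[i], gene_id = on_chr$gene_id[hit],
                 distance = 0, stringsAsFactors = FALSE)
    } else {
      gap <- pmax(on_chr$start - signals$end[i], signals$start[i] - on_chr$end)
      j <- which.min(gap)
      data.frame(signal_id = signals$signal_id[i], gene_id = on_chr$gene_id[j],
                 distance = gap[j], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p-value per gene set: with overlap
#' `k`, set size `K`, study size `n` and background size `N`,
#' `p = P(X >= k)` for `X ~ Hypergeom(K, N - K, n)`.
#'
#' @param study_genes character vector (must be a subset of the background).
#' @param background_genes character vector.
#' @param gene_sets named list of character vectors (intersected with the
#'   background).
#' @return data.frame (`set`, `overlap`, `set_size`, `study_size`,
#'   `background_size`, `p`).
#' @export
enrichment_test <- function(study_genes, background_genes, gene_sets) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  check_that(all(study_genes %in% background_genes),
             "study genes must be a subset of the background")
  N <- length(background_genes)
  n <- length(study_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background_genes)
    K <- length(set)
    k <- length(intersect(study_genes, set))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, study_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
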