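## Seeded synthetic-data generator.
##
## Emulates the data shapes of the study design: a crossbred cohort of ~100
## milking buffalo with whole-genome SNP dosages, blood expression with a
## cis-genetic architecture, multi-parity test-day records under the
## random-regression model, and a small pedigree roughly twice the size of
## the phenotyped cohort. Every generator takes (or derives) a seed and is
## byte-reproducible.

#' Simulation configuration
#'
#' Collects the knobs shared by the generators. Defaults describe the
#' pipeline's reference panel: 100 phenotyped/genotyped animals, 5000 SNPs
#' spread over 5 chromosomes of 50 Mb, 300 genes, a modest blood cis
#' heritability, and three lactations recorded roughly monthly between 5 and
#' 300 days in milk.
#'
#' @param n_animals number of phenotyped + genotyped animals.
#' @param n_snps total SNP count across chromosomes.
#' @param n_genes gene count, evenly spaced along the chromosomes.
#' @param n_chr chromosome count; each chromosome has length `chr_len_bp`.
#' @param chr_len_bp chromosome length in bp.
#' @param maf_range length-2 numeric, allele-frequency range in (0, 0.5].
#' @param ld_rho adjacent-marker haplotype correlation in [0, 1).
#' @param p_causal_cis fraction of cis SNPs with nonzero expression effects.
#' @param h2_cis cis heritability of expression, in [0, 1).
#' @param h2_trait not used directly; the test-day variance components in
#'   `varcomps` control trait heritability. Kept for reporting.
#' @param n_parities lactations per animal (1-3).
#' @param dim_grid sorted integer days in milk within [5, 300] at which
#'   test-day records are taken.
#' @param varcomps [variance_components()] for the test-day model.
#' @param missing_rate per-entry genotype missingness rate (default 0:
#'   pre-QC missingness is opt-in).
#' @param seed integer seed; every generator derives its stream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 100, n_snps = 5000, n_genes = 300,
                       n_chr = 5, chr_len_bp = 5e7,
                       maf_range = c(0.05, 0.5), ld_rho = 0.3,
                       p_causal_cis = 0.1, h2_cis = 0.1, h2_trait = 0.25,
                       n_parities = 3, dim_grid = seq(5L, 300L, by = 30L),
                       varcomps = variance_components(),
                       missing_rate = 0, seed = 1L) {
  fr <- c(p_causal_cis, h2_cis, h2_trait, missing_rate)
  check_that(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
  check_that(h2_cis < 1, "h2_cis must be < 1")
  check_that(length(maf_range) == 2 && maf_range[1] <= maf_range[2] &&
               maf_range[1] > 0 && maf_range[2] <= 0.5,
             "maf_range must be increasing within (0, 0.5]")
  check_that(ld_rho >= 0 && ld_rho < 1, "ld_rho must lie in [0, 1)")
  dim_grid <- as.integer(dim_grid)
  check_that(!is.unsorted(dim_grid) && min(dim_grid) >= 5L && max(dim_grid) <= 300L,
             "dim_grid must be sorted within [5, 300]")
  check_that(n_animals >= 2 && n_snps >= 1 && n_genes >= 1,
             "counts must be positive")
  check_that(n_parities >= 1 && n_parities <= 3, "n_parities must be 1-3")
  structure(list(n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
                 n_genes = as.integer(n_genes), n_chr = as.integer(n_chr),
                 chr_len_bp = as.numeric(chr_len_bp), maf_range = maf_range,
                 ld_rho = ld_rho, p_causal_cis = p_causal_cis, h2_cis = h2_cis,
                 h2_trait = h2_trait, n_parities = as.integer(n_parities),
                 dim_grid = dim_grid, varcomps = varcomps,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a small multi-generation pedigree
#'
#' Founders form generation 0; each later generation holds `n_founders`
#' offspring whose sire and dam are drawn (distinct) from all earlier
#' generations, so parents always precede offspring and the pedigree is
#' acyclic by construction.
#'
#' @param n_founders founders (>= 2).
#' @param n_generations generations after the founders (>= 0).
#' @param seed integer seed.
#' @return data.frame `(id, sire, dam)`, topologically ordered; founder
#'   parents are `NA`.
#' @export
simulate_pedigree <- function(n_founders, n_generations, seed = 1L) {
  check_that(n_founders >= 2, "need at least 2 founders")
  check_that(n_generations >= 0, "n_generations must be >= 0")
  n_total <- n_founders * (n_generations + 1L)
  id <- sprintf("A%04d", seq_len(n_total))
  sire <- dam <- rep(NA_character_, n_total)
  with_seed(seed, {
    for (g in seq_len(n_generations)) {
      prev <- seq_len(n_founders * g)           # all earlier animals
      idx <- n_founders * g + seq_len(n_founders)
      for (i in idx) {
        pr <- sample(prev, 2L)
        sire[i] <- id[pr[1]]
        dam[i] <- id[pr[2]]
      }
    }
  })
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

## deterministic SNP map: positions uniform per chromosome, sorted
sim_snp_map <- function(cfg) {
  per_chr <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chr + 1)))
  with_seed(cfg$seed + 11L, {
    maps <- lapply(seq_len(cfg$n_chr), function(cc) {
      pos <- sort(sample.int(cfg$chr_len_bp, per_chr[cc]))
      ra <- matrix(sample(c("A", "C", "G", "T"), 2L * per_chr[cc], replace = TRUE),
                   ncol = 2)
      same <- ra[, 1] == ra[, 2]
      ra[same, 2] <- chartr("ACGT", "CGTA", ra[same, 1])
      data.frame(chr = as.character(cc), pos = pos,
                 ref = ra[, 1], alt = ra[, 2], stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  })
}

#' Simulate LD-structured genotype dosages
#'
#' Haplotypes follow a first-order Markov copying process within each
#' chromosome: the first marker allele is Bernoulli(p_1); each subsequent
#' allele copies its left neighbour with probability `ld_rho` and is
#' otherwise drawn fresh from Bernoulli(p_j). Adjacent-marker haplotype
#' correlation is then `ld_rho` up to allele-frequency heterogeneity.
#' Dosage = sum of two independent haplotypes, so entries are in {0, 1, 2}.
#'
#' @param cfg [sim_config()].
#' @param sample_ids optional sample ids (length `cfg$n_animals`); default
#'   `S0001..`.
#' @return list with `G` ([geno_matrix()], dosages counting the simulated
#'   target allele) and `freq` (the per-SNP target-allele frequencies used
#'   for simulation).
#' @export
simulate_genotypes <- function(cfg, sample_ids = NULL) {
  map <- sim_snp_map(cfg)
  m <- nrow(map)
  nh <- 2L * cfg$n_animals
  with_seed(cfg$seed + 23L, {
    p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    H <- matrix(0L, nrow = nh, ncol = m)
    new_chr <- c(TRUE, map$chr[-1] != map$chr[-m])
    for (j in seq_len(m)) {
      if (new_chr[j]) {
        H[, j] <- rbinom(nh, 1L, p[j])
      } else {
        copy <- runif(nh) < cfg$ld_rho
        H[, j] <- ifelse(copy, H[, j - 1L], rbinom(nh, 1L, p[j]))
      }
    }
    dos <- H[seq(1, nh, by = 2), , drop = FALSE] + H[seq(2, nh, by = 2), , drop = FALSE]
    if (cfg$missing_rate > 0) {
      dos[matrix(runif(length(dos)) < cfg$missing_rate, nrow(dos))] <- NA_real_
    }
    storage.mode(dos) <- "double"
    rownames(dos) <- sample_ids %||% sprintf("S%04d", seq_len(cfg$n_animals))
    map$minor <- map$alt   # simulated target allele plays the alt/minor role
    map$snp_id <- snp_id_string(map$chr, map$pos, map$ref, map$alt)
    list(G = geno_matrix(dos, map[, c("snp_id", "chr", "pos", "ref", "alt", "minor")]),
         freq = p)
  })
}

## Evenly spaced gene models along the simulated chromosomes.
sim_gene_annotation <- function(cfg) {
  per_chr <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chr + 1)))
  with_seed(cfg$seed + 31L, {
    out <- lapply(seq_len(cfg$n_chr), function(cc) {
      k <- per_chr[cc]
      if (k == 0) return(NULL)
      centers <- round(seq(cfg$chr_len_bp / (k + 1), cfg$chr_len_bp * k / (k + 1),
                           length.out = k))
      len <- round(runif(k, 5e3, 5e4))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      start <- pmax(1, centers - len %/% 2)
      end <- start + len
      data.frame(gene_id = sprintf("G%s_%03d", cc, seq_len(k)), chr = as.character(cc),
                 start = start, end = end, strand = strand,
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, out)
    ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
    rownames(ann) <- NULL
    ann
  })
}

#' Simulate cis-regulated gene expression
#'
#' For each gene, cis SNPs are those within 1 Mb of the TSS. A fraction
#' `p_causal_cis` of them (at least one, when `h2_cis > 0`) receive i.i.d.
#' normal effects, rescaled so the genetic variance of `G w` accounts for
#' `h2_cis` of the unit total variance; the residual is i.i.d. normal. A
#' baseline shifts each gene to a positive TPM-like scale.
#'
#' @param G [geno_matrix()] from [simulate_genotypes()].
#' @param cfg [sim_config()].
#' @param genes optional gene annotation (defaults to the deterministic
#'   layout implied by `cfg`).
#' @param cis_window cis window half-width in bp (default 1e6).
#' @return list: `E` genes x samples expression matrix; `genes` annotation;
#'   `truth` per-gene list of data.frames `(snp_id, effect)` (full cis set,
#'   zeros for non-causal SNPs); `no_cis` ids of genes with an empty cis set
#'   (expression is then pure noise).
#' @export
simulate_expression <- function(G, cfg, genes = NULL, cis_window = 1e6) {
  genes <- genes %||% sim_gene_annotation(cfg)
  n <- nrow(G$dosage)
  with_seed(cfg$seed + 47L, {
    base <- runif(nrow(genes), 8, 40)   # baseline keeps values positive
    E <- matrix(NA_real_, nrow(genes), n,
                dimnames = list(genes$gene_id, rownames(G$dosage)))
    truth <- vector("list", nrow(genes))
    names(truth) <- genes$gene_id
    no_cis <- character(0)
    for (g in seq_len(nrow(genes))) {
      cis <- select_cis_snps(genes$tss[g], genes$chr[g], G$map, window = cis_window)
      eff <- numeric(length(cis))
      gv <- rep(0, n)
      if (length(cis) == 0L) {
        no_cis <- c(no_cis, genes$gene_id[g])
      } else if (cfg$h2_cis > 0) {
        k <- max(1L, round(cfg$p_causal_cis * length(cis)))
        causal <- sample(seq_along(cis), k)
        eff[causal] <- rnorm(k)
        gv <- as.vector(G$dosage[, cis, drop = FALSE] %*% eff)
        s <- sd(gv)
        if (s > 0) {
          scale <- sqrt(cfg$h2_cis) / s
          eff <- eff * scale
          gv <- gv * scale
        } else {
          eff[] <- 0
          gv[] <- 0
        }
      }
      resid_sd <- sqrt(max(1 - var(gv), 1e-8))
      E[g, ] <- base[g] + gv + rnorm(n, sd = resid_sd)
      truth[[g]] <- data.frame(snp_id = as.character(cis), effect = eff,
                               stringsAsFactors = FALSE)
    }
    E[E < 0] <- 0
    list(E = E, genes = genes, truth = truth, no_cis = no_cis)
  })
}

#' Derive an RNA-seq style count matrix from simulated expression
#'
#' Counts are Poisson with rate proportional to expression x gene length x
#' sample depth, so TPM computed from them recovers the simulated
#' expression profile up to per-sample normalisation.
#'
#' @param E genes x samples expression matrix (TPM-like scale).
#' @param genes gene annotation with `start`/`end` (span = effective length).
#' @param cfg [sim_config()] (seed source).
#' @param mean_depth mean per-sample sequencing depth factor.
#' @return integer count matrix, genes x samples, with a `length` attribute.
#' @export
simulate_counts <- function(E, genes, cfg, mean_depth = 30) {
  len <- genes$end - genes$start + 1
  with_seed(cfg$seed + 53L, {
    depth <- runif(ncol(E), 0.5, 1.5) * mean_depth
    lam <- sweep(E * (len / 1e4), 2, depth, `*`)
    cnt <- matrix(rpois(length(lam), lam), nrow(E), ncol(E),
                  dimnames = dimnames(E))
    attr(cnt, "length") <- len
    cnt
  })
}

#' Variance components of the random-regression test-day model
#'
#' 4x4 covariance matrices of the additive-genetic (`K_a`) and permanent
#' environment (`K_p`) Legendre regression coefficients, plus the residual
#' variance. Defaults are on a daily-milk-yield (kg) scale and give a daily
#' heritability around 0.2 at mid-lactation.
#'
#' @param K_a,K_p symmetric PSD 4x4 matrices.
#' @param sigma_e2 residual variance (> 0).
#' @return list of class `variance_components`.
#' @export
variance_components <- function(K_a = diag(c(1.0, 0.3, 0.1, 0.05)),
                                K_p = diag(c(0.8, 0.25, 0.1, 0.05)),
                                sigma_e2 = 1.5) {
  check_psd <- function(M, nm) {
    check_that(is.matrix(M) && all(dim(M) == c(4, 4)), nm, " must be 4x4")
    check_that(max(abs(M - t(M))) < 1e-8, nm, " must be symmetric")
    check_that(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8,
               nm, " must be positive semi-definite")
  }
  check_psd(K_a, "K_a"); check_psd(K_p, "K_p")
  check_that(sigma_e2 > 0, "sigma_e2 must be > 0")
  structure(list(K_a = K_a, K_p = K_p, sigma_e2 = sigma_e2),
            class = "variance_components")
}

## multivariate normal draws (rows) with covariance S; deterministic given RNG state
rmvn <- function(n, S) {
  ev <- eigen(S, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(n * nrow(S)), n) %*% rt
}

#' Simulate multi-parity test-day records
#'
#' Forward simulation of the random-regression test-day model: fixed
#' herd-test-date (HTD), calving year-season (YS) and month-of-calving (MC)
#' class effects, fixed third-order Legendre regressions on days in milk,
#' additive-genetic and permanent-environment random regression coefficient
#' vectors drawn from `A (x) K_a` and `I (x) K_p`, and i.i.d. residuals.
#' Phenotyped animals are the last `cfg$n_animals` pedigree entries; every
#' animal x parity gets one record per `cfg$dim_grid` day (>= 5 records).
#'
#' @param ped pedigree data.frame `(id, sire, dam)`.
#' @param cfg [sim_config()].
#' @param b_fixed fixed Legendre regression coefficients (length 4).
#' @param sd_htd,sd_ys,sd_mc SDs of the class-effect draws.
#' @param mu baseline added to every record.
#' @param n_herds herds crossed with test dates to form HTD levels.
#' @return list: `records` data.frame `(animal_id, parity, dim, htd, ys, mc,
#'   value)`; `truth` list with `true_breeding_values` (mean daily additive
#'   value over DIM 5..300), `additive_coeffs`, `pe_coeffs`,
#'   `fixed_effects` (named level -> value maps), `b_fixed`.
#' @export
simulate_testday <- function(ped, cfg, b_fixed = c(12, -1, 0.5, -0.25),
                             sd_htd = 0.5, sd_ys = 0.5, sd_mc = 0.3,
                             mu = 0, n_herds = 2) {
  vc <- cfg$varcomps
  q <- nrow(ped)
  check_that(cfg$n_animals <= q, "pedigree smaller than n_animals")
  pheno_ids <- ped$id[(q - cfg$n_animals + 1L):q]
  A <- build_numerator_relationship(ped)
  with_seed(cfg$seed + 61L, {
    ## coefficient draws: vec ordered animal-major -> covariance A (x) K_a
    a_mat <- rmvn_kron(A, vc$K_a)           # q x 4
    p_mat <- rmvn(cfg$n_animals, vc$K_p)    # phenotyped only
    rownames(a_mat) <- ped$id
    rownames(p_mat) <- pheno_ids
    ## herd-test-date: herds crossed with 12 monthly calendar buckets; each
    ## animal x parity calves at a random offset, so HTD is not confounded
    ## with DIM and the fixed design stays identifiable
    htd_levels <- as.vector(outer(seq_len(n_herds), 0:11,
                                  function(h, d) sprintf("H%d_D%02d", h, d)))
    ys_levels <- sprintf("YS%d", 1:4)
    mc_levels <- sprintf("MC%02d", 1:12)
    eff_htd <- stats::setNames(rnorm(length(htd_levels), sd = sd_htd), htd_levels)
    eff_ys <- stats::setNames(rnorm(length(ys_levels), sd = sd_ys), ys_levels)
    eff_mc <- stats::setNames(rnorm(length(mc_levels), sd = sd_mc), mc_levels)
    herd <- sample(seq_len(n_herds), cfg$n_animals, replace = TRUE)
    Phi <- legendre_basis(cfg$dim_grid)     # |grid| x 4
    rec <- vector("list", cfg$n_animals * cfg$n_parities)
    k <- 0L
    for (i in seq_len(cfg$n_animals)) {
      aid <- pheno_ids[i]
      for (par in seq_len(cfg$n_parities)) {
        ys <- sample(ys_levels, 1L)
        mc <- sample(mc_levels, 1L)
        calve_off <- sample.int(365L, 1L) - 1L
        htd <- sprintf("H%d_D%02d", herd[i],
                       ((calve_off + cfg$dim_grid) %/% 30L) %% 12L)
        gen <- as.vector(Phi %*% a_mat[aid, ])
        pe <- as.vector(Phi %*% p_mat[aid, ])
        y <- mu + eff_htd[htd] + eff_ys[ys] + eff_mc[mc] +
          as.vector(Phi %*% b_fixed) + gen + pe +
          rnorm(length(cfg$dim_grid), sd = sqrt(vc$sigma_e2))
        k <- k + 1L
        rec[[k]] <- data.frame(animal_id = aid, parity = par,
                               dim = cfg$dim_grid, htd = htd, ys = ys, mc = mc,
                               value = unname(y), stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    phibar <- colMeans(legendre_basis(5:300))
    tbv <- as.vector(a_mat %*% phibar)
    names(tbv) <- ped$id
    list(records = records,
         truth = list(true_breeding_values = tbv,
                      additive_coeffs = a_mat, pe_coeffs = p_mat,
                      fixed_effects = list(htd = eff_htd, ys = eff_ys, mc = eff_mc),
                      b_fixed = b_fixed, mu = mu))
  })
}

## draw q x 4 coefficients with vec covariance A (x) K (animal-major rows)
rmvn_kron <- function(A, K) {
  q <- nrow(A)
  La <- chol_psd(A)
  Lk <- chol_psd(K)
  Zm <- matrix(rnorm(q * nrow(K)), q)
  La %*% Zm %*% t(Lk)
}

## lower-triangular PSD square root via eigen (chol fails on singular A)
chol_psd <- function(M) {
  ev <- eigen(M, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}
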