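test_that("GReX imputation is the aligned matrix product", {
  w <- stats::setNames(c(1, 1, 1), paste0("1_", c(1000, 2000, 3000), "_A_G"))
  G1 <- matrix(c(0, 1, 2), 1, dimnames = list("s1", names(w)))
  expect_equal(impute_grex(G1, w), 3)
  expect_equal(impute_grex(G1, w * 0), 0)

  withr::with_seed(61, {
    G <- rand_dosages(20, 5, seed = 61)
    wv <- stats::setNames(rnorm(5), colnames(G))
    expect_equal(impute_grex(G, wv), as.vector(G %*% wv), tolerance = 1e-12)
  })
  suppressWarnings(
    expect_error(impute_grex(G1, stats::setNames(1, "1_999_A_G")),
                 "zero aligned"))
  expect_warning(
    impute_grex(G1, stats::setNames(c(1, 1), c("1_1000_A_G", "1_999_C_T"))),
    "dropped")
})

test_that("the LD reference is definitionally consistent and PSD-repaired", {
  withr::with_seed(62, {
    G <- rand_dosages(200, 6, seed = 62)
    gm <- as_geno(G)
    w <- list(list(gene_id = "g1", snp_ids = colnames(G)[1:4]),
              list(gene_id = "g2", snp_ids = colnames(G)[3:6]))
    ld <- build_ld_reference(gm, w)
    ref <- ld$g1
    expect_equal(ref$corr, ref$cov / sqrt(outer(ref$var, ref$var)),
                 tolerance = 1e-12)
    expect_equal(unname(diag(ref$cov)), unname(ref$var), tolerance = 1e-12)
    expect_true(isSymmetric(ref$cov))
  })
  ## duplicated SNP column: correlation 1, PSD repair engages
  D <- rand_dosages(50, 2, seed = 63)
  D <- cbind(D, D[, 2])
  colnames(D)[3] <- "1_9000_A_G"
  gm2 <- as_geno(D)
  w2 <- list(list(gene_id = "g", snp_ids = colnames(D)))
  ld2 <- build_ld_reference(gm2, w2)
  expect_true(ld2$g$psd_repaired)
  expect_gt(ld2$g$corr[2, 3], 0.999)

  ## independent SNPs, n = 1000: small off-diagonal correlation
  big <- rand_dosages(1000, 30, seed = 64)
  ldb <- build_ld_reference(as_geno(big),
                            list(list(gene_id = "g", snp_ids = colnames(big))))
  off <- ldb$g$corr[upper.tri(ldb$g$corr)]
  expect_lt(mean(abs(off)), 0.05)
})

test_that("burden Z statistics match hand evaluations", {
  expect_equal(fusion_z(1, 2.5, matrix(1)), 2.5)
  expect_equal(fusion_z(c(1, 1), c(2, 2), diag(2)), 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(fusion_z(c(1, 1), c(2, 2), matrix(1, 2, 2)), 2, tolerance = 1e-12)
  expect_error(fusion_z(c(1, 1), 2, diag(2)), "dimension")
  expect_true(is.na(fusion_z(c(0, 0), c(1, 1), diag(2))))

  ## single SNP: sigma cancels, sign follows w
  expect_equal(spredixcan_z(3, 1.7, matrix(4), 4), 1.7, tolerance = 1e-12)
  expect_equal(spredixcan_z(-3, 1.7, matrix(4), 4), -1.7, tolerance = 1e-12)
  expect_error(spredixcan_z(1, 1, matrix(-1), -1), "negative")

  ## unit-variance reference: the two statistics coincide
  withr::with_seed(65, {
    R <- stats::cov2cor(crossprod(matrix(rnorm(40), 10, 4)))
    w <- rnorm(4); z <- rnorm(4)
    expect_equal(spredixcan_z(w, z, R, rep(1, 4)), fusion_z(w, z, R),
                 tolerance = 1e-12)
  })
})

test_that("burden Z is invariant to flipping a SNP's allele coding", {
  withr::with_seed(66, {
    G <- rand_dosages(300, 5, seed = 66)
    gm <- as_geno(G)
    w <- rnorm(5); z <- rnorm(5)
    ld <- build_ld_reference(gm, list(list(gene_id = "g", snp_ids = colnames(G))))
    zf <- fusion_z(w, z, ld$g$corr)
    zs <- spredixcan_z(w, z, ld$g$cov, ld$g$var)
    ## flip SNP 2: dosage -> 2 - dosage, w -> -w, z -> -z
    G2 <- G; G2[, 2] <- 2 - G[, 2]
    ld2 <- build_ld_reference(as_geno(G2),
                              list(list(gene_id = "g", snp_ids = colnames(G))))
    w2 <- w; w2[2] <- -w[2]
    z2 <- z; z2[2] <- -z[2]
    expect_equal(fusion_z(w2, z2, ld2$g$corr), zf, tolerance = 1e-10)
    expect_equal(spredixcan_z(w2, z2, ld2$g$cov, ld2$g$var), zs, tolerance = 1e-10)
  })
})

test_that("stage II matches the individual-level GReX regression when the cohort is its own reference", {
  withr::with_seed(67, {
    n <- 500
    G <- rand_dosages(n, 12, seed = 67)
    gm <- as_geno(G)
    w <- stats::setNames(rnorm(12), colnames(G))
    y <- rnorm(n)   # null trait: weak per-SNP associations
    ss <- single_snp_scan(y, gm)
    ld <- build_ld_reference(gm, list(list(gene_id = "g", snp_ids = colnames(G))))
    zs <- spredixcan_z(w, ss$z, ld$g$cov, ld$g$var)
    grex <- impute_grex(gm, w)
    ft <- summary(stats::lm(y ~ grex))$coefficients
    z_ind <- ft["grex", "t value"]
    expect_lt(abs(zs - z_ind), 0.05)
  })
})

test_that("significance calls, overlaps and thresholds behave as documented", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    n_snps_used = 3,
                    z_fusion = c(0, 4.6637, NA),
                    p_fusion = c(1, 2 * pnorm(-4.6637), NA),
                    z_spredixcan = c(0, 4.6637, 1),
                    p_spredixcan = c(1, 2 * pnorm(-4.6637), 2 * pnorm(-1)))
  called <- call_significant(res, alpha = 0.05, n_effective = 6389)
  expect_identical(called$sig_fusion, "b")      # p ~ 3.1e-6 < 7.83e-6
  expect_identical(called$sig_spredixcan, "b")
  expect_false(any(called$results$significant_fusion[c(1, 3)]))

  expect_identical(overlap_genes(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_identical(overlap_genes(character(0), c("x")), character(0))
  expect_identical(overlap_genes(c("x", "y"), c("x", "y")), c("x", "y"))
})

test_that("signal annotation uses a closed 25 kb window with nearest-gene fallback", {
  genes <- data.frame(gene_id = paste0("g", 1:5), chr = "1",
                      start = c(100, 50000, 200000, 400000, 700000),
                      end = c(20000, 90000, 260000, 420000, 710000))
  sig <- data.frame(signal_id = c("in_gene", "boundary", "nearest"),
                    chr = "1",
                    start = c(10000, 175000, 550000),
                    end = c(10000, 175000, 550000))
  ann <- annotate_signals(sig, genes, window = 25000)
  expect_equal(ann$gene_id[ann$signal_id == "in_gene"], "g1")
  expect_equal(ann$distance[ann$signal_id == "in_gene"], 0)
  ## gene starting exactly 25 kb downstream is included (closed interval)
  expect_true("g3" %in% ann$gene_id[ann$signal_id == "boundary"])
  ## no overlap within 25 kb: single nearest gene with its distance
  near <- ann[ann$signal_id == "nearest", ]
  expect_equal(near$gene_id, "g4")
  expect_equal(near$distance, 130000)   # 550000 - 420000 (g4 end)
  expect_error(annotate_signals(sig, genes[0, ]), "empty")
})

test_that("hypergeometric enrichment matches closed form and a sampling oracle", {
  bg <- paste0("g", 1:20)
  study <- paste0("g", 1:5)
  sets <- list(all5 = paste0("g", 1:5), none = paste0("g", 16:20),
               half = paste0("g", 4:13))
  et <- enrichment_test(study, bg, sets)
  expect_equal(et$p[et$set == "all5"], 1 / choose(20, 5), tolerance = 1e-9)
  expect_equal(et$p[et$set == "none"], 1)   # upper tail includes k = 0
  ## simulation oracle for the 'half' set
  withr::with_seed(68, {
    draws <- replicate(1e5, length(intersect(sample(bg, 5), sets$half)))
    k_obs <- length(intersect(study, sets$half))
    p_mc <- mean(draws >= k_obs)
    se_mc <- sqrt(p_mc * (1 - p_mc) / 1e5)
    expect_lt(abs(et$p[et$set == "half"] - p_mc), 3 * se_mc + 1e-12)
  })
  expect_error(enrichment_test(c("zz"), bg, sets), "subset")
})
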