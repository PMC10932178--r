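test_that("exact HWE test equals the enumeration oracle exhaustively (totals <= 50)", {
  worst <- 0
  worst_case <- c(0L, 0L, 0L)
  for (n in 1:50) {
    for (nAA in 0:n) {
      for (nAa in 0:(n - nAA)) {
        naa <- n - nAA - nAa
        d <- abs(hwe_exact_test(nAA, nAa, naa) - hwe_oracle(nAA, nAa, naa))
        if (d > worst) {
          worst <- d
          worst_case <- c(nAA, nAa, naa)
        }
      }
    }
  }
  expect_lt(worst, 1e-10,
            label = sprintf("max |p - oracle| (worst at %d/%d/%d)",
                            worst_case[1], worst_case[2], worst_case[3]))
})

test_that("exact HWE test handles the canonical endpoint cases", {
  expect_identical(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)  # most probable configuration
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(-1, 0, 1), ">= 0")
  expect_error(hwe_exact_test(0, 0, 0), "> 0")
})

test_that("QC filters apply in order and the report matches a hand tally", {
  ## fixture with planted violations, 40 animals x 200 SNPs (enough SNPs
  ## that one missing entry keeps an animal above the 0.99 call rate)
  withr::with_seed(5, {
    n <- 40
    G <- rand_dosages(n, 200, seed = 5, maf = rep(0.3, 200))
    ## SNP 1: 5% missing -> fails snp call rate 0.99
    G[1:2, 1] <- NA
    ## SNP 2: monomorphic -> MAF 0
    G[, 2] <- 0
    ## SNP 3: rare (1 het) -> MAF 1/80 < 0.05
    G[, 3] <- c(1, rep(0, n - 1))
    ## SNP 4: all hets -> extreme HWE violation
    G[, 4] <- 1
    gm <- as_geno(G)
    res <- apply_qc(gm, qc_thresholds())
    rep_ <- res$report
    expect_equal(rep_$removed[rep_$step == "individual_call_rate"], 0)
    expect_equal(rep_$removed[rep_$step == "snp_call_rate"], 1)
    expect_equal(rep_$removed[rep_$step == "maf"], 2)
    expect_equal(rep_$removed[rep_$step == "hwe"], 1)
    expect_equal(ncol(res$G$dosage), 196)
    expect_false(anyNA(res$G$dosage))
    ## idempotence
    res2 <- apply_qc(res$G, qc_thresholds())
    expect_identical(res2$G$dosage, res$G$dosage)
  })
})

test_that("QC removes low-call-rate individuals and errors when nothing survives", {
  withr::with_seed(6, {
    G <- rand_dosages(30, 8, seed = 6)
    G[1, 1:5] <- NA    # individual 1 call rate 3/8
    gm <- as_geno(G)
    res <- apply_qc(gm, qc_thresholds())
    expect_equal(nrow(res$G$dosage), 29)
    mono <- as_geno(matrix(0, 10, 2,
                           dimnames = list(NULL, c("1_100_A_G", "1_200_A_G"))))
    expect_error(apply_qc(mono, qc_thresholds()), "all SNPs removed")
  })
})

test_that("VanRaden kinship matches hand computation and its scaling property", {
  ## 3 animals x 2 SNPs hand instance
  D <- matrix(c(0, 1, 2,
                1, 1, 0), nrow = 3,
              dimnames = list(NULL, c("1_100_A_G", "1_200_C_T")))
  gm <- as_geno(D)
  K <- compute_kinship(gm)
  p <- colMeans(D) / 2
  M <- sweep(D, 2, 2 * p)
  K_hand <- M %*% t(M) / (2 * sum(p * (1 - p)))
  expect_equal(K, K_hand, ignore_attr = TRUE)
  expect_true(isSymmetric(K))

  ## duplicate genotypes give identical entries
  D2 <- rbind(D, D[3, ])
  rownames(D2) <- NULL
  K2 <- compute_kinship(as_geno(D2))
  expect_equal(K2[3, 4], K2[3, 3])
  expect_equal(K2[4, 4], K2[3, 3])

  ## mean diagonal ~ 1 for unrelated animals at 1000 SNPs
  G <- rand_dosages(60, 1000, seed = 7)
  Kbig <- compute_kinship(as_geno(G))
  expect_lt(abs(mean(diag(Kbig)) - 1), 0.1)
  expect_gte(min(eigen(Kbig, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("principal components separate planted subpopulations and are centered", {
  withr::with_seed(8, {
    n_half <- 40; p <- 300
    f1 <- runif(p, 0.1, 0.5)
    shift <- sample(c(-0.25, 0.25), p, replace = TRUE)
    f2 <- pmin(pmax(f1 + shift, 0.05), 0.95)
    G <- rbind(sapply(f1, function(f) rbinom(n_half, 2, f)),
               sapply(f2, function(f) rbinom(n_half, 2, f)))
    colnames(G) <- paste0("1_", seq_len(p) * 500, "_A_G")
    pcs <- compute_pcs(as_geno(G), 3)
    expect_equal(colMeans(pcs), rep(0, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    grp <- rep(1:2, each = n_half)
    ## PC1 separates the groups: silhouette-like margin > 0
    expect_gt(abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1])),
              mean(c(sd(pcs[grp == 1, 1]), sd(pcs[grp == 2, 1]))))
    ## deterministic sign convention
    pcs2 <- compute_pcs(as_geno(G), 3)
    expect_identical(pcs, pcs2)
    expect_error(compute_pcs(as_geno(G), 80), "rank")
  })
})
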