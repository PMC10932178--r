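test_that("simulated pedigrees are acyclic, ordered, and seed-deterministic", {
  p0 <- simulate_pedigree(2, 0, seed = 1)
  expect_equal(nrow(p0), 2)
  expect_true(all(is.na(p0$sire)) && all(is.na(p0$dam)))

  p1 <- simulate_pedigree(4, 1, seed = 1)
  off <- p1[5:8, ]
  expect_true(all(off$sire %in% p1$id[1:4]))
  expect_true(all(off$dam %in% p1$id[1:4]))

  a <- simulate_pedigree(10, 3, seed = 7)
  b <- simulate_pedigree(10, 3, seed = 7)
  expect_identical(a, b)
  ## parents precede offspring everywhere
  idx <- match(a$id, a$id)
  si <- match(a$sire, a$id)
  expect_true(all(is.na(si) | si < idx))
  expect_error(simulate_pedigree(1, 2), "founders")
})

test_that("genotype simulation honours LD, MAF range and dosage bounds", {
  cfg0 <- sim_config(n_animals = 500, n_snps = 400, n_chr = 1, ld_rho = 0,
                     seed = 2)
  g0 <- simulate_genotypes(cfg0)
  expect_true(all(g0$G$dosage %in% c(0, 1, 2)))
  d <- g0$G$dosage
  r_adj <- sapply(2:ncol(d), function(j) suppressWarnings(cor(d[, j - 1], d[, j])))
  expect_lt(mean(abs(r_adj), na.rm = TRUE), 0.1)

  cfg9 <- sim_config(n_animals = 500, n_snps = 400, n_chr = 1, ld_rho = 0.9,
                     seed = 2)
  g9 <- simulate_genotypes(cfg9)
  d9 <- g9$G$dosage
  r9 <- sapply(2:ncol(d9), function(j) suppressWarnings(cor(d9[, j - 1], d9[, j])))
  expect_lt(abs(mean(r9, na.rm = TRUE) - 0.9), 0.15)

  ## empirical frequencies inside the configured range (+ sampling slack)
  p_emp <- colMeans(d9) / 2
  expect_true(all(p_emp > 0.05 - 0.06 & p_emp < 0.5 + 0.06))

  expect_identical(simulate_genotypes(cfg9)$G$dosage, d9)
})

test_that("expression simulation calibrates the cis variance fraction", {
  cfg <- sim_config(n_animals = 500, n_snps = 300, n_genes = 10, n_chr = 1,
                    chr_len_bp = 2e7, h2_cis = 0.5, p_causal_cis = 0.1,
                    seed = 3)
  gen <- simulate_genotypes(cfg)
  ex <- simulate_expression(gen$G, cfg)
  ratios <- vapply(seq_len(nrow(ex$genes)), function(g) {
    tr <- ex$truth[[g]]
    gv <- gen$G$dosage[, tr$snp_id, drop = FALSE] %*% tr$effect
    var(as.vector(gv)) / var(ex$E[g, ])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.1)

  ## null architecture: regression R2 of expression on causal dosages ~ 0
  cfg0 <- sim_config(n_animals = 500, n_snps = 300, n_genes = 5, n_chr = 1,
                     chr_len_bp = 2e7, h2_cis = 0, seed = 4)
  ex0 <- simulate_expression(gen$G, cfg0)
  expect_true(all(vapply(ex0$truth, function(t) all(t$effect == 0), logical(1))))

  ex_rep <- simulate_expression(gen$G, cfg)
  expect_identical(ex_rep$E, ex$E)
})

test_that("test-day generator reproduces the degenerate and null cases", {
  ped <- simulate_pedigree(6, 1, seed = 1)
  vc0 <- variance_components(K_a = diag(4) * 0 + diag(4) * 1e-12,
                             K_p = diag(4) * 1e-12, sigma_e2 = 1e-12)
  cfg <- sim_config(n_animals = 6, n_parities = 1, varcomps = vc0, seed = 1)
  td <- simulate_testday(ped, cfg, b_fixed = rep(0, 4), sd_htd = 0, sd_ys = 0,
                         sd_mc = 0, mu = 3.5)
  expect_equal(td$records$value, rep(3.5, nrow(td$records)), tolerance = 1e-4)
  ## every animal x parity has >= 5 records
  tab <- table(td$records$animal_id, td$records$parity)
  expect_true(all(tab >= 5))
})

test_that("parent-offspring phenotypic resemblance is positive with nonzero K_a", {
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    ped <- simulate_pedigree(40, 4, seed = 100 + r)   # 200 animals
    cfg <- sim_config(n_animals = 120, seed = 100 + r)
    td <- simulate_testday(ped, cfg)
    tbv <- td$truth$true_breeding_values
    ## mean daily deviation per phenotyped animal after removing the grand curve
    dev <- tapply(td$records$value, td$records$animal_id, mean)
    kid <- ped$id[!is.na(ped$sire) & ped$sire %in% names(dev) &
                    ped$id %in% names(dev)]
    if (length(kid) < 10) next
    cc <- cov(dev[kid], dev[ped$sire[match(kid, ped$id)]])
    if (cc > 0) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.8 * n_rep))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_config(h2_cis = 1.2), "fraction")
  expect_error(sim_config(dim_grid = c(4, 10)), "dim_grid")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
})
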