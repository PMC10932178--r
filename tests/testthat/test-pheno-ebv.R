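test_that("Legendre basis matches closed-form endpoint values and is orthonormal", {
  expect_equal(unname(legendre_basis(5)),
               c(0.70711, -1.22474, 1.58114, -1.87083), tolerance = 1e-5)
  expect_equal(unname(legendre_basis(300)),
               c(0.70711, 1.22474, 1.58114, 1.87083), tolerance = 1e-5)
  ## interior point: phi1 = sqrt(3/2) w
  w153 <- -1 + 2 * (153 - 5) / 295
  expect_equal(unname(legendre_basis(153))[2], sqrt(1.5) * w153, tolerance = 1e-12)
  expect_error(legendre_basis(152.5), "integer")
  expect_error(legendre_basis(301), "outside")

  ## int phi_m phi_n over [-1,1] = delta_mn on a fine grid
  grid <- seq(-1, 1, length.out = 200001)
  P <- cbind(1, grid, (3 * grid^2 - 1) / 2, (5 * grid^3 - 3 * grid) / 2)
  phi <- sweep(P, 2, sqrt((2 * (0:3) + 1) / 2), `*`)
  wts <- c(0.5, rep(1, length(grid) - 2), 0.5) * (grid[2] - grid[1])
  Gram <- crossprod(phi, wts * phi)
  expect_equal(Gram, diag(4), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fixed-factor screening keeps real effects and calibrates type I error", {
  ## strong HTD effect (3 residual SDs) is retained
  withr::with_seed(11, {
    n <- 500
    htd <- sample(c("h1", "h2"), n, replace = TRUE)
    noise <- factor(sample(letters[1:4], n, replace = TRUE))
    rec <- data.frame(value = 3 * (htd == "h2") + rnorm(n), htd = htd,
                      noise = noise)
    expect_true("htd" %in% screen_fixed_factors(rec, c("htd", "noise")))
  })
  ## pure-noise factor retained at ~ alpha rate
  hits <- vapply(1:50, function(r) withr::with_seed(1000 + r, {
    rec <- data.frame(value = rnorm(200),
                      nf = sample(letters[1:5], 200, replace = TRUE))
    "nf" %in% screen_fixed_factors(rec, "nf")
  }), logical(1))
  expect_lte(sum(hits), 5 + 4)   # binomial(50, .05) + ~3 SD slack
  expect_identical(screen_fixed_factors(data.frame(value = 1:5), character(0)),
                   character(0))
  expect_warning(
    screen_fixed_factors(data.frame(value = rnorm(10), solo = "x"), "solo"),
    "single-level")
})

test_that("numerator relationship matrix follows the tabular method", {
  founders <- data.frame(id = c("a", "b", "c"), sire = NA, dam = NA)
  expect_equal(build_numerator_relationship(founders),
               diag(3), ignore_attr = TRUE)
  po <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
                   dam = c(NA, NA, "d"))
  A <- build_numerator_relationship(po)
  expect_equal(A["s", "o"], 0.5)
  ## offspring of full sibs: F = 0.25, diagonal 1.25
  fs <- data.frame(id = c("f1", "f2", "s1", "s2", "o"),
                   sire = c(NA, NA, "f1", "f1", "s1"),
                   dam = c(NA, NA, "f2", "f2", "s2"))
  A2 <- build_numerator_relationship(fs)
  expect_equal(A2["o", "o"], 1.25)
  expect_true(isSymmetric(A2))
  expect_gte(min(eigen(A2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_true(all(diag(A2) >= 1))
  bad <- data.frame(id = c("x", "y"), sire = c("y", NA), dam = NA)
  expect_error(build_numerator_relationship(bad), "topologically")
})

test_that("MME solutions equal the dense GLS oracle on small instances", {
  vc <- variance_components()
  for (seed in 1:4) {
    withr::with_seed(seed, {
      nf <- sample(3:5, 1)
      ped <- simulate_pedigree(nf, 1, seed = seed)      # <= 10 animals
      q <- nrow(ped)
      nrec <- 3 * q
      rec <- data.frame(animal_id = sample(ped$id, nrec, replace = TRUE),
                        parity = 1,
                        dim = sample(seq(5, 300, by = 7), nrec, replace = TRUE),
                        value = rnorm(nrec, 10),
                        grp = sample(c("g1", "g2"), nrec, replace = TRUE))
      sol <- fit_rr_testday_model(rec, ped, vc, "grp")
      A <- build_numerator_relationship(ped)
      Phi <- legendre_basis(rec$dim)
      X <- cbind(Phi, grp = as.numeric(rec$grp == "g2"))
      ai <- match(rec$animal_id, ped$id)
      pids <- ped$id[sort(unique(ai))]
      pii <- match(rec$animal_id, pids)
      Z <- matrix(0, nrec, 4 * q); W <- matrix(0, nrec, 4 * length(pids))
      for (r in seq_len(nrec)) {
        Z[r, (ai[r] - 1) * 4 + 1:4] <- Phi[r, ]
        W[r, (pii[r] - 1) * 4 + 1:4] <- Phi[r, ]
      }
      Ga <- kronecker(A, vc$K_a)
      Gp <- kronecker(diag(length(pids)), vc$K_p)
      V <- Z %*% Ga %*% t(Z) + W %*% Gp %*% t(W) + vc$sigma_e2 * diag(nrec)
      Vi <- solve(V)
      b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% rec$value)
      a_gls <- Ga %*% t(Z) %*% Vi %*% (rec$value - X %*% b)
      expect_equal(unname(sol$fixed_solutions), as.vector(b), tolerance = 1e-8)
      expect_equal(as.vector(t(sol$additive_coeffs)), as.vector(a_gls),
                   tolerance = 1e-8)
    })
  }
})

test_that("fixed regressions are recovered in the near-noiseless limit", {
  ped <- data.frame(id = sprintf("x%d", 1:4), sire = NA, dam = NA)
  b_true <- c(10, -2, 1, -0.5)
  dims <- seq(5, 300, by = 5)
  rec <- data.frame(animal_id = rep(ped$id, each = length(dims)), parity = 1,
                    dim = rep(dims, 4),
                    value = rep(as.vector(legendre_basis(dims) %*% b_true), 4))
  vc <- variance_components(K_a = diag(4) * 1e-8, K_p = diag(4) * 1e-8,
                            sigma_e2 = 1e-8)
  sol <- fit_rr_testday_model(rec, ped, vc, character(0))
  expect_equal(unname(sol$fixed_solutions[1:4]), b_true, tolerance = 1e-3)
})

test_that("EBV shift equivariance: adding a constant moves only the intercept", {
  withr::with_seed(21, {
    ped <- simulate_pedigree(5, 1, seed = 21)
    cfg <- sim_config(n_animals = 8, n_parities = 2, seed = 21)
    td <- simulate_testday(ped, cfg)
    vc <- cfg$varcomps
    s1 <- fit_rr_testday_model(td$records, ped, vc, c("ys"))
    rec2 <- td$records
    rec2$value <- rec2$value + 7
    s2 <- fit_rr_testday_model(rec2, ped, vc, c("ys"))
    expect_equal(s1$ebv, s2$ebv, tolerance = 1e-8)
    ## only the constant-term regression shifts (by 7 / phi0)
    expect_equal(unname(s2$fixed_solutions["phi0"] - s1$fixed_solutions["phi0"]),
                 7 / unname(legendre_basis(5)[1]), tolerance = 1e-6)
  })
})

test_that("EBV aggregation follows the mean daily additive value", {
  a <- rbind(c(2, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 0, 0))
  rownames(a) <- c("m1", "m2", "m3")
  ebv <- summarize_ebv(a)
  expect_equal(unname(ebv["m1"]), 0.70711 * 2, tolerance = 1e-4)
  expect_lt(abs(ebv["m2"]), 0.01 * 3)
  expect_identical(unname(ebv["m3"]), 0)
})
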