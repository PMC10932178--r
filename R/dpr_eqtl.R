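## Stage I: per-gene cis-eQTL effect sizes by Dirichlet process regression.
##
## Model for one gene with expression vector E (length n) and cis dosage
## matrix G (n x p, columns centered):
##
##   E = G w + eps,          eps ~ N(0, sigma_eps^2 I)
##   w_l | sigma_l^2 ~ N(0, sigma_l^2)
##   sigma_l^2 ~ H,  H ~ DP(InvGamma(a0, b0), alpha)
##
## i.e. the per-SNP effect-size variances follow an unknown distribution
## with a Dirichlet process prior, so the effect-size distribution adapts
## between sparse and highly polygenic architectures. Inference is
## truncated stick-breaking mean-field variational Bayes over
## (w, component assignments z, sticks v, component precisions tau_k,
## residual precision tau_e); all updates are conjugate coordinate ascent,
## the evidence lower bound (ELBO) is computed each sweep and must not
## decrease. The fit is deterministic given the inputs and hyperparameters
## (no Monte Carlo).

#' DPR hyperparameters
#'
#' @param k_trunc stick-breaking truncation level (>= 1; `k_trunc = 1`
#'   collapses the prior to a single normal component, i.e. ridge
#'   regression).
#' @param dp_alpha DP concentration.
#' @param ig_a0,ig_b0 inverse-gamma base-measure shape/scale (also used for
#'   the residual-variance prior).
#' @param max_iter maximum coordinate-ascent sweeps.
#' @param tol convergence tolerance on the relative ELBO change.
#' @param cv_folds cross-validation folds (default 5).
#' @param cv_seed seed for the CV fold permutation (default 42).
#' @return list of class `dpr_hyperparams`.
#' @export
dpr_hyperparams <- function(k_trunc = 4L, dp_alpha = 1, ig_a0 = 0.1,
                            ig_b0 = 0.1, max_iter = 1000L, tol = 1e-5,
                            cv_folds = 5L, cv_seed = 42L) {
  check_that(k_trunc >= 1, "k_trunc must be >= 1")
  check_that(tol > 0, "tol must be > 0")
  check_that(cv_folds >= 2, "cv_folds must be >= 2")
  structure(list(k_trunc = as.integer(k_trunc), dp_alpha = dp_alpha,
                 ig_a0 = ig_a0, ig_b0 = ig_b0, max_iter = as.integer(max_iter),
                 tol = tol, cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed)),
            class = "dpr_hyperparams")
}

#' Select cis SNPs around a TSS
#'
#' SNPs on the gene's chromosome with `|pos - TSS| <= window` (closed
#' interval on both sides).
#'
#' @param gene_tss TSS position (1-based).
#' @param chromosome chromosome id.
#' @param snps SNP metadata data.frame with `snp_id`, `chr`, `pos`.
#' @param window half-width in bp (default 1 Mb).
#' @return character vector of cis SNP ids (possibly empty), in map order.
#' @export
select_cis_snps <- function(gene_tss, chromosome, snps, window = 1e6) {
  hit <- snps$chr == as.character(chromosome) &
    abs(snps$pos - gene_tss) <= window
  snps$snp_id[hit]
}

#' Fit DPR cis-eQTL weights for one gene
#'
#' Returns the variational posterior mean effect sizes on the per-allele
#' scale: expression is centered and dosages are column-centered but not
#' variance-standardised, so downstream burden statistics can use the
#' reference-panel dosage variances explicitly.
#'
#' @param E_g expression vector (length n, nonzero variance).
#' @param G_cis n x p cis dosage matrix (p >= 1), sample-aligned with `E_g`.
#' @param hp [dpr_hyperparams()].
#' @return list of class `eqtl_weights`: `snp_ids`, `w` (posterior mean),
#'   `sigma_e2_hat` (posterior-mean residual variance), `prior_var`
#'   (per-component posterior-mean effect variances), `train_r2`, `elbo`
#'   (per-sweep trace), `n_iter`, `converged`, plus centering metadata
#'   (`g_center`, `e_center`) used for out-of-sample prediction.
#' @export
fit_dpr_weights <- function(E_g, G_cis, hp = dpr_hyperparams()) {
  G_cis <- as.matrix(G_cis)
  n <- nrow(G_cis); p <- ncol(G_cis)
  check_that(p >= 1, "no cis SNPs")
  check_that(length(E_g) == n, "E_g and G_cis sample counts differ")
  check_that(sd(E_g) > 0, "zero-variance expression")
  e_center <- mean(E_g)
  ## expression is standardised internally (the weakly informative
  ## inverse-gamma base measure then sits on a unit-variance scale) and the
  ## weights are rescaled back, so the fit is exactly scale-equivariant
  e_scale <- sd(E_g)
  y <- (E_g - e_center) / e_scale
  g_center <- colMeans(G_cis)
  G <- sweep(G_cis, 2, g_center)
  K <- hp$k_trunc
  a0 <- hp$ig_a0; b0 <- hp$ig_b0; alpha <- hp$dp_alpha

  GtG <- crossprod(G)
  Gty <- as.vector(crossprod(G, y))
  yty <- sum(y^2)

  ## deterministic initialisation: responsibilities uniform, residual
  ## precision at 1/var(y), component precisions on a geometric grid around
  ## the "variance split evenly over p SNPs" scale
  r <- matrix(1 / K, p, K)
  vary <- yty / n
  E_tau_e <- 1 / vary
  Elog_tau_e <- log(E_tau_e)
  E_tau_k <- (p / vary) * 4^(seq_len(K) - (K + 1) / 2)
  Elog_tau_k <- log(E_tau_k)
  Elog_pi <- rep(-log(K), K)
  elbo_trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  digam <- digamma

  for (it in seq_len(hp$max_iter)) {
    ## q(w) = N(m, S)
    d <- as.vector(r %*% E_tau_k)               # per-SNP prior precision
    S <- solve(E_tau_e * GtG + diag(d, p))
    m <- E_tau_e * as.vector(S %*% Gty)
    Ew2 <- m^2 + diag(S)

    ## q(z)
    lr <- matrix(Elog_pi, p, K, byrow = TRUE) +
      0.5 * matrix(Elog_tau_k, p, K, byrow = TRUE) -
      0.5 * outer(Ew2, E_tau_k)
    lr <- lr - apply(lr, 1, max)
    r <- exp(lr); r <- r / rowSums(r)

    Nk <- colSums(r)
    ## q(tau_k)
    ak <- a0 + 0.5 * Nk
    bk <- b0 + 0.5 * as.vector(crossprod(r, Ew2))
    E_tau_k <- ak / bk
    Elog_tau_k <- digam(ak) - log(bk)

    ## q(v) sticks (component K fixed at v = 1 by truncation)
    if (K > 1) {
      g1 <- 1 + Nk[-K]
      g2 <- alpha + rev(cumsum(rev(Nk)))[-1]   # sum_{j>k} N_j
      Elog_v <- digam(g1) - digam(g1 + g2)
      Elog_1mv <- digam(g2) - digam(g1 + g2)
      Elog_pi <- c(Elog_v, 0) + c(0, cumsum(Elog_1mv))
    }

    ## q(tau_e)
    quad <- yty - 2 * sum(m * Gty) + sum(GtG * (S + tcrossprod(m)))
    ae <- a0 + n / 2
    be <- b0 + 0.5 * quad
    E_tau_e <- ae / be
    Elog_tau_e <- digam(ae) - log(be)

    ## ELBO
    elbo <- dpr_elbo(n, p, K, a0, b0, alpha, yty, quad, m, S, Ew2, r,
                     ak, bk, E_tau_k, Elog_tau_k,
                     if (K > 1) g1 else NULL, if (K > 1) g2 else NULL,
                     Elog_pi, ae, be, E_tau_e, Elog_tau_e)
    if (length(elbo_trace) > 0 &&
        elbo < elbo_old - 1e-6 * (abs(elbo_old) + 1)) {
      stop(sprintf("ELBO decreased at sweep %d (%.8g -> %.8g)", it,
                   elbo_old, elbo))
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_old) &&
        abs(elbo - elbo_old) <= hp$tol * (abs(elbo_old) + 1e-8)) {
      converged <- TRUE
      elbo_old <- elbo
      break
    }
    elbo_old <- elbo
  }

  pred <- as.vector(G %*% m)
  train_r2 <- if (sd(pred) > 0) cor(pred, y)^2 else 0
  m <- m * e_scale                       # back to the input expression scale
  structure(list(snp_ids = colnames(G_cis), w = stats::setNames(m, colnames(G_cis)),
                 sigma_e2_hat = be / ae * e_scale^2,
                 prior_var = bk / ak * e_scale^2,
                 resp = r, train_r2 = train_r2, elbo = elbo_trace,
                 n_iter = length(elbo_trace), converged = converged,
                 g_center = g_center, e_center = e_center, hp = hp),
            class = "eqtl_weights")
}

## ELBO of the mean-field approximation; one value per sweep.
dpr_elbo <- function(n, p, K, a0, b0, alpha, yty, quad, m, S, Ew2, r,
                     ak, bk, E_tau_k, Elog_tau_k, g1, g2, Elog_pi,
                     ae, be, E_tau_e, Elog_tau_e) {
  ld <- determinant(S, logarithm = TRUE)$modulus
  lik <- 0.5 * n * (Elog_tau_e - log(2 * pi)) - 0.5 * E_tau_e * quad
  pw <- sum(r * (0.5 * matrix(Elog_tau_k - log(2 * pi), p, K, byrow = TRUE) -
                   0.5 * outer(Ew2, E_tau_k)))
  pz <- sum(r * matrix(Elog_pi, p, K, byrow = TRUE))
  pv <- if (K > 1) {
    Elog_1mv <- digamma(g2) - digamma(g1 + g2)
    sum(log(alpha) + (alpha - 1) * Elog_1mv)
  } else 0
  ptau <- sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elog_tau_k - b0 * E_tau_k)
  ptaue <- a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elog_tau_e - b0 * E_tau_e
  Hw <- 0.5 * (p * log(2 * pi) + p + as.numeric(ld))
  Hz <- -sum(r[r > 0] * log(r[r > 0]))
  Hv <- if (K > 1) {
    sum(lbeta(g1, g2) - (g1 - 1) * digamma(g1) - (g2 - 1) * digamma(g2) +
          (g1 + g2 - 2) * digamma(g1 + g2))
  } else 0
  Htau <- sum(ak - log(bk) + lgamma(ak) + (1 - ak) * digamma(ak))
  Htaue <- ae - log(be) + lgamma(ae) + (1 - ae) * digamma(ae)
  lik + pw + pz + pv + ptau + ptaue + Hw + Hz + Hv + Htau + Htaue
}

#' Predict expression from fitted weights
#'
#' @param object `eqtl_weights` fit.
#' @param newdata dosage matrix with columns matching the fit's SNPs.
#' @param ... unused.
#' @return numeric prediction vector (on the original expression scale).
#' @export
predict.eqtl_weights <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Gc <- sweep(newdata[, object$snp_ids, drop = FALSE], 2, object$g_center)
  as.vector(Gc %*% object$w) + object$e_center
}

#' 5-fold cross-validated prediction R-squared
#'
#' Folds are contiguous blocks of a permutation seeded by `hp$cv_seed`;
#' per-fold refits produce pooled out-of-fold predictions, and the CV R2 is
#' the squared Pearson correlation of those predictions with the observed
#' expression. Deterministic given inputs and `cv_seed`.
#'
#' @inheritParams fit_dpr_weights
#' @return list: `cv_r2`, `pred` (pooled out-of-fold predictions),
#'   `folds` (fold index per sample).
#' @export
cross_validate <- function(E_g, G_cis, hp = dpr_hyperparams()) {
  G_cis <- as.matrix(G_cis)
  n <- nrow(G_cis)
  check_that(n >= hp$cv_folds, "fewer samples than folds")
  ## contiguous blocks of a seeded permutation
  perm <- with_seed(hp$cv_seed, sample.int(n))
  split_sizes <- diff(round(seq(0, n, length.out = hp$cv_folds + 1)))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(hp$cv_folds), times = split_sizes)
  pred <- numeric(n)
  for (f in seq_len(hp$cv_folds)) {
    test <- folds == f
    fit <- fit_dpr_weights(E_g[!test], G_cis[!test, , drop = FALSE], hp)
    pred[test] <- predict(fit, G_cis[test, , drop = FALSE])
  }
  cv_r2 <- if (sd(pred) > 0) cor(pred, E_g)^2 else 0
  list(cv_r2 = cv_r2, pred = pred, folds = folds)
}

#' Train and cross-validate weights for many genes
#'
#' Convenience driver for the per-gene stage-I loop: cis-SNP selection,
#' DPR fit, and 5-fold CV R2.
#'
#' @param expr genes x samples expression matrix (rownames = gene ids).
#' @param G [geno_matrix()] (post-QC), samples aligned with `expr` columns.
#' @param genes gene annotation data.frame (`gene_id`, `chr`, `tss`).
#' @param hp [dpr_hyperparams()].
#' @param window cis window half-width in bp.
#' @param run_cv compute CV R2 (default TRUE).
#' @return list of per-gene `eqtl_weights` (with `$gene_id` and `$cv_r2`
#'   added); genes without cis SNPs or without expression rows are skipped.
#' @export
train_weights_all <- function(expr, G, genes, hp = dpr_hyperparams(),
                              window = 1e6, run_cv = TRUE) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    if (!gid %in% rownames(expr)) next
    cis <- select_cis_snps(genes$tss[g], genes$chr[g], G$map, window = window)
    if (length(cis) == 0L) next
    Gc <- G$dosage[, cis, drop = FALSE]
    e <- expr[gid, ]
    if (sd(e) == 0) next
    fit <- fit_dpr_weights(e, Gc, hp)
    fit$gene_id <- gid
    fit$cv_r2 <- if (run_cv) cross_validate(e, Gc, hp)$cv_r2 else NA_real_
    out[[gid]] <- fit
  }
  out
}

#' Retain prediction models by cross-validated R-squared
#'
#' @param weights list of `eqtl_weights` (each with `cv_r2`).
#' @param cv_r2_min retention threshold; models are kept iff
#'   `cv_r2 > cv_r2_min` (strict), preserving input order.
#' @return filtered list.
#' @export
retain_models <- function(weights, cv_r2_min = 0.005) {
  keep <- vapply(weights, function(w) isTRUE(w$cv_r2 > cv_r2_min), logical(1))
  weights[keep]
}

#' Weight tables for a list of fitted genes
#'
#' @param weights list of `eqtl_weights` with `gene_id`.
#' @param map SNP metadata (`snp_id`, `chr`, `pos`, `ref`, `alt`).
#' @return list of two data.frames: `weights` (gene_id, snp_id, chr, pos,
#'   ref, alt, weight) and `models` (gene_id, n_snps, train_r2, cv_r2,
#'   cv_seed).
#' @export
weights_table <- function(weights, map) {
  wt <- do.call(rbind, lapply(weights, function(w) {
    i <- match(w$snp_ids, map$snp_id)
    data.frame(gene_id = w$gene_id, snp_id = w$snp_ids, chr = map$chr[i],
               pos = map$pos[i], ref = map$ref[i], alt = map$alt[i],
               weight = unname(w$w), stringsAsFactors = FALSE)
  }))
  md <- do.call(rbind, lapply(weights, function(w) {
    data.frame(gene_id = w$gene_id, n_snps = length(w$w),
               train_r2 = w$train_r2, cv_r2 = w$cv_r2,
               cv_seed = w$hp$cv_seed, stringsAsFactors = FALSE)
  }))
  rownames(wt) <- rownames(md) <- NULL
  list(weights = wt, models = md)
}
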