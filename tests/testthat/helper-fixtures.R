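## Shared fixtures, built in code at test time.

## small random dosage matrix with named columns
rand_dosages <- function(n, p, seed = 1, maf = NULL) {
  withr::with_seed(seed, {
    freq <- maf %||% runif(p, 0.1, 0.5)
    G <- sapply(freq, function(f) rbinom(n, 2, f))
    colnames(G) <- paste0("1_", seq_len(p) * 1000, "_A_G")
    G
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## geno_matrix wrapper around a plain dosage matrix
as_geno <- function(G) {
  ids <- colnames(G)
  parts <- strsplit(ids, "_", fixed = TRUE)
  map <- data.frame(snp_id = ids,
                    chr = vapply(parts, `[`, "", 1),
                    pos = as.integer(vapply(parts, `[`, "", 2)),
                    ref = vapply(parts, `[`, "", 3),
                    alt = vapply(parts, `[`, "", 4),
                    minor = vapply(parts, `[`, "", 4),
                    stringsAsFactors = FALSE)
  rownames(G) <- sprintf("S%03d", seq_len(nrow(G)))
  geno_matrix(G, map)
}

## planted cis architecture: returns y (expression), G (dosages), w (truth)
planted_gene <- function(n, p, h2, k_causal = max(1, round(0.1 * p)), seed = 1) {
  withr::with_seed(seed, {
    G <- rand_dosages(n, p, seed = seed + 1)
    w <- rep(0, p)
    w[sample(p, k_causal)] <- rnorm(k_causal)
    gv <- as.vector(G %*% w)
    if (h2 > 0 && sd(gv) > 0) {
      sc <- sqrt(h2) / sd(gv)
      w <- w * sc
      gv <- gv * sc
    } else {
      w[] <- 0
      gv[] <- 0
    }
    y <- gv + rnorm(n, sd = sqrt(max(1 - h2, 1e-8)))
    list(y = y, G = G, w = w)
  })
}

## independent enumeration oracle for the exact HWE test: log-factorial
## probabilities, two-sided by summing configurations no more likely than
## the observed one
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- 2 * min(n_AA, n_aa) + n_Aa
  if (nr == 0 || nr == 2 * n) return(1)
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
      lfactorial(hom_c) + lfactorial(nr) + lfactorial(2 * n - nr) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}
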