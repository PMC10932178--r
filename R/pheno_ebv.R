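## Random-regression test-day model.
##
## Test-day records y are modelled as fixed class effects (herd-test-date,
## calving year-season, month of calving), fixed Legendre regressions on
## days in milk (DIM), random additive-genetic and permanent-environment
## Legendre regressions, and an i.i.d. residual:
##
##   y = HTD + YS + MC + sum_n b_n phi_n(w) + sum_n a_mn phi_n(w)
##       + sum_n p_mn phi_n(w) + e
##
## with third-order (4-term) normalised Legendre polynomials phi_n of the
## standardised DIM w in [-1, 1]. Additive coefficient vectors a_m have
## covariance A (x) K_a across animals (A = pedigree numerator relationship
## matrix), permanent-environment vectors p_m have I (x) K_p, residual
## variance sigma_e^2. Solved by Henderson's mixed-model equations; the
## scalar EBV per animal is the mean daily additive genetic value over DIM
## 5..300.

#' Normalised Legendre polynomial basis on the DIM scale
#'
#' Days in milk are standardised to `w = -1 + 2 (DIM - 5) / (300 - 5)` and
#' the basis is the Kirkpatrick-normalised Legendre polynomials
#' `phi_n(w) = sqrt((2n + 1) / 2) P_n(w)` for `n = 0..order`.
#'
#' @param dim integer day(s) in milk within `dim_range`.
#' @param order highest polynomial order (default 3).
#' @param dim_range lower/upper DIM bounds (default `c(5, 300)`).
#' @return for a single day, a numeric vector of length `order + 1`;
#'   otherwise a `length(dim) x (order + 1)` matrix.
#' @export
legendre_basis <- function(dim, order = 3L, dim_range = c(5L, 300L)) {
  check_that(all(dim == round(dim)), "DIM must be integer-valued days")
  check_that(all(dim >= dim_range[1] & dim <= dim_range[2]),
             "DIM outside [", dim_range[1], ", ", dim_range[2], "]")
  w <- -1 + 2 * (dim - dim_range[1]) / (dim_range[2] - dim_range[1])
  P <- matrix(0, length(w), order + 1L)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- w
  if (order >= 2) for (n in 1:(order - 1L)) {
    ## Bonnet recursion (n+1) P_{n+1} = (2n+1) w P_n - n P_{n-1}
    P[, n + 2L] <- ((2 * n + 1) * w * P[, n + 1L] - n * P[, n]) / (n + 1)
  }
  phi <- sweep(P, 2, sqrt((2 * (0:order) + 1) / 2), `*`)
  colnames(phi) <- paste0("phi", 0:order)
  if (length(dim) == 1L) phi[1, ] else phi
}

#' Screen candidate fixed factors with partial F-tests
#'
#' Fits one ordinary linear model of the trait on all candidate class
#' factors jointly and retains factors whose partial (drop-one) F-test has
#' p < `alpha`. Factors with a single observed level are excluded with a
#' warning rather than an error.
#'
#' @param records test-day record data.frame; must contain `value` and the
#'   candidate factor columns.
#' @param candidate_factors character vector of column names to screen.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained factor names (possibly empty).
#' @export
screen_fixed_factors <- function(records, candidate_factors, alpha = 0.05) {
  if (length(candidate_factors) == 0L) return(character(0))
  check_that(all(candidate_factors %in% names(records)),
             "candidate factor(s) not in records")
  nlev <- vapply(candidate_factors,
                 function(f) length(unique(records[[f]])), integer(1))
  if (any(nlev < 2L)) {
    warning("single-level factor(s) excluded from screening: ",
            paste(candidate_factors[nlev < 2L], collapse = ", "))
    candidate_factors <- candidate_factors[nlev >= 2L]
  }
  if (length(candidate_factors) == 0L) return(character(0))
  dat <- records[, c("value", candidate_factors), drop = FALSE]
  for (f in candidate_factors) dat[[f]] <- factor(dat[[f]])
  fml <- stats::reformulate(candidate_factors, response = "value")
  fit <- stats::lm(fml, data = dat)
  dr <- stats::drop1(fit, test = "F")
  pv <- dr[["Pr(>F)"]][match(candidate_factors, rownames(dr))]
  candidate_factors[!is.na(pv) & pv < alpha]
}

#' Pedigree numerator relationship matrix (Henderson tabular method)
#'
#' @param ped data.frame `(id, sire, dam)` with parents preceding offspring;
#'   unknown parents are `NA`. A parent id absent from `id`, an offspring
#'   preceding its parent, or a duplicate id is a structural error.
#' @return symmetric matrix `A` with `A_ii = 1 + F_i` (F = inbreeding
#'   coefficient), dimnames = animal ids.
#' @export
build_numerator_relationship <- function(ped) {
  id <- as.character(ped$id)
  check_that(!anyDuplicated(id), "duplicate animal ids in pedigree")
  q <- length(id)
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  bad_s <- !is.na(ped$sire) & is.na(si)
  bad_d <- !is.na(ped$dam) & is.na(di)
  check_that(!any(bad_s | bad_d), "pedigree parent id not present as an animal id")
  check_that(all(is.na(si) | si < seq_len(q)) && all(is.na(di) | di < seq_len(q)),
             "pedigree not topologically ordered (parent after offspring, or a cycle)")
  A <- matrix(0, q, q, dimnames = list(id, id))
  for (i in seq_len(q)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else rep(0, i - 1L)
      ad_ <- if (!is.na(d)) A[j, d] else rep(0, i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
  }
  A
}

#' Fit the random-regression test-day model by Henderson's MME
#'
#' Assembles and solves the mixed-model equations with the fixed design
#' (retained class factors, first level of each constrained to zero, plus
#' the four fixed Legendre regressions) and random additive and
#' permanent-environment regression coefficient blocks with covariances
#' `A (x) K_a` and `I (x) K_p`. Additive coefficients are carried for every
#' pedigree member, including non-phenotyped ancestors.
#'
#' @param records data.frame `(animal_id, parity, dim, value, <factors>)`.
#' @param ped pedigree data.frame `(id, sire, dam)`.
#' @param vc [variance_components()].
#' @param retained_factors character vector of class-factor columns to fit
#'   (typically from [screen_fixed_factors()]).
#' @return list of class `rr_solution`: `fixed_solutions` (named vector;
#'   `phi0..phi3` are the fixed regressions, `<factor>.<level>` the class
#'   effects with the first level of each factor fixed at 0),
#'   `additive_coeffs` (pedigree animals x 4), `pe_coeffs` (phenotyped
#'   animals x 4), `ebv` (named per-animal scalar, all pedigree members),
#'   plus the inputs' bookkeeping.
#' @export
fit_rr_testday_model <- function(records, ped, vc, retained_factors = character(0)) {
  check_that(inherits(vc, "variance_components"), "vc must be variance_components()")
  ids <- as.character(ped$id)
  ai <- match(as.character(records$animal_id), ids)
  check_that(!anyNA(ai), "record animal absent from pedigree")
  n <- nrow(records)
  q <- length(ids)
  pheno_ids <- ids[sort(unique(ai))]
  np <- length(pheno_ids)
  Phi <- legendre_basis(records$dim)
  if (is.null(dim(Phi))) Phi <- matrix(Phi, nrow = 1)

  ## fixed design: Legendre regressions + treatment-coded class factors
  X <- Phi
  colnames(X) <- paste0("phi", 0:3)
  for (f in retained_factors) {
    lev <- sort(unique(as.character(records[[f]])))
    if (length(lev) < 2L) next
    Ff <- outer(as.character(records[[f]]), lev[-1], `==`) * 1
    colnames(Ff) <- paste0(f, ".", lev[-1])
    X <- cbind(X, Ff)
  }

  ## random incidence: 4 columns per animal (additive over pedigree, pe over
  ## phenotyped animals), animal-major ordering
  ridx <- seq_len(n)
  coef_cols <- function(a) as.vector(rbind((a - 1L) * 4L + 1L, (a - 1L) * 4L + 2L,
                                           (a - 1L) * 4L + 3L, (a - 1L) * 4L + 4L))
  Z <- Matrix::sparseMatrix(i = rep(ridx, each = 4L), j = coef_cols(ai),
                            x = as.vector(t(Phi)), dims = c(n, 4L * q))
  pi_ <- match(as.character(records$animal_id), pheno_ids)
  W <- Matrix::sparseMatrix(i = rep(ridx, each = 4L), j = coef_cols(pi_),
                            x = as.vector(t(Phi)), dims = c(n, 4L * np))

  A <- build_numerator_relationship(ped)
  Ainv <- solve(A)
  Kainv <- solve(vc$K_a)
  Kpinv <- solve(vc$K_p)
  s2 <- vc$sigma_e2

  y <- records$value
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(Z, X))
  XtZ <- t(XtZ)
  XtW <- t(as.matrix(Matrix::crossprod(W, X)))
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  ZtW <- as.matrix(Matrix::crossprod(Z, W))
  WtW <- as.matrix(Matrix::crossprod(W))
  Ga <- kronecker(Ainv, Kainv) * s2
  Gp <- kronecker(diag(np), Kpinv) * s2
  C <- rbind(
    cbind(XtX, XtZ, XtW),
    cbind(t(XtZ), ZtZ + Ga, ZtW),
    cbind(t(XtW), t(ZtW), WtW + Gp))
  rhs <- c(crossprod(X, y), as.vector(Matrix::crossprod(Z, y)),
           as.vector(Matrix::crossprod(W, y)))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations singular; check fixed-effect identifiability: ",
         conditionMessage(e), call. = FALSE))

  nf <- ncol(X)
  fixed <- stats::setNames(sol[seq_len(nf)], colnames(X))
  a_hat <- matrix(sol[nf + seq_len(4L * q)], nrow = q, byrow = TRUE,
                  dimnames = list(ids, paste0("phi", 0:3)))
  p_hat <- matrix(sol[nf + 4L * q + seq_len(4L * np)], nrow = np, byrow = TRUE,
                  dimnames = list(pheno_ids, paste0("phi", 0:3)))
  out <- list(fixed_solutions = fixed, additive_coeffs = a_hat,
              pe_coeffs = p_hat, retained_factors = retained_factors,
              vc = vc, n_records = n)
  out$ebv <- summarize_ebv(out)
  class(out) <- "rr_solution"
  out
}

#' @export
print.rr_solution <- function(x, ...) {
  cat(sprintf("rr_solution: %d records, %d pedigree animals, %d fixed effects\n",
              x$n_records, nrow(x$additive_coeffs), length(x$fixed_solutions)))
  invisible(x)
}

#' Collapse breeding-value curves to one EBV per animal
#'
#' The scalar EBV is the mean daily additive genetic value over the full
#' lactation window: `EBV_m = mean_{t in 5..300} sum_n a_mn phi_n(w_t)`
#' (equivalently the 296-day additive total divided by 296).
#'
#' @param sol `rr_solution` from [fit_rr_testday_model()], or a matrix of
#'   additive coefficients (animals x 4).
#' @param dim_range DIM window (default `c(5, 300)`).
#' @return named numeric vector of per-animal EBVs.
#' @export
summarize_ebv <- function(sol, dim_range = c(5L, 300L)) {
  a <- if (is.matrix(sol)) sol else sol$additive_coeffs
  phibar <- colMeans(legendre_basis(seq(dim_range[1], dim_range[2]),
                                    dim_range = dim_range))
  stats::setNames(as.vector(a %*% phibar), rownames(a))
}
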