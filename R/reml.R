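# Restricted maximum likelihood for the single-random-effect model
#   y = X b + g + e,  g ~ N(0, sa2 K),  e ~ N(0, se2 I)
# profiled over the total variance and optimized in one dimension over
# the ratio lambda = sa2 / se2, after rotating by the eigenvectors of K.

# Core REML criterion on eigen-rotated data. d: eigenvalues of K,
# yr = U'y, xr = U'X.
reml_neg_loglik <- function(log_lambda, d, yr, xr) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  xv <- xr / v
  xtvx <- crossprod(xr, xv)
  beta <- solve(xtvx, crossprod(xv, yr))
  r <- yr - xr %*% beta
  n <- length(yr); p <- ncol(xr)
  quad <- sum(r^2 / v)
  s2 <- quad / (n - p)
  0.5 * ((n - p) * log(s2) + sum(log(v)) +
           determinant(xtvx, logarithm = TRUE)$modulus + (n - p))
}

fit_reml_ratio <- function(d, yr, xr, interval = c(-12, 12)) {
  opt <- stats::optimize(reml_neg_loglik, interval = interval,
                         d = d, yr = yr, xr = xr, tol = 1e-8)
  lambda <- exp(opt$minimum)
  v <- lambda * d + 1
  xv <- xr / v
  xtvx <- crossprod(xr, xv)
  beta <- solve(xtvx, crossprod(xv, yr))
  r <- yr - xr %*% beta
  n <- length(yr); p <- ncol(xr)
  se2 <- sum(r^2 / v) / (n - p)
  at_boundary <- opt$minimum <= interval[1] + 1e-6 ||
    opt$minimum >= interval[2] - 1e-6
  list(lambda = lambda, sigma_a2 = lambda * se2, sigma_e2 = se2,
       loglik = -opt$objective, beta = drop(beta),
       at_boundary = at_boundary)
}

#' GRM-REML variance components and heritability
#'
#' Fits `y = Xb + g + e` with `g ~ N(0, sigma_a^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by REML: eigendecomposition of the
#' relationship matrix `K` followed by one-dimensional optimization over
#' the variance ratio. Narrow-sense heritability is
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`.
#'
#' The kinship is trace-normalized (scaled to mean diagonal 1) before
#' fitting, so `sigma_a^2` is the additive variance of an average
#' individual and `h2` is on the phenotypic-variance scale even for
#' inbred panels, whose raw standardized GRMs have mean diagonal near
#' `1 + F`. For outbred panels the normalization is a near no-op.
#'
#' A warning is issued for degenerate kinship (near-duplicate samples
#' inflate the estimate toward 1).
#'
#' @param relmat a [relationship_matrix()] (positive semi-definite).
#' @param trait numeric response, one value per sample.
#' @param covariates optional numeric matrix/data frame of fixed-effect
#'   covariates (intercept added automatically).
#' @return A list of class `variance_components`: `sigma_a2`, `sigma_e2`,
#'   `h2`, `loglik`, `converged` (FALSE when the ratio hit the search
#'   boundary), `n`.
#' @export
heritability <- function(relmat, trait, covariates = NULL) {
  k <- unclass(relmat)
  stopifnot(nrow(k) == length(trait))
  k <- k * nrow(k) / sum(diag(k))
  x <- cbind(`(Intercept)` = rep(1, length(trait)),
             if (!is.null(covariates)) as.matrix(covariates))
  offdiag <- k[upper.tri(k)]
  if (any(offdiag > 0.95 * max(diag(k)))) {
    warning("degenerate kinship: near-duplicate samples present; ",
            "heritability will be biased upward")
  }
  eig <- eigen(k, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yr <- crossprod(eig$vectors, trait)
  xr <- crossprod(eig$vectors, x)
  fit <- fit_reml_ratio(d, yr, xr)
  structure(
    list(sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
         h2 = fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2),
         loglik = fit$loglik, converged = !fit$at_boundary,
         n = length(trait)),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> h2 = %.3f (sigma_a2 = %.3g, sigma_e2 = %.3g)%s\n",
    x$h2, x$sigma_a2, x$sigma_e2,
    if (x$converged) "" else " [boundary]"))
  invisible(x)
}

# REML log-likelihood for a low-rank kinship K = Z Z' / q built from q
# marker dosage columns (used by the iterative scan's model-selection
# step). Only the q nonzero eigenvalues are materialized.
reml_loglik_lowrank <- function(y, x, z) {
  n <- length(y)
  if (is.null(z) || ncol(z) == 0) {
    # sigma_a2 = 0: ordinary least squares restricted likelihood
    qr_x <- qr(x)
    r <- stats::lm.fit(x, y)$residuals
    s2 <- sum(r^2) / (n - ncol(x))
    xtx <- crossprod(x)
    return(-0.5 * ((n - ncol(x)) * log(s2) +
                     determinant(xtx, logarithm = TRUE)$modulus +
                     (n - ncol(x))))
  }
  zs <- scale(z)
  zs[is.nan(zs)] <- 0
  zs <- zs / sqrt(ncol(zs))
  sv <- svd(zs, nu = ncol(zs), nv = 0)
  q <- length(sv$d)
  u <- sv$u
  d_nz <- sv$d^2
  # rotate into span(U) and its complement
  yu <- crossprod(u, y)
  xu <- crossprod(u, x)
  y_perp2 <- sum(y^2) - sum(yu^2)
  # For the orthogonal complement, V = I, so residual algebra splits.
  neg <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- lambda * d_nz + 1
    # X'V^-1X = X'X - Xu'(1 - 1/v)Xu ; likewise for X'V^-1y and y'V^-1y
    w <- 1 - 1 / v
    xtvx <- crossprod(x) - crossprod(xu, xu * w)
    xtvy <- crossprod(x, y) - crossprod(xu, yu * w)
    ytvy <- sum(y^2) - sum(yu^2 * w)
    beta <- solve(xtvx, xtvy)
    quad <- ytvy - crossprod(xtvy, beta)
    p <- ncol(x)
    s2 <- drop(quad) / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(v)) +
             determinant(xtvx, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(neg, c(-12, 12), tol = 1e-7)
  -opt$objective
}
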