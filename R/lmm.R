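#' Precompute the spectral decomposition of a kinship matrix
#'
#' All likelihood evaluations run on the rotated basis U'z where
#' K = U diag(lambda) U', so repeated evaluations at new variance ratios or
#' transformed phenotypes cost O(N^2) instead of O(N^3).
#'
#' @param K symmetric positive semi-definite kinship matrix (or an object
#'   already produced by this function, returned unchanged).
#' @return An object of class \code{lmm_kernel} with elements \code{U},
#'   \code{lambda} and \code{n}.
#' @export
lmm_kernel <- function(K) {
  if (inherits(K, "lmm_kernel")) return(K)
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop("kinship matrix must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -1e-8 * max(abs(lam), 1))
    stop(sprintf("kinship matrix is not positive semi-definite (smallest eigenvalue %.3e)",
                 min(lam)))
  lam[lam < 0] <- 0
  structure(list(U = e$vectors, lambda = lam, n = nrow(K)),
            class = "lmm_kernel")
}

# Profiled Gaussian likelihood on the rotated basis.
#
# Covariance is sigma_e^2 * V with V = delta_g*diag(lambda) + I plus
# optional rank-one terms delta_j * gt_j gt_j' (rotated selected SNPs,
# columns of Gt), handled by a Woodbury low-rank update. beta is profiled
# by GLS and sigma_e^2 in closed form (ML: q/N, REML: q/(N-C)).
#
# Returns the pieces needed both for the objective and for analytic
# gradients downstream.
.lmm_profile <- function(zt, Xt, lambda, delta_g, Gt = NULL,
                         delta_x = NULL, reml = FALSE) {
  n <- length(zt)
  C <- ncol(Xt)
  D <- delta_g * lambda + 1
  m <- if (is.null(Gt)) 0L else ncol(Gt)
  if (m > 0L) {
    W <- Gt / D
    M <- diag(1 / delta_x, m) + crossprod(Gt, W)
    Mchol <- chol(M)
    Minv <- chol2inv(Mchol)
    logdetV <- sum(log(D)) + 2 * sum(log(diag(Mchol))) + sum(log(delta_x))
    vsolve <- function(v) v / D - W %*% (Minv %*% crossprod(W, v))
  } else {
    W <- NULL; Minv <- NULL
    logdetV <- sum(log(D))
    vsolve <- function(v) v / D
  }
  VX <- vsolve(Xt)
  XtVX <- crossprod(Xt, VX)
  XtVz <- crossprod(VX, zt)
  beta <- solve(XtVX, XtVz)
  r <- zt - Xt %*% beta
  u <- vsolve(r)
  q <- drop(crossprod(r, u))
  if (reml) {
    df <- n - C
    sigma2 <- q / df
    nll <- 0.5 * (df * log(2 * pi) + logdetV +
                    determinant(XtVX, logarithm = TRUE)$modulus +
                    df * log(sigma2) + df)
  } else {
    sigma2 <- q / n
    nll <- 0.5 * (n * log(2 * pi) + logdetV + n * log(sigma2) + n)
  }
  list(nll = as.numeric(nll), beta = drop(beta), sigma2 = sigma2,
       r = drop(r), u = drop(u), q = q, D = D, W = W, Minv = Minv,
       logdetV = logdetV, vsolve = vsolve)
}

#' Negative log likelihood of a linear mixed model
#'
#' Evaluates -log N(z | X beta, sigma_g^2 K + sum_j sigma_j^2 g_j g_j' +
#' sigma_e^2 I) at the supplied parameter values, through the spectral
#' decomposition of K plus a low-rank update for the extra components.
#'
#' @param z numeric phenotype vector on the latent (Gaussian) scale.
#' @param X design matrix (with intercept).
#' @param K kinship matrix or \code{\link{lmm_kernel}}.
#' @param extra_components list of rank-one genetic components, each a list
#'   with elements \code{g} (standardized SNP vector) and \code{sigma2}.
#' @param beta fixed-effect vector.
#' @param sigma_g2 polygenic variance (>= 0).
#' @param sigma_e2 residual variance (> 0).
#' @return The scalar negative log likelihood.
#' @export
lmm_nll <- function(z, X, K, extra_components = list(), beta,
                    sigma_g2, sigma_e2) {
  kern <- lmm_kernel(K)
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  if (sigma_g2 < 0) stop("sigma_g2 must be >= 0")
  n <- kern$n
  stopifnot(length(z) == n, nrow(X) == n)
  zt <- crossprod(kern$U, z)
  Xt <- crossprod(kern$U, X)
  extras <- Filter(function(e) e$sigma2 > 0, extra_components)
  m <- length(extras)
  Gt <- if (m) crossprod(kern$U, do.call(cbind, lapply(extras, `[[`, "g")))
        else NULL
  delta_x <- if (m) vapply(extras, `[[`, numeric(1), "sigma2") / sigma_e2
             else NULL
  D <- (sigma_g2 / sigma_e2) * kern$lambda + 1
  r <- drop(zt - Xt %*% beta)
  if (m) {
    W <- Gt / D
    M <- diag(1 / delta_x, m) + crossprod(Gt, W)
    Mchol <- chol(M)
    logdetV <- sum(log(D)) + 2 * sum(log(diag(Mchol))) + sum(log(delta_x))
    u <- r / D - drop(W %*% (chol2inv(Mchol) %*% crossprod(W, r)))
  } else {
    logdetV <- sum(log(D))
    u <- r / D
  }
  q <- sum(r * u)
  smallest <- sigma_e2 * min(D)
  if (!is.finite(logdetV) || smallest <= 0)
    stop(sprintf("indefinite covariance (smallest eigenvalue %.3e)", smallest))
  0.5 * (n * log(2 * pi) + n * log(sigma_e2) + logdetV + q / sigma_e2)
}

#' Variance-component fit of a standard LMM
#'
#' Profiles the variance ratio delta = sigma_g^2/sigma_e^2 of the model
#' z ~ N(X beta, sigma_g^2 K + sigma_e^2 I) on the rotated basis, by REML
#' (default) or ML, with a one-dimensional search over log delta. The
#' boundary delta -> 0 is checked explicitly; a boundary fit reports
#' heritability 0 with a warning.
#'
#' @param z phenotype vector (latent scale).
#' @param X design matrix.
#' @param K kinship matrix or \code{\link{lmm_kernel}}.
#' @param reml use REML (TRUE) or ML (FALSE).
#' @param interval search interval for log delta.
#' @return List with \code{h2}, \code{sigma_g2}, \code{sigma_e2},
#'   \code{delta}, \code{beta}, \code{nll}, \code{boundary}.
#' @export
fit_lmm <- function(z, X, K, reml = TRUE, interval = c(-20, 15)) {
  kern <- lmm_kernel(K)
  zt <- crossprod(kern$U, z)
  Xt <- crossprod(kern$U, X)
  obj <- function(ld)
    .lmm_profile(zt, Xt, kern$lambda, exp(ld), reml = reml)$nll
  # coarse grid first: the profiled ML criterion can decay slowly towards
  # the delta -> Inf boundary when the null space of K lies inside the
  # column span of X (centered genotypes plus an intercept), so a blind
  # one-dimensional search may skip an interior optimum
  grid <- seq(interval[1], interval[2], length.out = 36)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  if (i == length(grid)) {
    # the ML criterion's slow decay towards delta -> Inf (see above) can
    # undercut a statistically meaningful interior optimum; prefer the
    # deepest interior local minimum when one exists
    interior <- which(diff(sign(diff(vals))) > 0) + 1L
    if (length(interior)) i <- interior[which.min(vals[interior])]
  }
  if (i > 1L && i < length(grid)) {
    opt <- stats::optimize(obj, interval = c(grid[i - 1], grid[i + 1]),
                           tol = 1e-7)
  } else {
    opt <- list(minimum = grid[i], objective = vals[i])
  }
  nll0 <- .lmm_profile(zt, Xt, kern$lambda, 0, reml = reml)$nll
  boundary <- FALSE
  if (nll0 <= opt$objective + 1e-9 || opt$minimum <= interval[1] + 1e-3) {
    delta <- 0
    boundary <- TRUE
  } else {
    delta <- exp(opt$minimum)
    boundary <- opt$minimum >= interval[2] - 1e-3
  }
  prof <- .lmm_profile(zt, Xt, kern$lambda, delta, reml = reml)
  if (boundary)
    warning("variance-ratio estimate at the search boundary (h2 = ",
            ifelse(delta == 0, "0", "~1"), ")")
  list(h2 = delta / (1 + delta), sigma_g2 = delta * prof$sigma2,
       sigma_e2 = prof$sigma2, delta = delta, beta = prof$beta,
       nll = prof$nll, boundary = boundary)
}
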