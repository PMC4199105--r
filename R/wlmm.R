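#' Extended negative log likelihood of the warped LMM
#'
#' The likelihood of the observed phenotype y under the model in which
#' z = f(y) is Gaussian with covariance sigma_g^2 K + sum_j sigma_j^2
#' g_j g_j' + sigma_e^2 I: the latent-scale LMM negative log likelihood
#' minus the log-Jacobian sum(log f'(y_n)). This is the quantity the
#' fitter minimizes; the Jacobian term penalizes transformations that
#' achieve Gaussianity by flattening the data.
#'
#' @param y observed phenotype vector.
#' @param X design matrix.
#' @param K kinship matrix or \code{\link{lmm_kernel}}.
#' @param state list with elements \code{beta}, \code{sigma_g2},
#'   \code{sigma_e2}, \code{warp} (a \code{\link{warp_params}}) and
#'   optionally \code{extra_components} (as in \code{\link{lmm_nll}}).
#' @return Scalar extended negative log likelihood.
#' @export
extended_nll <- function(y, X, K, state) {
  z <- warp(y, state$warp)
  extras <- state$extra_components
  if (is.null(extras)) extras <- list()
  lmm_nll(z, X, K, extras, state$beta, state$sigma_g2, state$sigma_e2) -
    sum(log(warp_derivative(y, state$warp)))
}

# Builds the profiled extended-NLL objective and its analytic gradient on
# the unconstrained parameter vector
#   theta = (warp parameters, log delta_g, log delta_1..log delta_m)
# with beta and sigma_e^2 profiled in closed form. Works on the rotated
# basis of the kinship spectrum; extra rank-one components enter through a
# Woodbury update.
.wlmm_objective <- function(y, X, kern, template, G_extras = NULL) {
  U <- kern$U
  lambda <- kern$lambda
  n <- kern$n
  Xt <- crossprod(U, X)
  m <- if (is.null(G_extras)) 0L else ncol(G_extras)
  Gt <- if (m) crossprod(U, G_extras) else NULL
  P <- length(.warp_theta(template))

  unpack <- function(theta) {
    list(p = .warp_from_theta(theta[seq_len(P)], template),
         delta_g = exp(theta[P + 1]),
         delta_x = if (m) exp(theta[P + 1 + seq_len(m)]) else NULL)
  }
  # The model's intercept absorbs any constant in f, so the warp's output
  # is centred at the phenotype median during optimization: a saturated
  # step can legitimately carry an enormous constant (it acts as an
  # exponential term in the warp), and without centring that constant
  # annihilates the significant digits of z. The gradient is unaffected
  # exactly: the offset direction is V-orthogonal to the GLS residual.
  med_y <- stats::median(y)
  # optim calls fn and gr at the same point; cache the profile work
  cache <- new.env(parent = emptyenv())
  core <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache)
    s <- unpack(theta)
    z <- warp(y, s$p) - warp(med_y, s$p)
    zt <- crossprod(U, z)
    prof <- .lmm_profile(zt, Xt, lambda, s$delta_g, Gt, s$delta_x)
    jac <- sum(log(warp_derivative(y, s$p)))
    cache$theta <- theta
    cache$s <- s
    cache$prof <- prof
    cache$val <- prof$nll - jac
    cache
  }
  evaluate <- function(theta, grad = FALSE) {
    cc <- core(theta)
    s <- cc$s
    prof <- cc$prof
    val <- cc$val
    if (!grad) return(val)

    g <- numeric(P + 1 + m)
    u <- prof$u
    q <- max(prof$q, 1e-300)
    if (P > 0) {
      wg <- .warp_grad(y, s$p)
      u_orig <- U %*% u
      g[seq_len(P)] <- (n / q) * drop(crossprod(wg$dz, u_orig)) -
        colSums(wg$dlogj)
    }
    D <- prof$D
    if (m) {
      W <- prof$W
      Minv <- prof$Minv
      tr_lam <- sum(lambda / D) - sum(Minv * crossprod(W, lambda * W))
      VinvG <- W %*% sweep(Minv, 2, s$delta_x, "/")  # V^{-1} Gt = W M^{-1} Delta^{-1}
      tr_g <- colSums(Gt * VinvG)
      gu <- drop(crossprod(Gt, u))
      g[P + 1 + seq_len(m)] <-
        s$delta_x * (0.5 * tr_g - (n / (2 * q)) * gu^2)
    } else {
      tr_lam <- sum(lambda / D)
    }
    g[P + 1] <- s$delta_g *
      (0.5 * tr_lam - (n / (2 * q)) * sum(lambda * u^2))
    attr(val, "gradient") <- g
    val
  }
  list(
    fn = function(theta) as.numeric(evaluate(theta)),
    gr = function(theta) attr(evaluate(theta, grad = TRUE), "gradient"),
    unpack = unpack, n_warp = P, n_extra = m
  )
}

# Default warp template: near-identity with I steps located at the
# quantiles of the pre-scaled phenotype.
.wlmm_template <- function(y, family, steps) {
  if (family == "tanh_step") {
    mu <- stats::median(y)
    s <- stats::mad(y)
    if (s <= 0) s <- stats::sd(y)
    if (s <= 0) stop("phenotype has zero spread")
    u <- (y - mu) / s
    probs <- seq_len(steps) / (steps + 1)
    warp_params("tanh_step", d = 1,
                a = rep(1e-3, steps), b = rep(1, steps),
                c = -as.numeric(stats::quantile(u, probs)),
                pre_center = mu, pre_scale = s)
  } else if (family == "boxcox") {
    .check_positive(y, "boxcox")
    warp_params("boxcox", lambda = 1)
  } else warp_params(family)
}

.theta_bounds <- function(template, n_total) {
  P <- length(.warp_theta(template))
  lower <- rep(-30, n_total)
  upper <- rep(30, n_total)
  # variance ratios share the search range of fit_lmm so the identity
  # family reduces exactly to the standard LMM fit
  lower[(P + 1):n_total] <- -20
  upper[(P + 1):n_total] <- 15
  if (template$family == "tanh_step") {
    I <- length(template$a)
    lower[2 * I + seq_len(I)] <- -1e3   # step locations c_i
    upper[2 * I + seq_len(I)] <- 1e3
  } else if (template$family == "boxcox") {
    lower[1] <- -5
    upper[1] <- 5
  }
  list(lower = lower, upper = upper)
}

#' Fit a warped linear mixed model
#'
#' Jointly estimates a monotone phenotype transformation and the variance
#' components of an LMM by minimizing the extended negative log likelihood
#' (latent-scale Gaussian likelihood minus the warp's log-Jacobian).
#' Fixed effects and the residual variance are profiled in closed form on
#' the rotated kinship basis every step; the remaining parameters (warp
#' parameters and log variance ratios) are optimized by L-BFGS-B with
#' analytic gradients. Because the objective is multi-modal in the warp
#' parameters, the best of several seeded random restarts is returned.
#'
#' @param y observed phenotype vector (no missing values; join/drop first).
#' @param X design matrix with intercept; defaults to intercept only.
#' @param K kinship matrix or \code{\link{lmm_kernel}}.
#' @param family warping family; \code{"identity"} reduces the fit to a
#'   standard LMM maximum-likelihood fit.
#' @param steps number of tanh step functions (default 3).
#' @param restarts number of random restarts (default 5).
#' @param seed integer seed controlling restart jitter; fits are
#'   deterministic given the seed.
#' @param extras optional list of pre-selected rank-one components, each a
#'   list with \code{index} (column in the SNP matrix), \code{g}
#'   (standardized SNP vector) and optionally \code{sigma2} (start value).
#' @param init optional warm start: a list with \code{warp},
#'   \code{delta_g} and optionally \code{delta_x}; when given, a single
#'   optimization run starts there (used by forward selection so the
#'   objective never increases across iterations).
#' @param maxit maximum L-BFGS-B iterations per restart.
#' @return An object of class \code{wlmm_fit}: the fitted
#'   \code{warp_params}, \code{beta}, variance components (ML at the joint
#'   optimum), the transformed phenotype \code{z}, the extended
#'   log-likelihood \code{loglik}, selected components and optimizer
#'   diagnostics. The kinship spectrum and training data are retained for
#'   downstream prediction.
#' @export
wlmm_fit <- function(y, X = NULL, K,
                     family = c("tanh_step", "boxcox", "identity", "log"),
                     steps = 3, restarts = 5, seed = 1,
                     extras = list(), init = NULL, maxit = 300) {
  family <- match.arg(family)
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y must be finite; drop missing values first")
  if (length(y) < 10L) stop("at least 10 complete samples are required")
  kern <- lmm_kernel(K)
  if (kern$n != length(y)) stop("dimensions of y and K do not conform")
  if (is.null(X)) X <- make_design(n = length(y))
  X <- as.matrix(X)

  template <- .wlmm_template(y, family, steps)
  if (!is.null(init) && init$warp$family == family &&
      family == "tanh_step") {
    # carry the gauge-fixed slope and pre-scaling of the warm start
    template$d <- init$warp$d
    template$pre_center <- init$warp$pre_center
    template$pre_scale <- init$warp$pre_scale
  }
  m <- length(extras)
  G_extras <- if (m) do.call(cbind, lapply(extras, `[[`, "g")) else NULL
  obj <- .wlmm_objective(y, X, kern, template, G_extras)
  P <- obj$n_warp
  nb <- .theta_bounds(template, P + 1 + m)

  base_theta <- c(.warp_theta(template), 0,
                  if (m) log(vapply(extras, function(e)
                    if (is.null(e$sigma2)) 1e-4 else max(e$sigma2, 1e-8),
                    numeric(1))))
  starts <- list()
  if (!is.null(init)) {
    th <- c(.warp_theta(init$warp), log(max(init$delta_g, 1e-12)))
    if (m) {
      dx <- rep(1e-6, m)
      if (!is.null(init$delta_x))
        dx[seq_along(init$delta_x)] <- pmax(init$delta_x, 1e-12)
      th <- c(th, log(dx))
    }
    starts[[1]] <- pmin(pmax(th, nb$lower), nb$upper)
  } else {
    set.seed(seed)
    starts[[1]] <- base_theta
    for (r in seq_len(max(restarts - 1, 0))) {
      th <- base_theta + c(stats::rnorm(P, 0, 0.5), stats::rnorm(1, 0, 1),
                           if (m) stats::rnorm(m, 0, 1))
      starts[[r + 1]] <- pmin(pmax(th, nb$lower), nb$upper)
    }
  }

  # The gradient with respect to log delta_g vanishes as delta_g -> 0, so
  # a quasi-Newton run can stall near that boundary even when a much
  # better ratio exists. After each run, rescan delta_g on a coarse log
  # grid at the fitted warp and re-optimize if the grid finds better.
  run_one <- function(theta0) {
    res <- stats::optim(theta0, fn = obj$fn, gr = obj$gr,
                        method = "L-BFGS-B",
                        lower = nb$lower, upper = nb$upper,
                        control = list(maxit = maxit, factr = 1e7))
    for (cycle in 1:3) {
      th <- res$par
      grid <- seq(-20, 15, length.out = 36)
      vals <- vapply(grid, function(ld) {
        th[P + 1] <- ld
        obj$fn(th)
      }, numeric(1))
      if (min(vals) < res$value - 1e-6) {
        th[P + 1] <- grid[which.min(vals)]
        res2 <- stats::optim(th, fn = obj$fn, gr = obj$gr,
                             method = "L-BFGS-B",
                             lower = nb$lower, upper = nb$upper,
                             control = list(maxit = maxit, factr = 1e7))
        if (res2$value < res$value) res <- res2 else break
      } else break
    }
    res
  }
  best <- NULL
  diag_rows <- list()
  for (r in seq_along(starts)) {
    fit_r <- tryCatch(run_one(starts[[r]]), error = function(e) NULL)
    if (is.null(fit_r)) {
      diag_rows[[r]] <- data.frame(restart = r, value = NA_real_,
                                   convergence = -1L, iterations = NA_integer_)
      next
    }
    diag_rows[[r]] <- data.frame(restart = r, value = fit_r$value,
                                 convergence = fit_r$convergence,
                                 iterations = fit_r$counts[["function"]])
    if (is.null(best) || fit_r$value < best$value) best <- fit_r
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (is.null(best))
    stop("no optimizer restart converged; diagnostics:\n",
         paste(utils::capture.output(print(diagnostics)), collapse = "\n"))

  s <- obj$unpack(best$par)
  if (family == "tanh_step")
    s$p$shift <- s$p$shift + warp(stats::median(y), s$p)
  z <- warp(y, s$p)
  zt <- crossprod(kern$U, z)
  Xt <- crossprod(kern$U, X)
  prof <- .lmm_profile(zt, Xt, kern$lambda, s$delta_g,
                       if (m) crossprod(kern$U, G_extras) else NULL,
                       s$delta_x)
  sigma_e2 <- prof$sigma2
  comp <- if (m) lapply(seq_len(m), function(j) {
    list(index = extras[[j]]$index, g = extras[[j]]$g,
         sigma2 = s$delta_x[j] * sigma_e2)
  }) else list()

  structure(list(
    warp = s$p, beta = prof$beta,
    sigma_g2 = s$delta_g * sigma_e2, sigma_e2 = sigma_e2,
    delta_g = s$delta_g, delta_x = s$delta_x,
    extra_components = comp,
    z = z, loglik = -best$value, nll_extended = best$value,
    family = family, y = y, X = X, kern = kern,
    diagnostics = diagnostics,
    converged = best$convergence == 0, seed = seed
  ), class = "wlmm_fit")
}

#' @export
print.wlmm_fit <- function(x, ...) {
  cat("Warped LMM fit\n")
  cat(sprintf("  samples: %d, warp family: %s\n", length(x$y), x$family))
  cat(sprintf("  extended log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g (ML), h2[ML] = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$delta_g / (1 + x$delta_g)))
  if (length(x$extra_components))
    cat(sprintf("  %d forward-selected variance component(s)\n",
                length(x$extra_components)))
  invisible(x)
}
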