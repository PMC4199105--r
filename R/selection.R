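#' Mixed-model single-SNP association scan
#'
#' Tests every SNP as a fixed effect added to the design X under the
#' Gaussian model z ~ N(., gamma * C + I) (scaled by a residual variance),
#' where C is the current genetic covariance. The variance ratio gamma is
#' profiled: exactly under the null by a one-dimensional search, and per
#' SNP over a dense logarithmic grid around the null optimum (the grid
#' always contains the null optimum, so the likelihood-ratio statistic is
#' non-negative). With \code{profile_delta = FALSE} the covariance is held
#' fixed at the null optimum and the test is an exact generalized
#' least-squares likelihood-ratio test. P-values come from the chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param z phenotype on the latent scale.
#' @param X design matrix (intercept included).
#' @param snps standardized sample-by-SNP matrix.
#' @param K genetic covariance (matrix or \code{\link{lmm_kernel}});
#'   typically the kinship matrix, or the full kernel including selected
#'   components during forward selection.
#' @param profile_delta profile the variance ratio per SNP (default TRUE).
#' @param grid_span half-width, in decades, of the per-SNP gamma grid.
#' @param grid_points number of grid points.
#' @param exclude integer indices of SNPs to skip (reported with p = NA).
#' @return A data.frame with one row per SNP: \code{snp_id}, \code{beta}
#'   (GLS effect at the null covariance), \code{stat} (LRT chi-squared),
#'   \code{pvalue}, \code{qvalue} (Storey), and \code{collinear} flag.
#'   The null variance ratio is attached as attribute \code{delta_null}.
#' @export
single_snp_scan <- function(z, X, snps, K, profile_delta = TRUE,
                            grid_span = 2, grid_points = 21,
                            exclude = integer(0)) {
  kern <- lmm_kernel(K)
  snps <- as.matrix(snps)
  n <- kern$n
  S <- ncol(snps)
  stopifnot(length(z) == n, nrow(X) == n, nrow(snps) == n)
  lambda <- kern$lambda
  # normalize the phenotype scale for conditioning; the LRT statistic is
  # invariant, the effect size is rescaled back below
  zsd <- stats::sd(z)
  if (zsd <= 0) stop("phenotype has zero variance")
  z <- z / zsd
  zt <- drop(crossprod(kern$U, z))
  Xt <- crossprod(kern$U, X)
  Gt <- crossprod(kern$U, snps)
  G2 <- Gt^2

  null_fit <- suppressWarnings(fit_lmm(z, X, kern, reml = FALSE))
  gamma0 <- null_fit$delta
  nll_null <- null_fit$nll

  if (!profile_delta) {
    grid <- gamma0
  } else if (gamma0 > 0) {
    grid <- unique(c(gamma0,
                     gamma0 * 10^seq(-grid_span, grid_span,
                                     length.out = grid_points)))
  } else {
    grid <- c(0, 10^seq(-4, 2, length.out = grid_points))
  }

  nll_best <- rep(Inf, S)
  beta_hat <- rep(NA_real_, S)
  collinear <- rep(FALSE, S)
  const <- 0.5 * n * (log(2 * pi) + 1)
  for (gamma in grid) {
    w <- 1 / (gamma * lambda + 1)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    A <- solve(XtWX)
    XtWz <- drop(crossprod(XtW, zt))
    rss_null <- sum(w * zt^2) - drop(crossprod(XtWz, A %*% XtWz))
    gWz <- drop(crossprod(Gt, w * zt))
    gWX <- crossprod(Gt, XtW)                 # S x C
    gWg <- drop(crossprod(G2, w))
    gAX <- gWX %*% A
    gPg <- gWg - rowSums(gAX * gWX)
    gPz <- gWz - drop(gAX %*% XtWz)
    bad <- gPg <= 1e-10 * pmax(gWg, 1e-300)
    expl <- ifelse(bad, 0, gPz^2 / pmax(gPg, 1e-300))
    rss <- pmax(rss_null - expl, 1e-300)
    nll_g <- const + 0.5 * (sum(log1p(gamma * lambda)) + n * log(rss / n))
    upd <- nll_g < nll_best
    nll_best[upd] <- nll_g[upd]
    if (gamma == gamma0) {
      beta_hat <- ifelse(bad, NA_real_, gPz / pmax(gPg, 1e-300))
      collinear <- bad
    }
  }
  stat <- pmax(2 * (nll_null - nll_best), 0)
  pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pv[collinear] <- 1
  stat[collinear] <- 0
  if (length(exclude)) {
    pv[exclude] <- NA_real_
    stat[exclude] <- NA_real_
  }
  beta_hat <- beta_hat * zsd
  ids <- colnames(snps)
  if (is.null(ids)) ids <- paste0("snp", seq_len(S))
  tab <- data.frame(snp_id = ids, beta = beta_hat, stat = stat,
                    pvalue = pv, collinear = collinear,
                    stringsAsFactors = FALSE)
  ok <- !is.na(tab$pvalue)
  tab$qvalue <- NA_real_
  if (any(ok)) tab$qvalue[ok] <- qvalues(tab$pvalue[ok])
  attr(tab, "delta_null") <- gamma0
  tab
}

#' Storey q-values
#'
#' Positive-FDR q-values with the null proportion pi0 estimated by
#' Storey's smoother over a lambda grid; for fewer than 100 tests pi0 is
#' fixed at 1, which makes the q-values identical to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param pi0 optionally fix the null proportion (e.g. 1).
#' @return Vector of q-values, in [0, 1], monotone non-decreasing in the
#'   p-value ranks; attribute \code{pi0} records the estimate used.
#' @export
qvalues <- function(pvals, pi0 = NULL) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(pvals > l) / (1 - l),
                        numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(pi0 * m * pvals[o] / (m - seq_len(m) + 1), 1)
  q <- cummin(q)
  out <- q[ro]
  attr(out, "pi0") <- pi0
  out
}

#' Forward selection of large-effect loci
#'
#' Iterates: fit the warped LMM, scan all SNPs against the current
#' transformed phenotype under the current genetic covariance, and if the
#' most significant SNP reaches the q-value threshold, absorb it into the
#' model as an extra rank-one variance component (a random effect, never a
#' fixed effect) and refit starting from the previous optimum. The loop
#' stops when no SNP is significant at the FDR threshold or the iteration
#' cap is reached. Selected components improve the reconstruction of the
#' transformation; downstream heritability estimation and prediction use
#' the polygenic kinship only.
#'
#' @param y observed phenotype.
#' @param X design matrix; intercept-only when NULL.
#' @param K kinship matrix (a full matrix is required so the covariance
#'   can be re-assembled as components are added).
#' @param snps standardized sample-by-SNP matrix (scan candidates).
#' @param family,steps,restarts,seed,maxit passed to \code{\link{wlmm_fit}}.
#' @param fdr q-value threshold for selection (default 0.05).
#' @param max_iter safety cap on selection iterations (default 20).
#' @param pos optional per-SNP genomic positions used to break q-value
#'   ties (smaller position, then SNP identifier).
#' @return A \code{wlmm_fit} whose \code{extra_components} hold the
#'   selected SNPs, with \code{$selected} (a data.frame: rank, index,
#'   snp_id, qvalue at selection, sigma2 after the final refit) and
#'   \code{$selection_converged}.
#' @export
forward_select <- function(y, X = NULL, K, snps,
                           family = "tanh_step", steps = 3,
                           restarts = 5, seed = 1, fdr = 0.05,
                           max_iter = 20, maxit = 300, pos = NULL) {
  K <- as.matrix(K)
  snps <- as.matrix(snps)
  ids <- colnames(snps)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(snps)))
  if (is.null(pos)) pos <- seq_len(ncol(snps))
  kern <- lmm_kernel(K)

  fit <- wlmm_fit(y, X, kern, family = family, steps = steps,
                  restarts = restarts, seed = seed, maxit = maxit)
  Xd <- fit$X
  extras <- list()
  sel <- list()
  nll_path <- fit$nll_extended
  converged <- FALSE
  for (iter in seq_len(max_iter + 1L)) {
    # current genetic covariance delta_g*K + sum_j delta_j g_j g_j'
    if (length(extras)) {
      Cmat <- fit$delta_g * K
      for (j in seq_along(extras))
        Cmat <- Cmat + fit$delta_x[j] * tcrossprod(extras[[j]]$g)
      scan_kern <- lmm_kernel(Cmat)
    } else {
      scan_kern <- structure(list(U = kern$U,
                                  lambda = fit$delta_g * kern$lambda,
                                  n = kern$n), class = "lmm_kernel")
    }
    taken <- vapply(extras, `[[`, numeric(1), "index")
    tab <- single_snp_scan(fit$z, Xd, snps, scan_kern,
                           exclude = as.integer(taken))
    ok <- which(!is.na(tab$qvalue))
    if (!length(ok)) { converged <- TRUE; break }
    ord <- ok[order(tab$qvalue[ok], tab$pvalue[ok], pos[ok], ids[ok])]
    best <- ord[1]
    if (tab$qvalue[best] > fdr || iter > max_iter) {
      converged <- tab$qvalue[best] > fdr
      break
    }
    # start the new component near the variance its scan statistic implies,
    # where the log-scale gradient is informative
    delta_new <- max(tab$stat[best] / kern$n, 1e-3)
    extras[[length(extras) + 1L]] <-
      list(index = best, g = snps[, best], sigma2 = delta_new)
    sel[[length(sel) + 1L]] <-
      data.frame(rank = length(sel) + 1L, index = best, snp_id = ids[best],
                 qvalue = tab$qvalue[best], stringsAsFactors = FALSE)
    refit <- wlmm_fit(y, Xd, kern, family = family, steps = steps,
                      seed = seed, extras = extras, maxit = maxit,
                      init = list(warp = fit$warp, delta_g = fit$delta_g,
                                  delta_x = c(fit$delta_x, delta_new)))
    if (refit$nll_extended > fit$nll_extended) {
      # the aggressive start moved into a worse valley; restart from the
      # previous optimum with the new component switched off
      alt <- wlmm_fit(y, Xd, kern, family = family, steps = steps,
                      seed = seed, extras = extras, maxit = maxit,
                      init = list(warp = fit$warp, delta_g = fit$delta_g,
                                  delta_x = c(fit$delta_x, 1e-10)))
      if (alt$nll_extended < refit$nll_extended) refit <- alt
    }
    fit <- refit
    nll_path <- c(nll_path, fit$nll_extended)
  }
  selected <- if (length(sel)) do.call(rbind, sel)
              else data.frame(rank = integer(0), index = integer(0),
                              snp_id = character(0), qvalue = numeric(0))
  if (nrow(selected))
    selected$sigma2 <- vapply(fit$extra_components, `[[`, numeric(1),
                              "sigma2")
  fit$selected <- selected
  fit$selection_converged <- converged
  fit$nll_path <- nll_path
  fit$fdr <- fdr
  fit
}
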