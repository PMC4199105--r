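#' Narrow-sense (chip) heritability on the latent scale
#'
#' Re-estimates the variance components of the fitted latent phenotype z
#' by REML with the polygenic kinship only -- forward-selected components
#' are deliberately dropped, since they exist to reconstruct the
#' transformation, not to enter the heritability -- and reports
#' h2 = sigma_g2 / (sigma_g2 + sigma_e2).
#'
#' @param fit a \code{\link{wlmm_fit}} (or \code{\link{forward_select}}
#'   result).
#' @param bootstrap number of bootstrap replicates for an empirical SD of
#'   h2; each replicate re-fits REML on a random 90\% subsample. 0 (the
#'   default) skips the bootstrap.
#' @param K kinship matrix; only needed when \code{bootstrap > 0} (the
#'   subsampled kinship cannot be formed from the stored spectrum alone).
#' @param seed seed for the bootstrap resampling.
#' @return Object of class \code{h2_estimate}: \code{h2},
#'   \code{sigma_g2}, \code{sigma_e2} (REML), \code{boundary} flag, and
#'   \code{bootstrap_sd} when requested.
#' @export
estimate_h2 <- function(fit, bootstrap = 0, K = NULL, seed = 1) {
  stopifnot(inherits(fit, "wlmm_fit"))
  reml <- withCallingHandlers(
    fit_lmm(fit$z, fit$X, fit$kern, reml = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  if (reml$boundary)
    warning("REML variance estimate at the sigma_g2 = 0 boundary; h2 = 0")
  boot_sd <- NA_real_
  if (bootstrap > 0) {
    if (is.null(K))
      K <- fit$kern$U %*% (fit$kern$lambda * t(fit$kern$U))
    n <- length(fit$z)
    set.seed(seed)
    h2b <- vapply(seq_len(bootstrap), function(b) {
      idx <- sort(sample.int(n, size = floor(0.9 * n)))
      suppressWarnings(
        fit_lmm(fit$z[idx], fit$X[idx, , drop = FALSE],
                K[idx, idx], reml = TRUE)$h2)
    }, numeric(1))
    boot_sd <- stats::sd(h2b)
  }
  structure(list(h2 = reml$h2, sigma_g2 = reml$sigma_g2,
                 sigma_e2 = reml$sigma_e2, boundary = reml$boundary,
                 bootstrap_sd = boot_sd),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.4f (sigma_g2 = %.4g, sigma_e2 = %.4g, REML)\n",
              x$h2, x$sigma_g2, x$sigma_e2))
  if (!is.na(x$bootstrap_sd))
    cat(sprintf("  bootstrap SD = %.4f\n", x$bootstrap_sd))
  invisible(x)
}

#' Predict phenotypes for new individuals
#'
#' Computes the best linear unbiased predictor of the latent phenotype for
#' new samples, z* = x* beta + sigma_g2 k* (sigma_g2 K + sigma_e2 I)^{-1}
#' (z - X beta), using REML variance components and the polygenic kinship
#' only (forward-selected components are excluded), then maps it back to
#' the original measurement scale through the inverse warping function.
#'
#' @param object a \code{\link{wlmm_fit}}.
#' @param X_star design matrix for the new samples (same columns as the
#'   training design).
#' @param k_star relatedness block between new and training samples, one
#'   row per new sample, from \code{\link{kinship_cross}} (same
#'   standardized SNP set as the training kinship).
#' @param components optional list overriding the REML variance
#'   components: elements \code{sigma_g2}, \code{sigma_e2} and optionally
#'   \code{beta}. By default REML estimates are recomputed from the fit.
#' @param ... unused.
#' @return data.frame with \code{z_star} (latent-scale BLUP) and
#'   \code{y_star} (original scale, via the inverse warp).
#' @export
predict.wlmm_fit <- function(object, X_star, k_star, components = NULL,
                             ...) {
  X_star <- as.matrix(X_star)
  k_star <- as.matrix(k_star)
  if (ncol(k_star) != length(object$z))
    stop("k_star must have one column per training sample; got ",
         ncol(k_star), " columns for ", length(object$z), " samples")
  if (ncol(X_star) != ncol(object$X))
    stop("X_star must match the training design columns")
  kern <- object$kern
  if (is.null(components)) {
    reml <- suppressWarnings(fit_lmm(object$z, object$X, kern,
                                     reml = TRUE))
  } else {
    delta <- components$sigma_g2 / components$sigma_e2
    beta <- components$beta
    if (is.null(beta)) {
      zt <- crossprod(kern$U, object$z)
      Xt <- crossprod(kern$U, object$X)
      beta <- .lmm_profile(zt, Xt, kern$lambda, delta)$beta
    }
    reml <- list(delta = delta, beta = beta)
  }
  r <- object$z - drop(object$X %*% reml$beta)
  rt <- drop(crossprod(kern$U, r))
  w <- rt / (reml$delta * kern$lambda + 1)
  alpha <- reml$delta * drop(kern$U %*% w)   # delta (delta K + I)^{-1} r
  z_star <- drop(X_star %*% reml$beta) + drop(k_star %*% alpha)
  y_star <- invert_warp(z_star, object$warp)
  data.frame(z_star = z_star, y_star = y_star)
}

#' Mixed-model GWAS on the warped phenotype
#'
#' Transforms the phenotype through a fitted warp (by default, one learned
#' with forward selection so large-effect loci do not distort the
#' transformation) and runs a single-SNP mixed-model scan of every marker
#' against the transformed phenotype under the polygenic covariance
#' sigma_g2 K + sigma_e2 I, with the variance ratio profiled per SNP.
#'
#' @param y observed phenotype.
#' @param X design matrix; intercept-only when NULL.
#' @param K kinship matrix.
#' @param snps standardized sample-by-SNP matrix.
#' @param fit optional pre-computed \code{\link{wlmm_fit}}; when NULL one
#'   is fitted here.
#' @param forward_selection when fitting internally, interleave forward
#'   selection of large-effect loci (default TRUE).
#' @param threshold genome-wide significance threshold on p-values
#'   (default 5e-8).
#' @param chrom,pos optional per-SNP coordinates copied to the output.
#' @param loco leave-one-chromosome-out: test each chromosome's SNPs
#'   under a kinship built from all other chromosomes, avoiding proximal
#'   contamination. Requires \code{chrom} and the standardized SNP matrix
#'   covering at least two chromosomes. Default FALSE (single genome-wide
#'   kinship).
#' @param ... passed to \code{\link{forward_select}} /
#'   \code{\link{wlmm_fit}}.
#' @return data.frame with per-SNP \code{chrom}, \code{pos},
#'   \code{snp_id}, \code{beta}, \code{stat}, \code{pvalue},
#'   \code{qvalue}, \code{significant}; attributes \code{lambda_gc}
#'   (genomic-control inflation factor: median chi-squared over its null
#'   median) and \code{fit}.
#' @export
gwas_scan <- function(y, X = NULL, K, snps, fit = NULL,
                      forward_selection = TRUE, threshold = 5e-8,
                      chrom = NULL, pos = NULL, loco = FALSE, ...) {
  snps <- as.matrix(snps)
  if (is.null(fit)) {
    fit <- if (forward_selection)
      forward_select(y, X, K, snps, ...)
    else wlmm_fit(y, X, K, ...)
  }
  if (loco) {
    if (is.null(chrom)) stop("loco scanning requires per-SNP chrom codes")
    if (length(unique(chrom)) < 2L)
      stop("loco scanning requires SNPs on at least two chromosomes")
    tab <- NULL
    for (cc in unique(chrom)) {
      off <- chrom != cc
      K_off <- compute_kinship(snps[, off, drop = FALSE])
      part <- single_snp_scan(fit$z, fit$X, snps[, !off, drop = FALSE],
                              lmm_kernel(K_off))
      part$.idx <- which(!off)
      tab <- rbind(tab, part)
    }
    tab <- tab[order(tab$.idx), ]
    tab$.idx <- NULL
    rownames(tab) <- NULL
    # q-values over the combined genome-wide scan
    tab$qvalue <- qvalues(tab$pvalue)
  } else {
    tab <- single_snp_scan(fit$z, fit$X, snps, lmm_kernel(K))
  }
  tab$significant <- !is.na(tab$pvalue) & tab$pvalue <= threshold
  tab <- cbind(
    chrom = if (is.null(chrom)) rep(NA_integer_, nrow(tab)) else chrom,
    pos = if (is.null(pos)) seq_len(nrow(tab)) else pos,
    tab)
  lambda_gc <- stats::median(tab$stat, na.rm = TRUE) /
    stats::qchisq(0.5, df = 1)
  attr(tab, "lambda_gc") <- lambda_gc
  attr(tab, "threshold") <- threshold
  attr(tab, "fit") <- fit
  tab
}
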