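#' Simulation configuration
#'
#' Describes one cell of the simulation design: binomially sampled
#' biallelic genotypes, an additive polygenic latent trait with exact
#' in-sample variance fractions, and an observed phenotype obtained by
#' blending the latent trait with a nonlinear transform,
#' y_obs = t * y + (1 - t) * f(y). t = 1 leaves the trait untransformed;
#' t = 0 applies the transform fully (for f = exp the ideal recovery
#' transformation is then the log).
#'
#' @param n number of samples.
#' @param s number of SNPs.
#' @param n_causal number of causal SNPs (<= s).
#' @param h2 narrow-sense heritability of the latent trait, in (0, 1).
#' @param covar_frac fraction of latent variance from a simulated
#'   covariate (default 0); \code{h2 + covar_frac} must be < 1.
#' @param transform nonlinear transform family: \code{"exp"} (applied to
#'   the standardized latent trait to avoid overflow) or
#'   \code{"identity"}.
#' @param t blend between untransformed (1) and fully transformed (0).
#' @param maf minor-allele-frequency range, within [0.01, 0.5].
#' @param seed integer seed; all draws are deterministic given it.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n, s, n_causal, h2, covar_frac = 0,
                       transform = c("exp", "identity"), t = 0,
                       maf = c(0.05, 0.5), seed = 1) {
  transform <- match.arg(transform)
  if (n < 2) stop("n must be at least 2")
  if (n_causal > s) stop("n_causal cannot exceed the number of SNPs")
  if (n_causal < 1) stop("n_causal must be at least 1")
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (covar_frac < 0 || h2 + covar_frac >= 1)
    stop("variance fractions h2 + covar_frac must stay below 1")
  if (t < 0 || t > 1) stop("blend t must lie in [0, 1]")
  if (length(maf) != 2 || maf[1] > maf[2] ||
      maf[1] < 0.01 || maf[2] > 0.5)
    stop("maf must be a range within [0.01, 0.5]")
  structure(list(n = as.integer(n), s = as.integer(s),
                 n_causal = as.integer(n_causal), h2 = h2,
                 covar_frac = covar_frac, transform = transform,
                 t = t, maf = maf, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic genotypes
#'
#' Draws per-SNP allele frequencies uniformly from the configured range
#' and dosages as Binomial(2, maf_s), independently across SNPs (no
#' linkage disequilibrium is emulated).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{\link{genotype_data}} with attribute \code{maf}
#'   (the per-SNP sampled frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  maf_s <- stats::runif(config$s, config$maf[1], config$maf[2])
  d <- matrix(stats::rbinom(config$n * config$s, 2,
                            rep(maf_s, each = config$n)),
              nrow = config$n, ncol = config$s)
  g <- genotype_data(d, sample_ids = sprintf("ind%04d", seq_len(config$n)),
                     snp_ids = sprintf("snp%05d", seq_len(config$s)),
                     chrom = rep(1L, config$s), pos = seq_len(config$s))
  attr(g, "maf") <- maf_s
  g
}

# centre a vector and rescale to an exact sample variance
.exact_var <- function(v, target) {
  v <- v - mean(v)
  sv <- stats::sd(v)
  if (sv == 0) stop("degenerate component with zero variance")
  v * sqrt(target) / sv
}

#' Simulate a phenotype on given genotypes
#'
#' Draws Gaussian causal effects on standardized dosages, a covariate
#' contribution and Gaussian noise, orthogonalizes the pieces in sample
#' and rescales each to its exact configured variance fraction (so the
#' realized heritability equals \code{config$h2} by construction, not
#' merely in expectation). The observed phenotype blends the latent trait
#' with the nonlinear transform: y_obs = t*y + (1-t)*f(y), with
#' f(y) = exp((y - m)/s) standardized to avoid overflow (m, s recorded in
#' the truth record).
#'
#' @param g a \code{\link{genotype_data}}.
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{latent}, \code{observed}, \code{covariate}
#'   (NULL when \code{covar_frac} is 0), the orthogonal variance
#'   \code{components} (genetic/covariate/noise) and a \code{truth} record
#'   (causal indices on the retained standardized SNPs, effects, realized
#'   h2, blend t, transform parameters).
#' @export
simulate_phenotype <- function(g, config) {
  stopifnot(inherits(g, "genotype_data"), inherits(config, "sim_config"))
  std <- suppressMessages(standardize_genotypes(g))
  set.seed(config$seed + 500009L)
  n <- nrow(std)
  causal <- sort(sample.int(ncol(std), config$n_causal))
  effects <- stats::rnorm(config$n_causal)
  gc <- .exact_var(drop(std[, causal, drop = FALSE] %*% effects),
                   config$h2)
  covar <- NULL
  cc <- rep(0, n)
  if (config$covar_frac > 0) {
    covar <- stats::rnorm(n)
    cc <- .exact_var(stats::residuals(stats::lm(covar ~ gc)),
                     config$covar_frac)
  }
  noise_frac <- 1 - config$h2 - config$covar_frac
  e <- stats::rnorm(n)
  e <- .exact_var(stats::residuals(stats::lm(e ~ gc + cc)), noise_frac)
  latent <- gc + cc + e

  m <- mean(latent)
  s <- stats::sd(latent)
  f_latent <- switch(config$transform,
                     exp = exp((latent - m) / s),
                     identity = latent)
  observed <- config$t * latent + (1 - config$t) * f_latent
  list(latent = latent, observed = observed, covariate = covar,
       components = list(genetic = gc, covariate = cc, noise = e),
       truth = list(causal = causal, effects = effects,
                    h2 = config$h2, covar_frac = config$covar_frac,
                    t = config$t, transform = config$transform,
                    transform_center = m, transform_scale = s))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genotypes, standardized dosages, kinship and
#' phenotype in one call.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{geno}, \code{std}, \code{K}, \code{latent},
#'   \code{observed}, \code{covariate}, \code{truth}.
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genotypes(config)
  std <- suppressMessages(standardize_genotypes(g))
  K <- compute_kinship(std)
  ph <- simulate_phenotype(g, config)
  list(geno = g, std = std, K = K, latent = ph$latent,
       observed = ph$observed, covariate = ph$covariate,
       components = ph$components, truth = ph$truth)
}

# Heritability estimators compared in the bias experiment. Phenotypes
# that are not strictly positive are shifted before log / Box-Cox
# preprocessing (min to a small positive offset), mirroring common
# practice for those static transforms.
.shift_positive <- function(y) {
  if (min(y) > 0) return(y)
  y - min(y) + 1e-3 * stats::sd(y)
}

.h2_by_method <- function(method, y, X, kern, K, std, restarts, seed,
                          forward_selection) {
  switch(method,
    lmm_raw = suppressWarnings(fit_lmm(y, X, kern, reml = TRUE)$h2),
    lmm_log = suppressWarnings(
      fit_lmm(log(.shift_positive(y)), X, kern, reml = TRUE)$h2),
    lmm_boxcox = {
      yp <- .shift_positive(y)
      bc <- MASS::boxcox(yp ~ 1, lambda = seq(-2, 2, 0.01),
                         plotit = FALSE)
      lam <- bc$x[which.max(bc$y)]
      suppressWarnings(
        fit_lmm(boxcox_warp(yp, lam), X, kern, reml = TRUE)$h2)
    },
    warpedlmm = {
      ft <- if (forward_selection)
        suppressWarnings(forward_select(y, X, K, std,
                                        restarts = restarts, seed = seed))
      else suppressWarnings(wlmm_fit(y, X, kern,
                                     restarts = restarts, seed = seed))
      suppressWarnings(estimate_h2(ft)$h2)
    },
    stop("unknown method: ", method))
}

#' Heritability-bias benchmark over a simulation grid
#'
#' For every cell of a simulation grid and every estimator, simulates
#' replicate datasets, estimates heritability, and tabulates the bias
#' h2_hat - h2_true. Identical seeds reproduce identical tables.
#'
#' @param grid data.frame with columns \code{n}, \code{s},
#'   \code{n_causal}, \code{h2}, \code{t} and optionally
#'   \code{covar_frac}, \code{transform}.
#' @param methods subset of \code{c("lmm_raw", "lmm_log", "lmm_boxcox",
#'   "warpedlmm")}.
#' @param replicates replicates per cell (default 50).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param forward_selection let the warped fit run forward selection
#'   (default TRUE).
#' @param restarts restarts for the warped fit.
#' @return data.frame with one row per (cell, method): the cell fields,
#'   \code{method}, \code{mean_bias}, \code{sd_bias},
#'   \code{mean_rel_bias} (relative to true h2), \code{n_ok},
#'   \code{n_failed}. The per-replicate estimates are attached as
#'   attribute \code{replicates}.
#' @export
run_bias_experiment <- function(grid, methods = c("warpedlmm", "lmm_raw"),
                                replicates = 50, seed = 1,
                                forward_selection = TRUE, restarts = 5) {
  methods <- match.arg(methods,
                       c("lmm_raw", "lmm_log", "lmm_boxcox", "warpedlmm"),
                       several.ok = TRUE)
  grid <- as.data.frame(grid)
  if (is.null(grid$covar_frac)) grid$covar_frac <- 0
  if (is.null(grid$transform)) grid$transform <- "exp"
  long <- list()
  for (cell in seq_len(nrow(grid))) {
    gr <- grid[cell, ]
    for (rep_i in seq_len(replicates)) {
      rep_seed <- seed + 100003L * (cell - 1L) + rep_i
      cfg <- sim_config(n = gr$n, s = gr$s, n_causal = gr$n_causal,
                        h2 = gr$h2, covar_frac = gr$covar_frac,
                        transform = gr$transform, t = gr$t,
                        seed = rep_seed)
      dat <- simulate_dataset(cfg)
      kern <- lmm_kernel(dat$K)
      X <- if (is.null(dat$covariate)) make_design(n = cfg$n)
           else make_design(matrix(dat$covariate, ncol = 1,
                                   dimnames = list(NULL, "covar")))
      for (method in methods) {
        h2_hat <- tryCatch(
          .h2_by_method(method, dat$observed, X, kern, dat$K, dat$std,
                        restarts, rep_seed, forward_selection),
          error = function(e) {
            message(sprintf("cell %d rep %d method %s failed: %s",
                            cell, rep_i, method, conditionMessage(e)))
            NA_real_
          })
        long[[length(long) + 1L]] <- data.frame(
          cell = cell, n = gr$n, s = gr$s, n_causal = gr$n_causal,
          h2 = gr$h2, covar_frac = gr$covar_frac,
          transform = gr$transform, t = gr$t, method = method,
          rep = rep_i, h2_hat = h2_hat, stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, long)
  long$bias <- long$h2_hat - long$h2
  keys <- c("cell", "n", "s", "n_causal", "h2", "covar_frac",
            "transform", "t", "method")
  parts <- split(long, long[keys], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    ok <- !is.na(p$h2_hat)
    cbind(p[1, keys],
          data.frame(mean_bias = mean(p$bias[ok]),
                     sd_bias = stats::sd(p$bias[ok]),
                     mean_rel_bias = mean(p$bias[ok]) / p$h2[1],
                     n_ok = sum(ok), n_failed = sum(!ok)))
  }))
  rownames(out) <- NULL
  out <- out[order(out$cell, out$method), ]
  attr(out, "replicates") <- long
  out
}
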