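test_that("extended NLL with an identity warp equals the plain LMM NLL", {
  set.seed(31)
  n <- 15
  std <- small_std_geno(n, 30, seed = 31)
  K <- compute_kinship(std)
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  state <- list(beta = 0.1, sigma_g2 = 0.6, sigma_e2 = 0.4,
                warp = warp_params("identity"))
  expect_identical(extended_nll(y, X, K, state),
                   lmm_nll(y, X, K, beta = 0.1, sigma_g2 = 0.6,
                           sigma_e2 = 0.4))
  # and it matches the dense oracle (latent-likelihood part, Jacobian 0)
  oracle <- dense_mvn_nll(y, X %*% 0.1, 0.6 * K + 0.4 * diag(n))
  expect_equal(extended_nll(y, X, K, state), oracle, tolerance = 1e-8)
})

test_that("an affine warp f(y) = 2y shifts the extended NLL by exactly the
           change-of-variables terms", {
  set.seed(32)
  n <- 20
  K <- compute_kinship(small_std_geno(n, 40, seed = 32))
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  s1 <- list(beta = 0.3, sigma_g2 = 0.5, sigma_e2 = 0.7,
             warp = warp_params("identity"))
  # doubling the latent scale: beta and variances transform accordingly,
  # the Gaussian NLL gains N log 2 and the Jacobian term removes it
  s2 <- list(beta = 0.6, sigma_g2 = 2.0, sigma_e2 = 2.8,
             warp = warp_params("tanh_step", d = 2, a = 0, b = 1, c = 0))
  e1 <- extended_nll(y, X, K, s1)
  e2 <- extended_nll(y, X, K, s2)
  expect_equal(e2, e1, tolerance = 1e-10)
  # the Gaussian part alone differs by N log 2
  l1 <- lmm_nll(y, X, K, beta = 0.3, sigma_g2 = 0.5, sigma_e2 = 0.7)
  l2 <- lmm_nll(2 * y, X, K, beta = 0.6, sigma_g2 = 2, sigma_e2 = 2.8)
  expect_equal(l2 - l1, n * log(2), tolerance = 1e-10)
})

test_that("analytic gradient of the profiled extended NLL matches finite
           differences for every parameter", {
  set.seed(33)
  cfg <- sim_config(n = 50, s = 80, n_causal = 10, h2 = 0.4, t = 0,
                    seed = 33)
  dat <- simulate_dataset(cfg)
  kern <- lmm_kernel(dat$K)
  X <- make_design(n = 50)
  tmpl <- warplmm:::.wlmm_template(dat$observed, "tanh_step", 3)
  tmpl$a <- c(0.3, 0.5, 0.2); tmpl$b <- c(1.2, 0.7, 2)
  tmpl$c <- c(-0.5, 0.1, 0.8)
  Gx <- dat$std[, 1:2]
  obj <- warplmm:::.wlmm_objective(dat$observed, X, kern, tmpl, Gx)
  theta <- c(warplmm:::.warp_theta(tmpl), log(0.8), log(0.3), log(0.1))
  g_an <- obj$gr(theta)
  h <- 1e-6
  g_fd <- vapply(seq_along(theta), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (obj$fn(tp) - obj$fn(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_fd), 1e-3)), 1e-5)

  # Box-Cox family, no extra components
  yb <- exp(dat$latent / 2 + 1)
  objb <- warplmm:::.wlmm_objective(yb, X, kern,
                                    warp_params("boxcox", lambda = 1),
                                    NULL)
  thb <- c(0.6, log(0.5))
  gb <- objb$gr(thb)
  gfd <- vapply(seq_along(thb), function(k) {
    tp <- thb; tm <- thb
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (objb$fn(tp) - objb$fn(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gb - gfd) / pmax(abs(gfd), 1e-3)), 1e-5)
})

test_that("identity-family fit equals standard LMM maximum likelihood", {
  set.seed(34)
  # s < n so the ML variance ratio has an interior optimum
  cfg <- sim_config(n = 60, s = 40, n_causal = 20, h2 = 0.5, t = 1,
                    seed = 34)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$latent, NULL, dat$K,
                                  family = "identity", restarts = 2))
  ml <- suppressWarnings(fit_lmm(dat$latent, make_design(n = 60), dat$K,
                                 reml = FALSE))
  expect_equal(-ft$loglik, ml$nll, tolerance = 1e-6)
  expect_equal(ft$delta_g / (1 + ft$delta_g), ml$h2, tolerance = 1e-4)
  expect_equal(ft$z, unname(dat$latent))
})

test_that("on untransformed data the fitted warp is near-linear over the
           data mass", {
  cfg <- sim_config(n = 1000, s = 1200, n_causal = 50, h2 = 0.4, t = 1,
                    seed = 35)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$observed, NULL, dat$K, seed = 35))
  yg <- sort(dat$observed)
  fg <- warp(yg, ft$warp)
  aff <- lm(fg ~ yg)
  # deviation from the best affine fit, relative to the warped-scale SD
  # (the latent scale itself is only identified up to an affine map);
  # the unpenalized likelihood can place an occasional sharp local step,
  # so near-linearity is asserted for the bulk of the data
  expect_lt(median(abs(residuals(aff))) / sd(fg), 0.02)
  expect_gt(summary(aff)$r.squared, 0.999)
})

test_that("on exp-transformed data the recovered warp composed with exp is
           near-affine (the log is recovered)", {
  cfg <- sim_config(n = 1000, s = 1200, n_causal = 50, h2 = 0.4, t = 0,
                    seed = 36)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(forward_select(dat$observed, NULL, dat$K,
                                        dat$std, seed = 36))
  u <- sort((dat$latent - mean(dat$latent)) / sd(dat$latent))
  fg <- warp(exp(u), ft$warp)          # should be ~ affine in u
  aff <- lm(fg ~ u)
  expect_lt(median(abs(residuals(aff))) / sd(fg), 0.05)
  expect_gt(summary(aff)$r.squared, 0.99)
})

test_that("heritability is recovered without material bias on
           exp-transformed replicates (n = 500, h2 = 0.4)", {
  h2 <- vapply(1:50, function(r) {
    cfg <- sim_config(n = 500, s = 800, n_causal = 100, h2 = 0.4, t = 0,
                      seed = 5000 + r)
    dat <- simulate_dataset(cfg)
    ft <- suppressWarnings(wlmm_fit(dat$observed, NULL, dat$K,
                                    seed = 5000 + r))
    suppressWarnings(estimate_h2(ft)$h2)
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.4), 0.03)
})

test_that("fits are deterministic under a fixed seed", {
  cfg <- sim_config(n = 60, s = 80, n_causal = 10, h2 = 0.4, t = 0,
                    seed = 37)
  dat <- simulate_dataset(cfg)
  f1 <- suppressWarnings(wlmm_fit(dat$observed, NULL, dat$K, seed = 9))
  f2 <- suppressWarnings(wlmm_fit(dat$observed, NULL, dat$K, seed = 9))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$z, f2$z)
})
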