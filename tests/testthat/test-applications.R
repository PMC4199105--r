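test_that("heritability is reported exactly as sigma_g2/(sigma_g2+sigma_e2)", {
  cfg <- sim_config(n = 100, s = 150, n_causal = 30, h2 = 0.5, t = 1,
                    seed = 51)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$latent, NULL, dat$K,
                                  family = "identity", restarts = 1))
  h2 <- estimate_h2(ft)
  expect_equal(h2$h2, h2$sigma_g2 / (h2$sigma_g2 + h2$sigma_e2),
               tolerance = 1e-12)
  expect_true(h2$h2 >= 0 && h2$h2 <= 1)
})

test_that("BLUP matches a dense conditional-Gaussian oracle on a
           12-train / 3-target split", {
  cfg <- sim_config(n = 15, s = 100, n_causal = 20, h2 = 0.8, t = 1,
                    seed = 61)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  std_all <- suppressMessages(standardize_genotypes(g))
  K_all <- compute_kinship(std_all)
  tr <- 1:12; te <- 13:15
  ft <- suppressWarnings(wlmm_fit(ph$latent[tr], NULL, K_all[tr, tr],
                                  family = "identity", restarts = 1))
  pr <- predict(ft, X_star = matrix(1, 3, 1), k_star = K_all[te, tr])

  reml <- suppressWarnings(fit_lmm(ph$latent[tr], matrix(1, 12, 1),
                                   K_all[tr, tr]))
  V <- reml$sigma_g2 * K_all[tr, tr] + reml$sigma_e2 * diag(12)
  cross <- reml$sigma_g2 * K_all[te, tr]
  oracle <- reml$beta + cross %*% solve(V, ph$latent[tr] - reml$beta)
  expect_equal(pr$z_star, unname(drop(oracle)), tolerance = 1e-8)
  expect_equal(pr$y_star, pr$z_star, tolerance = 1e-8)  # identity warp
})

test_that("with sigma_g2 = 0 predictions collapse to the fixed effects,
           and with sigma_e2 -> 0 training samples are reproduced", {
  cfg <- sim_config(n = 40, s = 120, n_causal = 20, h2 = 0.5, t = 0,
                    seed = 53)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(forward_select(dat$observed, NULL, dat$K,
                                        dat$std, seed = 53, restarts = 2))
  Kd <- dat$K
  pr0 <- predict(ft, X_star = matrix(1, 40, 1), k_star = Kd,
                 components = list(sigma_g2 = 0, sigma_e2 = 1))
  expect_equal(pr0$z_star, rep(pr0$z_star[1], 40), tolerance = 1e-10)

  pr1 <- predict(ft, X_star = matrix(1, 40, 1), k_star = Kd,
                 components = list(sigma_g2 = 1, sigma_e2 = 1e-12))
  # f^{-1}(z_hat) on training samples reproduces the observed phenotype
  expect_lt(max(abs(pr1$z_star - ft$z)), 1e-4 * sd(ft$z))
  expect_lt(max(abs(pr1$y_star - dat$observed)),
            1e-3 * sd(dat$observed))
})

test_that("forward-selected components change neither heritability nor
           predictions", {
  cfg <- sim_config(n = 60, s = 100, n_causal = 10, h2 = 0.4, t = 0,
                    seed = 54)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$observed, NULL, dat$K, seed = 54,
                                  restarts = 2))
  h2_before <- suppressWarnings(estimate_h2(ft)$h2)
  pr_before <- predict(ft, matrix(1, 5, 1), dat$K[1:5, ])
  ft2 <- ft
  ft2$extra_components <- list(list(index = 3, g = dat$std[, 3],
                                    sigma2 = 0.5))
  expect_identical(suppressWarnings(estimate_h2(ft2)$h2), h2_before)
  expect_identical(predict(ft2, matrix(1, 5, 1), dat$K[1:5, ]), pr_before)
})

test_that("heritability is invariant to affine rescaling of the observed
           phenotype", {
  cfg <- sim_config(n = 150, s = 250, n_causal = 30, h2 = 0.4, t = 0,
                    seed = 55)
  dat <- simulate_dataset(cfg)
  f1 <- suppressWarnings(wlmm_fit(dat$observed, NULL, dat$K, seed = 55))
  f2 <- suppressWarnings(wlmm_fit(7 * dat$observed - 3, NULL, dat$K,
                                  seed = 55))
  h1 <- suppressWarnings(estimate_h2(f1)$h2)
  h2 <- suppressWarnings(estimate_h2(f2)$h2)
  # the objective differs only by a constant, so agreement is limited by
  # the optimizer's relative stopping rule, not by the model
  expect_lt(abs(h1 - h2), 0.02)
})

test_that("with an identity warp the GWAS scan equals the raw-scale scan", {
  cfg <- sim_config(n = 120, s = 200, n_causal = 20, h2 = 0.4, t = 1,
                    seed = 56)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$latent, NULL, dat$K,
                                  family = "identity", restarts = 1))
  gs <- gwas_scan(dat$latent, NULL, dat$K, dat$std, fit = ft)
  raw <- single_snp_scan(dat$latent, make_design(n = 120), dat$std,
                         dat$K)
  expect_equal(gs$pvalue, raw$pvalue, tolerance = 1e-10)
  expect_true(is.numeric(attr(gs, "lambda_gc")))
  expect_true(all(c("chrom", "pos", "snp_id", "beta", "stat", "pvalue",
                    "qvalue", "significant") %in% colnames(gs)))
})

test_that("LOCO scanning tests each chromosome under the off-chromosome
           kinship", {
  cfg <- sim_config(n = 100, s = 120, n_causal = 20, h2 = 0.4, t = 1,
                    seed = 59)
  dat <- simulate_dataset(cfg)
  chrom <- rep(1:2, each = ncol(dat$std) / 2)
  ft <- suppressWarnings(wlmm_fit(dat$latent, NULL, dat$K,
                                  family = "identity", restarts = 1))
  gl <- gwas_scan(dat$latent, NULL, dat$K, dat$std, fit = ft,
                  chrom = chrom, loco = TRUE)
  # manual check for chromosome 1: kinship from chromosome 2 only
  K2 <- compute_kinship(dat$std[, chrom == 2])
  manual <- single_snp_scan(ft$z, ft$X, dat$std[, chrom == 1], K2)
  expect_equal(gl$pvalue[chrom == 1], manual$pvalue, tolerance = 1e-10)
  expect_error(gwas_scan(dat$latent, NULL, dat$K, dat$std, fit = ft,
                         loco = TRUE), "chrom")
})

test_that("prediction errors early on malformed inputs", {
  cfg <- sim_config(n = 30, s = 50, n_causal = 10, h2 = 0.4, t = 1,
                    seed = 57)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$latent, NULL, dat$K,
                                  family = "identity", restarts = 1))
  expect_error(predict(ft, matrix(1, 2, 1), dat$K[1:2, 1:10]),
               "one column per training sample")
  expect_error(predict(ft, matrix(1, 2, 3), dat$K[1:2, ]),
               "match the training design")
})

test_that("bootstrap SD of heritability is produced and plausible", {
  cfg <- sim_config(n = 150, s = 200, n_causal = 40, h2 = 0.5, t = 1,
                    seed = 58)
  dat <- simulate_dataset(cfg)
  ft <- suppressWarnings(wlmm_fit(dat$latent, NULL, dat$K,
                                  family = "identity", restarts = 1))
  h2 <- suppressWarnings(estimate_h2(ft, bootstrap = 10, K = dat$K))
  expect_false(is.na(h2$bootstrap_sd))
  expect_gt(h2$bootstrap_sd, 0)
  expect_lt(h2$bootstrap_sd, 0.5)
})
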