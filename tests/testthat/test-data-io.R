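test_that("read_plink decodes hand-constructed .bed bytes", {
  # 3 samples x 2 SNPs. Two-bit codes per sample, lowest bits first:
  #   dosage 2 -> 00, dosage 1 -> 10, dosage 0 -> 11, missing -> 01
  # SNP1 dosages (0, 1, 2) -> codes (3, 2, 0) -> byte 3 + 2*4 + 0*16 = 11
  # SNP2 dosages (2, NA, 0) -> codes (0, 1, 3) -> byte 0 + 1*4 + 3*16 = 52
  prefix <- file.path(tempdir(), "fix1")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11, 52)), paste0(prefix, ".bed"))
  writeLines(c("1\ts1\t0\t100\tA\tG", "1\ts2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t0\t-9", "f2\ti2\t0\t0\t0\t-9",
               "f3\ti3\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  g <- read_plink(prefix)
  expect_equal(unname(g$dosages),
               rbind(c(0, 2), c(1, NA), c(2, 0)))
  expect_equal(g$sample_ids, c("i1", "i2", "i3"))
  expect_equal(g$snp_ids, c("s1", "s2"))
  expect_equal(g$pos, c(100L, 200L))
})

test_that("read_plink rejects a .bed whose size disagrees with .fam/.bim", {
  # .bed sized for 5 samples (2 bytes per SNP) against a 3-row .fam
  prefix <- file.path(tempdir(), "fix2")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11, 0, 52, 0)), paste0(prefix, ".bed"))
  writeLines(c("1\ts1\t0\t100\tA\tG", "1\ts2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t0\t-9", "f2\ti2\t0\t0\t0\t-9",
               "f3\ti3\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "format error")
  expect_error(read_plink(file.path(tempdir(), "nosuch")), "not found")
})

test_that("PLINK write/read round trip preserves dosages and identifiers", {
  set.seed(5)
  d <- matrix(sample(c(0, 1, 2, NA), 9 * 7, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 9, 7)
  d[1, ] <- c(0, 1, 2, 0, 1, 2, NA)  # ensure all codes appear
  g <- genotype_data(d, sample_ids = sprintf("id%02d", 1:9),
                     snp_ids = sprintf("rs%d", 1:7),
                     chrom = rep(1L, 7), pos = 1:7)
  prefix <- file.path(tempdir(), "fix3")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$sample_ids, g$sample_ids)
  expect_equal(g2$snp_ids, g$snp_ids)
})

test_that("genotype CSV round trip and input validation", {
  d <- rbind(c(0, 2), c(1, 1), c(2, 0))
  g <- genotype_data(d)
  path <- file.path(tempdir(), "geno.csv")
  utils::write.csv(data.frame(id = g$sample_ids, g$dosages,
                              check.names = FALSE),
                   path, row.names = FALSE)
  g2 <- read_genotype_csv(path)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_error(genotype_data(rbind(c(0, 3), c(1, 1))), "0, 1, 2")
  expect_error(genotype_data(d, sample_ids = c("a", "a", "b")), "unique")
})

test_that("standardization centres, scales, drops monomorphic SNPs and
           mean-imputes missing entries", {
  d <- cbind(c(0, 1, 2), c(2, 2, 2))
  expect_message(std <- standardize_genotypes(genotype_data(d)),
                 "monomorphic")
  expect_equal(ncol(std), 1L)
  expect_equal(mean(std[, 1]), 0, tolerance = 1e-12)
  expect_equal(var(std[, 1]), 1, tolerance = 1e-10)

  # hand computation for a column with one missing value:
  # observed (0, 1, 2, 1): mean 1, var 2/3 -> std obs (-sqrt(1.5), 0,
  # sqrt(1.5), 0), missing cell -> 0
  d2 <- cbind(c(0, 1, NA, 2, 1), c(0, 0, 1, 2, 1))
  std2 <- standardize_genotypes(genotype_data(d2))
  expect_equal(unname(std2[3, 1]), 0)
  expect_equal(unname(std2[, 1]),
               c(-sqrt(1.5), 0, 0, sqrt(1.5), 0), tolerance = 1e-12)

  expect_error(standardize_genotypes(genotype_data(cbind(c(2, 2, 2)))),
               "no informative SNPs")
})

test_that("phenotype/covariate readers and sample joining", {
  pp <- file.path(tempdir(), "pheno.csv")
  writeLines(c("id,trait", "i1,1.5", "i2,NA", paste0("i", 3:14, ",", 3:14)),
             pp)
  y <- read_phenotype(pp, "trait")
  expect_equal(unname(y[c("i1", "i3")]), c(1.5, 3))
  expect_true(is.na(y["i2"]))

  set.seed(1)
  d <- matrix(sample(0:2, 15 * 4, replace = TRUE), 15, 4)
  g <- genotype_data(d, sample_ids = paste0("i", 1:15))
  expect_message(al <- align_samples(g, y), "dropped")
  expect_equal(length(al$y), 13L)  # i2 missing phenotype, i15 absent
  expect_equal(al$geno$sample_ids, paste0("i", c(1, 3:14)))
  expect_equal(colnames(al$X), "(Intercept)")
})
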