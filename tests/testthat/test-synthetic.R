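# Synthetic-data generator: genotypes, phenotypes, summary statistics and
# the two-sample dataset writer.

test_that("genotype dosages are in range and deterministic given the seed", {
  G1 <- simulate_genotypes(200, 5, c(0.1, 0.4), seed = 11)
  G2 <- simulate_genotypes(200, 5, c(0.1, 0.4), seed = 11)
  expect_identical(G1, G2)
  expect_true(all(G1 %in% 0:2))
  # rare-allele boundary: frequencies near the lower bound, dosages valid
  Gr <- simulate_genotypes(100, 3, c(0.001, 0.001), seed = 1)
  expect_true(all(Gr %in% 0:2))
  expect_lt(mean(colMeans(Gr) / 2), 0.02)
  expect_error(simulate_genotypes(10, 2, c(0, 0.5)))
  expect_error(simulate_genotypes(0, 2, c(0.1, 0.5)))
})

test_that("empirical allele frequencies match the drawn MAFs (binomial oracle)", {
  G <- simulate_genotypes(10000, 50, c(0.05, 0.5), seed = 1)
  maf <- attr(G, "maf")
  emp <- colMeans(G) / 2
  tol <- 3 * sqrt(maf * (1 - maf) / (2 * 10000))
  expect_true(all(abs(emp - maf) <= tol))
})

test_that("adding SNPs does not perturb earlier columns' draws", {
  G1 <- simulate_genotypes(500, 10, c(0.05, 0.5), seed = 7)
  G2 <- simulate_genotypes(500, 25, c(0.05, 0.5), seed = 7)
  expect_identical(G1[, 1:10], G2[, 1:10])
  expect_identical(attr(G1, "maf"), attr(G2, "maf")[1:10])
})

test_that("instruments explain the configured fraction of exposure variance", {
  cfg <- synthetic_config(n_exposure_cohort = 100000, n_snps = 96,
                          exposure_h2 = 0.016, seed = 5)
  ss <- adipomr:::stage_seeds(cfg$seed)
  G <- simulate_genotypes(cfg$n_exposure_cohort, cfg$n_snps,
                          c(cfg$maf_low, cfg$maf_high),
                          seed = ss[["geno_exposure"]])
  mod <- true_model(cfg, attr(G, "maf"))
  ph <- simulate_phenotypes(G, mod, cfg, what = "exposure")
  r2 <- variance_explained(genotypes = G, exposure = ph$exposure)
  expect_lt(abs(r2 - 0.016), 0.003)
})

test_that("the solved intercept hits the target prevalence", {
  cfg <- synthetic_config(n_outcome_cohort = 50000, n_exposure_cohort = 1000,
                          n_snps = 30, outcome_prevalence = 0.10, seed = 9)
  ss <- adipomr:::stage_seeds(cfg$seed)
  G <- simulate_genotypes(cfg$n_outcome_cohort, cfg$n_snps,
                          c(cfg$maf_low, cfg$maf_high),
                          seed = ss[["geno_outcome"]])
  mod <- true_model(cfg, attr(G, "maf"))
  ph <- simulate_phenotypes(G, mod, cfg)
  expect_gte(mean(ph$outcome), 0.095)
  expect_lte(mean(ph$outcome), 0.105)
})

test_that("per-SNP regression slopes match closed-form least squares", {
  G <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 1,
              dimnames = list(NULL, "rs1"))
  y <- c(1, 1, 2, 2, 3, 3)
  st <- compute_summary_stats(G, y, "continuous")
  expect_equal(st$beta, 1.0, tolerance = 1e-12)
  # against lm() on a random fixture
  set.seed(3)
  G2 <- simulate_genotypes(80, 4, c(0.2, 0.5), seed = 3)
  y2 <- rnorm(80) + 0.3 * G2[, 2]
  st2 <- compute_summary_stats(G2, y2, "continuous")
  for (j in 1:4) {
    ref <- summary(lm(y2 ~ G2[, j]))$coefficients[2, ]
    expect_equal(st2$beta[j], unname(ref["Estimate"]), tolerance = 1e-8)
    expect_equal(st2$se[j], unname(ref["Std. Error"]), tolerance = 1e-8)
    expect_equal(st2$pval[j], unname(ref["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("per-SNP logistic slopes match glm()", {
  set.seed(4)
  G <- simulate_genotypes(500, 3, c(0.2, 0.5), seed = 4)
  y <- rbinom(500, 1, plogis(-1 + 0.4 * G[, 1]))
  st <- compute_summary_stats(G, y, "binary")
  for (j in 1:3) {
    ref <- summary(glm(y ~ G[, j], family = binomial))$coefficients[2, ]
    expect_equal(st$beta[j], unname(ref["Estimate"]), tolerance = 1e-6)
    expect_equal(st$se[j], unname(ref["Std. Error"]), tolerance = 1e-6)
  }
})

test_that("degenerate phenotypes flag every SNP and yield empty output", {
  G <- simulate_genotypes(50, 4, c(0.2, 0.5), seed = 2)
  st <- compute_summary_stats(G, rep(2.5, 50), "continuous")
  expect_equal(nrow(st), 0)
  expect_equal(nrow(attr(st, "dropped")), 4)
  # monomorphic SNP is flagged and excluded with a log entry
  G[, 2] <- 0
  y <- rnorm(50)
  st2 <- compute_summary_stats(G, y, "continuous")
  expect_equal(nrow(st2), 3)
  expect_true("rs2" %in% attr(st2, "dropped")$variant_id)
  expect_error(compute_summary_stats(G, c(y[-1], 5), "binary"),
               "0/1")
})

test_that("null outcome associations have uniform p-values (type I error)", {
  cfg <- synthetic_config(n_exposure_cohort = 100, n_outcome_cohort = 4000,
                          n_snps = 200, true_effect = 0,
                          outcome_prevalence = 0.3, seed = 21)
  ss <- adipomr:::stage_seeds(cfg$seed)
  G <- simulate_genotypes(cfg$n_outcome_cohort, cfg$n_snps,
                          c(cfg$maf_low, cfg$maf_high),
                          seed = ss[["geno_outcome"]])
  mod <- true_model(cfg, attr(G, "maf"))
  ph <- simulate_phenotypes(G, mod, cfg)
  st <- compute_summary_stats(G, ph$outcome, "binary")
  frac <- mean(st$pval < 0.05)
  # binomial 99.7% band around 0.05 with 200 SNPs
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("two-sample dataset generation is byte-identical given the seed", {
  cfg <- small_config(seed = 13, second_exposure = list(h2 = 0.04, cor = 0.5))
  d1 <- file.path(tempdir(), "synthA"); d2 <- file.path(tempdir(), "synthB")
  generate_two_sample_dataset(cfg, dir = d1)
  generate_two_sample_dataset(cfg, dir = d2)
  for (f in c("exposure.tsv", "exposure2.tsv", "outcome.tsv", "truth.txt"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("write-then-read round trip preserves records exactly", {
  cfg <- small_config(seed = 17)
  ds <- generate_two_sample_dataset(cfg)
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(ds$exposure, path)
  back <- read_summary_stats(path)
  expect_equal(back[, names(ds$exposure)], ds$exposure,
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("planted outliers and pleiotropy modes are wired into the truth", {
  cfg <- small_config(seed = 19, pleiotropy_mode = "planted_outliers",
                      n_outliers = 3, outlier_effect = 0.2)
  ds <- generate_two_sample_dataset(cfg)
  tm <- ds$true_model
  expect_length(tm$outlier_idx, 3)
  # direct effects oriented to the exposure-increasing allele
  expect_true(all(abs(tm$per_snp_direct_effects[tm$outlier_idx]) == 0.2))
  expect_equal(sign(tm$per_snp_direct_effects[tm$outlier_idx]),
               sign(tm$per_snp_exposure_effects[tm$outlier_idx]))
  expect_true(all(tm$per_snp_direct_effects[-tm$outlier_idx] == 0))
  expect_error(synthetic_config(pleiotropy_mode = "none", n_outliers = 2))
  cfg2 <- small_config(seed = 19, pleiotropy_mode = "none")
  expect_true(all(true_model(cfg2, rep(0.3, 20))$per_snp_direct_effects == 0))
})
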