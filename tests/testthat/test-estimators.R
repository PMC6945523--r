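# Wald ratios, IVW, weighted median, MR-Egger, multivariable MR.

test_that("Wald ratio estimates are element-wise division with delta SE", {
  ins <- data.frame(variant_id = "rs1", gamma = 0.2, se_gamma = 0.01,
                    Gamma = 0.02, se_Gamma = 0.01)
  r <- ratio_estimates(ins)
  expect_equal(r$ratio, 0.10)
  expect_equal(r$se_ratio, 0.05)
  # brute-force recomputation on a random set
  ins2 <- make_instruments(J = 25, seed = 41)
  r2 <- ratio_estimates(ins2)
  expect_equal(r2$ratio, ins2$Gamma / ins2$gamma, tolerance = 1e-15)
  expect_equal(r2$se_ratio, ins2$se_Gamma / abs(ins2$gamma), tolerance = 1e-15)
  # allele-flip symmetry: negating both associations leaves the ratio alone
  flipped <- ins2
  flipped$gamma <- -flipped$gamma
  flipped$Gamma <- -flipped$Gamma
  expect_equal(ratio_estimates(flipped)$ratio, r2$ratio)
  # zero exposure association is undefined
  ins2$gamma[3] <- 0
  expect_error(ratio_estimates(ins2), "rs3")
})

test_that("IVW collapses to the single ratio at J = 1 and matches the closed form", {
  one <- data.frame(variant_id = "rs1", gamma = 0.2, se_gamma = 0.01,
                    Gamma = 0.02, se_Gamma = 0.01)
  est <- mr_ivw(one)
  expect_equal(est$beta, 0.10)
  expect_equal(est$se, 0.05)
  expect_true(is.na(est$cochran_q))
  # three hand-specified ratios: weighted mean with w = 1/se^2
  r <- c(0.10, 0.12, 0.08); s <- c(0.02, 0.03, 0.04)
  ins <- data.frame(variant_id = paste0("v", 1:3), gamma = 1,
                    se_gamma = 1e-6, Gamma = r, se_Gamma = s)
  w <- 1 / s^2
  expect_equal(mr_ivw(ins, "fixed")$beta, sum(w * r) / sum(w),
               tolerance = 1e-12)
  expect_equal(mr_ivw(ins, "fixed")$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("IVW fixed effect equals the no-intercept WLS slope (identity)", {
  for (s in 1:20) {
    set.seed(1000 + s)
    ins <- make_instruments(J = sample(3:30, 1), beta = runif(1, -0.3, 0.3),
                            seed = 100 + s)
    fit <- lm(Gamma ~ 0 + gamma, data = ins, weights = 1 / ins$se_Gamma^2)
    expect_equal(mr_ivw(ins, "fixed")$beta, unname(coef(fit)),
                 tolerance = 1e-10)
  }
})

test_that("random-effects SE never falls below the fixed-effect SE", {
  for (s in 1:10) {
    set.seed(2000 + s)
    ins <- make_instruments(J = 15, seed = 200 + s,
                            alpha = rnorm(15, 0, 0.02 * (s %% 2)))
    expect_gte(mr_ivw(ins)$se, mr_ivw(ins, "fixed")$se)
  }
})

weighted_median_point_of <- function(ins)
  mr_weighted_median(ins, n_boot = 100, seed = 1)$beta

test_that("estimators are invariant to instrument order and representation", {
  ins <- make_instruments(J = 20, seed = 51)
  set.seed(52)
  perm <- sample(20)
  shuffled <- ins[perm, ]
  repped <- ins
  flip <- c(TRUE, FALSE)[1 + (seq_len(20) %% 2)]
  repped$gamma[flip] <- -repped$gamma[flip]
  repped$Gamma[flip] <- -repped$Gamma[flip]
  for (alt in list(shuffled, repped)) {
    expect_equal(mr_ivw(alt)$beta, mr_ivw(ins)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(alt)$beta, mr_egger(ins)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(alt)$egger_intercept, mr_egger(ins)$egger_intercept,
                 tolerance = 1e-12)
    expect_equal(weighted_median_point_of(alt), weighted_median_point_of(ins),
                 tolerance = 1e-12)
  }
})

test_that("weighted median reduces to the simple median and honours dominance", {
  # equal weights, odd J
  r <- c(0.05, 0.2, 0.11, 0.08, 0.30)
  ins <- data.frame(variant_id = paste0("v", 1:5), gamma = 1, se_gamma = 1e-6,
                    Gamma = r, se_Gamma = 0.01)
  suppressWarnings(est <- mr_weighted_median(ins, n_boot = 50, seed = 1))
  expect_equal(est$beta, median(r))
  # one SNP carries > 50% of the weight: its ratio is returned exactly
  ins$se_Gamma <- c(0.1, 0.1, 0.001, 0.1, 0.1)
  suppressWarnings(est2 <- mr_weighted_median(ins, n_boot = 50, seed = 1))
  expect_equal(est2$beta, 0.11)
  # estimate always lies within the ratio range; bootstrap is seeded
  ins2 <- make_instruments(J = 9, seed = 61)
  e1 <- mr_weighted_median(ins2, n_boot = 200, seed = 5)
  e2 <- mr_weighted_median(ins2, n_boot = 200, seed = 5)
  expect_identical(e1$beta, e2$beta)
  expect_identical(e1$se, e2$se)
  rr <- ratio_estimates(ins2)$ratio
  expect_gte(e1$beta, min(rr))
  expect_lte(e1$beta, max(rr))
  expect_error(mr_weighted_median(ins2[1:2, ]))
  expect_warning(mr_weighted_median(ins2, n_boot = 50, seed = 1), "n_boot")
})

test_that("MR-Egger recovers an exactly constant pleiotropic offset", {
  set.seed(71)
  gamma <- runif(8, 0.02, 0.1)
  cst <- 0.03; slope <- 0.12
  ins <- data.frame(variant_id = paste0("v", 1:8), gamma = gamma,
                    se_gamma = 0.005, Gamma = cst + slope * gamma,
                    se_Gamma = 0.01)
  est <- mr_egger(ins)
  expect_equal(est$beta, slope, tolerance = 1e-10)
  expect_equal(est$egger_intercept, cst, tolerance = 1e-10)
  expect_equal(est$cochran_q, 0, tolerance = 1e-16)
  # guards
  expect_error(mr_egger(ins[1:2, ]))
  ins$gamma <- 0.05
  expect_error(mr_egger(ins), "spread")
})

test_that("the Egger intercept detects directional pleiotropy", {
  hits <- vapply(1:50, function(s) {
    set.seed(400 + s)
    alpha <- rnorm(60, 0.04, 0.01)  # consistent direct effects
    ins <- make_instruments(J = 60, beta = 0.1, alpha = alpha, seed = 500 + s)
    eg <- mr_egger(ins)
    eg$intercept_p < 0.05 && eg$egger_intercept > 0
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("MVMR with a zero second exposure equals univariable IVW", {
  ins <- add_second_exposure(make_instruments(J = 12, seed = 81))
  ins$gamma2 <- 0
  mv <- mr_mvmr(ins)
  uni <- mr_ivw(ins)
  expect_equal(mv$exposure1$beta, uni$beta, tolerance = 1e-12)
  expect_equal(mv$exposure1$se, uni$se, tolerance = 1e-12)
  expect_null(mv$exposure2)
  # exact collinearity is a hard error
  ins2 <- add_second_exposure(make_instruments(J = 12, seed = 82))
  ins2$gamma2 <- 2 * ins2$gamma
  expect_error(mr_mvmr(ins2), "collinear")
})

test_that("MVMR recovers opposite-signed direct effects from summary data", {
  # Gamma built directly from the structural model with known noise scale
  recover <- function(seed) {
    set.seed(seed)
    J <- 40
    g1 <- rnorm(J, 0.05, 0.02)
    g2 <- 0.5 * g1 + sqrt(0.75) * rnorm(J, 0, 0.02) + 0.025
    se_G <- 0.01
    ins <- data.frame(variant_id = paste0("v", 1:J),
                      gamma = g1, se_gamma = 1e-4,
                      gamma2 = g2, se_gamma2 = 1e-4,
                      Gamma = 0.3 * g1 - 0.1 * g2 + rnorm(J, 0, se_G),
                      se_Gamma = se_G)
    mr_mvmr(ins)
  }
  ests <- lapply(1:30, recover)
  b1 <- vapply(ests, function(e) e$exposure1$beta, numeric(1))
  b2 <- vapply(ests, function(e) e$exposure2$beta, numeric(1))
  expect_lt(abs(mean(b1) - 0.3), 2 * sd(b1) / sqrt(30))
  expect_lt(abs(mean(b2) + 0.1), 2 * sd(b2) / sqrt(30))
})

test_that("estimate objects are internally consistent", {
  ins <- make_instruments(J = 10, seed = 91)
  est <- mr_ivw(ins)
  expect_equal(est$odds_ratio, exp(est$beta))
  expect_lt(est$ci_low, est$beta); expect_gt(est$ci_high, est$beta)
  expect_equal(unname(coef(est)), est$beta)
  ci <- confint(est)
  expect_equal(unname(ci[1, 1]), est$ci_low)
  expect_equal(est$pval, 2 * pnorm(-abs(est$beta / est$se)))
})
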