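#' Configure a synthetic two-sample MR study
#'
#' Collects and validates the full data-generating parameterization for the
#' synthetic GWAS module: cohort sizes, instrument count and allele-frequency
#' range, the fraction of exposure variance explained by the instruments, the
#' causal effect on the binary outcome, baseline outcome prevalence, and the
#' pleiotropy scenario. The defaults emulate the design of a two-sample MR
#' study of adiposity and cardiovascular disease: ~96 independent instruments
#' explaining ~1.6\% of exposure variance, two cohorts of 50,000, a low
#' outcome prevalence, and no pleiotropy.
#'
#' @param n_exposure_cohort Individuals in the exposure (SNP-exposure) cohort.
#' @param n_outcome_cohort Individuals in the disjoint outcome cohort.
#' @param n_snps Number of independent biallelic instruments (J).
#' @param maf_low,maf_high Minor-allele-frequency bounds, `0 < maf_low <=
#'   maf_high <= 0.5`.
#' @param exposure_h2 Fraction of exposure variance explained by the
#'   instruments jointly, in `[0, 1)`. The exposure is scaled to unit
#'   variance, so this is also the instruments' R-squared at large n.
#' @param true_effect Causal log odds ratio per unit of exposure.
#' @param outcome_prevalence Target marginal event probability in `(0, 1)`;
#'   the intercept of the liability model is solved numerically to hit it.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (direct SNP-outcome
#'   effects with zero mean), `"directional"` (nonzero mean, violating the
#'   InSIDE-free validity of IVW), or `"planted_outliers"` (a few SNPs with
#'   large fixed direct effects).
#' @param pleiotropy_sd SD of the per-SNP direct log-odds effects.
#' @param pleiotropy_mean Mean direct effect under `"directional"` mode.
#' @param pleiotropy_frac Fraction of SNPs carrying pleiotropic effects under
#'   `"balanced"`/`"directional"` modes (1 = all).
#' @param n_outliers Number of planted outlier SNPs (only with
#'   `pleiotropy_mode = "planted_outliers"`).
#' @param outlier_effect Direct log odds ratio per allele of each planted
#'   outlier SNP.
#' @param second_exposure Optional list describing a second, correlated
#'   exposure for multivariable MR: `list(h2 =, cor =, true_effect =)` where
#'   `cor` is the correlation of per-SNP instrument effects between the two
#'   exposures (e.g. fat mass and fat-free mass index both loading on the
#'   same variants).
#' @param seed Master seed; all stages derive independent streams from it.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_two_sample_dataset()]
#' @export
synthetic_config <- function(n_exposure_cohort = 50000L,
                             n_outcome_cohort = 50000L,
                             n_snps = 96L,
                             maf_low = 0.05, maf_high = 0.5,
                             exposure_h2 = 0.016,
                             true_effect = log(1.10),
                             outcome_prevalence = 0.10,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional",
                                                 "planted_outliers"),
                             pleiotropy_sd = 0,
                             pleiotropy_mean = 0,
                             pleiotropy_frac = 1,
                             n_outliers = 0L,
                             outlier_effect = 0,
                             second_exposure = NULL,
                             seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(
    n_exposure_cohort >= 1, n_outcome_cohort >= 1, n_snps >= 1,
    is.numeric(maf_low), is.numeric(maf_high),
    maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
    exposure_h2 >= 0, exposure_h2 < 1,
    outcome_prevalence > 0, outcome_prevalence < 1,
    pleiotropy_sd >= 0, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
    n_outliers >= 0, n_outliers <= n_snps
  )
  if (pleiotropy_mode != "planted_outliers" && n_outliers > 0)
    stop("n_outliers must be 0 unless pleiotropy_mode = 'planted_outliers'")
  if (!is.null(second_exposure)) {
    stopifnot(is.list(second_exposure))
    second_exposure <- list(
      h2 = second_exposure$h2 %||% exposure_h2,
      cor = second_exposure$cor %||% 0.5,
      true_effect = second_exposure$true_effect %||% 0
    )
    stopifnot(second_exposure$h2 >= 0, second_exposure$h2 < 1,
              abs(second_exposure$cor) <= 1)
  }
  structure(list(
    n_exposure_cohort = as.integer(n_exposure_cohort),
    n_outcome_cohort = as.integer(n_outcome_cohort),
    n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high,
    exposure_h2 = exposure_h2, true_effect = true_effect,
    outcome_prevalence = outcome_prevalence,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_frac = pleiotropy_frac,
    n_outliers = as.integer(n_outliers), outlier_effect = outlier_effect,
    second_exposure = second_exposure,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed per-stage sub-seeds spawned from the master seed, so that e.g. the
# outcome-cohort draws do not shift when the exposure cohort grows. Genotype
# columns and per-SNP effects additionally use stage_seed + j streams, so
# raising n_snps leaves earlier SNPs' draws untouched.
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(2^30, 8L)
  names(s) <- c("maf", "effects", "pleiotropy", "geno_exposure",
                "geno_outcome", "noise_exposure", "noise_outcome", "alleles")
  s
}

#' Simulate unlinked biallelic genotype dosages
#'
#' Each column j draws its minor-allele frequency uniformly within
#' `maf_bounds` and then n dosages from Binomial(2, maf_j); columns are
#' independent (instruments are index SNPs from distinct loci, so linkage is
#' not modelled). Column j is a deterministic function of `(seed, j, n)`:
#' adding SNPs never perturbs earlier columns.
#'
#' @param n Number of individuals (rows).
#' @param n_snps Number of SNPs (columns).
#' @param maf_bounds Length-2 vector of minor-allele-frequency bounds.
#' @param seed Integer seed for this stage.
#' @param maf Optional vector of fixed allele frequencies (overrides the
#'   uniform draw; recycled to `n_snps`).
#' @return An `n x n_snps` integer matrix of dosages in \{0, 1, 2\} with the
#'   drawn frequencies in `attr(, "maf")`.
#' @export
simulate_genotypes <- function(n, n_snps, maf_bounds = c(0.05, 0.5),
                               seed = 1L, maf = NULL) {
  stopifnot(n >= 1, n_snps >= 1, length(maf_bounds) == 2,
            maf_bounds[1] > 0, maf_bounds[1] <= maf_bounds[2],
            maf_bounds[2] <= 0.5)
  if (!is.null(maf)) maf <- rep_len(maf, n_snps)
  G <- matrix(0L, n, n_snps)
  p <- numeric(n_snps)
  for (j in seq_len(n_snps)) {
    set.seed(seed + j)
    p[j] <- if (is.null(maf)) runif(1, maf_bounds[1], maf_bounds[2]) else maf[j]
    G[, j] <- rbinom(n, 2L, p[j])
  }
  colnames(G) <- paste0("rs", seq_len(n_snps))
  attr(G, "maf") <- p
  G
}

#' Draw the structural (true) model of a synthetic study
#'
#' Draws per-SNP exposure effects scaled so the instruments jointly explain
#' `exposure_h2` of a unit-variance exposure, per-SNP direct (pleiotropic)
#' outcome effects according to the configured scenario, and — when a second
#' exposure is configured — a second effect vector with the requested
#' cross-loading correlation. The returned object carries the ground truth
#' that every downstream estimator targets.
#'
#' @param config A [synthetic_config()].
#' @param maf Per-SNP allele frequencies (used to scale effects so that
#'   genetic variance `sum(2 p (1-p) gamma^2)` equals the target h2).
#' @return A list of class `true_model`: `per_snp_exposure_effects`,
#'   `per_snp_exposure2_effects` (or NULL), `per_snp_direct_effects`,
#'   `outlier_idx`, `true_effect`, `true_effect2`.
#' @export
true_model <- function(config, maf) {
  stopifnot(inherits(config, "synthetic_config"),
            length(maf) == config$n_snps)
  ss <- stage_seeds(config$seed)
  J <- config$n_snps
  raw <- raw2 <- numeric(J)
  has2 <- !is.null(config$second_exposure)
  rho <- if (has2) config$second_exposure$cor else 0
  for (j in seq_len(J)) {
    set.seed(ss[["effects"]] + j)
    z <- rnorm(2L)
    raw[j] <- z[1]
    raw2[j] <- rho * z[1] + sqrt(max(0, 1 - rho^2)) * z[2]
  }
  vj <- 2 * maf * (1 - maf)
  scale_to_h2 <- function(r, h2) {
    gv <- sum(vj * r^2)
    if (h2 == 0 || gv == 0) rep(0, J) else r * sqrt(h2 / gv)
  }
  gamma <- scale_to_h2(raw, config$exposure_h2)
  gamma2 <- if (has2) scale_to_h2(raw2, config$second_exposure$h2) else NULL

  # Directional pleiotropy and planted outliers are expressed relative to
  # the exposure-increasing allele (alpha aligned with sign(gamma)): a
  # consistent direct-effect direction for the allele that raises the
  # exposure, as in InSIDE-violating scenarios. Balanced pleiotropy is
  # zero-mean, so orientation is immaterial.
  alpha <- rep(0, J)
  outlier_idx <- integer(0)
  set.seed(ss[["pleiotropy"]])
  orient <- ifelse(gamma >= 0, 1, -1)
  if (config$pleiotropy_mode %in% c("balanced", "directional")) {
    mu <- if (config$pleiotropy_mode == "directional") config$pleiotropy_mean else 0
    carrier <- if (config$pleiotropy_frac >= 1) seq_len(J) else
      sort(sample.int(J, max(1L, round(config$pleiotropy_frac * J))))
    alpha[carrier] <- orient[carrier] *
      rnorm(length(carrier), mu, config$pleiotropy_sd)
  } else if (config$pleiotropy_mode == "planted_outliers" &&
             config$n_outliers > 0) {
    outlier_idx <- sort(sample.int(J, config$n_outliers))
    alpha[outlier_idx] <- orient[outlier_idx] * config$outlier_effect
  }
  structure(list(
    per_snp_exposure_effects = gamma,
    per_snp_exposure2_effects = gamma2,
    per_snp_direct_effects = alpha,
    outlier_idx = outlier_idx,
    true_effect = config$true_effect,
    true_effect2 = if (has2) config$second_exposure$true_effect else NULL
  ), class = "true_model")
}

#' Simulate exposure and outcome phenotypes from genotypes
#'
#' The exposure is `X_i = sum_j gamma_j g_ij + e_i` with the residual scaled
#' so that the instruments explain `exposure_h2` of a unit-variance exposure.
#' The binary outcome follows a logistic model
#' `logit(p_i) = b0 + theta * X_i (+ theta2 * X2_i) + sum_j alpha_j g_ij`,
#' with the intercept `b0` solved by root-finding so the expected marginal
#' event rate equals `outcome_prevalence` (absolute tolerance 5e-4 on the
#' expectation; the realized rate then differs only by binomial noise).
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param model A [true_model()] conforming to the genotype columns.
#' @param config The [synthetic_config()].
#' @param noise_seed,outcome_seed Stage seeds for the residual and Bernoulli
#'   draws (defaults derived from `config$seed`).
#' @param what `"both"` (default), `"exposure"` or `"outcome"`.
#' @return A list with `exposure` (numeric), `exposure2` (numeric or NULL)
#'   and `outcome` (integer 0/1 or NULL), plus the solved intercept `b0`.
#' @export
simulate_phenotypes <- function(genotypes, model, config,
                                noise_seed = NULL, outcome_seed = NULL,
                                what = c("both", "exposure", "outcome")) {
  what <- match.arg(what)
  stopifnot(inherits(model, "true_model"),
            length(model$per_snp_exposure_effects) == ncol(genotypes))
  ss <- stage_seeds(config$seed)
  noise_seed <- noise_seed %||% ss[["noise_exposure"]]
  outcome_seed <- outcome_seed %||% ss[["noise_outcome"]]
  n <- nrow(genotypes)
  has2 <- !is.null(model$per_snp_exposure2_effects)

  set.seed(noise_seed)
  gX <- drop(genotypes %*% model$per_snp_exposure_effects)
  X <- gX + rnorm(n, 0, sqrt(1 - config$exposure_h2))
  X2 <- NULL
  if (has2) {
    gX2 <- drop(genotypes %*% model$per_snp_exposure2_effects)
    X2 <- gX2 + rnorm(n, 0, sqrt(1 - config$second_exposure$h2))
  }
  y <- NULL
  b0 <- NA_real_
  if (what != "exposure") {
    eta <- model$true_effect * X
    if (has2) eta <- eta + model$true_effect2 * X2
    if (any(model$per_snp_direct_effects != 0))
      eta <- eta + drop(genotypes %*% model$per_snp_direct_effects)
    f <- function(b) mean(stats::plogis(b + eta)) - config$outcome_prevalence
    b0 <- uniroot(f, c(-40, 20), tol = 5e-4)$root
    set.seed(outcome_seed)
    y <- rbinom(n, 1L, stats::plogis(b0 + eta))
  }
  list(exposure = X, exposure2 = X2, outcome = y, b0 = b0)
}

#' Per-SNP GWAS summary statistics from individual-level data
#'
#' Regresses the phenotype on each SNP separately — simple linear regression
#' for a continuous trait, logistic regression for a binary trait — exactly
#' as GWAS summary statistics are produced, and returns one record per SNP:
#' the per-allele slope (log odds ratio for binary traits), its standard
#' error, a two-sided Wald p-value and the sample size. The effect allele is
#' the counted (dosage) allele; its frequency is taken from the dosages.
#' Monomorphic or non-converged SNPs are excluded and logged in
#' `attr(, "dropped")`.
#'
#' @param genotypes Dosage matrix (individuals x SNPs, values 0/1/2).
#' @param phenotype Numeric phenotype; for `kind = "binary"` must be 0/1.
#' @param kind `"continuous"` or `"binary"`.
#' @param effect_alleles,other_alleles Optional per-SNP allele labels
#'   (defaults "A"/"G").
#' @return A summary-statistics data frame (see [read_summary_stats()] for
#'   the column contract) with excluded SNPs in `attr(, "dropped")`.
#' @export
compute_summary_stats <- function(genotypes, phenotype,
                                  kind = c("continuous", "binary"),
                                  effect_alleles = NULL,
                                  other_alleles = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(phenotype) == nrow(genotypes))
  J <- ncol(genotypes)
  ids <- colnames(genotypes) %||% paste0("rs", seq_len(J))
  if (kind == "binary") {
    if (!all(phenotype %in% c(0, 1)))
      stop("binary phenotype must be coded 0/1")
    fit <- .logistic_scan_cpp(genotypes, as.integer(phenotype))
  } else {
    fit <- .linear_scan_cpp(genotypes, as.numeric(phenotype))
  }
  out <- data.frame(
    variant_id = ids,
    effect_allele = effect_alleles %||% rep("A", J),
    other_allele = other_alleles %||% rep("G", J),
    eaf = colMeans(genotypes) / 2,
    beta = fit$beta, se = fit$se, pval = fit$pval,
    n = nrow(genotypes),
    stringsAsFactors = FALSE
  )
  flagged <- which(fit$flagged)
  dropped <- data.frame(variant_id = ids[flagged],
                        reason = rep("monomorphic or unstable fit",
                                     length(flagged)),
                        stringsAsFactors = FALSE)
  out <- out[!fit$flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# Deterministic non-palindromic allele labels per SNP (palindromic A/T, C/G
# pairs are avoided so that harmonization of the generator's own output is
# exact; real-data ambiguity is exercised through hand-built fixtures).
assign_alleles <- function(n_snps, seed) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  set.seed(seed)
  idx <- sample.int(nrow(pairs), n_snps, replace = TRUE)
  list(effect = pairs[idx, 1], other = pairs[idx, 2])
}

#' Generate a full two-sample synthetic MR dataset
#'
#' Runs the complete generative model: genotypes for two disjoint cohorts
#' sharing the same allele frequencies, exposure phenotype(s) in cohort A,
#' the binary outcome in cohort B, and per-SNP summary statistics for each —
#' linear regression slopes in the exposure cohort, logistic log odds ratios
#' in the outcome cohort. This mirrors a two-sample design where exposure
#' associations come from a published meta-analysis and outcome associations
#' from a separate biobank. When a second exposure is configured both
#' exposure tables come from cohort A (as when fat mass and fat-free mass
#' are measured in the same biobank).
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, writes `exposure.tsv`,
#'   (`exposure2.tsv`,) `outcome.tsv` and a flat `truth.txt` key-value
#'   sidecar there, reproducibly.
#' @return An object of class `mr_synth_dataset`: list with `exposure`,
#'   `exposure2` (or NULL), `outcome` summary-statistic data frames, the
#'   `true_model`, the realized outcome prevalence, and the config.
#' @examples
#' cfg <- synthetic_config(n_exposure_cohort = 2000, n_outcome_cohort = 2000,
#'                         n_snps = 20, exposure_h2 = 0.05,
#'                         outcome_prevalence = 0.2, seed = 7)
#' ds <- generate_two_sample_dataset(cfg)
#' head(ds$exposure)
#' @export
generate_two_sample_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ss <- stage_seeds(config$seed)
  GA <- simulate_genotypes(config$n_exposure_cohort, config$n_snps,
                           c(config$maf_low, config$maf_high),
                           seed = ss[["geno_exposure"]])
  maf <- attr(GA, "maf")
  model <- true_model(config, maf)
  al <- assign_alleles(config$n_snps, ss[["alleles"]])

  phenA <- simulate_phenotypes(GA, model, config,
                               noise_seed = ss[["noise_exposure"]],
                               what = "exposure")
  exposure <- compute_summary_stats(GA, phenA$exposure, "continuous",
                                    al$effect, al$other)
  exposure2 <- NULL
  if (!is.null(config$second_exposure))
    exposure2 <- compute_summary_stats(GA, phenA$exposure2, "continuous",
                                       al$effect, al$other)
  rm(GA)

  GB <- simulate_genotypes(config$n_outcome_cohort, config$n_snps,
                           c(config$maf_low, config$maf_high),
                           seed = ss[["geno_outcome"]], maf = maf)
  phenB <- simulate_phenotypes(GB, model, config,
                               noise_seed = ss[["noise_exposure"]] + 2^20,
                               outcome_seed = ss[["noise_outcome"]],
                               what = "both")
  outcome <- compute_summary_stats(GB, phenB$outcome, "binary",
                                   al$effect, al$other)
  ds <- structure(list(
    exposure = exposure, exposure2 = exposure2, outcome = outcome,
    true_model = model, realized_prevalence = mean(phenB$outcome),
    config = config
  ), class = "mr_synth_dataset")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_summary_stats(exposure, file.path(dir, "exposure.tsv"))
    if (!is.null(exposure2))
      write_summary_stats(exposure2, file.path(dir, "exposure2.tsv"))
    write_summary_stats(outcome, file.path(dir, "outcome.tsv"))
    truth <- c(
      sprintf("true_effect\t%.17g", model$true_effect),
      if (!is.null(model$true_effect2))
        sprintf("true_effect2\t%.17g", model$true_effect2),
      sprintf("n_outliers\t%d", length(model$outlier_idx)),
      if (length(model$outlier_idx))
        sprintf("outlier_ids\t%s",
                paste0("rs", model$outlier_idx, collapse = ",")),
      sprintf("realized_prevalence\t%.17g", ds$realized_prevalence)
    )
    writeLines(truth, file.path(dir, "truth.txt"))
  }
  ds
}
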