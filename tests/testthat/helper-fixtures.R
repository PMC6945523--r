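# Shared fixture builders: everything is generated in code at test time.

# A random but reproducible instrument set on the summary scale (no cohort
# simulation): gamma ~ N(0.05, 0.015), Gamma generated from a true slope
# plus optional per-SNP direct effects, Gaussian noise at the reported SEs.
make_instruments <- function(J = 10, beta = 0.1, alpha = rep(0, J),
                             se_gamma = 0.005, se_Gamma = 0.02, seed = 1) {
  set.seed(seed)
  gamma <- rnorm(J, 0.05, 0.015)
  gamma[abs(gamma) < 0.005] <- 0.02
  Gamma <- beta * gamma + alpha + rnorm(J, 0, se_Gamma)
  structure(
    data.frame(variant_id = paste0("rs", seq_len(J)),
               aligned_allele = "A",
               gamma = gamma, se_gamma = se_gamma,
               Gamma = Gamma, se_Gamma = se_Gamma,
               eaf = runif(J, 0.1, 0.5), stringsAsFactors = FALSE),
    class = c("instrument_set", "data.frame"),
    exposure_name = "exposure", unit = "kg/m^2")
}

# Add a correlated second exposure to an instrument set.
add_second_exposure <- function(ins, cor = 0.5, se_gamma2 = 0.005,
                                seed = 2) {
  set.seed(seed)
  z <- rnorm(nrow(ins), 0.05, 0.015)
  ins$gamma2 <- cor * (ins$gamma - mean(ins$gamma)) / sd(ins$gamma) * 0.015 +
    sqrt(1 - cor^2) * (z - 0.05) + 0.05
  ins$se_gamma2 <- se_gamma2
  ins
}

# A minimal valid summary-statistics data frame.
make_records <- function(ids, beta = 0.05, se = 0.005, pval = 1e-10,
                         ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                         info = NA_real_, hwe_p = NA_real_) {
  k <- length(ids)
  data.frame(variant_id = ids,
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             beta = rep_len(beta, k), se = rep_len(se, k),
             pval = rep_len(pval, k), n = rep_len(n, k),
             eaf = rep_len(eaf, k), info = rep_len(info, k),
             hwe_p = rep_len(hwe_p, k), stringsAsFactors = FALSE)
}

# Recast an instrument set as exposure/outcome record tables (used for the
# harmonization idempotence and representation-invariance checks).
set_to_records <- function(ins) {
  flip_oa <- c(A = "G", C = "A", G = "A", T = "C")
  list(
    exposure = data.frame(
      variant_id = ins$variant_id, effect_allele = ins$aligned_allele,
      other_allele = flip_oa[ins$aligned_allele],
      beta = ins$gamma, se = ins$se_gamma, pval = 1e-10, n = 1e5,
      eaf = ins$eaf, stringsAsFactors = FALSE),
    outcome = data.frame(
      variant_id = ins$variant_id, effect_allele = ins$aligned_allele,
      other_allele = flip_oa[ins$aligned_allele],
      beta = ins$Gamma, se = ins$se_Gamma, pval = 0.5, n = 1e5,
      eaf = ins$eaf, stringsAsFactors = FALSE))
}

# Swap-and-negate the allele representation of chosen record rows.
swap_representation <- function(records, rows) {
  tmp <- records$effect_allele[rows]
  records$effect_allele[rows] <- records$other_allele[rows]
  records$other_allele[rows] <- tmp
  records$beta[rows] <- -records$beta[rows]
  records$eaf[rows] <- 1 - records$eaf[rows]
  records
}

# A small full-cohort synthetic configuration for end-to-end tests.
small_config <- function(...) {
  synthetic_config(n_exposure_cohort = 2000, n_outcome_cohort = 2000,
                   n_snps = 20, exposure_h2 = 0.05,
                   outcome_prevalence = 0.2, ...)
}
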