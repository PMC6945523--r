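## Instrument-strength and design diagnostics: variance explained, F and
## conditional F statistics, and analytic power for binary-outcome MR.

#' Exposure variance explained by the instruments
#'
#' Two routes. The summary route sums per-SNP contributions
#' `2 p_j (1 - p_j) gamma_j^2 / var(X)` using effect-allele frequencies
#' (with `var(X) = 1` for betas reported in SD units, the usual convention
#' for standardized GWAS effects). The raw route fits the multiple
#' regression of the exposure on all instruments and returns its R-squared.
#'
#' @param records Summary-statistics data frame with `eaf` and `beta`
#'   (summary route), or `NULL` when raw data are supplied.
#' @param genotypes,exposure Optional raw dosage matrix and exposure vector
#'   (raw route; overrides the summary route).
#' @param var_x Exposure variance for the summary route (default 1).
#' @return R-squared in `[0, 1)`.
#' @export
variance_explained <- function(records = NULL, genotypes = NULL,
                               exposure = NULL, var_x = 1) {
  if (!is.null(genotypes)) {
    stopifnot(!is.null(exposure), length(exposure) == nrow(genotypes))
    return(summary(lm(exposure ~ genotypes))$r.squared)
  }
  stopifnot(!is.null(records))
  if (is.null(records$eaf) || anyNA(records$eaf))
    stop("summary-route variance explained needs effect-allele frequencies")
  r2 <- sum(2 * records$eaf * (1 - records$eaf) * records$beta^2) / var_x
  min(r2, 1 - 1e-12)
}

#' Univariable instrument F statistic
#'
#' `F = (n - k - 1)/k * R^2/(1 - R^2)`: the usual first-stage F for k
#' instruments jointly explaining `r_squared` of the exposure in a sample
#' of n. Values above 10 are conventionally taken to indicate that weak
#' instrument bias is negligible; the result carries a `weak` attribute
#' flagging F <= 10.
#'
#' @param r_squared Variance explained, in `[0, 1)`.
#' @param n Sample size; must exceed `k + 1`.
#' @param k Instrument count.
#' @return The F statistic (with `attr(, "weak")`).
#' @export
f_statistic <- function(r_squared, n, k) {
  stopifnot(r_squared >= 0, r_squared < 1, k >= 1, n > k + 1)
  f <- (n - k - 1) / k * r_squared / (1 - r_squared)
  attr(f, "weak") <- !(f > 10)
  f
}

#' Conditional instrument strength for two-exposure multivariable MR
#'
#' Summary-data conditional F in the Sanderson-Windmeijer spirit: for each
#' exposure, the other exposure's instrument effects are regressed out of
#' its own (weighted by the inverse squared SE of the exposure of interest),
#' and the conditional F is the mean weighted squared residual,
#' `sum_j w_j e_j^2 / (J - p)` with `p` the number of conditioning slopes
#' fitted. This measures how much independent instrument signal remains for
#' one exposure once the shared component with the other is removed: with
#' orthogonal (or zero) conditioning effects it collapses to the mean
#' per-SNP chi-square, i.e. the univariable strength, while identical
#' effect vectors drive it towards 0.
#'
#' @param instruments An `instrument_set` with `gamma, se_gamma, gamma2,
#'   se_gamma2`; at least 3 instruments.
#' @return Named numeric vector `c(exposure1 =, exposure2 =)` of
#'   conditional F statistics.
#' @export
conditional_f <- function(instruments) {
  check_instruments(instruments, 3L, need_second = TRUE)
  one <- function(g, se_g, g_other) {
    w <- 1 / se_g^2
    J <- length(g)
    if (all(g_other == 0)) return(sum(w * g^2) / J)
    denom <- sum(w * g_other^2)
    if (denom <= 0) return(sum(w * g^2) / J)
    d <- sum(w * g * g_other) / denom
    e <- g - d * g_other
    f <- sum(w * e^2) / (J - 1)
    if (f < 1e-8)
      warning("conditional F near zero: exposure effects nearly collinear")
    f
  }
  c(exposure1 = one(instruments$gamma, instruments$se_gamma,
                    instruments$gamma2),
    exposure2 = one(instruments$gamma2, instruments$se_gamma2,
                    instruments$gamma))
}

#' Analytic power for binary-outcome MR
#'
#' Normal-approximation power for the two-sided Wald test of a causal odds
#' ratio in a two-sample MR with a binary outcome. The non-centrality is
#' `NCP = N * R^2 * phi * (1 - phi) * log(OR)^2` with `N` the total outcome
#' sample, `phi` the case fraction and `R^2` the exposure variance explained
#' by the instruments; power is
#' `pnorm(sqrt(NCP) - z) + pnorm(-sqrt(NCP) - z)` at the two-sided critical
#' value `z`, so the null odds ratio of 1 returns exactly `alpha`. Power is
#' symmetric in cases and controls and monotone in N, R-squared and
#' `|log(OR)|`.
#'
#' @param n_cases,n_controls Outcome-cohort case and control counts.
#' @param r_squared Instrument R-squared on the exposure.
#' @param odds_ratio Causal odds ratio per unit exposure to detect.
#' @param alpha Two-sided type-I error (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
mr_power <- function(n_cases, n_controls, r_squared, odds_ratio,
                     alpha = 0.05) {
  stopifnot(n_cases > 0, n_controls > 0, r_squared >= 0, r_squared < 1,
            odds_ratio > 0, alpha > 0, alpha < 1)
  n <- n_cases + n_controls
  phi <- n_cases / n
  ncp <- n * r_squared * phi * (1 - phi) * log(odds_ratio)^2
  z <- qnorm(1 - alpha / 2)
  pnorm(sqrt(ncp) - z) + pnorm(-sqrt(ncp) - z)
}

#' Instrument-strength report
#'
#' Bundles [variance_explained()], [f_statistic()] and (when a second
#' exposure is present) [conditional_f()] for an instrument set.
#'
#' @param instruments An `instrument_set` (needs `eaf` for the summary
#'   route).
#' @param n Exposure-cohort sample size.
#' @return List of class `strength_report`: `r_squared`, `f_stat`,
#'   `conditional_f` (or NULL), `n`, `k`.
#' @export
strength_report <- function(instruments, n) {
  r2 <- variance_explained(
    data.frame(eaf = instruments$eaf, beta = instruments$gamma))
  k <- nrow(instruments)
  cf <- if (!is.null(instruments$gamma2)) conditional_f(instruments)
  structure(list(r_squared = r2, f_stat = as.numeric(f_statistic(r2, n, k)),
                 conditional_f = cf, n = n, k = k),
            class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf("Instrument strength: R^2 = %.4f, F = %.1f (n = %d, k = %d)\n",
              x$r_squared, x$f_stat, x$n, x$k))
  if (!is.null(x$conditional_f))
    cat(sprintf("  conditional F: exposure 1 = %.1f, exposure 2 = %.1f\n",
                x$conditional_f[["exposure1"]], x$conditional_f[["exposure2"]]))
  invisible(x)
}
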