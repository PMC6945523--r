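## Core causal estimators for summary-data MR: per-SNP Wald ratios, IVW with
## multiplicative random effects, weighted median, MR-Egger, multivariable MR.
## All effects are on the log odds ratio scale per one unit of exposure.

Z975 <- qnorm(0.975)

new_mr_estimate <- function(method, beta, se, n_snps,
                            q = NA_real_, q_df = NA_real_,
                            egger_intercept = NULL, ...) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  est <- list(
    method = method, beta = beta, se = se,
    ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
    pval = 2 * pnorm(-abs(beta / se)),
    odds_ratio = exp(beta),
    or_ci_low = exp(beta - Z975 * se), or_ci_high = exp(beta + Z975 * se),
    n_snps = n_snps,
    cochran_q = q,
    q_pval = if (is.na(q) || is.na(q_df) || q_df < 1) NA_real_ else
      pchisq(q, df = q_df, lower.tail = FALSE),
    ...
  )
  if (!is.null(egger_intercept)) est <- c(est, egger_intercept)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs)\n", x$method, x$n_snps))
  cat(sprintf("  log-OR %.4f (SE %.4f), OR %.3f [95%% CI %.3f-%.3f], p = %.3g\n",
              x$beta, x$se, x$odds_ratio, x$or_ci_low, x$or_ci_high, x$pval))
  if (!is.na(x$cochran_q))
    cat(sprintf("  heterogeneity Q = %.2f (p = %.3g)\n", x$cochran_q, x$q_pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) setNames(object$beta, object$method)

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  matrix(c(object$beta - z * object$se, object$beta + z * object$se), 1, 2,
         dimnames = list(object$method,
                         sprintf("%g %%", c((1 - level) / 2,
                                            1 - (1 - level) / 2) * 100)))
}

# Weighted least squares with the SE-only (unscaled) covariance, so the
# multiplicative random-effects inflation can be applied explicitly and
# exact fits (zero residual) stay well defined.
wls_fit <- function(X, y, w) {
  xtwx <- crossprod(X, w * X)
  b <- drop(solve(xtwx, crossprod(X, w * y)))
  names(b) <- colnames(X)
  resid <- y - drop(X %*% b)
  list(coef = b,
       se_unscaled = setNames(sqrt(diag(solve(xtwx))), colnames(X)),
       q = sum(w * resid^2))
}

check_instruments <- function(instruments, min_n = 1L, need_second = FALSE) {
  stopifnot(is.data.frame(instruments))
  need <- c("gamma", "se_gamma", "Gamma", "se_Gamma")
  if (need_second) need <- c(need, "gamma2", "se_gamma2")
  missing <- setdiff(need, names(instruments))
  if (length(missing))
    stop("instrument set lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(instruments) < min_n)
    stop("need at least ", min_n, " instrument(s), have ", nrow(instruments))
  if (any(instruments$se_gamma <= 0) || any(instruments$se_Gamma <= 0))
    stop("all standard errors must be positive")
  invisible(instruments)
}

#' Per-SNP Wald ratio estimates
#'
#' For each instrument, the causal log odds ratio per unit exposure is the
#' SNP-outcome association divided by the SNP-exposure association,
#' `Gamma_j / gamma_j`, with the first-order delta-method standard error
#' `se_Gamma_j / |gamma_j|` (exposure-side uncertainty ignored, which makes
#' IVW algebraically identical to a weighted no-intercept regression).
#'
#' @param instruments An `instrument_set` from [harmonize()], or any data
#'   frame with columns `gamma, se_gamma, Gamma, se_Gamma`.
#' @param second_order If `TRUE`, use the second-order delta SE
#'   `sqrt(se_Gamma^2/gamma^2 + Gamma^2 se_gamma^2/gamma^4)`.
#' @return Data frame with `variant_id`, `ratio`, `se_ratio`, in input order.
#' @export
ratio_estimates <- function(instruments, second_order = FALSE) {
  check_instruments(instruments, 1L)
  zero <- which(instruments$gamma == 0)
  if (length(zero))
    stop("SNP-exposure association is exactly zero for: ",
         paste(instruments$variant_id[zero], collapse = ", "))
  se <- if (second_order)
    sqrt(instruments$se_Gamma^2 / instruments$gamma^2 +
         instruments$Gamma^2 * instruments$se_gamma^2 / instruments$gamma^4)
  else instruments$se_Gamma / abs(instruments$gamma)
  data.frame(
    variant_id = instruments$variant_id %||% paste0("snp", seq_len(nrow(instruments))),
    ratio = instruments$Gamma / instruments$gamma,
    se_ratio = se, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Combines the per-SNP Wald ratios by inverse-variance weighting,
#' `beta = sum(w_j r_j) / sum(w_j)` with `w_j = 1/se_ratio_j^2`. The
#' fixed-effect SE is `1/sqrt(sum(w_j))`; under the default multiplicative
#' random-effects model it is inflated by `max(1, sqrt(Q/(J-1)))` where Q is
#' Cochran's heterogeneity statistic, so between-instrument heterogeneity
#' widens — and never narrows — the interval. An additive
#' (DerSimonian-Laird) random-effects variant is available for comparison.
#' With a single instrument the result collapses to its ratio estimate and
#' Q is reported as absent.
#'
#' @param instruments An `instrument_set` (or compatible data frame).
#' @param effects_model `"multiplicative_random"` (default), `"fixed"`, or
#'   `"additive_random"` (DerSimonian-Laird).
#' @return An object of class `mr_estimate`.
#' @export
mr_ivw <- function(instruments,
                   effects_model = c("multiplicative_random", "fixed",
                                     "additive_random")) {
  effects_model <- match.arg(effects_model)
  check_instruments(instruments, 1L)
  r <- ratio_estimates(instruments)
  J <- nrow(r)
  w <- 1 / r$se_ratio^2
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (J == 1L)
    return(new_mr_estimate("IVW", beta, se_fixed, 1L))
  q <- sum(w * (r$ratio - beta)^2)
  se <- switch(effects_model,
    fixed = se_fixed,
    multiplicative_random = se_fixed * max(1, sqrt(q / (J - 1))),
    additive_random = {
      tau2 <- max(0, (q - (J - 1)) / (sum(w) - sum(w^2) / sum(w)))
      ws <- 1 / (r$se_ratio^2 + tau2)
      beta <- sum(ws * r$ratio) / sum(ws)
      sqrt(1 / sum(ws))
    })
  new_mr_estimate(paste0("IVW (", sub("_", " ", effects_model), ")"),
                  beta, se, J, q = q, q_df = J - 1)
}

# Weighted median of values r with weights w: the inverse of the weighted
# empirical CDF evaluated at 0.5. When the cumulative weight hits 0.5
# exactly between two values the two are averaged; a value carrying the
# majority of the weight is returned exactly.
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  j <- which(cw >= 0.5)[1]
  if (j < length(r) && abs(cw[j] - 0.5) < 1e-12) (r[j] + r[j + 1]) / 2 else r[j]
}

#' Weighted median estimate
#'
#' The median of the inverse-variance-weighted empirical distribution of the
#' per-SNP Wald ratios. Consistent when at least half of the weight comes
#' from valid instruments, making it robust to a minority of pleiotropic
#' SNPs. The standard error comes from a parametric bootstrap: the per-SNP
#' exposure and outcome associations are resampled from normal distributions
#' centred on their estimates with their reported SEs, the weighted median
#' recomputed, and the SD over replicates taken.
#'
#' @param instruments An `instrument_set`; at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000; fewer than 100 draws a
#'   warning).
#' @param seed Seed for the bootstrap.
#' @return An object of class `mr_estimate`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  check_instruments(instruments, 3L)
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable")
  r <- ratio_estimates(instruments)
  w <- 1 / r$se_ratio^2
  beta <- weighted_median_point(r$ratio, w)
  J <- nrow(r)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    g <- rnorm(J, instruments$gamma, instruments$se_gamma)
    G <- rnorm(J, instruments$Gamma, instruments$se_Gamma)
    ok <- g != 0
    rb <- G[ok] / g[ok]
    wb <- (g[ok] / instruments$se_Gamma[ok])^2
    weighted_median_point(rb, wb)
  }, numeric(1))
  se <- sd(boots)
  new_mr_estimate("Weighted median", beta, se, J)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the SNP-outcome associations on the
#' SNP-exposure associations \emph{with} an intercept, weights
#' `1/se_Gamma^2`. The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates the average directional pleiotropic
#' effect, and its test is the directional-pleiotropy diagnostic. Each pair
#' is first oriented so the exposure association is non-negative (negating
#' both when needed), which the intercept requires for identifiability.
#' Both coefficient SEs carry the multiplicative random-effects inflation
#' `max(1, sqrt(Q'/(J-2)))` from the residual heterogeneity.
#'
#' @param instruments An `instrument_set`; at least 3 instruments with
#'   spread in `|gamma|`.
#' @param t_dist If `TRUE`, coefficient p-values use the t distribution with
#'   J-2 df instead of the normal.
#' @return An `mr_estimate` with `egger_intercept`, `intercept_se`,
#'   `intercept_p` components.
#' @export
mr_egger <- function(instruments, t_dist = FALSE) {
  check_instruments(instruments, 3L)
  g <- instruments$gamma
  G <- instruments$Gamma
  flip <- g < 0
  g[flip] <- -g[flip]
  G[flip] <- -G[flip]
  if (sd(g) == 0)
    stop("no spread in |gamma|: Egger design matrix is degenerate")
  w <- 1 / instruments$se_Gamma^2
  J <- length(g)
  wls <- wls_fit(cbind(`(Intercept)` = 1, g = g), G, w)
  # residual heterogeneity inflates both SEs, floored at 1
  infl <- max(1, sqrt(wls$q / (J - 2)))
  se <- wls$se_unscaled * infl
  beta <- wls$coef[["g"]]
  a <- wls$coef[["(Intercept)"]]
  pfun <- if (t_dist) function(z) 2 * pt(-abs(z), df = J - 2) else
    function(z) 2 * pnorm(-abs(z))
  qprime <- wls$q
  est <- new_mr_estimate("MR-Egger", beta, se[["g"]], J,
                         q = qprime, q_df = J - 2,
                         egger_intercept = list(
                           egger_intercept = a,
                           intercept_se = se[["(Intercept)"]],
                           intercept_p = pfun(a / se[["(Intercept)"]])))
  est$pval <- pfun(beta / se[["g"]])
  est
}

#' Multivariable MR
#'
#' Weighted least-squares regression of the SNP-outcome associations on two
#' exposures' SNP-exposure associations jointly, \emph{without} intercept,
#' weights `1/se_Gamma^2`. Each coefficient is the direct effect of its
#' exposure, mutually adjusted for the other (e.g. fat mass and fat-free
#' mass indices instrumented by the same variants). SEs carry the
#' multiplicative random-effects inflation `max(1, sqrt(Q/(J-k)))`. An
#' exposure whose instrument effects are all exactly zero is dropped from
#' the fit (its direct effect is unidentified and returned as `NA`), so the
#' other exposure's estimate collapses to univariable IVW; genuinely
#' collinear non-zero effect vectors are an error.
#'
#' @param instruments An `instrument_set` carrying `gamma2`, `se_gamma2`;
#'   at least 3 instruments (and more than the number of exposures).
#' @return A list of class `mr_mvmr` with one `mr_estimate` per exposure
#'   (`exposure1`, `exposure2`).
#' @export
mr_mvmr <- function(instruments) {
  check_instruments(instruments, 3L, need_second = TRUE)
  J <- nrow(instruments)
  X <- cbind(g1 = instruments$gamma, g2 = instruments$gamma2)
  active <- colSums(X != 0) > 0
  if (!any(active)) stop("all exposure effects are zero")
  Xa <- X[, active, drop = FALSE]
  if (qr(Xa)$rank < ncol(Xa))
    stop("exposure effect vectors are collinear: MVMR design is rank-deficient")
  if (J < ncol(Xa) + 1) stop("need more instruments than exposures")
  w <- 1 / instruments$se_Gamma^2
  wls <- wls_fit(Xa, instruments$Gamma, w)
  infl <- max(1, sqrt(wls$q / (J - ncol(Xa))))
  se <- wls$se_unscaled * infl
  q <- wls$q
  b <- wls$coef
  mk <- function(nm, label) {
    if (!nm %in% colnames(Xa)) return(NULL)
    new_mr_estimate(paste0("MVMR (", label, ")"), b[[nm]], se[[nm]], J,
                    q = q, q_df = J - ncol(Xa))
  }
  out <- list(exposure1 = mk("g1", "exposure 1"),
              exposure2 = mk("g2", "exposure 2"))
  structure(out, class = "mr_mvmr")
}

#' @export
print.mr_mvmr <- function(x, ...) {
  cat("Multivariable MR direct effects\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  %s: unidentified (all instrument effects zero)\n", nm))
    } else {
      cat(sprintf("  %s: ", nm)); print(x[[nm]])
    }
  }
  invisible(x)
}
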