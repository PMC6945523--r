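#' Fit the full suite of MR estimators to an instrument set
#'
#' The central fitting function of the package. Given a harmonized
#' instrument set it runs the primary inverse-variance weighted analysis
#' and the requested sensitivity analyses — MR-PRESSO outlier detection
#' with outlier-corrected re-estimation, the weighted median, MR-Egger with
#' its directional-pleiotropy intercept test, and (when a second exposure
#' is present) multivariable MR — and returns a classed object with
#' `print`, `summary`, `coef`, `confint` and `plot` methods.
#'
#' @param instruments An `instrument_set` from [harmonize()].
#' @param methods Character vector from
#'   `c("ivw", "presso", "median", "egger", "mvmr")`. `"mvmr"` is skipped
#'   with a message unless the set carries second-exposure effects.
#' @param effects_model Random-effects flavour for IVW, see [mr_ivw()].
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param presso_n_sim Simulation count for MR-PRESSO.
#' @param presso_alpha Outlier threshold on the (adjusted) per-SNP p.
#' @param seed Seed shared by all stochastic components.
#' @return An object of class `mr_fit`: list with one element per fitted
#'   method (`ivw`, `presso`, `median`, `egger`, `mvmr`), the instrument
#'   set, and the call.
#' @examples
#' cfg <- synthetic_config(n_exposure_cohort = 2000, n_outcome_cohort = 2000,
#'                         n_snps = 20, exposure_h2 = 0.05,
#'                         outcome_prevalence = 0.2, seed = 3)
#' ins <- harmonize_dataset(generate_two_sample_dataset(cfg))
#' fit <- mr_fit(ins, methods = c("ivw", "median", "egger"), n_boot = 200)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(instruments,
                   methods = c("ivw", "presso", "median", "egger", "mvmr"),
                   effects_model = "multiplicative_random",
                   n_boot = 1000L, presso_n_sim = 1000L,
                   presso_alpha = 0.10, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_instruments(instruments, 1L)
  has2 <- !is.null(instruments$gamma2)
  out <- list(instruments = instruments, call = match.call())
  if ("ivw" %in% methods)
    out$ivw <- mr_ivw(instruments, effects_model = effects_model)
  if ("presso" %in% methods && nrow(instruments) >= 4)
    out$presso <- mr_presso(instruments, n_sim = presso_n_sim, seed = seed,
                            alpha = presso_alpha)
  if ("median" %in% methods && nrow(instruments) >= 3)
    out$median <- mr_weighted_median(instruments, n_boot = n_boot,
                                     seed = seed)
  if ("egger" %in% methods && nrow(instruments) >= 3)
    out$egger <- mr_egger(instruments)
  if ("mvmr" %in% methods && has2)
    out$mvmr <- mr_mvmr(instruments)
  structure(out, class = "mr_fit")
}

fit_estimates <- function(x) {
  ests <- list()
  if (!is.null(x$ivw)) ests$ivw <- x$ivw
  if (!is.null(x$presso) && !is.null(x$presso$corrected_estimate))
    ests$presso_corrected <- x$presso$corrected_estimate
  if (!is.null(x$median)) ests$median <- x$median
  if (!is.null(x$egger)) ests$egger <- x$egger
  if (!is.null(x$mvmr)) {
    if (!is.null(x$mvmr$exposure1)) ests$mvmr_exposure1 <- x$mvmr$exposure1
    if (!is.null(x$mvmr$exposure2)) ests$mvmr_exposure2 <- x$mvmr$exposure2
  }
  ests
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR fit: %d instruments, %s\n", nrow(x$instruments),
              attr(x$instruments, "exposure_name") %||% "exposure"))
  for (est in fit_estimates(x)) print(est)
  if (!is.null(x$presso))
    cat(sprintf("MR-PRESSO global p = %.4g; %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  invisible(x)
}

#' Tabular summary of an MR fit
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @return A `summary.mr_fit` object wrapping a data frame with one row per
#'   estimate: method, n_snps, beta, se, CI, p, OR with CI, heterogeneity Q
#'   and the Egger intercept columns.
#' @export
summary.mr_fit <- function(object, ...) {
  rows <- lapply(fit_estimates(object), function(e) data.frame(
    method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
    ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
    or = e$odds_ratio, or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
    q = e$cochran_q, q_pval = e$q_pval,
    egger_intercept = e$egger_intercept %||% NA_real_,
    intercept_p = e$intercept_p %||% NA_real_,
    stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n_snps = nrow(object$instruments),
                 presso = object$presso), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 3, ...) {
  cat("Mendelian randomization estimates (log-OR per unit exposure)\n")
  print(format(x$table, digits = digits), ...)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...)
  vapply(fit_estimates(object), function(e) e$beta, numeric(1))

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  ests <- fit_estimates(object)
  m <- t(vapply(ests, function(e) c(e$beta - z * e$se, e$beta + z * e$se),
                numeric(2)))
  colnames(m) <- sprintf("%g %%", c((1 - level) / 2,
                                    1 - (1 - level) / 2) * 100)
  m
}

#' Forest-style plot of an MR fit
#'
#' Draws the per-SNP Wald ratio estimates with 95% intervals and overlays
#' the combined estimates as vertical lines (base graphics).
#'
#' @param x An `mr_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot.mr_fit <- function(x, ...) {
  r <- ratio_estimates(x$instruments)
  ord <- order(r$ratio)
  r <- r[ord, ]
  J <- nrow(r)
  lo <- r$ratio - Z975 * r$se_ratio
  hi <- r$ratio + Z975 * r$se_ratio
  plot(r$ratio, seq_len(J), xlim = range(lo, hi, 0), pch = 19, cex = 0.5,
       xlab = "log-OR per unit exposure", ylab = "instrument rank",
       main = "Per-SNP Wald ratios and combined estimates", ...)
  segments(lo, seq_len(J), hi, seq_len(J), col = "grey60")
  abline(v = 0, lty = 3)
  ests <- fit_estimates(x)
  cols <- seq_along(ests) + 1
  for (i in seq_along(ests)) abline(v = ests[[i]]$beta, col = cols[i], lwd = 2)
  legend("topleft", legend = vapply(ests, `[[`, "", "method"),
         col = cols, lwd = 2, cex = 0.7, bty = "n")
  invisible(x)
}

#' @importFrom graphics abline legend segments
NULL
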