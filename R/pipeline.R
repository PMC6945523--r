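## Study-level orchestration: run the primary and sensitivity analyses for
## each exposure-outcome pair, apply the Bonferroni family correction, and
## emit a forest-style report table.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param n_outcomes Number of outcomes in the family.
#' @return The exact threshold `alpha_family / n_outcomes`, with its
#'   2-significant-figure display form in `attr(, "display")` (e.g.
#'   0.05/14 displays as 3.6e-03).
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_outcomes) {
  stopifnot(alpha_family > 0, alpha_family < 1)
  if (n_outcomes < 1) stop("n_outcomes must be at least 1")
  thr <- alpha_family / n_outcomes
  attr(thr, "display") <- signif(thr, 2)
  thr
}

#' Classify the evidence tier of an association
#'
#' Strict comparisons: `p < threshold` is `"significant"`,
#' `threshold <= p < alpha_family` is `"suggestive"` (a p exactly at the
#' corrected threshold is suggestive, not significant), anything else is
#' `"null"`.
#'
#' @param pval P-value(s) in `(0, 1]`.
#' @param threshold Bonferroni-corrected threshold.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return Character vector of tiers.
#' @export
classify_evidence <- function(pval, threshold, alpha_family = 0.05) {
  stopifnot(all(pval > 0), all(pval <= 1), threshold <= alpha_family)
  ifelse(pval < threshold, "significant",
         ifelse(pval < alpha_family, "suggestive", "null"))
}

#' Run a full multi-outcome MR analysis
#'
#' For each outcome: harmonize the exposure table(s) against the outcome
#' table, run the primary IVW analysis and the configured sensitivity
#' analyses via [mr_fit()], compute instrument-strength diagnostics, and
#' classify the evidence tier against the Bonferroni threshold for the
#' outcome family. Outcomes that fail harmonization produce a report row
#' with the failure reason; the run continues.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{exposure}{path to the exposure summary-statistics TSV, or a
#'       data frame.}
#'     \item{exposure2}{optional second exposure (for multivariable MR).}
#'     \item{outcomes}{named list of outcome TSV paths or data frames.}
#'     \item{methods}{methods passed to [mr_fit()]; default all.}
#'     \item{alpha_family}{family-wise alpha, default 0.05.}
#'     \item{n_outcomes}{family size for the correction; defaults to the
#'       number of outcome files.}
#'     \item{p_threshold, min_info, min_hwe_p}{instrument selection, see
#'       [select_instruments()]; default `p_threshold = 5e-8`.}
#'     \item{presso_n_sim, n_boot, seed}{stochastic settings.}
#'     \item{out_dir}{optional directory for the serialized report and
#'       per-method estimate TSVs.}
#'   }
#' @return An object of class `mr_report`: list with `table` (one
#'   `OutcomeReportRow` per outcome, sorted by descending primary OR),
#'   `fits` (named list of `mr_fit` objects), `threshold`, and `log`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$exposure),
            !is.null(config$outcomes), length(config$outcomes) >= 1)
  alpha_family <- config$alpha_family %||% 0.05
  n_outcomes <- config$n_outcomes %||% length(config$outcomes)
  thr <- bonferroni_threshold(alpha_family, n_outcomes)
  seed <- config$seed %||% 1L
  methods <- config$methods %||% c("ivw", "presso", "median", "egger", "mvmr")
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  load_tab <- function(x) if (is.data.frame(x)) x else read_summary_stats(x)
  exposure <- load_tab(config$exposure)
  exposure <- select_instruments(exposure,
                                 p_threshold = config$p_threshold %||% 5e-8,
                                 min_info = config$min_info %||% 0.8,
                                 min_hwe_p = config$min_hwe_p %||% 1e-6)
  prov <- attr(exposure, "provenance")
  if (nrow(prov)) note("instrument selection dropped %d record(s)", nrow(prov))
  if (nrow(exposure) == 0) stop("no instruments survive selection")
  exposure2 <- if (!is.null(config$exposure2)) load_tab(config$exposure2)

  fits <- list()
  rows <- list()
  for (nm in names(config$outcomes)) {
    outcome <- load_tab(config$outcomes[[nm]])
    ins <- tryCatch(
      harmonize(exposure, outcome, second_exposure_records = exposure2,
                exposure_name = config$exposure_name %||% "exposure"),
      error = function(e) e)
    if (inherits(ins, "error") || nrow(ins) == 0) {
      reason <- if (inherits(ins, "error")) conditionMessage(ins) else
        "no instruments after harmonization"
      note("outcome %s failed: %s", nm, reason)
      rows[[nm]] <- data.frame(outcome = nm, n_snps = 0L,
                               ivw_or = NA_real_, ivw_ci_low = NA_real_,
                               ivw_ci_high = NA_real_, ivw_p = NA_real_,
                               tier = reason, stringsAsFactors = FALSE)
      next
    }
    dropped <- attr(ins, "provenance")
    for (i in seq_len(nrow(dropped)))
      note("outcome %s: dropped %s (%s)", nm, dropped$variant_id[i],
           dropped$reason[i])
    fit <- mr_fit(ins, methods = methods,
                  n_boot = config$n_boot %||% 1000L,
                  presso_n_sim = config$presso_n_sim %||% 1000L,
                  seed = seed)
    fits[[nm]] <- fit
    tab <- summary(fit)$table
    primary <- fit$ivw
    if (is.null(primary)) stop("the IVW primary analysis cannot be disabled")
    row <- data.frame(
      outcome = nm, n_snps = primary$n_snps,
      ivw_or = primary$odds_ratio, ivw_ci_low = primary$or_ci_low,
      ivw_ci_high = primary$or_ci_high, ivw_p = primary$pval,
      tier = classify_evidence(primary$pval, thr, alpha_family),
      stringsAsFactors = FALSE)
    add <- function(label, e) {
      if (is.null(e)) return()
      row[[paste0(label, "_or")]] <<- e$odds_ratio
      row[[paste0(label, "_ci_low")]] <<- e$or_ci_low
      row[[paste0(label, "_ci_high")]] <<- e$or_ci_high
      row[[paste0(label, "_p")]] <<- e$pval
    }
    add("presso", fit$presso$corrected_estimate)
    if (!is.null(fit$presso)) {
      row$presso_global_p <- fit$presso$global_p
      row$presso_n_outliers <- length(fit$presso$outliers)
    }
    add("median", fit$median)
    add("egger", fit$egger)
    if (!is.null(fit$egger)) {
      row$egger_intercept <- fit$egger$egger_intercept
      row$egger_intercept_p <- fit$egger$intercept_p
    }
    if (!is.null(fit$mvmr)) {
      add("mvmr1", fit$mvmr$exposure1)
      add("mvmr2", fit$mvmr$exposure2)
    }
    rows[[nm]] <- row
  }
  tab <- rbind_fill(rows)
  ok <- !is.na(tab$ivw_or)
  tab <- rbind(tab[ok, , drop = FALSE][order(-tab$ivw_or[ok]), , drop = FALSE],
               tab[!ok, , drop = FALSE])
  rownames(tab) <- NULL
  report <- structure(list(table = tab, fits = fits, threshold = thr,
                           alpha_family = alpha_family,
                           n_outcomes = n_outcomes, log = log_lines,
                           seed = seed),
                      class = "mr_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# rbind data frames with unequal columns (base-only fill with NA)
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Serialize an analysis report
#'
#' Writes the report table (`report.tsv`), the flat per-method estimates
#' (`estimates.tsv`) and the decision log (`log.txt`) into a directory.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(report$table, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  est_rows <- list()
  for (nm in names(report$fits)) {
    tab <- summary(report$fits[[nm]])$table
    tab <- cbind(outcome = nm, tab)
    est_rows[[nm]] <- tab
  }
  if (length(est_rows))
    write.table(do.call(rbind, est_rows), file.path(dir, "estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf(
    "MR report: %d outcome(s); Bonferroni threshold %.3g (alpha %.2g / %d)\n",
    nrow(x$table), as.numeric(x$threshold), x$alpha_family, x$n_outcomes))
  show <- x$table[, intersect(c("outcome", "n_snps", "ivw_or", "ivw_ci_low",
                                "ivw_ci_high", "ivw_p", "tier"),
                              names(x$table)), drop = FALSE]
  show$ivw_or <- round(show$ivw_or, 2)
  show$ivw_ci_low <- round(show$ivw_ci_low, 2)
  show$ivw_ci_high <- round(show$ivw_ci_high, 2)
  show$ivw_p <- signif(show$ivw_p, 2)
  print.data.frame(show, ...)
  invisible(x)
}
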