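## GWAS summary-statistics I/O, instrument selection and allele harmonization.
##
## File dialect: tab-separated, UTF-8, required header columns
##   variant_id effect_allele other_allele beta se pval n
## optional columns: eaf info hwe_p. Extra columns are ignored.

.REQUIRED_COLS <- c("variant_id", "effect_allele", "other_allele",
                    "beta", "se", "pval", "n")
.OPTIONAL_COLS <- c("eaf", "info", "hwe_p")

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file into a validated data frame
#' of per-SNP association records. Every row is either parsed or rejected
#' with a line-numbered reason (non-positive SE, p-value outside (0,1],
#' identical alleles, unparseable numbers); alleles are upper-cased.
#' Rejected rows are reported in `attr(, "rejected")`.
#'
#' @param path Path to a TSV file with header
#'   `variant_id effect_allele other_allele beta se pval n` and optional
#'   `eaf`, `info`, `hwe_p` columns.
#' @return A data frame of records in file order, with a `rejected` data
#'   frame (line, variant_id, reason) attached as an attribute.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(.REQUIRED_COLS, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    out <- empty_sumstats()
    attr(out, "rejected") <- data.frame(line = integer(0),
                                        variant_id = character(0),
                                        reason = character(0))
    return(out)
  }
  df <- data.frame(
    variant_id = raw$variant_id,
    effect_allele = toupper(raw$effect_allele),
    other_allele = toupper(raw$other_allele),
    beta = suppressWarnings(as.numeric(raw$beta)),
    se = suppressWarnings(as.numeric(raw$se)),
    pval = suppressWarnings(as.numeric(raw$pval)),
    n = suppressWarnings(as.numeric(raw$n)),
    stringsAsFactors = FALSE
  )
  for (col in .OPTIONAL_COLS)
    df[[col]] <- if (col %in% names(raw))
      suppressWarnings(as.numeric(raw[[col]])) else NA_real_
  validate_sumstats(df, line_offset = 1L)
}

empty_sumstats <- function() {
  data.frame(variant_id = character(0), effect_allele = character(0),
             other_allele = character(0), beta = numeric(0), se = numeric(0),
             pval = numeric(0), n = numeric(0), eaf = numeric(0),
             info = numeric(0), hwe_p = numeric(0), stringsAsFactors = FALSE)
}

# Row-wise invariant enforcement shared by the reader and by in-memory
# record construction. line_offset accounts for the header line.
validate_sumstats <- function(df, line_offset = 0L) {
  for (col in .OPTIONAL_COLS)
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  reason <- rep(NA_character_, nrow(df))
  bad_num <- !complete.cases(df[, c("beta", "se", "pval", "n")])
  reason[bad_num] <- "unparseable or missing numeric field"
  ok <- is.na(reason)
  reason[ok & df$se <= 0] <- "non-positive SE"
  ok <- is.na(reason)
  reason[ok & (df$pval <= 0 | df$pval > 1)] <- "p-value outside (0,1]"
  ok <- is.na(reason)
  bases <- c("A", "C", "G", "T")
  reason[ok & !(df$effect_allele %in% bases & df$other_allele %in% bases)] <-
    "allele not in {A,C,G,T}"
  ok <- is.na(reason)
  reason[ok & df$effect_allele == df$other_allele] <- "identical alleles"
  keep <- is.na(reason)
  rejected <- data.frame(
    line = which(!keep) + line_offset,
    variant_id = df$variant_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write GWAS summary statistics
#'
#' Writes a summary-statistics data frame in the package's TSV dialect.
#' Optional columns that are entirely missing are omitted. Numbers are
#' written at full precision so a write-read round trip is lossless.
#'
#' @param records Summary-statistics data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  cols <- .REQUIRED_COLS
  for (col in .OPTIONAL_COLS)
    if (!is.null(records[[col]]) && any(!is.na(records[[col]])))
      cols <- c(cols, col)
  out <- records[, cols, drop = FALSE]
  for (col in setdiff(cols, c("variant_id", "effect_allele", "other_allele")))
    out[[col]] <- sprintf("%.17g", out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select genetic instruments from association records
#'
#' Applies the instrument-selection criteria used for GWAS-derived
#' instruments: genome-wide significance (`pval < p_threshold`, strict),
#' imputation quality (`info > min_info`, strict), and Hardy-Weinberg
#' equilibrium (`hwe_p >= min_hwe_p`). Filters act only on values that are
#' present: a record lacking the optional `info` or `hwe_p` columns is never
#' excluded on their account (published instrument lists typically lack
#' them). Every exclusion is logged with its first failing criterion in
#' `attr(, "provenance")`.
#'
#' @param records Summary-statistics data frame.
#' @param p_threshold Significance threshold, default the genome-wide
#'   `5e-8`; strict `<` comparison.
#' @param min_info Minimum imputation quality (strict `>`), default 0.8.
#' @param min_hwe_p Minimum Hardy-Weinberg exact-test p-value (`>=`),
#'   default `1e-6`.
#' @return The retained records, with a provenance log
#'   (variant_id, reason) attached. All records excluded produces an empty
#'   set with a warning; the estimation layer rejects empty sets.
#' @export
select_instruments <- function(records, p_threshold = 5e-8,
                               min_info = 0.8, min_hwe_p = 1e-6) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            min_info >= 0, min_info <= 1,
            min_hwe_p >= 0, min_hwe_p <= 1)
  for (col in .OPTIONAL_COLS)
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  reason <- rep(NA_character_, nrow(records))
  reason[records$pval >= p_threshold] <-
    sprintf("p >= %g", p_threshold)
  ok <- is.na(reason)
  reason[ok & !is.na(records$info) & records$info <= min_info] <-
    sprintf("imputation quality <= %g", min_info)
  ok <- is.na(reason)
  reason[ok & !is.na(records$hwe_p) & records$hwe_p < min_hwe_p] <-
    sprintf("Hardy-Weinberg p < %g", min_hwe_p)
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- data.frame(
    variant_id = records$variant_id[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(out) == 0 && nrow(records) > 0)
    warning("all records excluded by instrument selection")
  out
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) unname(.COMPLEMENT[a1] == a2)

# Swap-and-negate a record's allele representation (the involution used in
# harmonization): exchanging effect/other alleles negates beta and reflects
# the allele frequency.
flip_record <- function(rec) {
  tmp <- rec$effect_allele
  rec$effect_allele <- rec$other_allele
  rec$other_allele <- tmp
  rec$beta <- -rec$beta
  if (!is.null(rec$eaf)) rec$eaf <- 1 - rec$eaf
  rec
}

# Align one outcome-side record to the exposure's allele pair.
# Returns list(status, beta, eaf): status "ok", "mismatch" or "ambiguous".
align_alleles <- function(exp_ea, exp_oa, rec_ea, rec_oa, rec_beta, rec_eaf,
                          eaf_window) {
  pal <- is_palindromic(exp_ea, exp_oa)
  flip <- NA  # does the record's effect allele map to the exposure's other?
  if (rec_ea == exp_ea && rec_oa == exp_oa) flip <- FALSE
  else if (rec_ea == exp_oa && rec_oa == exp_ea) flip <- TRUE
  else if (!pal) {  # try strand complement (meaningless for palindromes)
    cea <- .COMPLEMENT[[rec_ea]]; coa <- .COMPLEMENT[[rec_oa]]
    if (cea == exp_ea && coa == exp_oa) flip <- FALSE
    else if (cea == exp_oa && coa == exp_ea) flip <- TRUE
  }
  if (is.na(flip)) return(list(status = "mismatch"))
  beta <- if (flip) -rec_beta else rec_beta
  eaf <- if (flip) 1 - rec_eaf else rec_eaf
  if (pal) {
    # Strand is unresolvable from labels; require informative, concordant
    # allele frequencies on both sides, else drop.
    exp_eaf <- attr(rec_eaf, "exp_eaf")  # set by caller
    if (is.na(eaf) || is.na(exp_eaf)) return(list(status = "ambiguous"))
    lo <- 0.5 - eaf_window; hi <- 0.5 + eaf_window
    if ((eaf >= lo && eaf <= hi) || (exp_eaf >= lo && exp_eaf <= hi))
      return(list(status = "ambiguous"))
    if ((eaf < 0.5) != (exp_eaf < 0.5)) return(list(status = "ambiguous"))
  }
  list(status = "ok", beta = beta, eaf = eaf)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects exposure and outcome (and optionally second-exposure) records
#' on variant ID and expresses all associations relative to the exposure's
#' effect allele. Outcome betas are sign-flipped when the outcome's effect
#' allele matches the exposure's other allele (directly or after strand
#' complement). Strand-ambiguous palindromic (A/T, C/G) SNPs are retained
#' only when allele frequencies are available on both sides, both are
#' informative (outside `0.5 +/- palindromic_eaf_window`), and concordant;
#' otherwise they are dropped. Every drop is logged with its reason.
#'
#' @param exposure_records,outcome_records Summary-statistics data frames.
#' @param second_exposure_records Optional second exposure table for
#'   multivariable MR.
#' @param palindromic_eaf_window Half-width of the uninformative
#'   allele-frequency band around 0.5 (default 0.08).
#' @param exposure_name,unit Labels carried into the instrument set.
#' @return An object of class `instrument_set`: a data frame with columns
#'   `variant_id, aligned_allele, gamma, se_gamma, Gamma, se_Gamma`
#'   (plus `gamma2, se_gamma2` when a second exposure is given), with the
#'   drop log in `attr(, "provenance")`.
#' @export
harmonize <- function(exposure_records, outcome_records,
                      second_exposure_records = NULL,
                      palindromic_eaf_window = 0.08,
                      exposure_name = "exposure", unit = "kg/m^2") {
  stopifnot(palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  if (anyDuplicated(exposure_records$variant_id))
    stop("duplicate variant_id in exposure records")
  has2 <- !is.null(second_exposure_records)
  prov <- list()
  log_drop <- function(id, reason)
    prov[[length(prov) + 1L]] <<- data.frame(variant_id = id, reason = reason,
                                             stringsAsFactors = FALSE)
  o_idx <- match(exposure_records$variant_id, outcome_records$variant_id)
  e2_idx <- if (has2)
    match(exposure_records$variant_id, second_exposure_records$variant_id)
  rows <- vector("list", nrow(exposure_records))
  for (i in seq_len(nrow(exposure_records))) {
    ex <- exposure_records[i, ]
    if (is.na(o_idx[i])) { log_drop(ex$variant_id, "missing in outcome"); next }
    if (has2 && is.na(e2_idx[i])) {
      log_drop(ex$variant_id, "missing in second exposure"); next
    }
    oc <- outcome_records[o_idx[i], ]
    oc_eaf <- oc$eaf %||% NA_real_
    attr(oc_eaf, "exp_eaf") <- ex$eaf %||% NA_real_
    al <- align_alleles(ex$effect_allele, ex$other_allele,
                        oc$effect_allele, oc$other_allele,
                        oc$beta, oc_eaf, palindromic_eaf_window)
    if (al$status == "mismatch") {
      log_drop(ex$variant_id, "allele mismatch"); next
    }
    if (al$status == "ambiguous") {
      log_drop(ex$variant_id, "palindromic, allele frequencies uninformative or discordant")
      next
    }
    row <- data.frame(
      variant_id = ex$variant_id, aligned_allele = ex$effect_allele,
      gamma = ex$beta, se_gamma = ex$se,
      Gamma = al$beta, se_Gamma = oc$se,
      eaf = ex$eaf %||% NA_real_, stringsAsFactors = FALSE)
    if (has2) {
      e2 <- second_exposure_records[e2_idx[i], ]
      e2_eaf <- e2$eaf %||% NA_real_
      attr(e2_eaf, "exp_eaf") <- ex$eaf %||% NA_real_
      al2 <- align_alleles(ex$effect_allele, ex$other_allele,
                           e2$effect_allele, e2$other_allele,
                           e2$beta, e2_eaf, palindromic_eaf_window)
      if (al2$status != "ok") {
        log_drop(ex$variant_id,
                 if (al2$status == "mismatch") "allele mismatch (second exposure)"
                 else "palindromic, allele frequencies uninformative or discordant (second exposure)")
        next
      }
      row$gamma2 <- al2$beta
      row$se_gamma2 <- e2$se
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(variant_id = character(0), aligned_allele = character(0),
                      gamma = numeric(0), se_gamma = numeric(0),
                      Gamma = numeric(0), se_Gamma = numeric(0),
                      eaf = numeric(0), stringsAsFactors = FALSE)
    if (has2) { out$gamma2 <- numeric(0); out$se_gamma2 <- numeric(0) }
  }
  rownames(out) <- NULL
  structure(out,
            provenance = if (length(prov)) do.call(rbind, prov) else
              data.frame(variant_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE),
            exposure_name = exposure_name, unit = unit,
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d SNP(s) for %s (per %s)\n",
              nrow(x), attr(x, "exposure_name"), attr(x, "unit")))
  dropped <- attr(x, "provenance")
  if (nrow(dropped))
    cat(sprintf("  %d SNP(s) dropped during harmonization\n", nrow(dropped)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

# Convert a synthetic dataset straight to an instrument set (the generator
# writes consistent alleles, so harmonization retains every shared SNP).
#' Harmonize a synthetic dataset into an instrument set
#'
#' Convenience wrapper running [harmonize()] on the components of a
#' [generate_two_sample_dataset()] result.
#' @param dataset An `mr_synth_dataset`.
#' @param ... Passed to [harmonize()].
#' @export
harmonize_dataset <- function(dataset, ...) {
  stopifnot(inherits(dataset, "mr_synth_dataset"))
  harmonize(dataset$exposure, dataset$outcome,
            second_exposure_records = dataset$exposure2, ...)
}
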