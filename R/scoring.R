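#' Score a sample against the IVD or DD rubric
#'
#' The IVD (tissue identity) rubric has six items, the DD (cellular
#' degeneration) rubric three; every item is graded 0, 1 or 2 by the rater.
#' The rubric total is the plain sum of the item grades (maximum 12 for IVD,
#' 6 for DD).  Alongside the total, each rubric carries a decision flag: for
#' the IVD score whether *any* item was graded 0 (a missing key feature or a
#' visible impurity), for the DD score whether any item was graded 2 (one
#' unambiguous sign of severe degeneration).
#'
#' @param items integer vector of item grades, each in \{0, 1, 2\}; length 6
#'   for `rubric = "IVD"`, length 3 for `rubric = "DD"`.
#' @param rubric `"IVD"` or `"DD"`.
#' @return list with elements `total` (integer) and `flag` (logical:
#'   any-item-zero for IVD, any-item-two for DD).
#' @examples
#' score_rubric(c(2, 2, 2, 2, 2, 2), "IVD")  # total 12, flag FALSE
#' score_rubric(c(2, 1, 0), "DD")            # total 3, flag TRUE
#' @export
score_rubric <- function(items, rubric = c("IVD", "DD")) {
  rubric <- match.arg(rubric)
  n_expected <- if (rubric == "IVD") 6L else 3L
  if (length(items) != n_expected)
    stop(sprintf("%s rubric needs %d item grades, got %d",
                 rubric, n_expected, length(items)), call. = FALSE)
  bad <- which(!(items %in% 0:2))
  if (length(bad))
    stop(sprintf("%s item %d has grade %s; grades must be 0, 1 or 2",
                 rubric, bad[1], deparse(items[bad[1]])), call. = FALSE)
  flag <- if (rubric == "IVD") any(items == 0) else any(items == 2)
  list(total = as.integer(sum(items)), flag = flag)
}

#' Classify tissue identity from the IVD score
#'
#' A sample is a *clear* AF or NP specimen when its IVD total exceeds 6 and
#' no single item was graded 0; otherwise its tissue character is *unknown*.
#'
#' @param total integer IVD total(s), 0-12.
#' @param any_zero logical: was any IVD item graded 0?
#' @return character vector, `"clear"` or `"unknown"`.
#' @examples
#' classify_ivd(10, FALSE)  # "clear"
#' classify_ivd(6, FALSE)   # "unknown" (boundary excluded)
#' classify_ivd(9, TRUE)    # "unknown"
#' @export
classify_ivd <- function(total, any_zero) {
  if (any(is.na(total)) || any(total < 0 | total > 12))
    stop("IVD total must be between 0 and 12", call. = FALSE)
  stopifnot(is.logical(any_zero), length(any_zero) == length(total))
  ifelse(total > 6 & !any_zero, "clear", "unknown")
}

#' Classify cellular degeneration from the DD score
#'
#' The default rule (`"strict_gt3"`) marks a sample *severe* when its DD
#' total exceeds 3 or any single item was graded 2.  The alternative `"ge3"`
#' mode uses total >= 3 instead; both are kept because the two thresholds
#' are each consistent with a different part of the published rubric
#' description, and only the strict rule reproduces the downstream cohort
#' counts (see the methods vignette).
#'
#' @param total integer DD total(s), 0-6.
#' @param any_two logical: was any DD item graded 2?
#' @param threshold_mode `"strict_gt3"` (default) or `"ge3"`.
#' @return character vector, `"mild"` or `"severe"`.
#' @examples
#' classify_dd(4, TRUE)              # "severe"
#' classify_dd(3, FALSE)             # "mild" under the default rule
#' classify_dd(3, FALSE, "ge3")      # "severe" under the alternative rule
#' @export
classify_dd <- function(total, any_two, threshold_mode = c("strict_gt3", "ge3")) {
  threshold_mode <- match.arg(threshold_mode)
  if (any(is.na(total)) || any(total < 0 | total > 6))
    stop("DD total must be between 0 and 6", call. = FALSE)
  stopifnot(is.logical(any_two), length(any_two) == length(total))
  severe <- if (threshold_mode == "strict_gt3") total > 3 | any_two
            else total >= 3 | any_two
  ifelse(severe, "severe", "mild")
}

#' Attach quality verdicts to a score sheet
#'
#' Adds per-sample columns `ivd_class` (clear/unknown), `dd_class`
#' (mild/severe) and `eligible_microarray` (clear AND mild) to a score
#' sheet as returned by [read_score_sheet()] or [simulate_score_sheet()].
#'
#' @param records score-sheet data frame carrying `ivd_total`,
#'   `ivd_any_zero`, `dd_total` and `dd_any_two`.
#' @param dd_rule passed to [classify_dd()].
#' @return `records` with the three verdict columns appended.
#' @export
sample_verdicts <- function(records, dd_rule = c("strict_gt3", "ge3")) {
  dd_rule <- match.arg(dd_rule)
  needed <- c("ivd_total", "ivd_any_zero", "dd_total", "dd_any_two")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("score sheet lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records$ivd_class <- classify_ivd(records$ivd_total, records$ivd_any_zero)
  records$dd_class <- classify_dd(records$dd_total, records$dd_any_two, dd_rule)
  records$eligible_microarray <-
    records$ivd_class == "clear" & records$dd_class == "mild"
  records
}

#' Summarise quality-gate pass rates for a cohort
#'
#' Counts, per compartment, how many samples are clear (IVD gate) and how
#' many are eligible for expression profiling (clear AND mild), plus the
#' overall severe-degeneration fraction.
#'
#' @inheritParams sample_verdicts
#' @return object of class `cohort_summary`: a list with `n_af`, `n_np`,
#'   `n_af_clear`, `n_np_clear`, `n_af_eligible`, `n_np_eligible`,
#'   `n_severe` and `fraction_severe`.
#' @export
summarize_cohort <- function(records, dd_rule = c("strict_gt3", "ge3")) {
  if (is.null(records) || nrow(records) == 0)
    stop("empty cohort: no sample records to summarise", call. = FALSE)
  v <- sample_verdicts(records, dd_rule)
  af <- v[v$compartment == "AF", ]
  np <- v[v$compartment == "NP", ]
  out <- list(
    n_af = nrow(af), n_np = nrow(np),
    n_af_clear = sum(af$ivd_class == "clear"),
    n_np_clear = sum(np$ivd_class == "clear"),
    n_af_eligible = sum(af$eligible_microarray),
    n_np_eligible = sum(np$eligible_microarray),
    n_severe = sum(v$dd_class == "severe"),
    fraction_severe = sum(v$dd_class == "severe") / nrow(v)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d AF / %d NP samples\n", x$n_af, x$n_np))
  cat(sprintf("  clear (IVD gate):     %d AF, %d NP\n",
              x$n_af_clear, x$n_np_clear))
  cat(sprintf("  eligible (IVD + DD):  %d AF, %d NP\n",
              x$n_af_eligible, x$n_np_eligible))
  cat(sprintf("  severe degeneration:  %d (%.0f%%)\n",
              x$n_severe, 100 * x$fraction_severe))
  invisible(x)
}

#' Select the expression-profiling cohort
#'
#' Keeps the samples passing both quality gates and then, per donor and
#' compartment, retains a single sample so that every chip comes from a
#' different donor.  The tie-break among a donor's eligible samples is:
#' highest IVD total, then lowest DD total, then lowest sample id.
#' Donor-level demographics (mean age, age range, gender split) are
#' computed over the union of donors contributing at least one chip and are
#' invariant to the tie-break.
#'
#' @inheritParams sample_verdicts
#' @return object of class `microarray_cohort`: list with `af_samples` and
#'   `np_samples` (selected sample ids), `donors`, `n_af`, `n_np`,
#'   `n_donors`, `mean_age`, `mean_age_rounded`, `age_range`,
#'   `female_count` and `male_count`.
#' @export
select_microarray_cohort <- function(records, dd_rule = c("strict_gt3", "ge3")) {
  v <- sample_verdicts(records, dd_rule)
  elig <- v[v$eligible_microarray, , drop = FALSE]
  pick <- function(comp) {
    e <- elig[elig$compartment == comp, , drop = FALSE]
    if (nrow(e) == 0) return(e)
    e <- e[order(e$donor_id, -e$ivd_total, e$dd_total, e$sample_id), ]
    e[!duplicated(e$donor_id), , drop = FALSE]
  }
  af <- pick("AF")
  np <- pick("NP")
  sel <- rbind(af, np)
  donors <- sort(unique(sel$donor_id))
  donor_rows <- sel[!duplicated(sel$donor_id), , drop = FALSE]
  out <- list(
    af_samples = af$sample_id, np_samples = np$sample_id,
    donors = donors,
    n_af = nrow(af), n_np = nrow(np), n_donors = length(donors),
    mean_age = if (nrow(donor_rows)) mean(donor_rows$age) else NA_real_,
    mean_age_rounded = if (nrow(donor_rows))
      as.integer(round_half_up(mean(donor_rows$age))) else NA_integer_,
    age_range = if (nrow(donor_rows)) range(donor_rows$age) else c(NA, NA),
    female_count = sum(donor_rows$gender == "f"),
    male_count = sum(donor_rows$gender == "m")
  )
  class(out) <- "microarray_cohort"
  out
}

#' @export
print.microarray_cohort <- function(x, ...) {
  cat(sprintf("Expression-profiling cohort: %d AF + %d NP samples, %d donors\n",
              x$n_af, x$n_np, x$n_donors))
  if (x$n_donors > 0)
    cat(sprintf("  mean age %d years (range %d-%d), female/male %d/%d\n",
                x$mean_age_rounded, x$age_range[1], x$age_range[2],
                x$female_count, x$male_count))
  invisible(x)
}
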