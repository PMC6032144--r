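#' Define an AF/NP marker panel
#'
#' The default panel is the 11-gene set nominated by the pairwise screen:
#' five AF markers (exclusively expressed in AF) and six NP markers
#' (up-regulated in NP but detectable in both tissues).
#'
#' @param af_markers ordered AF marker gene ids.
#' @param np_markers ordered NP marker gene ids.
#' @param ranges optional data frame of fitted ranges (`marker`, `tissue`,
#'   `low`, `high`) as produced by [fit_ranges()].
#' @return object of class `marker_panel`.
#' @export
marker_panel <- function(af_markers = c("LDB2", "ADGRL4", "EMCN",
                                        "ANKRD29", "OLFML2A"),
                         np_markers = c("SPTLC3", "ERFE", "DSC3",
                                        "DEFB1", "ARAP2", "CDKN2B"),
                         ranges = NULL) {
  if (anyDuplicated(c(af_markers, np_markers)))
    stop("marker ids must be unique across the panel", call. = FALSE)
  if (!is.null(ranges)) {
    stopifnot(all(c("marker", "tissue", "low", "high") %in% names(ranges)))
    if (any(ranges$low > ranges$high))
      stop("range low must not exceed high", call. = FALSE)
  }
  structure(list(af_markers = af_markers, np_markers = np_markers,
                 ranges = ranges),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker panel\n")
  cat("  AF markers:", paste(x$af_markers, collapse = ", "), "\n")
  cat("  NP markers:", paste(x$np_markers, collapse = ", "), "\n")
  cat(if (is.null(x$ranges)) "  ranges: not fitted\n"
      else sprintf("  ranges fitted for %d markers\n", nrow(x$ranges)))
  invisible(x)
}

#' Fit per-marker expression ranges on clear samples
#'
#' The reference range of each marker is the minimum-maximum of its
#' relative expression observed in *clear* samples of the marker's own
#' tissue (AF markers in clear AF, NP markers in clear NP) — the dashed
#' reference lines a practitioner would draw on a per-marker dot plot.
#' Values are used on the scale provided; missing values are skipped.
#'
#' @param panel a [marker_panel()].
#' @param af_expr,np_expr marker x sample matrix/data frame of relative
#'   expression in clear AF and clear NP samples (rownames = marker ids).
#' @return the panel with its `ranges` slot filled.
#' @export
fit_ranges <- function(panel, af_expr, np_expr) {
  stopifnot(inherits(panel, "marker_panel"))
  fit_one <- function(expr, markers, tissue) {
    expr <- as.matrix(expr)
    missing_m <- setdiff(markers, rownames(expr))
    if (length(missing_m))
      stop(sprintf("no %s expression values for marker(s): %s", tissue,
                   paste(missing_m, collapse = ", ")), call. = FALSE)
    do.call(rbind, lapply(markers, function(m) {
      v <- expr[m, ]
      v <- v[!is.na(v)]
      if (length(v) < 2)
        stop(sprintf(
          "marker %s has %d value(s) in clear %s samples; need at least 2",
          m, length(v), tissue), call. = FALSE)
      data.frame(marker = m, tissue = tissue,
                 low = min(v), high = max(v), stringsAsFactors = FALSE)
    }))
  }
  ranges <- rbind(fit_one(af_expr, panel$af_markers, "AF"),
                  fit_one(np_expr, panel$np_markers, "NP"))
  rownames(ranges) <- NULL
  panel$ranges <- ranges
  panel
}

#' Call a marker value against its reference range
#'
#' `+` when the value lies within the range (boundaries inclusive), `++`
#' when above it, `-` when below it or when there is no expression at all
#' (value 0), `NA` when the measurement is missing.
#'
#' @param value non-negative relative expression, or `NA` when missing.
#' @param low,high reference range (low <= high).
#' @return character vector of calls in `c("-", "+", "++", NA)`.
#' @export
call_marker <- function(value, low, high) {
  stopifnot(all(low <= high))
  if (any(value < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  ifelse(is.na(value), NA_character_,
         ifelse(value > high, "++",
                ifelse(value == 0 | value < low, "-", "+")))
}

#' Marker match percentage
#'
#' The fraction of a marker set's available (non-NA) calls that are
#' positive (`+` or `++`), as a nearest-integer percentage.  With no
#' available call the match is undefined (`NA`).
#'
#' @param calls character vector of calls `-`, `+`, `++` or `NA`, all from
#'   one marker set.
#' @return percentage 0-100 (nearest integer) or `NA`.
#' @examples
#' match_percent(c("+", "-", "++", "+", "+", "+"))  # 83
#' match_percent(c(NA, "+", "-", "-", "+", "-"))    # 40
#' @export
match_percent <- function(calls) {
  bad <- setdiff(unique(calls[!is.na(calls)]), c("-", "+", "++"))
  if (length(bad))
    stop("unknown call token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  avail <- calls[!is.na(calls)]
  if (length(avail) == 0) return(NA_real_)
  round_half_up(100 * sum(avail %in% c("+", "++")) / length(avail))
}

#' Verdict rule for marker-profile classification
#'
#' @param af_match_required AF-match percentage required for an AF verdict
#'   (default 100: every available AF marker positive).
#' @param np_match_min minimum NP-match percentage for an NP verdict
#'   (default 83, i.e. at least 5 of 6 available markers).
#' @param np_requires_af_zero must the AF match be 0% for an NP verdict?
#' @param min_available minimum number of available calls in the asserted
#'   marker set.
#' @return list of class `panel_rule`.
#' @export
panel_rule <- function(af_match_required = 100, np_match_min = 83,
                       np_requires_af_zero = TRUE, min_available = 3) {
  structure(list(af_match_required = af_match_required,
                 np_match_min = np_match_min,
                 np_requires_af_zero = np_requires_af_zero,
                 min_available = min_available),
            class = "panel_rule")
}

#' Classify one marker-call profile
#'
#' A sample is called AF when all its available AF markers are positive
#' (AF match at the required level), NP when it expresses no AF marker (AF
#' match 0%) and its NP match reaches the NP threshold, and undefined
#' otherwise.  A verdict is only asserted when enough marker calls are
#' available (`min_available` non-NA calls in the asserted set).
#'
#' @param af_calls,np_calls call vectors for the AF and NP marker sets.
#' @param rule a [panel_rule()].
#' @return list with `af_match`, `np_match` (percentages or `NA`) and
#'   `verdict` (`"AF"`, `"NP"` or `"undefined"`).
#' @export
classify_profile <- function(af_calls, np_calls, rule = panel_rule()) {
  stopifnot(inherits(rule, "panel_rule"))
  af_avail <- sum(!is.na(af_calls))
  np_avail <- sum(!is.na(np_calls))
  af_match <- match_percent(af_calls)
  np_match <- match_percent(np_calls)
  verdict <- "undefined"
  if (af_avail >= rule$min_available &&
      !is.na(af_match) && af_match >= rule$af_match_required) {
    verdict <- "AF"
  } else if (np_avail >= rule$min_available &&
             !is.na(np_match) && np_match >= rule$np_match_min &&
             (!rule$np_requires_af_zero ||
              (!is.na(af_match) && af_match == 0))) {
    verdict <- "NP"
  }
  list(af_match = af_match, np_match = np_match, verdict = verdict)
}

#' Classify a cohort of marker-call profiles
#'
#' Applies [classify_profile()] to every row of a call table (one row per
#' test sample: resection origin, sample id, one call per panel marker) and
#' tallies verdicts and origin confirmations.
#'
#' @param table call table as returned by [read_call_table()].
#' @param panel a [marker_panel()] naming the marker columns.
#' @param rule a [panel_rule()].
#' @return list with `verdicts` (per-sample data frame: `origin`,
#'   `sample_id`, `af_match`, `np_match`, `verdict`, `confirmed`) and
#'   `summary` (counts `n_af_verdict`, `n_np_verdict`, `n_undefined`,
#'   `confirmed_af`, `n_af_origin`, `confirmed_np`, `n_np_origin`).
#' @export
classify_cohort <- function(table, panel = marker_panel(),
                            rule = panel_rule()) {
  stopifnot(inherits(panel, "marker_panel"))
  markers <- c(panel$af_markers, panel$np_markers)
  missing_m <- setdiff(markers, names(table))
  if (length(missing_m))
    stop("call table lacks marker column(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    prof <- classify_profile(
      unlist(table[i, panel$af_markers], use.names = FALSE),
      unlist(table[i, panel$np_markers], use.names = FALSE), rule)
    data.frame(origin = table$origin[i], sample_id = table$sample_id[i],
               af_match = prof$af_match, np_match = prof$np_match,
               verdict = prof$verdict,
               confirmed = identical(prof$verdict, table$origin[i]),
               stringsAsFactors = FALSE)
  })
  verdicts <- if (length(rows)) do.call(rbind, rows)
    else data.frame(origin = character(), sample_id = integer(),
                    af_match = numeric(), np_match = numeric(),
                    verdict = character(), confirmed = logical(),
                    stringsAsFactors = FALSE)
  summary <- list(
    n_af_verdict = sum(verdicts$verdict == "AF"),
    n_np_verdict = sum(verdicts$verdict == "NP"),
    n_undefined = sum(verdicts$verdict == "undefined"),
    confirmed_af = sum(verdicts$confirmed & verdicts$origin == "AF"),
    n_af_origin = sum(verdicts$origin == "AF"),
    confirmed_np = sum(verdicts$confirmed & verdicts$origin == "NP"),
    n_np_origin = sum(verdicts$origin == "NP")
  )
  list(verdicts = verdicts, summary = summary)
}
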