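#' Run the full quality-assessment and marker pipeline
#'
#' Executes, in order: score-sheet validation and verdicts, cohort
#' summary, expression-cohort selection, score correlations, optionally
#' the pairwise DEG screen with candidate selection (when an expression
#' matrix is given), optionally marker-panel classification (when a call
#' table is given) and optionally qPCR quantification (when a Cq table is
#' given).  Any stage failure aborts with the stage name and cause.
#'
#' @param score_sheet score-sheet data frame or TSV path.
#' @param dd_rule degeneration decision rule, see [classify_dd()].
#' @param expression optional [expression_matrix()].
#' @param deg_args list of arguments passed on to [screen_degs()].
#' @param criteria optional [candidate_criteria()] applied to the screen
#'   (requires `noise_floor`).
#' @param noise_floor detection floor used for candidate selection.
#' @param call_table optional call-table data frame or TSV path.
#' @param panel [marker_panel()] used for classification.
#' @param rule [panel_rule()] used for classification.
#' @param cq_table optional Cq table (data frame or TSV path); requires
#'   `assays` and `groups` as in [quantify_cohort()].
#' @param assays,groups see [quantify_cohort()].
#' @param out_dir optional directory; per-stage TSV/JSON outputs are
#'   written there when given.
#' @return list of class `discqc_report` with elements `verdicts`,
#'   `summary`, `cohort`, `correlations` and, when inputs were supplied,
#'   `degs`, `candidates`, `panel_classification`, `qpcr`.
#' @export
run_pipeline <- function(score_sheet, dd_rule = c("strict_gt3", "ge3"),
                         expression = NULL, deg_args = list(),
                         criteria = NULL, noise_floor = NULL,
                         call_table = NULL, panel = marker_panel(),
                         rule = panel_rule(),
                         cq_table = NULL, assays = NULL, groups = NULL,
                         out_dir = NULL) {
  dd_rule <- match.arg(dd_rule)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  report <- list()
  records <- stage("score", {
    if (is.character(score_sheet)) read_score_sheet(score_sheet)
    else validate_score_sheet(score_sheet)
  })
  report$verdicts <- stage("score", sample_verdicts(records, dd_rule))
  report$summary <- stage("score", summarize_cohort(records, dd_rule))
  report$cohort <- stage("select", select_microarray_cohort(records, dd_rule))
  report$correlations <- stage("correlate", correlate_scores(records))
  if (!is.null(expression)) {
    report$degs <- stage("deg-screen",
      do.call(screen_degs, c(list(matrix = expression), deg_args)))
    if (!is.null(criteria)) {
      if (is.null(noise_floor))
        stop("pipeline stage \"select-candidates\" failed: ",
             "noise_floor is required with criteria", call. = FALSE)
      report$candidates <- stage("select-candidates",
        select_candidates(report$degs, criteria, noise_floor))
    }
  }
  if (!is.null(call_table)) {
    calls <- stage("panel-classify", {
      if (is.character(call_table)) read_call_table(call_table, panel)
      else call_table
    })
    report$panel_classification <- stage("panel-classify",
      classify_cohort(calls, panel, rule))
  }
  if (!is.null(cq_table)) {
    cq <- stage("qpcr", {
      if (is.character(cq_table)) read_cq_table(cq_table) else cq_table
    })
    report$qpcr <- stage("qpcr", quantify_cohort(cq, assays, groups))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(report$verdicts, file.path(out_dir, "verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$correlations, file.path(out_dir, "correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      c(unclass(report$summary),
        list(cohort = unclass(report$cohort))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(report$degs))
      write.table(report$degs, file.path(out_dir, "degs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$panel_classification))
      write.table(report$panel_classification$verdicts,
                  file.path(out_dir, "panel_verdicts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  class(report) <- "discqc_report"
  report
}

#' @export
print.discqc_report <- function(x, ...) {
  print(x$summary)
  print(x$cohort)
  cat("\nScore correlations (tie-corrected Spearman):\n")
  print(format(x$correlations, digits = 3), row.names = FALSE)
  if (!is.null(x$degs))
    cat(sprintf("\nDEG screen: %d genes retained (%d AF-up, %d NP-up)\n",
                nrow(x$degs), sum(x$degs$direction == "AF_up"),
                sum(x$degs$direction == "NP_up")))
  if (!is.null(x$panel_classification)) {
    s <- x$panel_classification$summary
    cat(sprintf("\nMarker-panel verdicts: %d AF, %d NP, %d undefined; confirmed %d/%d AF-origin, %d/%d NP-origin\n",
                s$n_af_verdict, s$n_np_verdict, s$n_undefined,
                s$confirmed_af, s$n_af_origin, s$confirmed_np, s$n_np_origin))
  }
  invisible(x)
}
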