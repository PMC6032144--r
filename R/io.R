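# Readers and writers for the delimited formats the pipeline consumes:
# score sheets (aggregated or item-level dialect), marker call tables,
# expression matrices (+ optional detection and probe-level companions),
# Cq tables and panel/assay JSON.  All tabular output is tab-separated
# UTF-8 with a single header row.

IVD_ITEM_COLS <- paste0("ivd_i", 1:6)
DD_ITEM_COLS <- paste0("dd_i", 1:3)
SHEET_META_COLS <- c("donor_id", "gender", "age", "sample_id",
                     "disc_level", "mri_grade", "compartment")

#' Read a sample score sheet
#'
#' One row per (sample, compartment).  Two dialects are accepted: item
#' grades (`ivd_i1..ivd_i6`, `dd_i1..dd_i3`), from which totals and flags
#' are derived, or pre-aggregated totals plus flags (`ivd_total`,
#' `ivd_any_zero`, `dd_total`, `dd_any_two`).  The first violated
#' constraint is reported with its row.
#'
#' @param path TSV file path.
#' @return validated score-sheet data frame (totals and flags always
#'   present).
#' @export
read_score_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("score sheet is empty: ", path, call. = FALSE)
  missing_meta <- setdiff(SHEET_META_COLS, names(d))
  if (length(missing_meta))
    stop("score sheet lacks column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  validate_score_sheet(d, source = path)
}

#' Validate a score sheet held in memory
#'
#' @param d score-sheet data frame in either dialect.
#' @param source label used in error messages.
#' @return the validated data frame with totals and flags filled in.
#' @export
validate_score_sheet <- function(d, source = "score sheet") {
  bad_comp <- which(!(d$compartment %in% c("AF", "NP")))
  if (length(bad_comp))
    stop(sprintf("%s row %d: compartment must be AF or NP", source,
                 bad_comp[1]), call. = FALSE)
  dup <- which(duplicated(d[, c("sample_id", "compartment")]))
  if (length(dup))
    stop(sprintf("%s row %d: duplicate (sample_id, compartment)", source,
                 dup[1]), call. = FALSE)
  has_items <- all(c(IVD_ITEM_COLS, DD_ITEM_COLS) %in% names(d))
  has_totals <- all(c("ivd_total", "ivd_any_zero",
                      "dd_total", "dd_any_two") %in% names(d))
  if (has_items) {
    for (i in seq_len(nrow(d))) {
      ivd <- tryCatch(
        score_rubric(as.integer(d[i, IVD_ITEM_COLS]), "IVD"),
        error = function(e) stop(sprintf("%s row %d: %s", source, i,
                                         conditionMessage(e)), call. = FALSE))
      dd <- tryCatch(
        score_rubric(as.integer(d[i, DD_ITEM_COLS]), "DD"),
        error = function(e) stop(sprintf("%s row %d: %s", source, i,
                                         conditionMessage(e)), call. = FALSE))
      if (has_totals &&
          (d$ivd_total[i] != ivd$total || d$dd_total[i] != dd$total))
        stop(sprintf("%s row %d: totals disagree with item grades",
                     source, i), call. = FALSE)
      d$ivd_total[i] <- ivd$total; d$ivd_any_zero[i] <- ivd$flag
      d$dd_total[i] <- dd$total; d$dd_any_two[i] <- dd$flag
    }
  } else if (has_totals) {
    if (any(d$ivd_total < 0 | d$ivd_total > 12))
      stop(source, ": IVD total out of range 0-12 in row ",
           which(d$ivd_total < 0 | d$ivd_total > 12)[1], call. = FALSE)
    if (any(d$dd_total < 0 | d$dd_total > 6))
      stop(source, ": DD total out of range 0-6 in row ",
           which(d$dd_total < 0 | d$dd_total > 6)[1], call. = FALSE)
    d$ivd_any_zero <- as.logical(d$ivd_any_zero)
    d$dd_any_two <- as.logical(d$dd_any_two)
    if (anyNA(d$ivd_any_zero) || anyNA(d$dd_any_two))
      stop(source, ": flags must be logical (TRUE/FALSE)", call. = FALSE)
  } else {
    stop(source, ": need either item-grade columns (ivd_i1..ivd_i6, ",
         "dd_i1..dd_i3) or totals + flags", call. = FALSE)
  }
  d
}

#' Write a score sheet
#'
#' @param records score-sheet data frame.
#' @param path output TSV path.
#' @param dialect write item grades (`"items"`, requires item columns) or
#'   aggregated totals + flags (`"totals"`).
#' @export
write_score_sheet <- function(records, path, dialect = c("totals", "items")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "items") c(SHEET_META_COLS, IVD_ITEM_COLS, DD_ITEM_COLS)
          else c(SHEET_META_COLS, "ivd_total", "ivd_any_zero",
                 "dd_total", "dd_any_two")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("cannot write dialect \"", dialect, "\": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a marker call table
#'
#' One row per test sample: `origin` (resection site, AF or NP),
#' `sample_id`, then one call column per panel marker with tokens `-`,
#' `+`, `++` or `NA`.  The Unicode minus sign (U+2212) is accepted as `-`.
#'
#' @param path TSV file path.
#' @param panel a [marker_panel()] whose markers must all be present as
#'   columns.
#' @return data frame with character call columns (`NA` = not available).
#' @export
read_call_table <- function(path, panel = marker_panel()) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "NA", fileEncoding = "UTF-8")
  if (nrow(d) == 0) stop("call table is empty: ", path, call. = FALSE)
  if (!all(c("origin", "sample_id") %in% names(d)))
    stop("call table needs columns origin and sample_id", call. = FALSE)
  markers <- c(panel$af_markers, panel$np_markers)
  missing_m <- setdiff(markers, names(d))
  if (length(missing_m))
    stop("call table lacks marker column(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  for (m in markers) {
    d[[m]] <- gsub("−", "-", d[[m]])
    bad <- which(!is.na(d[[m]]) & !(d[[m]] %in% c("-", "+", "++")))
    if (length(bad))
      stop(sprintf("call table row %d, marker %s: unknown token \"%s\"",
                   bad[1], m, d[[m]][bad[1]]), call. = FALSE)
  }
  d$sample_id <- as.integer(d$sample_id)
  d
}

#' Write a marker call table
#'
#' @param table call-table data frame.
#' @param path output TSV path.
#' @export
write_call_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix with group assignment
#'
#' The matrix TSV has `gene_id` as its first column and one column per
#' chip.  Group assignment comes from a JSON object mapping chip id to
#' `"AF"`/`"NP"`, or a named character vector.  Optional companions: a
#' detection TSV of the same shape holding TRUE/FALSE, and a wide
#' probe-level TSV (`gene_id`, `chip_id`, `p1..pP`).
#'
#' @param path matrix TSV path.
#' @param groups JSON path or named character vector (chip id -> group).
#' @param detection_path optional detection TSV path.
#' @param probe_path optional probe-level TSV path.
#' @param detection_floor optional floor used when no detection companion
#'   is given.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, groups, detection_path = NULL,
                                   probe_path = NULL,
                                   detection_floor = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id")
    stop("first column of an expression matrix must be gene_id",
         call. = FALSE)
  signal <- as.matrix(d[, -1, drop = FALSE])
  rownames(signal) <- d$gene_id
  if (is.character(groups) && length(groups) == 1 && file.exists(groups))
    groups <- unlist(jsonlite::read_json(groups))
  chip_groups <- groups[colnames(signal)]
  if (anyNA(chip_groups))
    stop("no group assignment for chip(s): ",
         paste(colnames(signal)[is.na(chip_groups)], collapse = ", "),
         call. = FALSE)
  detection <- NULL
  if (!is.null(detection_path)) {
    dd <- read.delim(detection_path, stringsAsFactors = FALSE,
                     check.names = FALSE)
    detection <- as.matrix(dd[, -1, drop = FALSE])
    rownames(detection) <- dd$gene_id
    detection <- detection[rownames(signal), colnames(signal)]
    mode(detection) <- "logical"
  }
  probes <- NULL
  if (!is.null(probe_path)) {
    pw <- read.delim(probe_path, stringsAsFactors = FALSE,
                     check.names = FALSE)
    pcols <- grep("^p[0-9]+$", names(pw), value = TRUE)
    probes <- array(NA_real_,
                    dim = c(nrow(signal), ncol(signal), length(pcols)),
                    dimnames = list(rownames(signal), colnames(signal),
                                    pcols))
    for (r in seq_len(nrow(pw)))
      probes[pw$gene_id[r], pw$chip_id[r], ] <-
        as.numeric(pw[r, pcols])
  }
  expression_matrix(signal = signal, group = unname(chip_groups),
                    probe_signals = probes, detection = detection,
                    detection_floor = detection_floor)
}

#' Write an expression matrix (and companions)
#'
#' @param em an [expression_matrix()].
#' @param path matrix TSV path.
#' @param groups_path optional JSON path for the chip-to-group map.
#' @param detection_path,probe_path optional companion TSV paths.
#' @export
write_expression_matrix <- function(em, path, groups_path = NULL,
                                    detection_path = NULL,
                                    probe_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  fmt <- function(m) signif(m, 6)
  write.table(data.frame(gene_id = em$gene_ids, fmt(em$signal),
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path))
    jsonlite::write_json(as.list(setNames(em$group, em$chip_ids)),
                         groups_path, auto_unbox = TRUE)
  if (!is.null(detection_path) && !is.null(em$detection))
    write.table(data.frame(gene_id = em$gene_ids, em$detection,
                           check.names = FALSE),
                detection_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(probe_path) && !is.null(em$probe_signals)) {
    p <- dim(em$probe_signals)[3]
    long <- do.call(rbind, lapply(seq_along(em$chip_ids), function(j) {
      data.frame(gene_id = em$gene_ids, chip_id = em$chip_ids[j],
                 fmt(matrix(em$probe_signals[, j, ], ncol = p,
                            dimnames = list(NULL, paste0("p", seq_len(p))))),
                 check.names = FALSE)
    }))
    write.table(long, probe_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a triplicate Cq table
#'
#' Columns `sample_id`, `gene_id`, `cq1`, `cq2`, `cq3`; blank cells are
#' missing replicates, a fully blank triplet means no amplification.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_cq_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("sample_id", "gene_id", "cq1")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols))
    stop("Cq table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d
}

#' Write a fitted marker panel to JSON
#'
#' @param panel a [marker_panel()].
#' @param path output JSON path.
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  jsonlite::write_json(
    list(af_markers = panel$af_markers, np_markers = panel$np_markers,
         ranges = panel$ranges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a marker panel from JSON
#'
#' @param path JSON path written by [write_panel_json()].
#' @return a [marker_panel()].
#' @export
read_panel_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- if (!is.null(j$ranges) && length(j$ranges))
    as.data.frame(j$ranges, stringsAsFactors = FALSE) else NULL
  marker_panel(af_markers = j$af_markers, np_markers = j$np_markers,
               ranges = ranges)
}

#' Path to a packaged fixture
#'
#' @param name fixture file name (`"table3.tsv"` or `"table5.tsv"`).
#' @return absolute path to the installed fixture.
#' @export
discqc_fixture <- function(name) {
  p <- system.file("extdata", name, package = "discQC")
  if (p == "") stop("no packaged fixture named ", name, call. = FALSE)
  p
}
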