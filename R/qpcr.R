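#' Define qPCR assays
#'
#' One row per assay: gene id, amplification efficiency E (2.0 = perfect
#' doubling per cycle) and whether the assay is one of the two reference
#' (housekeeping) genes used for normalisation.
#'
#' @param gene_id character vector of assay gene ids.
#' @param efficiency per-assay efficiencies in (1, 2.2].
#' @param is_reference logical vector; exactly two assays must be
#'   references (defaults name ATP5F1B and RPL13A).
#' @return data frame of class `qpcr_assays`.
#' @export
qpcr_assays <- function(gene_id, efficiency = 2.0,
                        is_reference = gene_id %in% c("ATP5F1B", "RPL13A")) {
  efficiency <- rep_len(efficiency, length(gene_id))
  if (any(efficiency <= 1 | efficiency > 2.2))
    stop("assay efficiencies must lie in (1, 2.2]", call. = FALSE)
  if (sum(is_reference) != 2)
    stop("exactly two reference assays are required, got ",
         sum(is_reference), call. = FALSE)
  if (anyDuplicated(gene_id))
    stop("duplicate assay gene ids", call. = FALSE)
  structure(data.frame(gene_id = gene_id, efficiency = efficiency,
                       is_reference = is_reference,
                       stringsAsFactors = FALSE),
            class = c("qpcr_assays", "data.frame"))
}

#' Efficiency-corrected relative expression (E-method)
#'
#' The efficiency-corrected abundance of an assay is E^(-Cq).  Relative
#' expression of the target is its abundance divided by the geometric mean
#' of the two reference-gene abundances:
#' \deqn{RE = E_t^{-Cq_t} / \sqrt{E_{r1}^{-Cq_{r1}} \cdot E_{r2}^{-Cq_{r2}}}}
#' An undetected target (no amplification) yields relative expression 0;
#' an undetected reference makes the sample unquantifiable and is an error.
#'
#' @param target_cq mean quantification cycle of the target, or `NA` when
#'   the target did not amplify.
#' @param ref_cq numeric length-2 vector of reference mean Cq values.
#' @param target_eff,ref_eff amplification efficiencies (default 2.0).
#' @return non-negative relative expression.
#' @examples
#' relative_expression(20, c(20, 20))  # 1 (self-normalisation)
#' relative_expression(19, c(20, 20))  # 2 (one-cycle doubling)
#' @export
relative_expression <- function(target_cq, ref_cq, target_eff = 2.0,
                                ref_eff = c(2.0, 2.0)) {
  if (length(ref_cq) != 2)
    stop("exactly two reference Cq values are required", call. = FALSE)
  if (anyNA(ref_cq))
    stop("undetected reference gene: sample not quantifiable", call. = FALSE)
  ref_eff <- rep_len(ref_eff, 2)
  if (is.na(target_cq)) return(0)
  target_eff^(-target_cq) /
    sqrt(ref_eff[1]^(-ref_cq[1]) * ref_eff[2]^(-ref_cq[2]))
}

# mean Cq per (sample, gene) from a triplicate table; a row present with
# all replicates blank encodes "no amplification" (undetected -> Cq NA but
# measured), whereas an absent row means the assay was never run
aggregate_cq <- function(cq_table) {
  rep_cols <- grep("^cq[0-9]+$", names(cq_table), value = TRUE)
  if (!length(rep_cols))
    stop("Cq table needs replicate columns cq1, cq2, ...", call. = FALSE)
  reps <- as.matrix(cq_table[, rep_cols, drop = FALSE])
  if (any(reps <= 0, na.rm = TRUE))
    stop("Cq values must be positive", call. = FALSE)
  data.frame(sample_id = cq_table$sample_id, gene_id = cq_table$gene_id,
             cq_mean = rowMeans(reps, na.rm = TRUE),  # NaN when all blank
             undetected = rowSums(!is.na(reps)) == 0,
             stringsAsFactors = FALSE)
}

#' Quantify a qPCR cohort and compare AF versus NP
#'
#' Aggregates triplicate Cq values per (sample, gene), computes
#' efficiency-corrected relative expression of every panel marker against
#' the two reference genes ([relative_expression()]), and tests each
#' marker between the clear AF and clear NP groups with the Mann-Whitney U
#' test (significance tiers: ns, `*` p < 0.05, `**` p < 0.01).
#'
#' Assays never run for a sample stay `NA`; assays run but without
#' amplification yield relative expression 0 ("no expression").  Samples
#' lacking either reference gene are skipped with a warning.
#'
#' @param cq_table long-format data frame: `sample_id`, `gene_id`,
#'   replicate columns `cq1`, `cq2`, `cq3` (blank = missing replicate; all
#'   blank = no amplification).
#' @param assays a [qpcr_assays()] table covering every measured gene.
#' @param groups named character vector mapping sample ids to `"AF"`,
#'   `"NP"` or `"unknown"`; only AF and NP samples enter the group test.
#' @return list with `expression` (sample x marker matrix of relative
#'   expression) and `tests` (per-marker data frame: `gene_id`, `U`, `p`,
#'   `signif`, `n_af`, `n_np`).
#' @export
quantify_cohort <- function(cq_table, assays, groups) {
  stopifnot(inherits(assays, "qpcr_assays"))
  unknown_genes <- setdiff(unique(cq_table$gene_id), assays$gene_id)
  if (length(unknown_genes))
    stop("no assay definition for gene(s): ",
         paste(unknown_genes, collapse = ", "), call. = FALSE)
  agg <- aggregate_cq(cq_table)
  refs <- assays$gene_id[assays$is_reference]
  targets <- assays$gene_id[!assays$is_reference]
  eff <- setNames(assays$efficiency, assays$gene_id)
  samples <- unique(agg$sample_id)
  expr <- matrix(NA_real_, length(samples), length(targets),
                 dimnames = list(as.character(samples), targets))
  for (s in samples) {
    a <- agg[agg$sample_id == s, , drop = FALSE]
    ref_rows <- a[match(refs, a$gene_id), ]
    if (anyNA(ref_rows$cq_mean) || any(ref_rows$undetected)) {
      warning("sample ", s, " lacks a reference gene; skipped",
              call. = FALSE)
      next
    }
    for (g in intersect(targets, a$gene_id)) {
      row <- a[a$gene_id == g, ]
      expr[as.character(s), g] <- relative_expression(
        if (row$undetected) NA_real_ else row$cq_mean,
        ref_rows$cq_mean, eff[g], eff[refs])
    }
  }
  grp <- groups[rownames(expr)]
  tests <- do.call(rbind, lapply(targets, function(g) {
    a_vals <- expr[which(grp == "AF"), g]
    b_vals <- expr[which(grp == "NP"), g]
    a_vals <- a_vals[!is.na(a_vals)]
    b_vals <- b_vals[!is.na(b_vals)]
    if (length(a_vals) == 0 || length(b_vals) == 0)
      return(data.frame(gene_id = g, U = NA_real_, p = NA_real_,
                        signif = NA_character_, n_af = length(a_vals),
                        n_np = length(b_vals), stringsAsFactors = FALSE))
    mw <- mann_whitney_u(a_vals, b_vals)
    data.frame(gene_id = g, U = mw$U, p = mw$p.value,
               signif = if (mw$p.value < 0.01) "**"
                        else if (mw$p.value < 0.05) "*" else "ns",
               n_af = length(a_vals), n_np = length(b_vals),
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(expression = expr, tests = tests)
}
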