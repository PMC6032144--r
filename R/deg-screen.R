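#' Construct a grouped expression matrix
#'
#' Container for gene x chip linear-scale signals with AF/NP group labels,
#' optional probe-level replicate signals and optional detection calls.
#' When probe-level signals are supplied without a summary signal, the
#' per-chip signal is the 20% trimmed mean over probes (a robust summary in
#' the spirit of probe-set condensation).  When detection calls are absent
#' and a `detection_floor` is given, a gene is called detected on a chip
#' when its signal reaches the floor.
#'
#' @param signal gene x chip matrix of non-negative linear signals
#'   (rownames = gene ids, colnames = chip ids), or `NULL` to derive it
#'   from `probe_signals`.
#' @param group character vector of `"AF"`/`"NP"` labels, one per chip.
#' @param probe_signals optional gene x chip x probe array of positive
#'   signals.
#' @param detection optional gene x chip logical matrix (TRUE = detected).
#' @param detection_floor optional positive scalar used to derive
#'   `detection` when it is not supplied.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(signal = NULL, group, probe_signals = NULL,
                              detection = NULL, detection_floor = NULL) {
  if (is.null(signal)) {
    if (is.null(probe_signals))
      stop("supply `signal`, `probe_signals` or both", call. = FALSE)
    signal <- apply(probe_signals, c(1, 2), mean, trim = 0.2)
  }
  signal <- as.matrix(signal)
  if (!all(group %in% c("AF", "NP")))
    stop("group labels must be \"AF\" or \"NP\"", call. = FALSE)
  if (length(group) != ncol(signal))
    stop("one group label per chip is required", call. = FALSE)
  if (any(signal < 0)) stop("signals must be non-negative", call. = FALSE)
  if (!is.null(probe_signals)) {
    if (!identical(dim(probe_signals)[1:2], dim(signal)))
      stop("probe_signals must be gene x chip x probe", call. = FALSE)
    if (any(probe_signals <= 0))
      stop("probe-level signals must be positive", call. = FALSE)
  }
  if (is.null(detection) && !is.null(detection_floor))
    detection <- detection_call(pmax(signal, .Machine$double.xmin),
                                detection_floor)
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dim(detection), dim(signal)))
      stop("detection matrix must match the signal matrix", call. = FALSE)
  }
  structure(list(gene_ids = rownames(signal), chip_ids = colnames(signal),
                 group = group, signal = signal,
                 probe_signals = probe_signals, detection = detection),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d chips (%d AF, %d NP)%s%s\n",
              nrow(x$signal), ncol(x$signal),
              sum(x$group == "AF"), sum(x$group == "NP"),
              if (!is.null(x$probe_signals))
                sprintf(", %d probes/set", dim(x$probe_signals)[3]) else "",
              if (!is.null(x$detection)) ", with detection calls" else ""))
  invisible(x)
}

#' Detection call from a signal floor
#'
#' A gene is called detected on a chip when its signal reaches the noise
#' floor (boundary inclusive).
#'
#' @param signal positive signal value(s).
#' @param floor positive detection floor.
#' @return logical, TRUE = detected.
#' @export
detection_call <- function(signal, floor) {
  stopifnot(length(floor) == 1, floor > 0)
  if (any(signal <= 0))
    stop("signals must be positive", call. = FALSE)
  signal >= floor
}

#' Compare one gene between one AF and one NP chip
#'
#' The signal log ratio (SLR) is the median over probes of the per-probe
#' log2 ratio AF/NP; the fold-change is 2^SLR.  The p-value is a two-sided
#' exact Wilcoxon signed-rank test of the per-probe log ratios against 0.
#' The change call is *increased* when FC exceeds `fc_call_threshold` at
#' p < `alpha`, *decreased* symmetrically, otherwise *no_change*.
#'
#' @param af_probes,np_probes positive probe-level signals (>= 5 probes).
#' @param fc_call_threshold fold-change margin for a change call.
#' @param alpha significance margin for a change call.
#' @return list with `slr`, `fc`, `change_call` and `p`.
#' @export
pairwise_compare <- function(af_probes, np_probes, fc_call_threshold = 2,
                             alpha = 0.05) {
  if (length(af_probes) != length(np_probes))
    stop("probe vectors must have equal length", call. = FALSE)
  if (length(af_probes) < 5)
    stop("need at least 5 probes per set", call. = FALSE)
  if (any(af_probes <= 0) || any(np_probes <= 0))
    stop("probe signals must be positive", call. = FALSE)
  lr <- log2(af_probes / np_probes)
  slr <- median(lr)
  p <- wilcoxon_signed_rank(lr)$p.value
  fc <- 2^slr
  call <- if (fc > fc_call_threshold && p < alpha) "increased"
          else if (fc < 1 / fc_call_threshold && p < alpha) "decreased"
          else "no_change"
  list(slr = slr, fc = fc, change_call = call, p = p)
}

# row-wise midranks of a matrix of absolute values (no zeros expected)
.row_ranks <- function(m) t(apply(m, 1, rank))

# vectorised per-row signed-rank p-values for a matrix of log ratios with
# a fixed number of columns; exact for tie-free rows, convolution otherwise
.signed_rank_p_rows <- function(lr) {
  p_count <- ncol(lr)
  nz <- rowSums(lr != 0)
  p <- numeric(nrow(lr))
  full <- nz == p_count
  if (any(full)) {
    a <- abs(lr[full, , drop = FALSE])
    rk <- .row_ranks(a)
    w <- rowSums(rk * (lr[full, , drop = FALSE] > 0))
    tied <- apply(a, 1, anyDuplicated) > 0
    pf <- numeric(sum(full))
    if (any(!tied)) {
      wv <- w[!tied]
      pf[!tied] <- pmin(1, 2 * pmin(psignrank(wv, p_count),
                                    psignrank(p_count * (p_count + 1) / 2 - wv,
                                              p_count)))
    }
    if (any(tied)) {
      idx <- which(tied)
      rows <- which(full)[idx]
      pf[idx] <- vapply(rows, function(i)
        wilcoxon_signed_rank(lr[i, ])$p.value, numeric(1))
    }
    p[full] <- pf
  }
  if (any(!full))
    p[!full] <- vapply(which(!full), function(i)
      wilcoxon_signed_rank(lr[i, ])$p.value, numeric(1))
  p
}

#' Screen for differentially expressed genes by all pairwise comparisons
#'
#' For every gene, every AF chip is compared against every NP chip
#' ([pairwise_compare()]).  A gene is retained as AF-up when at least a
#' `consistency` fraction of all pairs is called *increased* (NP-up
#' symmetrically with *decreased*).  Fold-changes of retained genes are
#' summarised as mean +/- SD over all pairs, reported on the up-regulated
#' tissue's scale (so NP-up genes also read FC > 1); records additionally
#' carry the matching change-call percentage, per-tissue detection
#' percentages, the median pairwise p-value and per-tissue signal means.
#'
#' Without probe-level signals the per-pair SLR is the plain signal log2
#' ratio and change calls use the fold-change margin only (no per-pair
#' p-value is available; `p_median` is NA).
#'
#' @param matrix an [expression_matrix()].
#' @param fc_threshold fold-change margin for per-pair change calls.
#' @param consistency minimum fraction of pairs with a matching change
#'   call, default 0.8.
#' @param alpha per-pair significance margin, default 0.05.
#' @return data frame of class `deg_records`, one row per retained gene:
#'   `gene_id`, `direction` (`AF_up`/`NP_up`), `fc_mean`, `fc_sd`,
#'   `change_pct`, `detection_pct_af`, `detection_pct_np`, `p_median`,
#'   `signal_mean_af`, `signal_mean_np`; sorted by direction then
#'   descending `fc_mean` (gene id breaks ties).
#' @export
screen_degs <- function(matrix, fc_threshold = 2, consistency = 0.8,
                        alpha = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"))
  af_idx <- which(matrix$group == "AF")
  np_idx <- which(matrix$group == "NP")
  if (length(af_idx) < 2 || length(np_idx) < 2)
    stop("need at least 2 chips per group", call. = FALSE)
  genes <- matrix$gene_ids
  n_genes <- length(genes)
  pairs <- expand.grid(af = af_idx, np = np_idx)
  n_pairs <- nrow(pairs)
  slr_all <- matrix(NA_real_, n_genes, n_pairs)
  p_all <- matrix(NA_real_, n_genes, n_pairs)
  has_probes <- !is.null(matrix$probe_signals)
  for (k in seq_len(n_pairs)) {
    i <- pairs$af[k]; j <- pairs$np[k]
    if (has_probes) {
      lr <- log2(matrix$probe_signals[, i, ] / matrix$probe_signals[, j, ])
      if (is.null(dim(lr))) lr <- base::matrix(lr, nrow = n_genes)
      slr_all[, k] <- apply(lr, 1, median)
      p_all[, k] <- .signed_rank_p_rows(lr)
    } else {
      slr_all[, k] <- log2(pmax(matrix$signal[, i], .Machine$double.xmin) /
                           pmax(matrix$signal[, j], .Machine$double.xmin))
    }
  }
  fc_all <- 2^slr_all
  sig_ok <- if (has_probes) p_all < alpha else TRUE
  inc <- fc_all > fc_threshold & sig_ok
  dec <- fc_all < 1 / fc_threshold & sig_ok
  inc_frac <- rowMeans(inc)
  dec_frac <- rowMeans(dec)
  keep_up <- inc_frac >= consistency
  keep_dn <- dec_frac >= consistency & !keep_up
  build <- function(idx, direction) {
    if (!length(idx)) return(NULL)
    fc_dir <- if (direction == "AF_up") fc_all[idx, , drop = FALSE]
              else 1 / fc_all[idx, , drop = FALSE]
    det <- matrix$detection
    data.frame(
      gene_id = genes[idx],
      direction = direction,
      fc_mean = rowMeans(fc_dir),
      fc_sd = apply(fc_dir, 1, sd),
      change_pct = 100 * (if (direction == "AF_up") inc_frac[idx]
                          else dec_frac[idx]),
      detection_pct_af = if (is.null(det)) NA_real_
        else 100 * rowMeans(det[idx, af_idx, drop = FALSE]),
      detection_pct_np = if (is.null(det)) NA_real_
        else 100 * rowMeans(det[idx, np_idx, drop = FALSE]),
      p_median = if (has_probes) apply(p_all[idx, , drop = FALSE], 1, median)
                 else NA_real_,
      signal_mean_af = rowMeans(matrix$signal[idx, af_idx, drop = FALSE]),
      signal_mean_np = rowMeans(matrix$signal[idx, np_idx, drop = FALSE]),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(build(which(keep_up), "AF_up"), build(which(keep_dn), "NP_up"))
  if (is.null(out))
    out <- data.frame(gene_id = character(), direction = character(),
                      fc_mean = numeric(), fc_sd = numeric(),
                      change_pct = numeric(), detection_pct_af = numeric(),
                      detection_pct_np = numeric(), p_median = numeric(),
                      signal_mean_af = numeric(), signal_mean_np = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$direction, -out$fc_mean, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_records", "data.frame")
  out
}

#' Marker-candidate filter criteria
#'
#' Defaults mirror the two-tier screen used to nominate the marker panel:
#' AF candidates are top-25 ranked genes with FC >= 24.4, median pairwise
#' p < 0.05 and zero detection in the NP (on/off genes); NP candidates are
#' top-16 ranked genes with FC >= 3.0 on the NP scale, full detection in
#' the NP and a stable NP signal mean (at least `np_signal_floor_mult`
#' times the noise floor).
#'
#' @param af_fc_min,af_p_max,af_np_detection_pct AF-candidate thresholds.
#' @param np_fc_min,np_detection_pct_min,np_signal_floor_mult NP-candidate
#'   thresholds.
#' @param top_k_af,top_k_np list depth cut after ranking by fold-change.
#' @param exclusion_list gene ids removed before ranking (stands in for the
#'   manual literature screen of candidates).
#' @return list of class `candidate_criteria`.
#' @export
candidate_criteria <- function(af_fc_min = 24.4, af_p_max = 0.05,
                               af_np_detection_pct = 0, np_fc_min = 3.0,
                               np_detection_pct_min = 100,
                               np_signal_floor_mult = 2.0,
                               top_k_af = 25, top_k_np = 16,
                               exclusion_list = character()) {
  stopifnot(af_fc_min > 0, np_fc_min > 0, af_p_max > 0,
            top_k_af >= 1, top_k_np >= 1, np_signal_floor_mult > 0)
  structure(list(af_fc_min = af_fc_min, af_p_max = af_p_max,
                 af_np_detection_pct = af_np_detection_pct,
                 np_fc_min = np_fc_min,
                 np_detection_pct_min = np_detection_pct_min,
                 np_signal_floor_mult = np_signal_floor_mult,
                 top_k_af = top_k_af, top_k_np = top_k_np,
                 exclusion_list = exclusion_list),
            class = "candidate_criteria")
}

#' Select marker candidates from screened genes
#'
#' Ranks each direction's retained genes by mean fold-change (descending,
#' gene id breaking ties), drops excluded genes, cuts each list at its
#' top-k depth and applies the direction's thresholds (see
#' [candidate_criteria()]).
#'
#' @param degs a `deg_records` data frame from [screen_degs()].
#' @param criteria a [candidate_criteria()] object.
#' @param noise_floor detection noise floor of the platform (same scale as
#'   the signals).
#' @return list with data frames `af_candidates` and `np_candidates`.
#' @export
select_candidates <- function(degs, criteria = candidate_criteria(),
                              noise_floor) {
  stopifnot(inherits(criteria, "candidate_criteria"), noise_floor > 0)
  if (nrow(degs) == 0)
    stop("no screened genes supplied", call. = FALSE)
  degs <- degs[!(degs$gene_id %in% criteria$exclusion_list), , drop = FALSE]
  ranked <- function(direction, k) {
    d <- degs[degs$direction == direction, , drop = FALSE]
    d <- d[order(-d$fc_mean, d$gene_id), , drop = FALSE]
    head(d, k)
  }
  af <- ranked("AF_up", criteria$top_k_af)
  af <- af[af$fc_mean >= criteria$af_fc_min &
           af$p_median < criteria$af_p_max &
           af$detection_pct_np == criteria$af_np_detection_pct, ,
           drop = FALSE]
  np <- ranked("NP_up", criteria$top_k_np)
  np <- np[np$fc_mean >= criteria$np_fc_min &
           np$detection_pct_np >= criteria$np_detection_pct_min &
           np$signal_mean_np >= criteria$np_signal_floor_mult * noise_floor, ,
           drop = FALSE]
  rownames(af) <- rownames(np) <- NULL
  list(af_candidates = af, np_candidates = np)
}
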