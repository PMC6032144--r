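#' Interpretation band for a correlation coefficient
#'
#' Bands on |r|: 0-0.19 very weak, 0.2-0.39 weak, 0.4-0.59 moderate,
#' 0.6-0.79 strong, 0.8-1.0 very strong.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return character vector of band labels.
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  stopifnot(all(a <= 1 + 1e-12))
  cut(pmin(a, 1), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("very weak", "weak", "moderate", "strong", "very strong"),
      right = FALSE)
}

#' Tie-corrected Spearman rank correlation
#'
#' Computes Spearman's r as the Pearson correlation of average (midrank)
#' ranks, which is the standard tie-corrected estimator, with a two-sided
#' p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no missing values.
#' @return object of class `spearman_cor`: list with `r`, `p`, `n` and
#'   `band` (see [correlation_band()]).
#' @examples
#' spearman_cor(1:5, c(2, 4, 5, 8, 9))$r  # 1
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3)
    stop("need at least 3 paired observations, got ", n, call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector: rank correlation is undefined", call. = FALSE)
  r <- cor(rank(x), rank(y))
  # t approximation; degenerate at |r| = 1 where p underflows to 0
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n,
                 band = as.character(correlation_band(r))),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman r = %+.3f (%s), p = %.3g, n = %d\n",
              x$r, x$band, x$p, x$n))
  invisible(x)
}

#' Correlate scoring outcome with donor age and MRI grade
#'
#' For each rubric total (IVD, DD), compartment (AF, NP) and covariate
#' (donor age, MRI degeneration grade), computes the tie-corrected Spearman
#' correlation over all samples of that compartment.
#'
#' @param records score sheet carrying `compartment`, `ivd_total`,
#'   `dd_total`, `age` and `mri_grade`.
#' @return data frame with one row per (score, compartment, covariate)
#'   combination and columns `r`, `p`, `n`, `band`.
#' @export
correlate_scores <- function(records) {
  needed <- c("compartment", "ivd_total", "dd_total", "age", "mri_grade")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("score sheet lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(score = c("IVD", "DD"), compartment = c("AF", "NP"),
                      covariate = c("age", "mri_grade"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- records[records$compartment == grid$compartment[i], , drop = FALSE]
    score_col <- if (grid$score[i] == "IVD") "ivd_total" else "dd_total"
    ct <- spearman_cor(s[[score_col]], s[[grid$covariate[i]]])
    data.frame(grid[i, ], r = ct$r, p = ct$p, n = ct$n, band = ct$band,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
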