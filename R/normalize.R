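#' Normalize counts to log2 counts-per-million
#'
#' The canonical expression scale for the paired test:
#' \eqn{e = \log_2(10^6 \cdot c / L + \mathrm{pseudocount})} with \eqn{L} the
#' sample's total count. CPM before the log and pseudocount sum to 1e6 per
#' sample, so the transform is invariant to sequencing depth.
#'
#' @param counts Numeric matrix, genes x samples, non-negative.
#' @param pseudocount Added inside the log; default 1 so a zero count maps to
#'   e = 0.
#' @return Matrix of the same shape, log2 scale.
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' normalize_log_cpm(m)  # log2(250001), log2(750001)
#' @export
normalize_log_cpm <- function(counts, pseudocount = 1) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  log2(sweep(counts, 2L, 1e6 / lib, `*`) + pseudocount)
}

#' Filter genes by expression in a reference sample set
#'
#' Keeps genes whose expression is at least `min_mean_e` in at least
#' `min_fraction_samples` of the reference samples (by default all columns;
#' in the pipeline, the adjacent normals). Gene order is preserved and the
#' operation is idempotent.
#'
#' @param expr Expression matrix (genes x samples), log2 scale.
#' @param min_mean_e Expression threshold (log2 CPM units).
#' @param min_fraction_samples Minimum fraction of reference samples at or
#'   above the threshold.
#' @param samples Optional character vector of reference sample ids (columns
#'   of `expr`) on which the criterion is evaluated.
#' @return The filtered expression matrix (all columns retained).
#' @export
filter_low_expression <- function(expr, min_mean_e = 1,
                                  min_fraction_samples = 0.5,
                                  samples = colnames(expr)) {
  stopifnot(is.finite(min_mean_e) || min_mean_e == -Inf,
            all(samples %in% colnames(expr)))
  ref <- expr[, samples, drop = FALSE]
  keep <- rowMeans(ref >= min_mean_e) >= min_fraction_samples
  expr[keep, , drop = FALSE]
}
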