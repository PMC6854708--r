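#' Pairwise transcriptome distances between sample groups
#'
#' Distance between two samples is 1 minus the Spearman correlation of their
#' expression vectors over all shared genes (0 for identical ranks, up to 2
#' for perfectly anti-ranked profiles). Three pair specifications mirror the
#' heterogeneity comparison of matched cohorts: all unordered pairs of
#' adjacent normals (or of primaries, for the inter-patient tumor
#' comparison); one matched normal-vs-primary pair per patient; one matched
#' primary-vs-PVTT pair per patient.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sheet Sample sheet data.frame.
#' @param pair_spec One of "within-normals", "within-primaries",
#'   "matched-normal-primary", "matched-primary-pvtt".
#' @return List of class `distance_summary`: `pair_spec`, `pairs`
#'   (data.frame sample1, sample2, distance), `mean_distance`.
#' @export
pairwise_distances <- function(expr, sheet,
                               pair_spec = c("within-normals",
                                             "within-primaries",
                                             "matched-normal-primary",
                                             "matched-primary-pvtt")) {
  pair_spec <- match.arg(pair_spec)
  pick <- function(tissue) {
    s <- sheet[sheet$tissue == tissue, , drop = FALSE]
    setNames(s$sample_id, s$patient_id)
  }
  if (startsWith(pair_spec, "within-")) {
    tissue <- c("within-normals" = "normal",
                "within-primaries" = "primary")[[pair_spec]]
    ns <- intersect(pick(tissue), colnames(expr))
    if (length(ns) < 2) stop("need >= 2 ", tissue, " samples for within-group distances")
    idx <- utils::combn(ns, 2)
    pairs <- data.frame(sample1 = idx[1, ], sample2 = idx[2, ],
                        stringsAsFactors = FALSE)
  } else {
    roles <- strsplit(sub("^matched-", "", pair_spec), "-")[[1]]
    a <- pick(roles[1]); b <- pick(roles[2])
    pats <- intersect(names(a), names(b))
    pats <- pats[a[pats] %in% colnames(expr) & b[pats] %in% colnames(expr)]
    if (!length(pats)) stop("no patient with the requested matched pair")
    pairs <- data.frame(sample1 = unname(a[pats]), sample2 = unname(b[pats]),
                        stringsAsFactors = FALSE)
  }
  pairs$distance <- vapply(seq_len(nrow(pairs)), function(i) {
    1 - cor(expr[, pairs$sample1[i]], expr[, pairs$sample2[i]],
            method = "spearman")
  }, numeric(1))
  structure(list(pair_spec = pair_spec, pairs = pairs,
                 mean_distance = mean(pairs$distance)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance_summary [%s]: %d pairs, mean distance %.4f\n",
              x$pair_spec, nrow(x$pairs), x$mean_distance))
  invisible(x)
}

#' Rank-sum comparison of two distance sets
#'
#' Two-sided Wilcoxon rank-sum test between the distance lists of two
#' [pairwise_distances()] summaries (exact when both groups have at most 10
#' untied values, tie-corrected normal approximation otherwise).
#'
#' @param a,b `distance_summary` objects (or numeric vectors).
#' @return List with `p_value`, `statistic`, and the two mean distances.
#' @export
compare_distance_sets <- function(a, b) {
  da <- if (inherits(a, "distance_summary")) a$pairs$distance else a
  db <- if (inherits(b, "distance_summary")) b$pairs$distance else b
  if (!length(da) || !length(db)) stop("empty distance set")
  ties <- anyDuplicated(c(da, db)) > 0
  exact <- length(da) <= 10 && length(db) <= 10 && !ties
  wt <- suppressWarnings(wilcox.test(da, db, exact = exact, correct = !exact))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       mean_a = mean(da), mean_b = mean(db))
}
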