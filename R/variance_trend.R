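#' Fit the mean-conditional variance trend from pooled normals
#'
#' Estimates \eqn{\sigma^2 | \mu}, the variance of one expression measurement
#' given its mean, from the adjacent-normal samples pooled across patients:
#' per gene, the mean and unbiased variance across normals are computed; genes
#' are sorted by mean and partitioned into `n_bins` equal-count bins; each
#' bin contributes (median of gene means, aggregate of gene variances) as one
#' knot of a piecewise-linear trend, constant beyond the outer knots.
#'
#' Bin variances are aggregated by the mean by default: at 19 replicates a
#' per-gene variance is distributed ~\eqn{\sigma^2 \chi^2_{18}/18}, whose
#' median sits ~4\% below \eqn{\sigma^2}, so a median-aggregated trend is
#' biased low and noisier; `aggregate = "median"` is available when the
#' normal pool is suspected to contain strong outlier genes.
#'
#' Patient-to-patient differences are deliberately not removed first: the
#' inter-normal variation is the reference scale of the test, which makes the
#' per-patient z conservative when biological patient effects are present.
#'
#' @param normals Expression matrix (genes x normal samples), log2 scale; at
#'   least 3 columns.
#' @param n_bins Number of equal-count bins (default 50); must be smaller
#'   than the number of genes.
#' @param variance_floor Lower bound applied to every bin variance (and to
#'   every evaluation), preventing infinite z-scores. Default 1e-4.
#' @param aggregate "mean" (default) or "median" bin aggregation.
#' @return Object of class `variance_trend`: list with `bin_centers`,
#'   `bin_variances`, `variance_floor`, `n_genes`, `n_samples`.
#' @seealso [eval_variance()]
#' @export
fit_variance_trend <- function(normals, n_bins = 50, variance_floor = 1e-4,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else median
  if (ncol(normals) < 3) {
    stop("insufficient replicates: need >= 3 normal samples, got ",
         ncol(normals))
  }
  stopifnot(n_bins >= 1, variance_floor > 0)
  n <- nrow(normals)
  if (n_bins >= n && n > 1) stop("n_bins must be smaller than the number of genes")
  mu <- rowMeans(normals)
  v <- rowSums((normals - mu)^2) / (ncol(normals) - 1)

  if (diff(range(mu)) < .Machine$double.eps^0.5) n_bins <- 1L
  o <- order(mu)
  bin <- ceiling(seq_len(n) * n_bins / n)   # equal-count bins over sorted genes
  centers <- tapply(mu[o], bin, median)
  vars <- tapply(v[o], bin, agg)
  # merge bins whose centers coincide (heavy ties in means)
  centers_u <- unique(centers)
  if (length(centers_u) < length(centers)) {
    vars <- tapply(vars, match(centers, centers_u), agg)
    centers <- centers_u
  }
  structure(
    list(
      bin_centers = as.numeric(centers),
      bin_variances = pmax(as.numeric(vars), variance_floor),
      variance_floor = variance_floor,
      n_genes = n, n_samples = ncol(normals)
    ),
    class = "variance_trend"
  )
}

#' Evaluate the variance trend at given means
#'
#' Linear interpolation between bin centers, clamped to the boundary bin
#' value outside the fitted range; never below the variance floor.
#'
#' @param trend A [fit_variance_trend()] object.
#' @param mu Numeric vector of mean expression values (log2 scale).
#' @return Positive variances, same length as `mu`.
#' @export
eval_variance <- function(trend, mu) {
  stopifnot(inherits(trend, "variance_trend"))
  if (any(!is.finite(mu))) stop("non-finite mean passed to eval_variance")
  out <- if (length(trend$bin_centers) == 1L) {
    rep(trend$bin_variances, length(mu))
  } else {
    approx(trend$bin_centers, trend$bin_variances, xout = mu, rule = 2)$y
  }
  pmax(out, trend$variance_floor)
}

#' @export
print.variance_trend <- function(x, ...) {
  cat(sprintf(
    "variance_trend: %d bins from %d genes x %d normals; sigma^2 in [%.3g, %.3g], floor %.1g\n",
    length(x$bin_centers), x$n_genes, x$n_samples,
    min(x$bin_variances), max(x$bin_variances), x$variance_floor
  ))
  invisible(x)
}

#' Serialize / read a fitted variance trend as TSV
#'
#' Two columns (bin_center, bin_variance) preceded by a
#' `# variance_floor=` header line.
#'
#' @param trend A `variance_trend` object.
#' @param path File path.
#' @return Invisibly `path` / the re-read `variance_trend`.
#' @export
write_variance_trend <- function(trend, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variance_floor=%.17g", trend$variance_floor), con)
  write.table(
    data.frame(bin_center = trend$bin_centers,
               bin_variance = trend$bin_variances),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_variance_trend
#' @export
read_variance_trend <- function(path) {
  first <- readLines(path, n = 1)
  floor_val <- as.numeric(sub("^# variance_floor=", "", first))
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  structure(
    list(bin_centers = df$bin_center, bin_variances = df$bin_variance,
         variance_floor = floor_val, n_genes = NA_integer_,
         n_samples = NA_integer_),
    class = "variance_trend"
  )
}
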