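#' Flag probes lying in strand-aware promoter windows
#'
#' A probe is in the promoter of its assigned gene when it lies within
#' TSS-1500 to TSS+500 (inclusive) on the gene's strand; for minus-strand
#' genes "upstream 1500" sits at larger coordinates. Implemented with
#' `GenomicRanges::promoters()`.
#'
#' @param probes Probe annotation data.frame (probe_id, chrom, pos, strand,
#'   gene_id; pos 1-based).
#' @param genes Gene annotation data.frame (0-based half-open start/end,
#'   strand).
#' @param upstream,downstream Window extent around the TSS in bp.
#' @return The probe data.frame with a logical `in_promoter` column.
#' @export
annotate_promoter_probes <- function(probes, genes,
                                     upstream = 1500, downstream = 500) {
  gr <- GRanges(
    genes$chrom,
    IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  # promoters(): [TSS-upstream, TSS+downstream-1]; +1 makes TSS+downstream inclusive
  prom <- suppressWarnings(promoters(gr, upstream = upstream,
                                     downstream = downstream + 1L))
  idx <- match(probes$gene_id, genes$gene_id)
  if (anyNA(idx)) {
    stop("probe assigned to unknown gene: ",
         probes$gene_id[which(is.na(idx))[1]])
  }
  probes$in_promoter <-
    probes$chrom == genes$chrom[idx] &
    probes$pos >= GenomicRanges::start(prom)[idx] &
    probes$pos <= GenomicRanges::end(prom)[idx]
  probes
}

#' Gene-level copy number from segmentation profiles
#'
#' Each gene's value per sample is the length-weighted mean of the segment
#' means overlapping its body; genes overlapping no segment are NA (flagged
#' missing). Discretization (inclusive at the boundaries): |value| >=
#' `threshold_single` gives state +/-1, |value| >= `threshold_double` gives
#' +/-2, else 0.
#'
#' @param segments SEG-style data.frame (Sample, Chromosome, Start, End,
#'   Num_Probes, Segment_Mean; 1-based inclusive).
#' @param genes Gene annotation data.frame (0-based half-open).
#' @param threshold_single,threshold_double Discretization cutoffs on the
#'   log2 ratio (defaults 0.2 and 1.0).
#' @return List of class `gene_cnv` with matrices `log2ratio` and `state`
#'   (genes x samples).
#' @export
map_genes_to_cnv <- function(segments, genes,
                             threshold_single = 0.2, threshold_double = 1.0) {
  samples <- unique(segments$Sample)
  ggr <- GRanges(genes$chrom, IRanges(genes$start + 1L, genes$end))
  vals <- matrix(NA_real_, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$Sample == s, , drop = FALSE]
    sgr <- GRanges(seg$Chromosome, IRanges(seg$Start, seg$End))
    hits <- findOverlaps(ggr, sgr)
    if (!length(hits)) next
    w <- width(pintersect(ggr[queryHits(hits)], sgr[subjectHits(hits)]))
    num <- tapply(w * seg$Segment_Mean[subjectHits(hits)], queryHits(hits), sum)
    den <- tapply(w, queryHits(hits), sum)
    vals[as.integer(names(num)), s] <- num / den
  }
  state <- sign(vals) * ((abs(vals) >= threshold_single) +
                         (abs(vals) >= threshold_double))
  structure(list(log2ratio = vals, state = state), class = "gene_cnv")
}

#' Call hypermethylated promoters from paired beta values
#'
#' Per promoter probe, the paired tumor-minus-normal beta difference across
#' patients and a paired t-test p-value, BH-adjusted across all promoter
#' probes; a gene is flagged hypermethylated when at least `min_probes`
#' probes satisfy q < `q_cut` and mean difference > `delta_cut`. Probes with
#' fewer than 3 complete pairs are excluded. The paired t-test stands in for
#' array-specific differential-methylation engines; the calling rule
#' (q-value and beta-difference thresholds on >= 2 promoter probes) is the
#' screen's contract.
#'
#' @param beta Beta matrix (probes x samples).
#' @param probes Probe annotation with `in_promoter` (see
#'   [annotate_promoter_probes()]); probes without the column are all treated
#'   as promoter probes.
#' @param sheet Sample sheet; pairs are patients with both a normal and a
#'   primary sample.
#' @param q_cut,delta_cut,min_probes Calling thresholds (defaults 1e-4, 0.2,
#'   2).
#' @return List with `genes` (character vector of flagged genes) and
#'   `probe_stats` (probe_id, gene_id, delta_beta, p, q, qualifies).
#' @export
call_hypermethylated_promoters <- function(beta, probes, sheet,
                                           q_cut = 1e-4, delta_cut = 0.2,
                                           min_probes = 2) {
  if (is.null(probes$in_promoter)) probes$in_promoter <- TRUE
  probes <- probes[probes$in_promoter & probes$probe_id %in% rownames(beta), ,
                   drop = FALSE]
  pats <- intersect(
    sheet$patient_id[sheet$tissue == "normal"],
    sheet$patient_id[sheet$tissue == "primary"]
  )
  ns <- sheet$sample_id[match(paste(pats, "normal"),
                              paste(sheet$patient_id, sheet$tissue))]
  ts <- sheet$sample_id[match(paste(pats, "primary"),
                              paste(sheet$patient_id, sheet$tissue))]
  dmat <- beta[probes$probe_id, ts, drop = FALSE] -
    beta[probes$probe_id, ns, drop = FALSE]

  npair <- rowSums(!is.na(dmat))
  ok <- npair >= 3
  if (any(!ok)) {
    message(sum(!ok), " probe(s) excluded with < 3 complete pairs")
  }
  delta <- rowMeans(dmat, na.rm = TRUE)
  sdv <- apply(dmat, 1L, sd, na.rm = TRUE)
  tstat <- delta / (sdv / sqrt(npair))
  p <- 2 * pt(-abs(tstat), npair - 1)
  p[sdv == 0 & delta == 0] <- 1          # identical pairs: no evidence
  p[sdv == 0 & delta != 0] <- 0          # constant nonzero shift
  p[!ok] <- NA
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  qualifies <- !is.na(q) & q < q_cut & delta > delta_cut
  stats <- data.frame(
    probe_id = probes$probe_id, gene_id = probes$gene_id,
    n_pairs = npair, delta_beta = delta, p = p, q = q,
    qualifies = qualifies, stringsAsFactors = FALSE
  )
  hits <- tapply(qualifies, probes$gene_id, sum)
  list(genes = sort(names(hits)[hits >= min_probes]), probe_stats = stats)
}

# One-sided Spearman correlation p-value: exact null distribution for small
# tie-free samples, t-approximation otherwise.
.spearman_one_sided <- function(x, y, side) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) return(c(rho = NA_real_, p = NA_real_, n = n))
  if (sd(x) == 0 || sd(y) == 0) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    alt <- if (side == "positive") "greater" else "less"
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE,
               alternative = alt)$p.value)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- pt(tt, n - 2, lower.tail = (side == "negative"))
  }
  c(rho = rho, p = p, n = n)
}

#' Spearman screen for candidate driver genes
#'
#' Correlates each gene's expression with a molecular covariate across tumor
#' samples: gene-level copy number (positive side) or promoter-probe beta
#' values (negative side). A gene is a candidate when its correlation passes
#' `rho_cut` on the required side with one-sided p < `p_cut`; with a
#' probe-level covariate a gene qualifies on its best promoter probe.
#' Genes with a constant covariate or fewer than 5 complete observations are
#' excluded (NA rho).
#'
#' @param expr Expression matrix (genes x samples), log2 scale.
#' @param covariate Matrix; rows are genes (when `feature_map` is NULL) or
#'   probes/features otherwise; columns are samples.
#' @param feature_map Optional data.frame (feature_id, gene_id) mapping
#'   covariate rows to genes (e.g. promoter probes).
#' @param side "positive" (copy number) or "negative" (methylation).
#' @param rho_cut Correlation magnitude cutoff (default 0.4).
#' @param p_cut One-sided p cutoff (default 0.05).
#' @param samples Sample ids used for the correlation; default the columns
#'   shared by `expr` and `covariate` (in the pipeline, the tumor samples).
#' @return data.frame (gene_id, rho, p_one_sided, n, best_feature,
#'   candidate), one row per screened gene.
#' @export
spearman_screen <- function(expr, covariate, feature_map = NULL,
                            side = c("positive", "negative"),
                            rho_cut = 0.4, p_cut = 0.05,
                            samples = intersect(colnames(expr),
                                                colnames(covariate))) {
  side <- match.arg(side)
  if (length(samples) < 5) stop("need >= 5 shared samples for the screen")
  e <- expr[, samples, drop = FALSE]
  cv <- covariate[, samples, drop = FALSE]

  if (is.null(feature_map)) {
    feature_map <- data.frame(feature_id = rownames(cv),
                              gene_id = rownames(cv),
                              stringsAsFactors = FALSE)
  }
  feature_map <- feature_map[feature_map$gene_id %in% rownames(e) &
                             feature_map$feature_id %in% rownames(cv), ,
                             drop = FALSE]
  res <- t(vapply(seq_len(nrow(feature_map)), function(i) {
    .spearman_one_sided(e[feature_map$gene_id[i], ],
                        cv[feature_map$feature_id[i], ], side)
  }, c(rho = 0, p = 0, n = 0)))

  sel <- if (side == "positive") function(r) which.max(r) else function(r) which.min(r)
  out <- do.call(rbind, lapply(split(seq_len(nrow(feature_map)),
                                     feature_map$gene_id), function(ii) {
    rho <- res[ii, "rho"]
    if (all(is.na(rho))) {
      return(data.frame(gene_id = feature_map$gene_id[ii[1]],
                        rho = NA_real_, p_one_sided = NA_real_,
                        n = max(res[ii, "n"]), best_feature = NA_character_,
                        candidate = FALSE, stringsAsFactors = FALSE))
    }
    best <- ii[!is.na(rho)][sel(rho[!is.na(rho)])]
    passes <- if (side == "positive") {
      res[best, "rho"] > rho_cut
    } else {
      res[best, "rho"] < -rho_cut
    }
    data.frame(
      gene_id = feature_map$gene_id[ii[1]],
      rho = res[best, "rho"], p_one_sided = res[best, "p"],
      n = res[best, "n"],
      best_feature = feature_map$feature_id[best],
      candidate = passes && res[best, "p"] < p_cut,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  nex <- sum(is.na(out$rho))
  if (nex) message(nex, " gene(s) excluded (constant covariate or too few observations)")
  out
}

#' Second-order independence of copy-number and methylation drivers
#'
#' Spearman correlation between the per-gene CNV-expression and
#' methylation-expression correlation vectors, plus a Fisher exact test on
#' the 2x2 overlap of the two candidate sets within a shared gene universe.
#'
#' @param cnv_rho,meth_rho Named numeric vectors of per-gene correlations.
#' @param cnv_set,meth_set Character vectors of candidate gene ids.
#' @param universe Character vector, the shared gene universe.
#' @return List with `rho_of_rhos`, `fisher_p`, `overlap`, `table`.
#' @export
second_order_independence <- function(cnv_rho, meth_rho, cnv_set, meth_set,
                                      universe) {
  if (!length(universe)) stop("empty gene universe")
  a <- cnv_rho[universe]
  b <- meth_rho[universe]
  rho2 <- cor(a, b, method = "spearman", use = "pairwise.complete.obs")
  in_a <- universe %in% cnv_set
  in_b <- universe %in% meth_set
  tab <- table(cnv = factor(in_a, c(TRUE, FALSE)),
               meth = factor(in_b, c(TRUE, FALSE)))
  list(rho_of_rhos = rho2,
       fisher_p = fisher.test(tab)$p.value,
       overlap = sum(in_a & in_b),
       table = tab)
}

#' Chromosome-arm enrichment of a candidate gene set
#'
#' For each arm, with x candidates of n on an arm holding a fraction p0 of
#' the universe, reports the enrichment tail P(X >= x) and the depletion tail
#' P(X <= x) of Binomial(n, p0), plus the fold x/(n p0).
#'
#' @param candidates Character vector of candidate gene ids (subset of the
#'   universe).
#' @param gene_to_arm Named character vector gene_id -> arm covering the
#'   universe.
#' @param universe Character vector of universe gene ids.
#' @return data.frame (arm, n_candidates, n_universe, fold, p_enrichment,
#'   p_depletion, direction), one row per arm present in the universe.
#' @export
arm_enrichment <- function(candidates, gene_to_arm, universe) {
  if (!all(candidates %in% universe)) {
    stop("candidates must be a subset of the universe")
  }
  miss <- universe[!universe %in% names(gene_to_arm) |
                     is.na(gene_to_arm[universe])]
  if (length(miss)) {
    message(length(miss), " universe gene(s) without an arm skipped")
    universe <- setdiff(universe, miss)
    candidates <- setdiff(candidates, miss)
  }
  arms <- sort(unique(gene_to_arm[universe]))
  n <- length(candidates)
  do.call(rbind, lapply(arms, function(a) {
    on_arm <- universe[gene_to_arm[universe] == a]
    x <- sum(candidates %in% on_arm)
    p0 <- length(on_arm) / length(universe)
    fold <- if (n > 0) (x / n) / p0 else NA_real_
    data.frame(
      arm = a, n_candidates = x, n_universe = length(on_arm), fold = fold,
      p_enrichment = pbinom(x - 1, n, p0, lower.tail = FALSE),
      p_depletion = pbinom(x, n, p0),
      direction = ifelse(is.na(fold) | fold == 1, "proportional",
                         ifelse(fold > 1, "enriched", "depleted")),
      stringsAsFactors = FALSE
    )
  }))
}
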