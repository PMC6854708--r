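#' Arm-level copy-number calls and cohort recurrence
#'
#' Per sample and arm, the length-weighted mean of overlapping segment means
#' and the fraction of the arm covered by gained (resp. lost) segments; a
#' gain is called when the weighted mean is >= `call_threshold` and gained
#' segments cover >= `min_fraction` of the arm (loss symmetric). Arms with no
#' covered base in a sample are neutral. Cohort-level: gain/loss frequency
#' across samples and a z-score standardizing the cohort mean arm log2 ratio
#' by the genome-wide SD of sample-arm means over sqrt(n samples). An arm is
#' flagged recurrent when frequency >= 0.5 and |z| >= 1.5 with matching sign.
#'
#' @param segments SEG-style data.frame covering the cohort (column Sample).
#' @param arms Arm coordinate table (arm, chrom, start, end; 1-based
#'   inclusive).
#' @param call_threshold Gain/loss cutoff on the weighted mean log2 ratio
#'   (default 0.1).
#' @param min_fraction Minimum covered-arm fraction supporting the call
#'   (default 0.5).
#' @param freq_cut,z_cut Recurrence cutoffs (defaults 0.5 and 1.5).
#' @return List with `sample_calls` (sample, arm, weighted mean, covered and
#'   gained/lost fractions, call) and `arm_summary` (arm, mean, z,
#'   freq_gain, freq_loss, recurrent).
#' @export
arm_level_calls <- function(segments, arms, call_threshold = 0.1,
                            min_fraction = 0.5, freq_cut = 0.5, z_cut = 1.5) {
  samples <- unique(segments$Sample)
  agr <- GRanges(arms$chrom, IRanges(arms$start, arms$end))
  arm_len <- as.numeric(arms$end - arms$start + 1)
  rows <- list()
  for (s in samples) {
    seg <- segments[segments$Sample == s, , drop = FALSE]
    sgr <- GRanges(seg$Chromosome, IRanges(seg$Start, seg$End))
    hits <- findOverlaps(agr, sgr)
    w <- width(pintersect(agr[queryHits(hits)], sgr[subjectHits(hits)]))
    mean_hit <- seg$Segment_Mean[subjectHits(hits)]
    qh <- factor(queryHits(hits), levels = seq_len(nrow(arms)))
    wsum <- as.numeric(tapply(w, qh, sum, default = 0))
    wmean <- as.numeric(tapply(w * mean_hit, qh, sum, default = 0)) / wsum
    gain_cov <- as.numeric(tapply(w * (mean_hit >= call_threshold), qh, sum,
                                  default = 0)) / arm_len
    loss_cov <- as.numeric(tapply(w * (mean_hit <= -call_threshold), qh, sum,
                                  default = 0)) / arm_len
    covered <- wsum / arm_len
    call <- ifelse(
      is.na(wmean) | wsum == 0, "neutral",
      ifelse(wmean >= call_threshold & gain_cov >= min_fraction, "gain",
             ifelse(wmean <= -call_threshold & loss_cov >= min_fraction,
                    "loss", "neutral")))
    if (any(wsum == 0)) {
      message("sample ", s, ": arm(s) with no covered base set neutral: ",
              paste(arms$arm[wsum == 0], collapse = ", "))
    }
    rows[[s]] <- data.frame(
      sample = s, arm = arms$arm, weighted_mean = ifelse(wsum == 0, NA, wmean),
      covered_fraction = covered, gain_fraction = gain_cov,
      loss_fraction = loss_cov, call = call, stringsAsFactors = FALSE
    )
  }
  sc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  genome_sd <- sd(sc$weighted_mean, na.rm = TRUE)
  n_samp <- length(samples)
  summ <- do.call(rbind, lapply(arms$arm, function(a) {
    sub <- sc[sc$arm == a, , drop = FALSE]
    m <- mean(sub$weighted_mean, na.rm = TRUE)
    z <- if (is.na(m) || m == 0) 0
         else if (is.na(genome_sd) || genome_sd == 0) Inf * sign(m)
         else m / (genome_sd / sqrt(n_samp))
    fg <- mean(sub$call == "gain")
    fl <- mean(sub$call == "loss")
    data.frame(
      arm = a, mean_log2ratio = m, z = z, freq_gain = fg, freq_loss = fl,
      recurrent = ifelse(fg >= freq_cut & z >= z_cut, "gain",
                         ifelse(fl >= freq_cut & z <= -z_cut, "loss", "none")),
      stringsAsFactors = FALSE
    )
  }))
  list(sample_calls = sc, arm_summary = summ)
}

#' Compare a focal-event frequency between two cohorts
#'
#' Odds ratio and two-sided Fisher exact p (probability-mass convention: sum
#' of all tables with the fixed margins whose probability does not exceed the
#' observed table's) for k1/n1 versus k2/n2 affected samples.
#'
#' @param k1,n1 Affected and total samples in cohort 1.
#' @param k2,n2 Affected and total samples in cohort 2.
#' @return List with `odds_ratio` (sample odds ratio; Inf/0 with empty
#'   cells, NaN if doubly degenerate), `p_value`, and `table`.
#' @examples
#' focal_frequency_compare(7, 19, 55, 375)$p_value  # 0.018
#' @export
focal_frequency_compare <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (n1 == 0 || n2 == 0) stop("cohort sizes must be positive")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2,
                dimnames = list(c("affected", "unaffected"),
                                c("cohort1", "cohort2")))
  list(
    odds_ratio = (k1 * (n2 - k2)) / ((n1 - k1) * k2),
    p_value = fisher.test(tab)$p.value,
    table = tab
  )
}
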