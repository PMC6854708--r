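#' Count cross-patient recurrence of individualized DE calls
#'
#' For each gene, `freq` is the number of patients in which it was called;
#' `n_up`/`n_down` split that count by direction (PVTT-relative), and
#' `majority_direction` is the larger of the two ("mixed" on a tie). With
#' `direction_consistent = TRUE` the recurrence frequency counts only the
#' dominant direction, i.e. `freq = max(n_up, n_down)`.
#'
#' @param de DETable from [run_idaseq()].
#' @param direction_consistent Require a shared direction when counting
#'   recurrence (default FALSE: any call counts).
#' @return data.frame with gene_id, freq, n_up, n_down, majority_direction,
#'   covering every gene in `de`.
#' @export
recurrence_counts <- function(de, direction_consistent = FALSE) {
  genes <- unique(de$gene_id)
  gidx <- factor(de$gene_id, levels = genes)
  called <- de$call
  n_up <- tapply(called & de$direction %in% "up", gidx, sum)
  n_down <- tapply(called & de$direction %in% "down", gidx, sum)
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  freq <- if (direction_consistent) pmax(n_up, n_down) else n_up + n_down
  data.frame(
    gene_id = genes,
    freq = freq,
    n_up = n_up,
    n_down = n_down,
    majority_direction = ifelse(
      n_up + n_down == 0, NA_character_,
      ifelse(n_up > n_down, "up", ifelse(n_down > n_up, "down", "mixed"))),
    stringsAsFactors = FALSE
  )
}

#' One-sided permutation FDR for recurrently called genes
#'
#' Null model: within each patient, the indicator vector of calls is shuffled
#' across genes (preserving that patient's number of calls — the dominant
#' nuisance, since call counts vary by orders of magnitude between patients —
#' while destroying gene identity). For each recurrence threshold k,
#' \deqn{FDR(k) = \min(1,\; \bar N_{null}(k) / \max(N_{obs}(k), 1))}
#' where \eqn{N(k)} counts genes with freq >= k. Estimates are made
#' non-increasing in k by a cumulative minimum. Thresholds never reached by
#' any permutation are reported as the upper bound \eqn{1/(B\,N_{obs}(k))}
#' and flagged; thresholds with no observed gene are NA.
#'
#' @param de DETable from [run_idaseq()].
#' @param B Number of permutations, at least 100 (default 1000).
#' @param seed Integer seed; results are deterministic given (de, B, seed).
#' @param direction_consistent Passed to [recurrence_counts()]; under this
#'   mode the shuffled calls keep their directions and the null frequency is
#'   the dominant-direction count.
#' @return List of class `permutation_fdr` with `fdr_table` (k, n_obs,
#'   mean_null, sd_null, fdr, upper_bound), `recurrence` (the
#'   [recurrence_counts()] table with an `fdr_at_freq` column), `B`, `seed`.
#' @export
permutation_fdr <- function(de, B = 1000, seed = 1,
                            direction_consistent = FALSE) {
  if (B < 100) stop("B must be >= 100 for a stable FDR estimate")
  rec <- recurrence_counts(de, direction_consistent)
  m <- nrow(rec)
  patients <- unique(de$patient_id)
  J <- length(patients)
  calls_up <- calls_down <- integer(J)
  for (j in seq_len(J)) {
    sub <- de[de$patient_id == patients[j] & de$call, , drop = FALSE]
    calls_up[j] <- sum(sub$direction %in% "up")
    calls_down[j] <- sum(sub$direction %in% "down")
  }

  n_obs <- vapply(seq_len(J), function(k) sum(rec$freq >= k), integer(1))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Nmat <- matrix(0L, B, J)
  for (b in seq_len(B)) {
    fu <- fd <- integer(m)
    for (j in seq_len(J)) {
      cj <- calls_up[j] + calls_down[j]
      if (cj == 0) next
      idx <- sample.int(m, cj)
      if (calls_up[j] > 0) {
        u <- idx[seq_len(calls_up[j])]
        fu[u] <- fu[u] + 1L
      }
      if (calls_down[j] > 0) {
        dn <- idx[calls_up[j] + seq_len(calls_down[j])]
        fd[dn] <- fd[dn] + 1L
      }
    }
    fr <- if (direction_consistent) pmax(fu, fd) else fu + fd
    tab <- tabulate(fr, nbins = J)
    Nmat[b, ] <- rev(cumsum(rev(tab)))
  }
  mean_null <- colMeans(Nmat)
  sd_null <- apply(Nmat, 2L, sd)

  fdr <- ifelse(n_obs == 0, NA_real_, pmin(1, mean_null / pmax(n_obs, 1)))
  upper <- n_obs > 0 & mean_null == 0
  fdr[upper] <- 1 / (B * n_obs[upper])
  ok <- !is.na(fdr)
  fdr[ok] <- cummin(fdr[ok])   # enforce monotone non-increase in k

  tab <- data.frame(k = seq_len(J), n_obs = n_obs, mean_null = mean_null,
                    sd_null = sd_null, fdr = fdr, upper_bound = upper)
  rec$fdr_at_freq <- ifelse(rec$freq >= 1,
                            fdr[pmax(pmin(rec$freq, J), 1L)], NA_real_)
  structure(list(fdr_table = tab, recurrence = rec, B = B, seed = seed),
            class = "permutation_fdr")
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat(sprintf("permutation_fdr: %d permutations over %d patients\n",
              x$B, nrow(x$fdr_table)))
  print(x$fdr_table[x$fdr_table$n_obs > 0, ], row.names = FALSE)
  invisible(x)
}
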