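#' Deterministic gene coordinate annotation for a simulated genome
#'
#' Lays the configured number of genes along 22 autosomes in contiguous
#' blocks, 100 kb apart and 20 kb wide, with random strands. Coordinates are
#' BED-style 0-based half-open. Chromosome lengths are attached as an
#' attribute so arm tables can be derived.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (1-based TSS position), plus attribute `chrom_lengths`.
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  streams <- .sim_streams(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(streams[["annotation"]])

  n <- config$n_genes
  n_chrom <- min(22L, n)
  chrom_of <- sort(rep_len(seq_len(n_chrom), n))
  idx_on_chrom <- sequence(tabulate(chrom_of))
  start <- (idx_on_chrom - 1L) * 100000L + 10000L   # 0-based
  end <- start + 20000L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = paste0("chr", chrom_of),
    start = start,
    end = end,
    strand = strand,
    tss = ifelse(strand == "+", start + 1L, end),
    stringsAsFactors = FALSE
  )
  lens <- vapply(split(genes$end, genes$chrom), max, numeric(1)) + 100000
  attr(genes, "chrom_lengths") <- lens[unique(genes$chrom)]
  genes
}

#' Chromosome-arm coordinate table for an annotation
#'
#' Splits each chromosome at 40% of its length into a p and a q arm
#' (1-based inclusive coordinates).
#'
#' @param genes Gene annotation from [simulate_gene_annotation()] (or any
#'   data.frame with a `chrom_lengths` attribute / supplied via `lengths`).
#' @param lengths Optional named vector of chromosome lengths overriding the
#'   attribute.
#' @param centromere_fraction Fractional position of the p/q boundary.
#' @return data.frame with columns `arm`, `chrom`, `start`, `end`.
#' @export
arm_table_from_annotation <- function(genes, lengths = NULL,
                                      centromere_fraction = 0.4) {
  if (is.null(lengths)) lengths <- attr(genes, "chrom_lengths")
  stopifnot(!is.null(lengths), !is.null(names(lengths)))
  cen <- floor(lengths * centromere_fraction)
  data.frame(
    arm = c(paste0(sub("^chr", "", names(lengths)), "p"),
            paste0(sub("^chr", "", names(lengths)), "q")),
    chrom = rep(names(lengths), 2L),
    start = c(rep(1, length(lengths)), cen + 1),
    end = c(cen, lengths),
    stringsAsFactors = FALSE
  )[order(rep(seq_along(lengths), 2L)), ]
}

#' Assign genes to chromosome arms
#'
#' Each gene is assigned by the arm containing its midpoint.
#'
#' @param genes Gene annotation data.frame (0-based half-open `start`/`end`).
#' @param arms Arm table as from [arm_table_from_annotation()].
#' @return Named character vector, gene_id -> arm.
#' @export
assign_arms <- function(genes, arms) {
  mid <- floor((genes$start + genes$end) / 2) + 1   # 1-based midpoint
  out <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(arms))) {
    hit <- genes$chrom == arms$chrom[i] & mid >= arms$start[i] & mid <= arms$end[i]
    out[hit] <- arms$arm[i]
  }
  setNames(out, genes$gene_id)
}

.make_sample_sheet <- function(config) {
  pid <- sprintf("P%02d", seq_len(config$n_patients))
  data.frame(
    sample_id = as.vector(t(outer(pid, c("_N", "_T", "_V"), paste0))),
    patient_id = rep(pid, each = 3L),
    tissue = rep(c("normal", "primary", "pvtt"), times = config$n_patients),
    stringsAsFactors = FALSE
  )
}

#' Simulate a matched-trio RNA-seq cohort with ground truth
#'
#' Draws gene-level counts for `n_patients` matched trios from a negative
#' binomial with mean \eqn{s_k \cdot 2^{g_i + a_{ij} + \Delta_{ijk}}} and
#' dispersion \eqn{\phi(\mu) = a/\mu + b}: \eqn{g_i} is the gene baseline,
#' \eqn{a_{ij}} a patient-specific profile shared by all three samples of
#' patient j, and \eqn{\Delta} collects the planted effects (tumor-vs-normal
#' on both tumor samples; progressive on the pvtt only; copy-number dosage
#' and methylation silencing on each tumor sample). The library factor
#' \eqn{s_k} scales each sample to its drawn expected depth.
#'
#' All randomness derives from `config$seed`; identical configs give
#' identical output. Configurations whose planted blocks would need more
#' distinct genes than exist are rejected (blocks are assigned disjoint gene
#' sets, so no (gene, patient) ever receives conflicting signs).
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (integer-valued matrix, genes x
#'   samples), `samples` (sample sheet data.frame: sample_id, patient_id,
#'   tissue), `truth` (data.frame gene_id, patient_id, effect_kind,
#'   effect_size; cohort-wide effects carry `patient_id = NA`; latent
#'   per-sample copy states and promoter beta shifts are attached as
#'   attributes `cnv_states` and `meth_delta_beta`), and `genes` (coordinate
#'   annotation).
#' @examples
#' sim <- simulate_trio_cohort(sim_config(n_genes = 200, n_patients = 4))
#' dim(sim$counts)
#' @export
simulate_trio_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  streams <- .sim_streams(config)
  genes <- simulate_gene_annotation(config)
  sheet <- .make_sample_sheet(config)
  n <- config$n_genes
  J <- config$n_patients
  tumor_samples <- sheet$sample_id[sheet$tissue != "normal"]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  ## ---- effect layout (its own stream) ----
  set.seed(streams[["effects"]])
  g0 <- rnorm(n, config$baseline_logmean[["location"]],
              config$baseline_logmean[["scale"]])
  A <- matrix(rnorm(n * J, 0, config$patient_effect_sd), n, J)

  truth <- list()
  tumor_lfc <- numeric(n)
  n_tum <- round(config$tumor_effect$fraction * n)
  if (n_tum > 0) {
    idx <- sample.int(n, n_tum)
    tumor_lfc[idx] <- rnorm(n_tum, 0, config$tumor_effect$lfc_sd)
    truth$tumor <- data.frame(
      gene_id = genes$gene_id[idx], patient_id = NA_character_,
      effect_kind = "tumor", effect_size = tumor_lfc[idx],
      stringsAsFactors = FALSE
    )
  }

  # Progressive blocks + recurrent genes draw from a shared pool of unused
  # genes so no (gene, patient) pair can receive two conflicting effects.
  avail <- seq_len(n)
  take <- function(k) {
    if (k > length(avail)) {
      stop("planted-effect blocks request more distinct genes than available; ",
           "overlapping blocks with conflicting signs are not allowed")
    }
    picked <- if (length(avail) == 1L) avail[seq_len(k)] else sample(avail, k)
    avail <<- setdiff(avail, picked)
    picked
  }
  prog <- matrix(0, n, J)  # log2 shift applied to the pvtt sample
  prog_rows <- list()
  for (blk in config$progressive_effect) {
    nb <- round(blk$gene_fraction * n)
    if (nb == 0) next
    gi <- take(nb)
    pj <- sample.int(J, blk$n_patients)
    sgn <- switch(blk$sign,
                  up = rep(1, nb), down = rep(-1, nb),
                  both = sample(c(-1, 1), nb, replace = TRUE))
    prog[gi, pj] <- prog[gi, pj] + sgn * blk$lfc
    prog_rows[[length(prog_rows) + 1L]] <- data.frame(
      gene_id = rep(genes$gene_id[gi], times = length(pj)),
      patient_id = rep(sprintf("P%02d", pj), each = nb),
      effect_kind = "progressive",
      effect_size = rep(sgn * blk$lfc, times = length(pj)),
      stringsAsFactors = FALSE
    )
  }
  if (config$n_recurrent_genes > 0) {
    gi <- take(config$n_recurrent_genes)
    for (ii in seq_along(gi)) {
      pj <- sample.int(J, config$recurrent_patients)
      sgn <- sample(c(-1, 1), 1L)
      prog[gi[ii], pj] <- prog[gi[ii], pj] + sgn * config$recurrent_lfc
      prog_rows[[length(prog_rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[gi[ii]],
        patient_id = sprintf("P%02d", sort(pj)),
        effect_kind = "progressive",
        effect_size = sgn * config$recurrent_lfc,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(prog_rows)) truth$progressive <- do.call(rbind, prog_rows)

  cnv_states <- NULL
  cnv_shift <- matrix(0, n, length(tumor_samples),
                      dimnames = list(genes$gene_id, tumor_samples))
  n_cnv <- round(config$cnv_driver_fraction * n)
  if (n_cnv > 0) {
    gi <- take(n_cnv)
    cnv_states <- matrix(
      sample(c(-1L, 0L, 1L, 2L), n_cnv * length(tumor_samples),
             replace = TRUE, prob = c(0.15, 0.30, 0.35, 0.20)),
      n_cnv, length(tumor_samples),
      dimnames = list(genes$gene_id[gi], tumor_samples)
    )
    cnv_shift[gi, ] <- config$dosage_slope * cnv_states
    truth$cnv <- data.frame(
      gene_id = genes$gene_id[gi], patient_id = NA_character_,
      effect_kind = "cnv_driver", effect_size = config$dosage_slope,
      stringsAsFactors = FALSE
    )
  }

  meth_delta <- NULL
  meth_shift <- matrix(0, n, length(tumor_samples),
                       dimnames = list(genes$gene_id, tumor_samples))
  n_meth <- round(config$meth_driver_fraction * n)
  if (n_meth > 0) {
    gi <- take(n_meth)
    meth_delta <- matrix(
      runif(n_meth * length(tumor_samples), 0.15, 0.55),
      n_meth, length(tumor_samples),
      dimnames = list(genes$gene_id[gi], tumor_samples)
    )
    meth_shift[gi, ] <- config$meth_slope * meth_delta
    truth$meth <- data.frame(
      gene_id = genes$gene_id[gi], patient_id = NA_character_,
      effect_kind = "meth_driver", effect_size = config$meth_slope,
      stringsAsFactors = FALSE
    )
  }

  ## ---- compose per-sample log2 means and draw counts (counts stream) ----
  log2mean <- matrix(0, n, nrow(sheet),
                     dimnames = list(genes$gene_id, sheet$sample_id))
  for (k in seq_len(nrow(sheet))) {
    j <- match(sheet$patient_id[k], sprintf("P%02d", seq_len(J)))
    m <- g0 + A[, j]
    if (sheet$tissue[k] != "normal") {
      m <- m + tumor_lfc +
        cnv_shift[, sheet$sample_id[k]] + meth_shift[, sheet$sample_id[k]]
      if (sheet$tissue[k] == "pvtt") m <- m + prog[, j]
    }
    log2mean[, k] <- m
  }

  set.seed(streams[["counts"]])
  lr <- log(config$library_size_range)
  libsize <- exp(runif(nrow(sheet), lr[1], lr[2]))
  rel <- 2^log2mean
  mu <- sweep(rel, 2L, libsize / colSums(rel), `*`)
  a <- config$dispersion_trend[["a"]]
  b <- config$dispersion_trend[["b"]]
  phi <- a / mu + b
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / phi),
    n, nrow(sheet), dimnames = dimnames(log2mean)
  )

  truth_df <- if (length(truth)) {
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_id = character(), patient_id = character(),
               effect_kind = character(), effect_size = numeric(),
               stringsAsFactors = FALSE)
  }
  key <- paste(truth_df$gene_id, truth_df$patient_id, truth_df$effect_kind)
  stopifnot(!anyDuplicated(key))
  attr(truth_df, "cnv_states") <- cnv_states
  attr(truth_df, "meth_delta_beta") <- meth_delta

  list(counts = counts, samples = sheet, truth = truth_df, genes = genes)
}

# Per-state segment-mean centers used when painting planted copy states into
# segmentation profiles.
.cnv_state_mean <- c(`-2` = -1.2, `-1` = -0.55, `0` = 0, `1` = 0.55, `2` = 1.2)

#' Simulate per-sample copy-number segmentation profiles
#'
#' Builds piecewise-constant segment profiles for every tumor sample
#' (primary and pvtt). Background arms get near-zero means with occasional
#' broad events, independent of expression; genes marked `cnv_driver` in the
#' truth table are carved into their own segments whose means encode the
#' copy states already planted in the expression, so planted dosage coupling
#' survives the SEG round trip.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_trio_cohort()] (carries the latent
#'   copy states).
#' @param genes Gene annotation; defaults to the config's own.
#' @return List with `segments` (data.frame: Sample, Chromosome, Start, End,
#'   Num_Probes, Segment_Mean; 1-based inclusive) and `gene_cnv`
#'   (gene-level summary from [map_genes_to_cnv()]).
#' @export
simulate_cnv_profiles <- function(config, truth,
                                  genes = simulate_gene_annotation(config)) {
  stopifnot(inherits(config, "sim_config"))
  streams <- .sim_streams(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(streams[["cnv"]])

  sheet <- .make_sample_sheet(config)
  tumor_samples <- sheet$sample_id[sheet$tissue != "normal"]
  states <- attr(truth, "cnv_states")
  arms <- arm_table_from_annotation(genes)
  chrom_len <- attr(genes, "chrom_lengths")

  rows <- list()
  for (s in tumor_samples) {
    # background mean per arm: mostly neutral, occasional broad event
    arm_mean <- rnorm(nrow(arms), 0, 0.05) +
      ifelse(runif(nrow(arms)) < 0.15, sample(c(-0.45, 0.45), nrow(arms), TRUE), 0)
    for (chrom in names(chrom_len)) {
      drv <- if (is.null(states)) character(0) else
        intersect(rownames(states), genes$gene_id[genes$chrom == chrom])
      gi <- genes[match(drv, genes$gene_id), , drop = FALSE]
      # 1-based inclusive driver intervals, padded 5 kb, sorted, guaranteed
      # disjoint by the 100 kb gene spacing
      dstart <- gi$start + 1L - 5000L
      dend <- gi$end + 5000L
      o <- order(dstart)
      dstart <- dstart[o]; dend <- dend[o]; drv <- drv[o]
      ai <- which(arms$chrom == chrom)
      for (a_row in ai) {
        lo <- arms$start[a_row]; hi <- arms$end[a_row]
        pos <- lo
        inside <- which(dstart <= hi & dend >= lo)
        for (d in inside) {
          s0 <- max(dstart[d], lo); e0 <- min(dend[d], hi)
          if (s0 > pos) {
            rows[[length(rows) + 1L]] <- data.frame(
              Sample = s, Chromosome = chrom, Start = pos, End = s0 - 1,
              Num_Probes = (s0 - pos) %/% 1000 + 2,
              Segment_Mean = arm_mean[a_row], stringsAsFactors = FALSE)
          }
          st <- states[drv[d], s]
          rows[[length(rows) + 1L]] <- data.frame(
            Sample = s, Chromosome = chrom, Start = s0, End = e0,
            Num_Probes = (e0 - s0 + 1) %/% 1000 + 2,
            Segment_Mean = .cnv_state_mean[as.character(st)] + rnorm(1, 0, 0.03),
            stringsAsFactors = FALSE)
          pos <- e0 + 1
        }
        if (pos <= hi) {
          rows[[length(rows) + 1L]] <- data.frame(
            Sample = s, Chromosome = chrom, Start = pos, End = hi,
            Num_Probes = (hi - pos + 1) %/% 1000 + 2,
            Segment_Mean = arm_mean[a_row], stringsAsFactors = FALSE)
        }
      }
    }
  }
  segments <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(segments = segments,
       gene_cnv = map_genes_to_cnv(segments, genes))
}

#' Simulate promoter methylation beta values
#'
#' Each gene receives `probes_per_gene` probes placed uniformly in its
#' strand-aware promoter window (TSS-1500 to TSS+500). Probe M-values are
#' Gaussian around a probe-specific baseline; beta values are the logistic
#' transform \eqn{\beta = 2^M / (1 + 2^M)}. Genes marked `meth_driver` have
#' all promoter probes shifted in tumor samples toward the planted
#' tumor-minus-normal beta difference (the same latent shifts already coupled,
#' negatively, into those genes' expression).
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_trio_cohort()].
#' @param genes Gene annotation; defaults to the config's own.
#' @return List with `beta` (probes x samples matrix in (0,1)) and `probes`
#'   (data.frame: probe_id, chrom, pos (1-based), strand, gene_id).
#' @export
simulate_methylation <- function(config, truth,
                                 genes = simulate_gene_annotation(config)) {
  stopifnot(inherits(config, "sim_config"))
  streams <- .sim_streams(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(streams[["meth"]])

  sheet <- .make_sample_sheet(config)
  k <- config$probes_per_gene
  n <- nrow(genes)
  off <- floor(runif(n * k, -1500, 501))   # offset from TSS, promoter window
  ori <- ifelse(genes$strand == "+", 1L, -1L)
  pos <- rep(genes$tss, each = k) + rep(ori, each = k) * off
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(n * k)),
    chrom = rep(genes$chrom, each = k),
    pos = pos,
    strand = rep(genes$strand, each = k),
    gene_id = rep(genes$gene_id, each = k),
    stringsAsFactors = FALSE
  )

  m0 <- rnorm(n * k, -2.5, 0.8)            # mostly unmethylated promoters
  M <- matrix(rep(m0, times = nrow(sheet)), n * k, nrow(sheet),
              dimnames = list(probes$probe_id, sheet$sample_id))
  delta <- attr(truth, "meth_delta_beta")
  if (!is.null(delta)) {
    beta0 <- m_to_beta(m0)
    for (s in colnames(delta)) {
      pr <- which(probes$gene_id %in% rownames(delta))
      target <- pmin(beta0[pr] + delta[probes$gene_id[pr], s], 0.97)
      M[pr, s] <- beta_to_m(target)
    }
  }
  M <- M + matrix(rnorm(length(M), 0, 0.35), nrow(M))
  list(beta = m_to_beta(M), probes = probes)
}

#' Convert between methylation beta and M values
#'
#' The logistic link \eqn{M = \log_2(\beta / (1-\beta))}; `m_to_beta(0)` is
#' 0.5.
#'
#' @param beta,m Numeric vectors/matrices.
#' @return The transformed values.
#' @export
beta_to_m <- function(beta) log2(beta / (1 - beta))

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)
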