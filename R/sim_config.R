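#' Configuration for the matched-trio cohort simulator
#'
#' Collects and validates every knob of the synthetic cohort generator. The
#' defaults describe a cohort of 19 patients, each contributing one adjacent
#' normal, one primary tumor and one PVTT sample, with negative-binomial
#' counts whose dispersion decreases with the mean
#' (\eqn{\phi(\mu) = a/\mu + b}), patient-specific expression profiles that
#' dominate within-patient tumor/PVTT differences, a large tumor-vs-normal
#' signature, progressive (primary-vs-PVTT) alterations concentrated in a few
#' patients, a small set of recurrently altered genes, and genes whose
#' expression is coupled to copy number dosage or promoter methylation.
#'
#' @param n_patients Number of patients; each gets exactly one normal, one
#'   primary and one pvtt sample.
#' @param n_genes Number of genes.
#' @param library_size_range Length-2 positive range; per-sample expected
#'   total counts are drawn log-uniformly inside it.
#' @param baseline_logmean Named vector `c(location=, scale=)`: per-gene
#'   baseline log2 relative expression is Normal(location, scale).
#' @param dispersion_trend Named vector `c(a=, b=)` giving the NB dispersion
#'   \eqn{\phi(\mu) = a/\mu + b} (\eqn{\mu} the count mean); both must be
#'   non-negative and not both zero.
#' @param patient_effect_sd SD (log2) of per-gene, per-patient expression
#'   deviations shared by all three samples of a patient.
#' @param tumor_effect List `(fraction, lfc_sd)`: the fraction of genes
#'   differentially expressed in cancerous tissue (both primary and pvtt)
#'   relative to normal, with log2 fold changes Normal(0, lfc_sd).
#' @param progressive_effect List of blocks, each a list
#'   `(gene_fraction, n_patients, lfc, sign)` planting primary-vs-PVTT changes
#'   of magnitude `lfc` (log2) on a random gene set, restricted to one random
#'   patient subset of the given size. `sign` is "up", "down" or "both"
#'   (random per gene). Applied to the pvtt sample only.
#' @param n_recurrent_genes Number of genes planted progressive in
#'   `recurrent_patients` patients each (subset drawn per gene), with
#'   magnitude `recurrent_lfc` and a consistent per-gene direction.
#' @param recurrent_patients,recurrent_lfc See `n_recurrent_genes`.
#' @param cnv_driver_fraction Fraction of genes whose expression follows a
#'   planted copy-number state, `dosage_slope` log2 units per copy.
#' @param dosage_slope See `cnv_driver_fraction`.
#' @param meth_driver_fraction Fraction of genes whose promoter is
#'   hypermethylated in tumors with expression shifted by `meth_slope` log2
#'   units per unit beta increase (negative for silencing).
#' @param meth_slope See `meth_driver_fraction`.
#' @param probes_per_gene Promoter methylation probes simulated per gene.
#' @param seed Integer seed; all generators derive independent sub-streams
#'   from it, so e.g. adding methylation does not perturb the counts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 500, n_patients = 6)
#' cfg$n_genes
#' @export
sim_config <- function(n_patients = 19L,
                       n_genes = 10000L,
                       library_size_range = c(1.5e7, 3e7),
                       baseline_logmean = c(location = 3, scale = 2),
                       dispersion_trend = c(a = 1, b = 0.02),
                       patient_effect_sd = 0.4,
                       tumor_effect = list(fraction = 0.35, lfc_sd = 1.5),
                       progressive_effect = list(
                         list(gene_fraction = 0.15, n_patients = 3L,
                              lfc = 2, sign = "both"),
                         list(gene_fraction = 0.005, n_patients = 5L,
                              lfc = 2, sign = "both")
                       ),
                       n_recurrent_genes = 20L,
                       recurrent_patients = 7L,
                       recurrent_lfc = 2,
                       cnv_driver_fraction = 0.04,
                       dosage_slope = 0.5,
                       meth_driver_fraction = 0.012,
                       meth_slope = -4,
                       probes_per_gene = 5L,
                       seed = 1L) {
  stopifnot(
    n_patients >= 1, n_genes >= 1,
    length(library_size_range) == 2, all(library_size_range > 0),
    library_size_range[1] <= library_size_range[2],
    length(baseline_logmean) == 2,
    baseline_logmean[["scale"]] >= 0,
    length(dispersion_trend) == 2,
    all(dispersion_trend >= 0), sum(dispersion_trend) > 0,
    patient_effect_sd >= 0,
    tumor_effect$fraction >= 0, tumor_effect$fraction <= 1,
    tumor_effect$lfc_sd >= 0,
    n_recurrent_genes >= 0, recurrent_patients >= 1,
    recurrent_patients <= n_patients,
    cnv_driver_fraction >= 0, cnv_driver_fraction <= 1,
    meth_driver_fraction >= 0, meth_driver_fraction <= 1,
    probes_per_gene >= 3,
    is.numeric(seed), length(seed) == 1
  )
  for (blk in progressive_effect) {
    stopifnot(
      blk$gene_fraction >= 0, blk$gene_fraction <= 1,
      blk$n_patients >= 1, blk$n_patients <= n_patients,
      blk$lfc >= 0, blk$sign %in% c("up", "down", "both")
    )
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_genes = as.integer(n_genes),
    library_size_range = as.numeric(library_size_range),
    baseline_logmean = baseline_logmean,
    dispersion_trend = dispersion_trend,
    patient_effect_sd = patient_effect_sd,
    tumor_effect = tumor_effect,
    progressive_effect = progressive_effect,
    n_recurrent_genes = as.integer(n_recurrent_genes),
    recurrent_patients = as.integer(recurrent_patients),
    recurrent_lfc = recurrent_lfc,
    cnv_driver_fraction = cnv_driver_fraction,
    dosage_slope = dosage_slope,
    meth_driver_fraction = meth_driver_fraction,
    meth_slope = meth_slope,
    probes_per_gene = as.integer(probes_per_gene),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d patients x 3 samples, %d genes, seed %d\n",
    x$n_patients, x$n_genes, x$seed
  ))
  invisible(x)
}

# Independent RNG sub-streams derived from the single global seed.  Each
# generator seeds from its own slot so the streams stay decoupled.
.sim_streams <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  s <- sample.int(2^30, 6L)
  names(s) <- c("annotation", "effects", "counts", "cnv", "meth", "spare")
  s
}
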