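#' Paired differential test for one patient
#'
#' For every gene, the primary/PVTT pair of the patient yields a difference
#' \eqn{d = e^p - e^t} (primary minus PVTT, log2) and mean
#' \eqn{\mu = (e^p + e^t)/2}; the statistic
#' \eqn{z = d / \sqrt{2\,\sigma^2|\mu}} is referred to the standard normal
#' (two-sided), and p-values are BH-adjusted across this patient's genes
#' only. `d > 0` means the gene is higher in the primary, reported as
#' direction "down" (PVTT relative to primary).
#'
#' @param expr Expression matrix (genes x samples), log2 scale, normalized
#'   identically to the trend's training data.
#' @param sheet Sample sheet data.frame (sample_id, patient_id, tissue).
#' @param patient Patient id with exactly one primary and one pvtt sample.
#' @param trend A [fit_variance_trend()] object.
#' @param alpha Within-patient BH threshold for `call`; default 0.1.
#' @return data.frame with columns patient_id, gene_id, d, mu, z, p, q, call,
#'   direction.
#' @export
patient_differential <- function(expr, sheet, patient, trend, alpha = 0.1) {
  sp <- sheet$sample_id[sheet$patient_id == patient & sheet$tissue == "primary"]
  st <- sheet$sample_id[sheet$patient_id == patient & sheet$tissue == "pvtt"]
  if (length(sp) != 1 || length(st) != 1) {
    stop("patient ", patient, " does not have exactly one primary and one pvtt sample")
  }
  if (!all(c(sp, st) %in% colnames(expr))) {
    stop("samples of patient ", patient, " missing from expression matrix")
  }
  if (nrow(expr) == 0) {
    return(data.frame(patient_id = character(), gene_id = character(),
                      d = numeric(), mu = numeric(), z = numeric(),
                      p = numeric(), q = numeric(), call = logical(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  ep <- expr[, sp]
  et <- expr[, st]
  d <- ep - et
  mu <- (ep + et) / 2
  z <- d / sqrt(2 * eval_variance(trend, mu))
  p <- 2 * pnorm(-abs(z))
  q <- p.adjust(p, method = "BH")
  data.frame(
    patient_id = patient,
    gene_id = rownames(expr),
    d = d, mu = mu, z = z, p = p, q = q,
    call = q < alpha,
    direction = ifelse(d > 0, "down", ifelse(d < 0, "up", NA_character_)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the individualized paired test over all paired patients
#'
#' Concatenates [patient_differential()] over every patient in the sheet with
#' a complete primary/pvtt pair.
#'
#' @inheritParams patient_differential
#' @param verbose If TRUE, message per-patient call counts.
#' @return data.frame of per-patient records (see [patient_differential()]).
#' @examples
#' sim <- simulate_trio_cohort(sim_config(n_genes = 300, n_patients = 5))
#' e <- normalize_log_cpm(sim$counts)
#' normals <- sim$samples$sample_id[sim$samples$tissue == "normal"]
#' tr <- fit_variance_trend(e[, normals], n_bins = 10)
#' de <- run_idaseq(e, sim$samples, tr)
#' table(de$call)
#' @export
run_idaseq <- function(expr, sheet, trend, alpha = 0.1, verbose = FALSE) {
  pats <- paired_patients(sheet)
  if (!length(pats)) stop("no patient with a complete primary/pvtt pair")
  out <- lapply(pats, function(pt) {
    res <- tryCatch(
      patient_differential(expr, sheet, pt, trend, alpha),
      error = function(e) stop("patient ", pt, ": ", conditionMessage(e))
    )
    if (verbose) {
      message(sprintf("%s: %d genes called at q < %g", pt, sum(res$call), alpha))
    }
    res
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
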