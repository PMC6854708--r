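# Shared fixture builders. Everything is generated in code at test time.

# A small, fast cohort config; override any field.
test_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_genes = 400L, n_patients = 8L, recurrent_patients = 4L,
    n_recurrent_genes = 5L, seed = 1L
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A config with every planted effect and all nuisance variation switched off.
null_config <- function(...) {
  test_config(
    patient_effect_sd = 0,
    tumor_effect = list(fraction = 0, lfc_sd = 0),
    progressive_effect = list(),
    n_recurrent_genes = 0,
    cnv_driver_fraction = 0,
    meth_driver_fraction = 0,
    ...
  )
}

# Hand-built flat variance trend (sigma^2 constant over the mean range).
flat_trend <- function(sigma2 = 0.5, floor = 1e-4) {
  structure(
    list(bin_centers = c(-100, 100), bin_variances = c(sigma2, sigma2),
         variance_floor = floor, n_genes = NA_integer_,
         n_samples = NA_integer_),
    class = "variance_trend"
  )
}

# Minimal DE table with prescribed calls for recurrence tests.
make_de_table <- function(n_genes, calls_per_patient,
                          direction = "down") {
  genes <- sprintf("g%04d", seq_len(n_genes))
  do.call(rbind, lapply(seq_along(calls_per_patient), function(j) {
    called <- seq_len(n_genes) <= calls_per_patient[j]
    data.frame(
      patient_id = sprintf("P%02d", j), gene_id = genes,
      d = 0, mu = 0, z = 0, p = 1, q = 1, call = called,
      direction = ifelse(called, direction, NA_character_),
      stringsAsFactors = FALSE
    )
  }))
}

# Poisson-binomial tail oracle by dynamic programming: P(S >= k), k = 1..J.
pois_binom_tail <- function(p) {
  f <- 1
  for (pj in p) f <- c(f * (1 - pj), 0) + c(0, f * pj)
  rev(cumsum(rev(f)))[-1]
}
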