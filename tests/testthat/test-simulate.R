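test_that("identical config and seed give identical cohorts, CNV and methylation", {
  cfg <- test_config(seed = 7L)
  a <- simulate_trio_cohort(cfg)
  b <- simulate_trio_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_cnv_profiles(cfg, a$truth, a$genes)$segments,
                   simulate_cnv_profiles(cfg, b$truth, b$genes)$segments)
  expect_identical(simulate_methylation(cfg, a$truth, a$genes)$beta,
                   simulate_methylation(cfg, b$truth, b$genes)$beta)
})

test_that("null configuration plants nothing and pairs differ only by noise", {
  sim <- simulate_trio_cohort(null_config(seed = 3L))
  expect_identical(nrow(sim$truth), 0L)
  # tumor and pvtt of one patient share the same NB mean: their log-CPM
  # difference is centered at zero
  e <- normalize_log_cpm(sim$counts)
  d <- e[, "P01_T"] - e[, "P01_V"]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("sample sheet assigns each patient exactly one sample per role", {
  sim <- simulate_trio_cohort(test_config())
  tab <- table(sim$samples$patient_id, sim$samples$tissue)
  expect_true(all(tab == 1))
  expect_setequal(paired_patients(sim$samples), unique(sim$samples$patient_id))
})

test_that("near-zero dispersion approaches the Poisson limit", {
  cfg <- null_config(
    n_genes = 600L, n_patients = 12L,
    dispersion_trend = c(a = 0, b = 1e-9),
    library_size_range = c(5e7, 5e7), seed = 5L
  )
  sim <- simulate_trio_cohort(cfg)
  normals <- sim$samples$sample_id[sim$samples$tissue == "normal"]
  cn <- sim$counts[, normals]
  m <- rowMeans(cn)
  v <- apply(cn, 1, var)
  keep <- m > 50   # variance/mean ratio is noisy for tiny counts
  expect_lt(abs(mean(v[keep] / m[keep]) - 1), 0.15)
})

test_that("simulated count moments match the NB mean-dispersion model", {
  # many normals, no biological effects: per-gene sample variance should
  # track mu + phi(mu) mu^2
  cfg <- null_config(
    n_genes = 300L, n_patients = 150L, recurrent_patients = 1L,
    dispersion_trend = c(a = 1, b = 0.02),
    library_size_range = c(2e7, 2e7), seed = 9L
  )
  sim <- simulate_trio_cohort(cfg)
  normals <- sim$samples$sample_id[sim$samples$tissue == "normal"]
  cn <- sim$counts[, normals]
  m <- rowMeans(cn)
  v <- apply(cn, 1, var)
  theo <- m + (1 / m + 0.02) * m^2
  keep <- m > 20
  ratio <- v[keep] / theo[keep]
  # Monte-Carlo error of a variance ratio at n=150 is ~ sqrt(2/149) ~ 12%
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("planted effects appear exactly once per (gene, patient, kind)", {
  sim <- simulate_trio_cohort(test_config(seed = 21L))
  key <- paste(sim$truth$gene_id, sim$truth$patient_id, sim$truth$effect_kind)
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(sim$truth$effect_kind %in%
                    c("tumor", "progressive", "cnv_driver", "meth_driver")))
})

test_that("over-subscribed planted blocks are rejected", {
  cfg <- test_config(progressive_effect = list(
    list(gene_fraction = 0.7, n_patients = 2L, lfc = 1, sign = "up"),
    list(gene_fraction = 0.7, n_patients = 2L, lfc = 1, sign = "down")
  ))
  expect_error(simulate_trio_cohort(cfg), "conflicting signs")
})

test_that("intra-patient tumor pairs are closer than inter-patient primaries", {
  sim <- simulate_trio_cohort(sim_config(n_genes = 3000L, seed = 13L))
  e <- normalize_log_cpm(sim$counts)
  normals <- sim$samples$sample_id[sim$samples$tissue == "normal"]
  ef <- filter_low_expression(e, samples = normals)
  within_pair <- pairwise_distances(ef, sim$samples, "matched-primary-pvtt")
  between <- pairwise_distances(ef, sim$samples, "within-primaries")
  expect_lt(within_pair$mean_distance, between$mean_distance)
})

test_that("CNV profiles honor planted copy states and round-trip through SEG", {
  cfg <- test_config(cnv_driver_fraction = 0.1, seed = 31L)
  sim <- simulate_trio_cohort(cfg)
  cnv <- simulate_cnv_profiles(cfg, sim$truth, sim$genes)
  states <- attr(sim$truth, "cnv_states")
  mapped <- cnv$gene_cnv$state[rownames(states), colnames(states)]
  expect_true(mean(mapped == states) > 0.95)

  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(cnv$segments, path)
  back <- read_seg(path)
  expect_equal(back$Segment_Mean, cnv$segments$Segment_Mean, tolerance = 1e-12)
  expect_equal(back$Start, cnv$segments$Start)

  # per-sample segments must not overlap within a chromosome
  seg1 <- cnv$segments[cnv$segments$Sample == cnv$segments$Sample[1], ]
  for (ch in unique(seg1$Chromosome)) {
    s <- seg1[seg1$Chromosome == ch, ]
    s <- s[order(s$Start), ]
    if (nrow(s) > 1) expect_true(all(s$Start[-1] > s$End[-nrow(s)]))
  }
})

test_that("without planted drivers gene copy states are independent of expression truth", {
  cfg <- null_config(seed = 17L)
  sim <- simulate_trio_cohort(cfg)
  cnv <- simulate_cnv_profiles(cfg, sim$truth, sim$genes)
  expect_null(attr(sim$truth, "cnv_states"))
  # states exist (background arms) but have no gene-level planted signal
  expect_true(all(dim(cnv$gene_cnv$state) == c(cfg$n_genes, 2 * cfg$n_patients)))
})

test_that("methylation betas stay in (0,1), respect the logistic link, and carry planted shifts", {
  expect_equal(m_to_beta(0), 0.5)
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(m_to_beta(beta_to_m(0.3)), 0.3)

  cfg <- test_config(meth_driver_fraction = 0.05, seed = 23L)
  sim <- simulate_trio_cohort(cfg)
  meth <- simulate_methylation(cfg, sim$truth, sim$genes)
  expect_true(all(meth$beta > 0 & meth$beta < 1))
  expect_identical(nrow(meth$beta), cfg$n_genes * cfg$probes_per_gene)

  # planted genes: tumor-minus-normal beta shift positive on their probes
  drv <- unique(sim$truth$gene_id[sim$truth$effect_kind == "meth_driver"])
  pr <- meth$probes$probe_id[meth$probes$gene_id %in% drv]
  normals <- sim$samples$sample_id[sim$samples$tissue == "normal"]
  tumors <- sim$samples$sample_id[sim$samples$tissue == "primary"]
  shift <- rowMeans(meth$beta[pr, tumors]) - rowMeans(meth$beta[pr, normals])
  expect_gt(mean(shift), 0.2)

  # unplanted genes: expected shift zero
  oth <- sample(setdiff(meth$probes$probe_id, pr), 200)
  shift0 <- rowMeans(meth$beta[oth, tumors]) - rowMeans(meth$beta[oth, normals])
  expect_lt(abs(mean(shift0)), 0.02)
})

test_that("probe positions fall in the strand-aware promoter window", {
  cfg <- test_config(seed = 29L)
  sim <- simulate_trio_cohort(cfg)
  meth <- simulate_methylation(cfg, sim$truth, sim$genes)
  ann <- annotate_promoter_probes(meth$probes, sim$genes)
  expect_true(all(ann$in_promoter))
})
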