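toy_genes <- data.frame(
  gene_id = c("plus", "minus"), chrom = c("chr1", "chr1"),
  start = c(10000L, 50000L), end = c(12000L, 52000L),
  strand = c("+", "-"), tss = c(10001L, 52000L),
  stringsAsFactors = FALSE
)

test_that("promoter windows are strand-aware and inclusive at both ends", {
  probes <- data.frame(
    probe_id = sprintf("cg%02d", 1:8),
    chrom = "chr1",
    #          + gene: [tss-1500, tss+500] = [8501, 10501]
    #          - gene: [tss-500, tss+1500] = [51500, 53500]
    pos = c(8501L, 10501L, 8500L, 10502L, 51500L, 53500L, 51499L, 53501L),
    strand = rep(c("+", "-"), each = 4),
    gene_id = rep(c("plus", "minus"), each = 4),
    stringsAsFactors = FALSE
  )
  ann <- annotate_promoter_probes(probes, toy_genes)
  expect_identical(ann$in_promoter,
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  # upstream of the minus-strand gene lies at larger coordinates
  expect_true(ann$in_promoter[ann$pos == 53500L])
})

test_that("gene copy number is the length-weighted segment mean with inclusive thresholds", {
  genes <- data.frame(
    gene_id = c("inside", "split", "orphan"), chrom = "chr1",
    start = c(1000L, 10000L, 90000L), end = c(2000L, 12000L, 91000L),
    strand = "+", tss = c(1001L, 10001L, 90001L), stringsAsFactors = FALSE
  )
  segs <- data.frame(
    Sample = "s1", Chromosome = "chr1",
    Start = c(1L, 5000L, 11001L), End = c(4999L, 11000L, 50000L),
    Num_Probes = 10L, Segment_Mean = c(0.8, 0.0, 0.4),
    stringsAsFactors = FALSE
  )
  cnv <- map_genes_to_cnv(segs, genes)
  expect_equal(cnv$log2ratio["inside", "s1"], 0.8)
  expect_equal(cnv$state["inside", "s1"], 1)
  # split 50/50 between means 0.0 and 0.4 -> 0.2, inclusive boundary -> state 1
  expect_equal(cnv$log2ratio["split", "s1"], 0.2)
  expect_equal(cnv$state["split", "s1"], 1)
  # no overlapping segment -> missing
  expect_true(is.na(cnv$log2ratio["orphan", "s1"]))

  # all-zero segments give state 0; |value| >= 1 gives state 2
  segs$Segment_Mean <- c(0, 0, 0)
  expect_true(all(map_genes_to_cnv(segs, genes)$state[1:2, ] == 0))
  segs$Segment_Mean <- c(-1.0, 0, 0)
  expect_equal(map_genes_to_cnv(segs, genes)$state["inside", "s1"], -2)
})

meth_fixture <- function(delta, n_probes = 4, n_pairs = 19, n_null = 30,
                         seed = 1) {
  set.seed(seed)
  genes <- c("hyper", sprintf("null%02d", seq_len(n_null)))
  probes <- data.frame(
    probe_id = sprintf("cg%03d", seq_len(n_probes * length(genes))),
    chrom = "chr1", pos = 1L, strand = "+",
    gene_id = rep(genes, each = n_probes),
    in_promoter = TRUE, stringsAsFactors = FALSE
  )
  pid <- sprintf("P%02d", seq_len(n_pairs))
  sheet <- data.frame(
    sample_id = c(paste0(pid, "_N"), paste0(pid, "_T")),
    patient_id = rep(pid, 2),
    tissue = rep(c("normal", "primary"), each = n_pairs),
    stringsAsFactors = FALSE
  )
  base <- matrix(0.2 + rnorm(nrow(probes) * n_pairs, 0, 0.03),
                 nrow(probes), n_pairs)
  tum <- base + rnorm(length(base), 0, 0.03)
  tum[probes$gene_id == "hyper", ] <- tum[probes$gene_id == "hyper", ] + delta
  beta <- pmin(pmax(cbind(base, tum), 0.001), 0.999)
  dimnames(beta) <- list(probes$probe_id, sheet$sample_id)
  list(beta = beta, probes = probes, sheet = sheet)
}

test_that("hypermethylation calling applies the q, delta and probe-count rules", {
  # identical tumor and normal betas: nothing flagged
  fx <- meth_fixture(delta = 0)
  fx$beta[, 20:38] <- fx$beta[, 1:19]
  res <- call_hypermethylated_promoters(fx$beta, fx$probes, fx$sheet)
  expect_identical(res$genes, character(0))

  # planted delta-beta 0.3 on 4 probes across 19 pairs is flagged
  fx <- meth_fixture(delta = 0.3)
  res <- call_hypermethylated_promoters(fx$beta, fx$probes, fx$sheet)
  expect_identical(res$genes, "hyper")
  expect_gte(sum(res$probe_stats$qualifies[res$probe_stats$gene_id == "hyper"]), 2)

  # a single qualifying probe is insufficient at min_probes = 2
  fx <- meth_fixture(delta = 0.3)
  hyper_probes <- fx$probes$probe_id[fx$probes$gene_id == "hyper"]
  tum_cols <- 20:38
  fx$beta[hyper_probes[-1], tum_cols] <- fx$beta[hyper_probes[-1], tum_cols] - 0.3
  res <- call_hypermethylated_promoters(fx$beta, fx$probes, fx$sheet)
  expect_identical(res$genes, character(0))
})

test_that("raising the delta cutoff never adds hypermethylated genes", {
  fx <- meth_fixture(delta = 0.25, seed = 4)
  cuts <- c(0.1, 0.2, 0.3, 0.5)
  sets <- lapply(cuts, function(dc) {
    call_hypermethylated_promoters(fx$beta, fx$probes, fx$sheet,
                                   delta_cut = dc)$genes
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("planted promoter shifts are recovered across replicates", {
  hits <- vapply(1:20, function(s) {
    fx <- meth_fixture(delta = 0.3, seed = s)
    "hyper" %in% call_hypermethylated_promoters(fx$beta, fx$probes, fx$sheet)$genes
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Spearman screen statistics match rank arithmetic", {
  # perfect monotone covariate
  e <- matrix(1:8, 1, 8, dimnames = list("g1", paste0("s", 1:8)))
  cv <- matrix(c(2, 4, 5, 7, 8, 10, 11, 20), 1, 8,
               dimnames = list("g1", paste0("s", 1:8)))
  res <- spearman_screen(e, cv, side = "positive")
  expect_equal(res$rho, 1)
  expect_true(res$candidate)

  # the 5-point example: ranks d^2 sum to 4 -> rho = 1 - 6*4/120 = 0.8
  e2 <- matrix(c(1, 2, 3, 4, 5), 1, 5, dimnames = list("g1", paste0("s", 1:5)))
  cv2 <- matrix(c(2, 1, 4, 3, 5), 1, 5, dimnames = list("g1", paste0("s", 1:5)))
  res2 <- spearman_screen(e2, cv2, side = "positive", rho_cut = 0.4)
  oracle <- 1 - 6 * sum((rank(e2[1, ]) - rank(cv2[1, ]))^2) / (5 * (5^2 - 1))
  expect_equal(res2$rho, oracle)
  expect_equal(res2$rho, 0.8)
  # exact one-sided p for n = 5 without ties
  expect_equal(res2$p_one_sided,
               cor.test(e2[1, ], cv2[1, ], method = "spearman",
                        alternative = "greater", exact = TRUE)$p.value)

  # constant covariate is excluded with NA rho
  cv3 <- matrix(1, 1, 8, dimnames = list("g1", paste0("s", 1:8)))
  expect_message(res3 <- spearman_screen(e, cv3, side = "positive"), "excluded")
  expect_true(is.na(res3$rho))
  expect_false(res3$candidate)
})

test_that("Spearman screen is invariant under monotone transforms", {
  set.seed(8)
  e <- matrix(rnorm(12), 1, 12, dimnames = list("g1", paste0("s", 1:12)))
  cv <- matrix(rnorm(12), 1, 12, dimnames = list("g1", paste0("s", 1:12)))
  a <- spearman_screen(e, cv, side = "positive")
  b <- spearman_screen(exp(e), cv^3, side = "positive")
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_one_sided, b$p_one_sided)
})

test_that("planted dosage genes are flagged and the null rate matches a permutation oracle", {
  set.seed(5)
  n_samp <- 38
  slope <- 0.5
  states <- matrix(sample(c(-1, 0, 1, 2), 60 * n_samp, TRUE,
                          prob = c(0.15, 0.3, 0.35, 0.2)), 60, n_samp)
  noise <- matrix(rnorm(60 * n_samp, 0, 0.45), 60, n_samp)
  e <- slope * states + noise
  dimnames(e) <- dimnames(states) <- list(sprintf("g%02d", 1:60),
                                          sprintf("s%02d", 1:n_samp))
  res <- spearman_screen(e, states, side = "positive")
  expect_gte(mean(res$candidate), 0.9)

  # null genes: flag rate agrees with a label-permutation oracle
  e0 <- matrix(rnorm(400 * n_samp), 400, n_samp,
               dimnames = list(sprintf("n%03d", 1:400), colnames(e)))
  st0 <- states[sample(1:60, 400, TRUE), ]
  rownames(st0) <- rownames(e0)
  res0 <- spearman_screen(e0, st0, side = "positive")
  null_rate <- mean(res0$candidate)
  perm_rate <- mean(vapply(1:400, function(i) {
    x <- e0[i, sample(n_samp)]
    r <- cor(x, st0[i, ], method = "spearman")
    r > 0.4
  }, logical(1)))
  se <- sqrt(perm_rate * (1 - perm_rate) / 400 + null_rate * (1 - null_rate) / 400)
  expect_lt(abs(null_rate - perm_rate), max(3 * se, 0.02))
})

test_that("second-order independence summarizes rho vectors and set overlap", {
  u <- sprintf("g%02d", 1:10)
  rho <- setNames(seq(0.1, 1, 0.1), u)
  res <- second_order_independence(rho, rho, u[1:3], u[1:3], u)
  expect_equal(res$rho_of_rhos, 1)

  # disjoint sets |A|=3, |B|=3, |U|=10: Fisher p from the hypergeometric sum
  res2 <- second_order_independence(rho, rev(rho), u[1:3], u[8:10], u)
  k <- 0:3
  probs <- dhyper(k, 3, 7, 3)
  p_oracle <- sum(probs[probs <= probs[1] * (1 + 1e-7)])
  expect_equal(res2$fisher_p, p_oracle)
  expect_identical(res2$overlap, 0L)

  # independent rho vectors: correlation of rhos near zero
  set.seed(3)
  big_u <- sprintf("G%04d", 1:2000)
  r1 <- setNames(rnorm(2000), big_u)
  r2 <- setNames(rnorm(2000), big_u)
  res3 <- second_order_independence(r1, r2, big_u[1:5], big_u[6:10], big_u)
  expect_lt(abs(res3$rho_of_rhos), 3 / sqrt(2000))

  expect_error(second_order_independence(rho, rho, u, u, character(0)),
               "empty")
})

test_that("arm enrichment tails equal closed-form binomial sums", {
  u <- sprintf("g%03d", 1:100)
  arm_of <- setNames(rep(c("1p", "1q"), c(10, 90)), u)
  # 8 of 20 candidates on an arm holding 10% of the universe
  cands <- c(u[1:8], u[11:22])
  res <- arm_enrichment(cands, arm_of, u)
  row <- res[res$arm == "1p", ]
  expect_equal(row$p_enrichment, sum(dbinom(8:20, 20, 0.1)))
  expect_equal(row$p_depletion, sum(dbinom(0:8, 20, 0.1)))
  expect_identical(row$direction, "enriched")
  # enrichment and depletion tails overlap only at the point mass
  expect_equal(row$p_enrichment + row$p_depletion, 1 + dbinom(8, 20, 0.1))

  # zero candidates on an arm: depletion tail is (1-p0)^n
  cands0 <- u[11:30]
  res0 <- arm_enrichment(cands0, arm_of, u)
  expect_equal(res0$p_depletion[res0$arm == "1p"], 0.9^20)

  # proportional allocation is never significantly enriched
  cands_prop <- c(u[1:2], u[11:28])   # 2/20 on an arm with p0 = 0.1
  resp <- arm_enrichment(cands_prop, arm_of, u)
  expect_true(all(resp$p_enrichment >= 0.5))

  expect_error(arm_enrichment("not_in_universe", arm_of, u), "subset")
})
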