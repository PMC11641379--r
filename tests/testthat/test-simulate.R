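test_that("simulation parameters are validated", {
  expect_error(sim_params(base_alpha = 0.9, effect_delta = 0.2))
  expect_error(sim_params(target_rois = "nothere"))
  expect_error(sim_params(G = 10, n_signal = 6))
  p <- sim_params()
  expect_equal(p$n_per_group, c(NEG = 172, POS = 126))
  expect_length(p$regions, 34)
})

test_that("generators are deterministic given a seed and leave the RNG untouched", {
  p <- sim_params(n_per_group = c(NEG = 5, POS = 5), G = 30, n_signal = 3)
  set.seed(901); before <- runif(1)
  set.seed(901)
  a <- simulate_cohort(p, seed = 1)
  b <- simulate_cohort(p, seed = 1)
  expect_identical(a, b)
  # the caller's RNG stream is not consumed by seeded generators
  expect_equal(runif(1), before)
  e1 <- simulate_expression_matrix(p, 1:34, seed = 2)
  e2 <- simulate_expression_matrix(p, 1:34, seed = 2)
  expect_identical(e1, e2)
  d1 <- simulate_donor_samples(p, e1$expr, seed = 3)
  d2 <- simulate_donor_samples(p, e1$expr, seed = 3)
  expect_identical(d1, d2)
  g1 <- simulate_gene_sets(e1$signal, colnames(e1$expr), set_size = 10, seed = 4)
  g2 <- simulate_gene_sets(e1$signal, colnames(e1$expr), set_size = 10, seed = 4)
  expect_identical(g1, g2)
})

test_that("simulated cohorts respect group sizes, covariate models, and CSF regions", {
  p <- sim_params(n_per_group = c(NEG = 500, POS = 500))
  co <- simulate_cohort(p, seed = 902)
  s <- co$subjects
  expect_equal(table(s$group)[["NEG_NEG"]], 500)
  neg <- s[s$group == "NEG_NEG", ]
  pos <- s[s$group == "POS_POS", ]
  # CSF values always inside the group's classification region
  expect_identical(unique(classify_csf_status(neg$abeta, neg$tau)), "NEG_NEG")
  expect_identical(unique(classify_csf_status(pos$abeta, pos$tau)), "POS_POS")
  # covariate means within ~3 standard errors of the configured targets
  expect_lt(abs(mean(neg$age) - 71.05), 3 * 7.10 / sqrt(500))
  expect_lt(abs(mean(pos$age) - 77.18), 3 * 7.92 / sqrt(500))
  expect_lt(abs(mean(pos$mmse) - 26.06), 3 * 4.62 / sqrt(500) + 0.2)
  expect_lt(abs(mean(neg$gender == "M") - 71 / 172), 3 * 0.5 / sqrt(500))
  expect_true(all(s$mmse >= 0 & s$mmse <= 30))
  # feature tables have the canonical shape
  expect_equal(dim(co$features[[1]]), c(34, 13))
  expect_equal(rownames(co$features[[1]]), dk_rois())
})

test_that("regional MS grows with the shared-component mixing weight", {
  ms_at <- function(alpha, seed, n = 60) {
    p <- sim_params(n_per_group = c(NEG = n, POS = 1), base_alpha = alpha,
                    effect_delta = 0)
    co <- simulate_cohort(p, seed = seed)
    mean(regional_ms_table(co$features))
  }
  m_lo <- ms_at(0.05, 903)
  m_mid <- ms_at(0.45, 903)
  m_hi <- ms_at(0.9, 903)
  expect_lt(m_lo, m_mid)
  expect_lt(m_mid, m_hi)
  expect_gt(ms_at(0.99, 904, n = 200), 0.9)  # near-total sharing saturates MS
})

test_that("a larger planted effect yields a larger mean target-region t", {
  mean_t <- function(delta) {
    p <- sim_params(n_per_group = c(NEG = 80, POS = 80), effect_delta = delta,
                    target_rois = "cuneus")
    co <- simulate_cohort(p, seed = 905)
    cm <- contrast_map(regional_ms_table(co$features), co$subjects)
    cm$t[cm$roi == "cuneus"]
  }
  ts <- c(mean_t(0.05), mean_t(0.15), mean_t(0.3))
  expect_true(all(diff(ts) > 0))
})

test_that("planted expression signal scales with the signal-to-noise ratio", {
  pattern <- sin(seq_len(34))
  p_hi <- sim_params(G = 60, n_signal = 10, signal_snr = 10)
  hi <- simulate_expression_matrix(p_hi, pattern, seed = 906)
  cors <- sapply(seq_len(nrow(hi$signal)), function(i)
    hi$signal$sign[i] * cor(hi$expr[, hi$signal$gene[i]], pattern))
  expect_true(all(cors > 0.9))
  expect_true(all(hi$expr >= 0 & hi$expr <= 1))
  p_no <- sim_params(G = 200, n_signal = 30, signal_snr = 0)
  no <- simulate_expression_matrix(p_no, pattern, seed = 907)
  cors0 <- sapply(seq_len(nrow(no$signal)), function(i)
    cor(no$expr[, no$signal$gene[i]], pattern))
  expect_lt(abs(mean(cors0)), 0.15)
  expect_error(simulate_expression_matrix(p_hi, rep(1, 34)), "constant")
})

test_that("donor samples stay assignable to their true centroids", {
  p <- sim_params(G = 20, n_signal = 2, n_donors = 2)
  e <- simulate_expression_matrix(p, 1:34, seed = 908)
  d <- simulate_donor_samples(p, e$expr, seed = 909)
  coords <- unique(d$samples[, c("donor_id", "sample_id", "x", "y", "z")])
  asg <- assign_samples_to_regions(coords, d$centroids, radius = 2)
  direct <- asg[!asg$fallback, ]
  # every emitted sample lands within the 2 mm radius of its own centroid
  expect_equal(nrow(direct), nrow(coords))
  true_roi <- sub("^D[0-9]+_(.*)_[0-9]+$", "\\1", direct$sample_id)
  expect_identical(direct$roi, true_roi)
  # single-probe genes select that probe trivially
  p1 <- sim_params(G = 15, n_signal = 2, probes_per_gene = 1)
  e1 <- simulate_expression_matrix(p1, 1:34, seed = 910)
  d1 <- simulate_donor_samples(p1, e1$expr, seed = 911)
  expr <- suppressMessages(
    prepare_expression(d1$samples, d1$probe_map, d1$centroids))
  expect_setequal(attr(expr, "selected_probes"), d1$probe_map$probe_id)
})

test_that("simulated gene sets honor the enrichment fraction", {
  p <- sim_params(G = 200, n_signal = 30)
  e <- simulate_expression_matrix(p, 1:34, seed = 912)
  bg <- colnames(e$expr)
  plus_genes <- e$signal$gene[e$signal$sign == 1]
  full <- simulate_gene_sets(e$signal, bg, set_size = 20,
                             enrichment_fraction = 1, seed = 913)
  expect_true(all(full$sets$enriched_plus %in% plus_genes))
  none <- simulate_gene_sets(e$signal, bg, set_size = 20,
                             enrichment_fraction = 0, seed = 914)
  expect_length(none$sets$enriched_plus, 20)
  expect_error(simulate_gene_sets(e$signal, bg[1:5], set_size = 10), "exceeds")
})
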