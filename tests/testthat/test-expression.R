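test_that("intensity filter retains probes at or above the threshold fraction", {
  samples <- data.frame(
    probe_id = rep(c("pA", "pB", "pC"), each = 4),
    above_background = c(rep(TRUE, 4),          # 100%
                         rep(FALSE, 4),         # 0%
                         TRUE, TRUE, FALSE, FALSE))  # exactly 50%
  kept <- filter_probes_intensity(samples)
  expect_setequal(kept, c("pA", "pC"))  # boundary is inclusive
  expect_error(filter_probes_intensity(samples[0, ]), "empty")
})

test_that("samples map to nearest centroids with per-donor fallback for empty regions", {
  cen <- data.frame(roi = dk_rois()[1:3],
                    x = c(0, 20, 40), y = 0, z = 0)
  coords <- data.frame(
    donor_id = "D1",
    sample_id = c("s1", "s2", "s3"),
    x = c(0, 20.5, 43), y = 0, z = 0)  # s3 is 3 mm from roi 3
  asg <- assign_samples_to_regions(coords, cen, radius = 2)
  expect_equal(asg$roi[asg$sample_id == "s1" & !asg$fallback], dk_rois()[1])
  expect_equal(asg$roi[asg$sample_id == "s2" & !asg$fallback], dk_rois()[2])
  # region 3 had no in-radius sample; its nearest donor sample is recruited
  fb <- asg[asg$fallback, ]
  expect_equal(fb$roi, dk_rois()[3])
  expect_equal(fb$sample_id, "s3")
  expect_error(assign_samples_to_regions(coords[0, ], cen), "no samples")
  bad_cen <- cen; bad_cen$roi[1] <- "nope"
  expect_error(assign_samples_to_regions(coords, bad_cen), "unknown region")
})

test_that("regional means average the samples assigned to a region", {
  cen <- data.frame(roi = dk_rois()[1:2], x = c(0, 20), y = 0, z = 0)
  coords <- data.frame(donor_id = "D1", sample_id = c("s1", "s2", "s3"),
                       x = c(0, 0.5, 20), y = 0, z = 0)
  asg <- assign_samples_to_regions(coords, cen)
  samples <- data.frame(donor_id = "D1",
                        sample_id = rep(c("s1", "s2", "s3"), each = 1),
                        probe_id = "p1", intensity = c(2, 4, 7))
  m <- region_mean_expression(samples, asg, rois = dk_rois()[1:2])
  expect_equal(m$D1["p1", dk_rois()[1]], 3)  # mean of 2 and 4
  expect_equal(m$D1["p1", dk_rois()[2]], 7)
})

test_that("differential stability equals the mean pairwise Spearman oracle", {
  rois <- dk_rois()[1:8]
  mk <- function(v) matrix(v, 1, 8, dimnames = list("p1", rois))
  # identical profiles -> DS 1; reversed ranks -> DS -1
  d1 <- list(A = mk(1:8), B = mk((1:8) * 3 + 2))
  expect_equal(unname(differential_stability(d1)), 1)
  d2 <- list(A = mk(1:8), B = mk(8:1))
  expect_equal(unname(differential_stability(d2)), -1)
  # 3 donors, random profiles, multiple probes, with missing regions
  set.seed(601)
  donors <- lapply(1:3, function(i) {
    m <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("p", 1:3), rois))
    m[, sample(8, 2)] <- NA
    m
  })
  names(donors) <- c("A", "B", "C")
  ds <- differential_stability(donors)
  for (pr in rownames(donors[[1]])) {
    vals <- c()
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- donors[[pair[1]]][pr, ]; b <- donors[[pair[2]]][pr, ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3) next
      ra <- rank(a[ok]); rb <- rank(b[ok])
      vals <- c(vals, sum((ra - mean(ra)) * (rb - mean(rb))) /
                  sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2)))
    }
    expect_lt(abs(ds[[pr]] - mean(vals)), 1e-12)
  }
  expect_error(differential_stability(d1[1]), "two donors")
  # constant profiles in every pair -> no usable pair
  dflat <- list(A = mk(rep(1, 8)), B = mk(rep(2, 8)))
  expect_error(differential_stability(dflat), "no donor pair")
})

test_that("probe selection takes the most stable probe with a deterministic tie-break", {
  pm <- data.frame(probe_id = c("p1", "p2", "p3", "p9", "p0"),
                   gene_id = c("g1", "g1", "g2", "g3", "g3"))
  ds <- c(p1 = 0.9, p2 = 0.2, p3 = 0.5, p9 = 0.7, p0 = 0.7)
  picked <- select_probe_per_gene(ds, pm)
  expect_equal(picked[["g1"]], "p1")
  expect_equal(picked[["g2"]], "p3")   # single probe
  expect_equal(picked[["g3"]], "p0")   # tie -> lexicographically smallest
  # gene with no scored probe is dropped with a message
  ds2 <- ds; ds2["p3"] <- NA
  expect_message(picked2 <- select_probe_per_gene(ds2, pm), "dropped")
  expect_false("g2" %in% names(picked2))
})

test_that("robust sigmoid normalization is monotone, unit-ranged, and affine-invariant", {
  set.seed(602)
  x <- rnorm(20)
  s <- robust_sigmoid_normalize(x)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_equal(order(s), order(x))  # strictly monotone
  # the sigmoid midpoint maps the median to 0.5 before rescaling
  x_odd <- c(1, 2, 3, 4, 10)
  raw <- 1 / (1 + exp(-(x_odd - median(x_odd)) / (IQR(x_odd) / 1.35)))
  expect_equal(raw[x_odd == median(x_odd)], 0.5)
  # affine transforms of the input give the identical output
  expect_lt(max(abs(s - robust_sigmoid_normalize(3.7 * x + 11))), 1e-10)
  expect_error(robust_sigmoid_normalize(rep(1, 5)), "IQR")
  expect_error(robust_sigmoid_normalize(c(1, 2)), "3 regions")
})

test_that("donor aggregation averages available blocks and flags empty cells", {
  b1 <- matrix(c(0.2, 0.4), 1, 2, dimnames = list("r", c("g1", "g2")))
  b2 <- matrix(c(0.6, NA), 1, 2, dimnames = list("r", c("g1", "g2")))
  agg <- aggregate_expression(list(b1, b2))
  expect_equal(agg["r", "g1"], 0.4)
  expect_equal(agg["r", "g2"], 0.4)  # single-donor cell passes through
  expect_equal(aggregate_expression(list(b1)), b1)
  b3 <- b2; b3[1, 1] <- NA
  expect_error(aggregate_expression(list(b2 * NA, b3)), "no donor coverage")
})

test_that("the donor pipeline recovers a planted regional gradient", {
  p <- sim_params(G = 40, n_signal = 5)
  gradient <- seq(0, 1, length.out = 34)
  truth <- simulate_expression_matrix(p, gradient, seed = 603)
  don <- simulate_donor_samples(p, truth$expr, seed = 604)
  expr <- suppressMessages(
    prepare_expression(don$samples, don$probe_map, don$centroids))
  expect_equal(dim(expr), c(34, 40))
  expect_true(all(expr >= 0 & expr <= 1))
  expect_false(anyNA(expr))
  sp <- sapply(colnames(expr), function(g)
    cor(expr[, g], truth$expr[, g], method = "spearman"))
  expect_gt(mean(sp), 0.8)
  # signal-gene columns track the planted gradient itself
  sig_sp <- sapply(truth$signal$gene, function(g)
    truth$signal$sign[truth$signal$gene == g] *
      cor(expr[, g], gradient, method = "spearman"))
  expect_gt(mean(sig_sp), 0.5)
})

test_that("expression matrices round-trip through TSV", {
  set.seed(605)
  expr <- matrix(runif(34 * 5), 34, 5,
                 dimnames = list(dk_rois(), paste0("g", 1:5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(expr, path)
  back <- read_expression_matrix(path)
  expect_equal(back, expr, tolerance = 1e-12)
})
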