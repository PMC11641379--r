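#' Simulation parameters for the synthetic study
#'
#' Bundles every knob of the synthetic-data generators, with defaults that
#' emulate the study conditions: group sizes 172 (biomarker-negative) and
#' 126 (biomarker-positive); per-group covariate means/SDs for age,
#' education and MMSE and the male proportions from the cohort summary; a
#' shared-component similarity model over 34 regions x 13 features with a
#' group increment of the mixing weight in a small set of target regions;
#' and an expression model where a subset of genes spatially tracks a
#' planted contrast pattern.
#'
#' @param n_per_group Integer pair `c(NEG, POS)` (default `c(172, 126)`).
#' @param regions Region labels (default [dk_rois()]).
#' @param n_features Features per region (default 13).
#' @param base_alpha Shared-component mixing weight in \[0, 1) common to all
#'   regions (default 0.3).
#' @param effect_delta Group increment of the mixing weight in the target
#'   regions for the positive group; may be negative (default 0.15).
#' @param target_rois Regions carrying the group effect (default: caudal
#'   anterior cingulate, lateral occipital, cuneus, pars triangularis).
#' @param covariate_params Per-group list with `age`, `education`, `mmse`
#'   (each `c(mean, sd)`) and `p_male`.
#' @param G Number of genes (default 1000).
#' @param n_signal Signal genes per sign (default 50).
#' @param signal_snr Signal-to-noise ratio of signal-gene columns
#'   (default 1).
#' @param n_donors Expression donors (default 6).
#' @param samples_per_region Tissue samples per covered region per donor
#'   (default 3).
#' @param probes_per_gene Microarray probes per gene, the first of which is
#'   low-noise (default 2).
#' @param background_rate Above-background probability for the low-noise
#'   probe; other probes use half of it (default 0.9).
#' @param donor_coverage Fraction of regions each donor samples
#'   (default 0.9).
#' @param probe_noise_sd Noise SD pair `c(good, bad)` on the unit intensity
#'   scale (default `c(0.1, 0.5)`).
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(n_per_group = c(NEG = 172, POS = 126),
                       regions = dk_rois(), n_features = 13,
                       base_alpha = 0.3, effect_delta = 0.15,
                       target_rois = c("caudalanteriorcingulate",
                                       "lateraloccipital", "cuneus",
                                       "parstriangularis"),
                       covariate_params = list(
                         NEG_NEG = list(age = c(71.05, 7.10),
                                        education = c(16.70, 2.38),
                                        mmse = c(28.85, 1.47),
                                        p_male = 71 / 172),
                         POS_POS = list(age = c(77.18, 7.92),
                                        education = c(16.01, 2.54),
                                        mmse = c(26.06, 4.62),
                                        p_male = 60 / 126)),
                       G = 1000, n_signal = 50, signal_snr = 1,
                       n_donors = 6, samples_per_region = 3,
                       probes_per_gene = 2, background_rate = 0.9,
                       donor_coverage = 0.9,
                       probe_noise_sd = c(good = 0.1, bad = 0.5)) {
  stopifnot(base_alpha >= 0, base_alpha + abs(effect_delta) < 1,
            all(target_rois %in% regions), 2 * n_signal <= G,
            n_features >= 2, all(n_per_group >= 1))
  structure(list(n_per_group = n_per_group, regions = regions,
                 n_features = n_features, base_alpha = base_alpha,
                 effect_delta = effect_delta, target_rois = target_rois,
                 covariate_params = covariate_params, G = G,
                 n_signal = n_signal, signal_snr = signal_snr,
                 n_donors = n_donors, samples_per_region = samples_per_region,
                 probes_per_gene = probes_per_gene,
                 background_rate = background_rate,
                 donor_coverage = donor_coverage,
                 probe_noise_sd = probe_noise_sd),
            class = "sim_params")
}

# truncated-normal draw by rejection; bounds may be one-sided
.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a biomarker-defined cohort with planted similarity effects
#'
#' Subject feature profiles follow a shared-component model: for subject s
#' and region i the 13-feature vector is
#' `sqrt(alpha_i) * l_si * g_s + sqrt(1 - alpha_i) * e_si` with `g_s` a
#' subject-level feature profile of unit-magnitude random-sign weights,
#' `l_si` a random region sign (+1 or -1), and `e_si` independent
#' standard-normal noise; each feature has unit variance and the shared
#' profile carries a fraction `alpha_i` of it. Unit-magnitude weights (not
#' Gaussian ones) let the inter-regional correlation reach 1 as `alpha`
#' does; Gaussian weights would leave near-zero-weight features as pure
#' noise and cap the similarity below 1. The
#' region sign matters: a sign-free shared term would be a constant
#' offset per feature column, which the pipeline's z-scoring removes exactly;
#' with it, the absolute inter-regional correlation approaches
#' `sqrt(alpha_i * alpha_j)`, so regional MS is increasing in `alpha` and
#' saturates at 1.
#' `alpha_i` equals `base_alpha` everywhere, plus `effect_delta` in the
#' target regions for positive-group subjects, so the group effect lives in
#' the similarity structure (not in feature means, which z-scoring removes).
#' Covariates are drawn per group from the configured means/SDs (MMSE
#' rounded and clipped to \[0, 30\]) and CSF concentrations are drawn inside
#' the group's classification region.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (optional).
#' @return List with `subjects` (covariate data frame) and `features`
#'   (named list of region-by-feature matrices).
#' @export
simulate_cohort <- function(params, seed = NULL) {
  .with_seed(seed, {
    groups <- rep(c("NEG_NEG", "POS_POS"), times = params$n_per_group)
    n <- length(groups)
    ids <- sprintf("S%04d", seq_len(n))
    cov <- lapply(seq_len(n), function(i) {
      cp <- params$covariate_params[[groups[i]]]
      mmse <- min(30, max(0, round(stats::rnorm(1, cp$mmse[1], cp$mmse[2]))))
      if (groups[i] == "NEG_NEG") {
        abeta <- .rtrunc_norm(1, 1400, 300, lower = 980)
        tau <- .rtrunc_norm(1, 18, 4, lower = 1, upper = 24)
      } else {
        abeta <- .rtrunc_norm(1, 650, 150, lower = 1, upper = 980 - 1e-9)
        tau <- .rtrunc_norm(1, 35, 10, lower = 24 + 1e-9)
      }
      data.frame(subject_id = ids[i], group = groups[i],
                 age = stats::rnorm(1, cp$age[1], cp$age[2]),
                 gender = if (stats::runif(1) < cp$p_male) "M" else "F",
                 education = stats::rnorm(1, cp$education[1], cp$education[2]),
                 mmse = mmse, abeta = abeta, tau = tau,
                 stringsAsFactors = FALSE)
    })
    subjects <- do.call(rbind, cov)
    R <- length(params$regions)
    alpha_base <- rep(params$base_alpha, R)
    target <- params$regions %in% params$target_rois
    features <- lapply(seq_len(n), function(i) {
      alpha <- alpha_base
      if (groups[i] == "POS_POS") alpha[target] <- alpha[target] + params$effect_delta
      g <- sample(c(-1, 1), params$n_features, replace = TRUE)
      loading <- sample(c(-1, 1), R, replace = TRUE)
      eps <- matrix(stats::rnorm(R * params$n_features), R, params$n_features)
      f <- (sqrt(alpha) * loading) %o% g + sqrt(1 - alpha) * eps
      dimnames(f) <- list(params$regions,
                          if (params$n_features == 13) msn_features()
                          else paste0("f", seq_len(params$n_features)))
      f
    })
    names(features) <- ids
    list(subjects = subjects, features = features)
  })
}

#' Simulate a region-by-gene expression matrix with planted signal genes
#'
#' Signal-gene columns equal the standardized planted pattern times
#' `signal_snr` (with a random sign, half positive, half negative) plus
#' standard-normal noise; null genes are pure noise. Every column is then
#' min-max rescaled to \[0, 1\].
#'
#' @param params A [sim_params()] object.
#' @param planted_pattern Length-34 nonconstant numeric vector, typically
#'   the regional contrast t-map.
#' @param seed Integer seed (optional).
#' @return List with `expr` (region-by-gene matrix in \[0, 1\]) and
#'   `signal` (data frame `gene`, `sign` in \{+1, -1\}).
#' @export
simulate_expression_matrix <- function(params, planted_pattern, seed = NULL) {
  if (stats::sd(planted_pattern) == 0) stop("planted pattern is constant",
                                            call. = FALSE)
  .with_seed(seed, {
    R <- length(params$regions)
    stopifnot(length(planted_pattern) == R)
    z <- as.vector(scale(planted_pattern))
    genes <- sprintf("g%05d", seq_len(params$G))
    sig_idx <- sample.int(params$G, 2 * params$n_signal)
    signs <- rep(c(1, -1), each = params$n_signal)
    expr <- matrix(stats::rnorm(R * params$G), R, params$G,
                   dimnames = list(params$regions, genes))
    expr[, sig_idx] <- expr[, sig_idx] +
      z %o% (signs * params$signal_snr)
    expr <- apply(expr, 2, function(x) (x - min(x)) / (max(x) - min(x)))
    rownames(expr) <- params$regions
    list(expr = expr,
         signal = data.frame(gene = genes[sig_idx], sign = signs,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate donor-level microarray samples from a ground-truth matrix
#'
#' Places the 34 region centroids on a 3-D grid with 20 mm spacing, lets
#' each donor sample a random subset of regions (`donor_coverage`) with
#' `samples_per_region` samples jittered at most 1 mm from the centroid,
#' and emits per-probe intensities as a donor-specific affine distortion of
#' the ground truth plus Gaussian noise. The first probe of each gene is
#' low-noise and more often flagged above background.
#'
#' @param params A [sim_params()] object.
#' @param expr Ground-truth region-by-gene matrix (values on the unit
#'   scale), rows named by region.
#' @param seed Integer seed (optional).
#' @return List with `samples` (long data frame `donor_id`, `sample_id`,
#'   `x`, `y`, `z`, `probe_id`, `intensity`, `above_background`),
#'   `probe_map` (`probe_id`, `gene_id`) and `centroids` (`roi`, `x`, `y`,
#'   `z`).
#' @export
simulate_donor_samples <- function(params, expr, seed = NULL) {
  rois <- rownames(expr)
  genes <- colnames(expr)
  .with_seed(seed, {
    grid <- expand.grid(x = seq(0, 100, by = 20), y = seq(0, 100, by = 20),
                        z = c(0, 20))
    centroids <- data.frame(roi = rois, grid[seq_along(rois), ],
                            stringsAsFactors = FALSE)
    rownames(centroids) <- NULL
    probe_map <- data.frame(
      probe_id = paste0("p_", rep(genes, each = params$probes_per_gene), "_",
                        rep(seq_len(params$probes_per_gene), length(genes))),
      gene_id = rep(genes, each = params$probes_per_gene),
      stringsAsFactors = FALSE)
    good <- rep(seq_len(params$probes_per_gene) == 1, length(genes))
    noise_sd <- ifelse(good, params$probe_noise_sd[1], params$probe_noise_sd[2])
    bg_rate <- ifelse(good, params$background_rate, params$background_rate / 2)
    n_cov <- max(3, round(params$donor_coverage * length(rois)))
    rows <- vector("list", params$n_donors)
    for (d in seq_len(params$n_donors)) {
      don <- sprintf("D%02d", d)
      gain <- exp(stats::rnorm(1, 0, 0.1))
      offset <- stats::rnorm(1, 0, 0.1)
      covered <- sort(sample.int(length(rois), n_cov))
      sample_rows <- vector("list", length(covered))
      for (ci in seq_along(covered)) {
        r <- covered[ci]
        per_region <- vector("list", params$samples_per_region)
        for (k in seq_len(params$samples_per_region)) {
          sid <- sprintf("%s_%s_%d", don, rois[r], k)
          jit <- stats::runif(3, -0.5, 0.5)
          truth <- expr[r, ]
          intensity <- gain * rep(truth, each = params$probes_per_gene) +
            offset + stats::rnorm(length(noise_sd), 0, noise_sd)
          per_region[[k]] <- data.frame(
            donor_id = don, sample_id = sid,
            x = centroids$x[r] + jit[1], y = centroids$y[r] + jit[2],
            z = centroids$z[r] + jit[3],
            probe_id = probe_map$probe_id,
            intensity = intensity,
            above_background = stats::rbinom(length(bg_rate), 1, bg_rate) == 1,
            stringsAsFactors = FALSE)
        }
        sample_rows[[ci]] <- do.call(rbind, per_region)
      }
      rows[[d]] <- do.call(rbind, sample_rows)
    }
    list(samples = do.call(rbind, rows), probe_map = probe_map,
         centroids = centroids)
  })
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds one enriched set per sign -- drawing `enrichment_fraction` of its
#' members from the same-signed planted signal genes and the rest uniformly
#' from the background -- plus `n_null` uniformly drawn null sets.
#'
#' @param signal Data frame `gene`, `sign` from
#'   [simulate_expression_matrix()].
#' @param background Background gene ids (must contain the signal genes).
#' @param set_size Genes per set (default 50).
#' @param n_null Number of null sets (default 5).
#' @param enrichment_fraction Fraction of an enriched set drawn from signal
#'   genes, in \[0, 1\] (default 0.5).
#' @param seed Integer seed (optional).
#' @return Collection as from [gene_set_collection()], with sets
#'   `enriched_plus`, `enriched_minus`, `null_01`, ...
#' @export
simulate_gene_sets <- function(signal, background, set_size = 50, n_null = 5,
                               enrichment_fraction = 0.5, seed = NULL) {
  stopifnot(enrichment_fraction >= 0, enrichment_fraction <= 1)
  if (set_size > length(background)) {
    stop("set_size exceeds the background", call. = FALSE)
  }
  .with_seed(seed, {
    draw_enriched <- function(sgn) {
      pool <- signal$gene[signal$sign == sgn]
      n_sig <- min(length(pool), round(enrichment_fraction * set_size))
      core <- sample(pool, n_sig)
      fill <- sample(setdiff(background, core), set_size - n_sig)
      c(core, fill)
    }
    sets <- list(enriched_plus = draw_enriched(1),
                 enriched_minus = draw_enriched(-1))
    for (k in seq_len(n_null)) {
      sets[[sprintf("null_%02d", k)]] <- sample(background, set_size)
    }
    gene_set_collection(sets, background)
  })
}
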