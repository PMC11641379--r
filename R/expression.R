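#' Filter microarray probes by above-background intensity
#'
#' A probe is retained when the fraction of tissue samples (pooled over
#' donors) in which its expression exceeds the background noise is at least
#' `min_fraction`. The comparison is inclusive, so a probe at exactly the
#' threshold fraction is kept.
#'
#' @param samples Long data frame with one row per (sample, probe) and
#'   columns `probe_id` and `above_background` (logical or 0/1).
#' @param min_fraction Minimum above-background fraction (default 0.5).
#' @return Character vector of retained probe ids.
#' @export
filter_probes_intensity <- function(samples, min_fraction = 0.5) {
  if (nrow(samples) == 0) stop("empty sample table", call. = FALSE)
  if (!all(c("probe_id", "above_background") %in% names(samples))) {
    stop("samples need columns probe_id and above_background", call. = FALSE)
  }
  frac <- tapply(as.numeric(samples$above_background), samples$probe_id, mean)
  names(frac)[frac >= min_fraction]
}

#' Assign tissue samples to atlas regions by centroid distance
#'
#' Each sample is assigned to the nearest region centroid provided the
#' Euclidean distance is within `radius` millimetres. Afterwards, for every
#' donor, any region left without samples receives that donor's single
#' globally nearest sample to its centroid, so every donor covers every
#' region.
#'
#' @param coords Data frame with one row per sample: `donor_id`,
#'   `sample_id`, `x`, `y`, `z` (same space as the centroids, mm).
#' @param centroids Data frame `roi`, `x`, `y`, `z` with the 34 canonical
#'   region labels.
#' @param radius Assignment radius in mm (default 2).
#' @return Data frame `donor_id`, `sample_id`, `roi`, `fallback` (logical);
#'   attribute `n_unassigned` counts samples outside every radius that were
#'   not recruited as fallbacks.
#' @export
assign_samples_to_regions <- function(coords, centroids, radius = 2) {
  if (nrow(coords) == 0) stop("no samples provided", call. = FALSE)
  unknown <- setdiff(centroids$roi, dk_rois())
  if (length(unknown) > 0) {
    stop("unknown region label(s) in centroids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cen <- as.matrix(centroids[, c("x", "y", "z")])
  pts <- as.matrix(coords[, c("x", "y", "z")])
  # all-pairs distances: samples x regions
  d2 <- outer(rowSums(pts^2), rowSums(cen^2), "+") - 2 * pts %*% t(cen)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  nearest <- max.col(-d, ties.method = "first")
  assigned_roi <- ifelse(d[cbind(seq_len(nrow(d)), nearest)] <= radius,
                         centroids$roi[nearest], NA_character_)
  out <- data.frame(donor_id = coords$donor_id, sample_id = coords$sample_id,
                    roi = assigned_roi, fallback = FALSE,
                    stringsAsFactors = FALSE)
  # per-donor fallback: empty regions recruit the donor's nearest sample
  extra <- list()
  for (don in unique(coords$donor_id)) {
    in_donor <- which(coords$donor_id == don)
    if (length(in_donor) == 0) stop("donor with zero samples: ", don, call. = FALSE)
    covered <- unique(out$roi[in_donor])
    for (j in which(!(centroids$roi %in% covered))) {
      best <- in_donor[which.min(d[in_donor, j])]
      extra[[length(extra) + 1]] <- data.frame(
        donor_id = don, sample_id = coords$sample_id[best],
        roi = centroids$roi[j], fallback = TRUE, stringsAsFactors = FALSE)
    }
  }
  used_fallback <- unique(unlist(lapply(extra, function(e)
    paste(e$donor_id, e$sample_id))))
  n_unassigned <- sum(is.na(out$roi) &
                      !(paste(out$donor_id, out$sample_id) %in% used_fallback))
  out <- rbind(out[!is.na(out$roi), , drop = FALSE], do.call(rbind, extra))
  if (n_unassigned > 0) {
    message(n_unassigned, " sample(s) beyond ", radius,
            " mm of every centroid and unused")
  }
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Mean expression per probe, region and donor
#'
#' Averages probe intensities over the samples assigned to each region,
#' separately per donor.
#'
#' @param samples Long data frame `donor_id`, `sample_id`, `probe_id`,
#'   `intensity`.
#' @param assignment Sample-to-region map from [assign_samples_to_regions()].
#' @return Named list (one element per donor) of probe-by-region matrices;
#'   regions follow the order of `rois`. Cells with no assigned samples are
#'   `NA`.
#' @param rois Region labels fixing column order (default [dk_rois()]).
#' @export
region_mean_expression <- function(samples, assignment, rois = dk_rois()) {
  donors <- sort(unique(assignment$donor_id))
  probes <- sort(unique(samples$probe_id))
  lapply(stats::setNames(donors, donors), function(don) {
    a <- assignment[assignment$donor_id == don, , drop = FALSE]
    s <- samples[samples$donor_id == don, , drop = FALSE]
    # a sample recruited as fallback for several regions contributes to each
    m <- matrix(NA_real_, length(probes), length(rois),
                dimnames = list(probes, rois))
    merged <- merge(s, a[, c("sample_id", "roi")], by = "sample_id")
    if (nrow(merged) > 0) {
      agg <- tapply(merged$intensity, list(merged$probe_id, merged$roi), mean)
      m[rownames(agg), colnames(agg)] <- agg
    }
    m
  })
}

#' Differential stability of probes across donors
#'
#' For each probe, the mean over all donor pairs of the Spearman rank
#' correlation between the two donors' regional expression profiles,
#' computed on the regions both donors sampled. Probes whose regional
#' profile is consistent across donors score near 1; the score selects the
#' representative probe per gene.
#'
#' @param donor_means Named list of probe-by-region matrices (one per
#'   donor), as from [region_mean_expression()]; `NA` marks unsampled
#'   regions.
#' @param min_common Minimum number of commonly sampled regions for a donor
#'   pair to count (default 3).
#' @return Named numeric vector of DS scores in \[-1, 1\], one per probe.
#' @export
differential_stability <- function(donor_means, min_common = 3) {
  if (length(donor_means) < 2) stop("need at least two donors", call. = FALSE)
  probes <- rownames(donor_means[[1]])
  pairs <- utils::combn(length(donor_means), 2)
  ds <- vapply(probes, function(pr) {
    vals <- numeric(0)
    for (k in seq_len(ncol(pairs))) {
      a <- donor_means[[pairs[1, k]]][pr, ]
      b <- donor_means[[pairs[2, k]]][pr, ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < min_common) next
      if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next  # rho undefined
      vals <- c(vals, stats::cor(a[ok], b[ok], method = "spearman"))
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  if (all(is.na(ds))) stop("no donor pair had enough usable regions", call. = FALSE)
  ds
}

#' Select one representative probe per gene by differential stability
#'
#' Keeps, for every gene, the probe with the highest DS score; ties break to
#' the lexicographically smallest probe id. Genes with no scored probe are
#' dropped with a message.
#'
#' @param ds Named DS score vector from [differential_stability()].
#' @param probe_map Data frame `probe_id`, `gene_id` (each probe maps to one
#'   gene).
#' @return Named character vector: selected probe id per gene.
#' @export
select_probe_per_gene <- function(ds, probe_map) {
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe_map must map each probe to exactly one gene", call. = FALSE)
  }
  ds <- ds[!is.na(ds)]
  pm <- probe_map[probe_map$probe_id %in% names(ds), , drop = FALSE]
  dropped <- setdiff(unique(probe_map$gene_id), unique(pm$gene_id))
  if (length(dropped) > 0) {
    message(length(dropped), " gene(s) with no retained probe dropped")
  }
  picked <- vapply(split(pm$probe_id, pm$gene_id), function(pr) {
    sc <- ds[pr]
    best <- pr[sc == max(sc)]
    sort(best)[1]
  }, character(1))
  picked
}

#' Scaled robust sigmoid normalization of one regional profile
#'
#' Outlier-resistant normalization: a logistic transform centred at the
#' median and scaled by IQR/1.35 (the IQR of a normal distribution is about
#' 1.35 standard deviations), followed by min-max rescaling to \[0, 1\] over
#' regions. Strictly monotone in the input.
#'
#' @param x Numeric vector of per-region values (length >= 3, IQR > 0).
#' @return Vector of the same length, min 0 and max 1.
#' @export
robust_sigmoid_normalize <- function(x) {
  if (length(x) < 3) stop("need at least 3 regions", call. = FALSE)
  if (anyNA(x)) stop("x must not contain NA", call. = FALSE)
  iqr <- stats::IQR(x)
  if (iqr == 0) stop("IQR is zero: degenerate profile", call. = FALSE)
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Average donor-normalized expression blocks
#'
#' Elementwise mean over donors of per-donor normalized region-by-gene
#' blocks; `NA` cells (genes dropped for a donor) are skipped. A cell with
#' no donor coverage at all is an error.
#'
#' @param blocks List of region-by-gene matrices with identical dimnames.
#' @return Region-by-gene matrix of donor means.
#' @export
aggregate_expression <- function(blocks) {
  if (length(blocks) == 0) stop("no donor blocks", call. = FALSE)
  acc <- array(0, dim(blocks[[1]]), dimnames(blocks[[1]]))
  cnt <- acc
  for (b in blocks) {
    ok <- !is.na(b)
    acc[ok] <- acc[ok] + b[ok]
    cnt <- cnt + ok
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)
    stop("region x gene cell(s) with no donor coverage, e.g. ",
         rownames(acc)[bad[1, 1]], " x ", colnames(acc)[bad[1, 2]],
         call. = FALSE)
  }
  acc / cnt
}

#' Donor microarray samples to a region-by-gene expression matrix
#'
#' Runs the full preprocessing chain: intensity-based probe filtering,
#' centroid-based assignment of samples to the 34 regions with per-donor
#' fallback, per-donor regional averaging, differential-stability probe
#' selection (one probe per gene), per-donor scaled robust sigmoid
#' normalization over regions, and unweighted donor averaging.
#'
#' @param samples Long data frame `donor_id`, `sample_id`, `x`, `y`, `z`,
#'   `probe_id`, `intensity`, `above_background`.
#' @param probe_map Data frame `probe_id`, `gene_id`.
#' @param centroids Data frame `roi`, `x`, `y`, `z`.
#' @param min_fraction Intensity-filter threshold (default 0.5).
#' @param radius Sample-assignment radius in mm (default 2).
#' @return Region-by-gene matrix (rows in [dk_rois()] order, values in
#'   \[0, 1\]); attribute `selected_probes` records the probe chosen per
#'   gene.
#' @export
prepare_expression <- function(samples, probe_map, centroids,
                               min_fraction = 0.5, radius = 2) {
  known <- samples$probe_id %in% probe_map$probe_id
  if (!all(known)) {
    message(sum(!known), " sample row(s) with unmapped probes dropped")
    samples <- samples[known, , drop = FALSE]
  }
  retained <- filter_probes_intensity(samples, min_fraction)
  if (length(retained) == 0) stop("no probe passed the intensity filter", call. = FALSE)
  samples <- samples[samples$probe_id %in% retained, , drop = FALSE]
  coords <- unique(samples[, c("donor_id", "sample_id", "x", "y", "z")])
  assignment <- assign_samples_to_regions(coords, centroids, radius)
  donor_means <- region_mean_expression(samples, assignment)
  ds <- differential_stability(donor_means)
  picked <- select_probe_per_gene(ds, probe_map)
  genes <- names(picked)
  rois <- dk_rois()
  blocks <- lapply(donor_means, function(m) {
    blk <- matrix(NA_real_, length(rois), length(genes),
                  dimnames = list(rois, genes))
    for (g in genes) {
      x <- m[picked[[g]], rois]
      if (anyNA(x)) next
      blk[, g] <- tryCatch(robust_sigmoid_normalize(x),
                           error = function(e) rep(NA_real_, length(x)))
    }
    blk
  })
  expr <- aggregate_expression(blocks)
  attr(expr, "selected_probes") <- picked
  expr
}

#' Read / write a region-by-gene expression matrix TSV
#'
#' The format has one header row (first column `roi`, remaining columns gene
#' ids) and one row per region.
#'
#' @param path TSV path.
#' @return `read_expression_matrix`: region-by-gene numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "roi") stop("first column must be 'roi'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$roi
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param expr Region-by-gene matrix with dimnames.
#' @return `write_expression_matrix`: `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(roi = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
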