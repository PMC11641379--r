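#' Z-score regional features across regions
#'
#' Normalizes each feature column of a region-by-feature matrix by
#' subtracting its mean and dividing by its sample standard deviation across
#' the regions, so that every feature contributes on a common scale to the
#' between-region correlation.
#'
#' @param x Numeric matrix, regions in rows, features in columns. Row names
#'   are region labels, column names feature names.
#' @return Matrix of the same shape; each column has mean 0 and sample SD 1.
#' @export
zscore_features <- function(x) {
  x <- .check_feature_matrix(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero-variance feature column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

.check_feature_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature table must be a numeric matrix (regions x features)",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("feature table contains missing or non-finite values", call. = FALSE)
  }
  x
}

#' Build a morphometric similarity network from a normalized feature table
#'
#' Computes the Pearson correlation between every pair of regional feature
#' profiles (rows), yielding a symmetric region-by-region similarity matrix
#' with unit diagonal -- the subject's morphometric similarity network.
#'
#' @param x Normalized region-by-feature matrix (see [zscore_features()]);
#'   at least two feature columns.
#' @return Symmetric numeric matrix (regions x regions), diagonal exactly 1.
#' @export
build_msn <- function(x) {
  x <- .check_feature_matrix(x)
  if (ncol(x) < 2) stop("need at least two features", call. = FALSE)
  row_sd <- apply(x, 1, stats::sd)
  bad <- row_sd == 0
  if (any(bad)) {
    nm <- rownames(x)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("region row(s) with zero variance across features: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(t(x))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Regional morphometric similarity
#'
#' Summarizes each region's overall similarity to the rest of the cortex as
#' the mean absolute off-diagonal correlation: for region i,
#' sum_{j != i} |m[i, j]| / (R - 1), where R is the number of regions.
#'
#' @param m Morphometric similarity network from [build_msn()].
#' @return Named numeric vector, one value in \[0, 1\] per region.
#' @export
regional_ms <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("m must be a square similarity matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) stop("m must be symmetric", call. = FALSE)
  a <- abs(m)
  diag(a) <- 0
  rowSums(a) / (nrow(m) - 1)
}

#' Read per-subject regional feature tables from a long TSV
#'
#' Expects columns `subject_id`, `roi`, `feature`, `value`. Each subject must
#' provide every canonical region exactly once per feature; tables are
#' reindexed to [dk_rois()] order (and to `features` order), and unknown
#' region labels are an error.
#'
#' @param path Path to the long-format TSV.
#' @param rois Canonical region labels (default [dk_rois()]).
#' @param features Expected feature names; default: the distinct feature
#'   names present, sorted to [msn_features()] order when they match it.
#' @return Named list of region-by-feature matrices, one per subject.
#' @export
load_feature_tables <- function(path, rois = dk_rois(), features = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "roi", "feature", "value")
  if (!all(needed %in% names(df))) {
    stop("feature TSV must have columns subject_id, roi, feature, value",
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$roi), rois)
  if (length(unknown) > 0) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(features)) {
    features <- unique(df$feature)
    if (setequal(features, msn_features())) features <- msn_features()
    else features <- sort(features)
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    m <- matrix(NA_real_, length(rois), length(features),
                dimnames = list(rois, features))
    idx <- cbind(match(d$roi, rois), match(d$feature, features))
    if (anyNA(idx)) stop("feature name not in expected set", call. = FALSE)
    m[idx] <- d$value
    if (anyNA(m)) {
      stop("subject ", d$subject_id[1], " is missing region x feature cells",
           call. = FALSE)
    }
    m
  })
  out[unique(df$subject_id)]
}

#' Write per-subject feature tables as a long TSV
#'
#' @param tables Named list of region-by-feature matrices.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tables <- function(tables, path) {
  rows <- lapply(names(tables), function(sid) {
    m <- tables[[sid]]
    data.frame(subject_id = sid,
               roi = rep(rownames(m), times = ncol(m)),
               feature = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compute regional morphometric similarity for every subject
#'
#' Convenience wrapper running [zscore_features()], [build_msn()] and
#' [regional_ms()] per subject.
#'
#' @param tables Named list of raw region-by-feature matrices.
#' @return Matrix, subjects in rows (named), regions in columns.
#' @export
regional_ms_table <- function(tables) {
  vals <- t(vapply(tables, function(m) regional_ms(build_msn(zscore_features(m))),
                   numeric(nrow(tables[[1]]))))
  rownames(vals) <- names(tables)
  vals
}
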