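# Evaluate code under a temporary RNG state so callers' streams are untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Standardize columns (mean 0, sample SD 1); zero-variance columns handled
# by the caller.
.standardize_cols <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  list(z = sweep(sweep(x, 2, mu, "-"), 2, sd, "/"), sd = sd)
}

#' One-component partial least squares with a univariate response
#'
#' Fits the first PLS component linking a region-by-gene expression matrix
#' (predictors) to a regional contrast map (response). Predictor columns are
#' standardized over regions and the response centred; the weight vector is
#' then the unit-normalized cross-covariance `t(X) %*% y` -- the direction
#' of maximal covariance with the response -- and the region scores are
#' `X %*% w`. Because a PLS component is sign-indeterminate, the component
#' is oriented so the score-response correlation is non-negative.
#'
#' @param X Region-by-gene numeric matrix (rows = regions); columns should
#'   be named with gene ids.
#' @param y Numeric response vector, one value per region (typically the
#'   per-region group t-statistics).
#' @param on_zero_variance What to do with zero-variance gene columns:
#'   `"drop"` (default, with a message) or `"error"`.
#' @return Object of class `"pls1"`: list with `weights` (unit norm, named),
#'   `scores` (length = regions), `r` (score-response Pearson correlation,
#'   >= 0), `r2`, `sign_flipped`, `dropped` (gene ids removed).
#' @export
fit_pls1 <- function(X, y, on_zero_variance = c("drop", "error")) {
  on_zero_variance <- match.arg(on_zero_variance)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0
  dropped <- character(0)
  if (any(zero)) {
    if (on_zero_variance == "error") {
      stop("zero-variance gene column(s): ",
           paste(utils::head(colnames(X)[zero], 5), collapse = ", "),
           call. = FALSE)
    }
    dropped <- colnames(X)[zero]
    message(length(dropped), " zero-variance gene column(s) dropped")
    X <- X[, !zero, drop = FALSE]
  }
  Xs <- .standardize_cols(X)$z
  yc <- y - mean(y)
  a <- drop(crossprod(Xs, yc))
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) stop("response is orthogonal to every predictor", call. = FALSE)
  w <- a / nrm
  scores <- drop(Xs %*% w)
  r <- stats::cor(scores, y)
  flipped <- r < 0
  if (flipped) {
    w <- -w
    scores <- -scores
    r <- -r
  }
  structure(list(weights = stats::setNames(w, colnames(X)),
                 scores = scores, r = r, r2 = r^2,
                 sign_flipped = flipped, dropped = dropped),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 fit:", length(x$weights), "genes,", length(x$scores), "regions\n")
  cat(sprintf("  score-response r = %.4f (r^2 = %.4f)\n", x$r, x$r2))
  invisible(x)
}

# score-response |r| for a permuted response; Xs already standardized
.pls1_stat <- function(Xs, y) {
  yc <- y - mean(y)
  a <- drop(crossprod(Xs, yc))
  t <- drop(Xs %*% a)
  s <- sqrt(sum(t^2)) * sqrt(sum(yc^2))
  if (s == 0) return(0)
  abs(sum(t * yc) / s)
}

#' Permutation test for the PLS score-response association
#'
#' Tests the significance of the one-component PLS association by permuting
#' the response values over regions and refitting; the test statistic is the
#' score-response correlation after the sign convention (always
#' non-negative). The Monte-Carlo p-value uses the add-one estimator
#' `(1 + #extreme) / (n_perm + 1)`. With `exact = TRUE`, all permutations of
#' the response are enumerated (feasible for few regions only) and
#' `p = #extreme / n!` with the identity permutation included.
#'
#' @param X Region-by-gene matrix (see [fit_pls1()]); zero-variance columns
#'   are dropped.
#' @param y Response vector.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed for the permutation stream (optional).
#' @param exact Enumerate all permutations instead of sampling.
#' @return List with `observed_stat`, `n_perm`, `n_at_least_as_extreme`,
#'   `p`, `exact`.
#' @export
permutation_test <- function(X, y, n_perm = 10000, seed = NULL, exact = FALSE) {
  fit <- suppressMessages(fit_pls1(X, y))
  keep <- setdiff(colnames(X), fit$dropped)
  Xk <- if (is.null(colnames(X))) X else X[, keep, drop = FALSE]
  Xs <- .standardize_cols(Xk)$z
  obs <- fit$r
  n <- length(y)
  eps <- 1e-12
  if (exact) {
    if (n > 9) stop("exact enumeration limited to 9 regions", call. = FALSE)
    perms <- .all_permutations(n)
    stats_all <- apply(perms, 1, function(ix) .pls1_stat(Xs, y[ix]))
    hits <- sum(stats_all >= obs - eps)
    return(list(observed_stat = obs, n_perm = nrow(perms),
                n_at_least_as_extreme = hits, p = hits / nrow(perms),
                exact = TRUE))
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  hits <- .with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      if (.pls1_stat(Xs, y[sample.int(n)]) >= obs - eps) h <- h + 1L
    }
    h
  })
  list(observed_stat = obs, n_perm = n_perm, n_at_least_as_extreme = hits,
       p = (1 + hits) / (n_perm + 1), exact = FALSE)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Bootstrap z-scores for PLS gene weights
#'
#' Quantifies each gene's contribution to the PLS component as
#' `z = weight / SE`, where the standard error is the standard deviation of
#' the gene's weight over bootstrap replicates obtained by resampling the
#' regions with replacement. Within each replicate the predictor columns are
#' re-standardized and the component refit; the replicate weight vector is
#' sign-aligned to the original (negated when its dot product with the
#' original weights is negative) because PLS components are
#' sign-indeterminate and unaligned replicates would inflate the SE.
#'
#' @param X Region-by-gene matrix.
#' @param y Response vector.
#' @param n_boot Number of bootstrap replicates (default 1000; >= 100
#'   recommended).
#' @param seed Integer seed for the resampling stream (optional).
#' @param max_retries Redraws allowed per replicate when a resample is
#'   degenerate (fewer than 3 distinct regions, a zero-variance column, or a
#'   constant response) before erroring (default 100).
#' @return Data frame `gene`, `weight`, `se`, `z`; genes with `se == 0`
#'   carry `z = NA` and are excluded from list selection.
#' @export
bootstrap_gene_zscores <- function(X, y, n_boot = 1000, seed = NULL,
                                   max_retries = 100) {
  fit <- suppressMessages(fit_pls1(X, y))
  keep <- setdiff(colnames(X), fit$dropped)
  Xk <- if (is.null(colnames(X))) X else X[, keep, drop = FALSE]
  w0 <- fit$weights
  n <- nrow(Xk)
  g <- ncol(Xk)
  sums <- .with_seed(seed, {
    s1 <- numeric(g)
    s2 <- numeric(g)
    for (b in seq_len(n_boot)) {
      wb <- NULL
      for (try in seq_len(max_retries)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) < 3) next
        Xb <- Xk[idx, , drop = FALSE]
        sdc <- apply(Xb, 2, stats::sd)
        yb <- y[idx]
        if (any(sdc == 0) || stats::sd(yb) == 0) next
        Xbs <- sweep(sweep(Xb, 2, colMeans(Xb), "-"), 2, sdc, "/")
        a <- drop(crossprod(Xbs, yb - mean(yb)))
        nrm <- sqrt(sum(a^2))
        if (nrm == 0) next
        wb <- a / nrm
        break
      }
      if (is.null(wb)) stop("could not draw a non-degenerate bootstrap resample",
                            call. = FALSE)
      if (sum(wb * w0) < 0) wb <- -wb  # sign alignment
      s1 <- s1 + wb
      s2 <- s2 + wb^2
    }
    list(s1 = s1, s2 = s2)
  })
  se <- sqrt(pmax(0, (sums$s2 - sums$s1^2 / n_boot) / (n_boot - 1)))
  z <- ifelse(se > 0, w0 / se, NA_real_)
  n_flag <- sum(se == 0)
  if (n_flag > 0) message(n_flag, " gene(s) with zero bootstrap SE flagged")
  data.frame(gene = names(w0), weight = unname(w0), se = se, z = unname(z),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the positively and negatively weighted gene lists
#'
#' Converts bootstrap z-scores to two-sided normal-tail p-values, adjusts
#' them by Benjamini-Hochberg over all scored genes, and selects the
#' positive list (z > `z_threshold`, q < `q_threshold`) and the negative
#' list (z < -`z_threshold`, q < `q_threshold`). Threshold comparisons are
#' strict. Both lists are sorted by |z| descending.
#'
#' @param scores Data frame from [bootstrap_gene_zscores()].
#' @param z_threshold Absolute z cut (default 3).
#' @param q_threshold FDR cut (default 0.05).
#' @return List with `plus` and `minus` (character vectors of gene ids) and
#'   `table` (the input plus `p`, `q`, `set` columns).
#' @export
select_gene_sets <- function(scores, z_threshold = 3, q_threshold = 0.05) {
  tab <- scores
  tab$p <- rep(NA_real_, nrow(tab))
  tab$q <- rep(NA_real_, nrow(tab))
  ok <- is.finite(tab$z)
  tab$p[ok] <- 2 * stats::pnorm(-abs(tab$z[ok]))
  tab$q[ok] <- bh_fdr(tab$p[ok])
  tab$set <- rep("NONE", nrow(tab))
  tab$set[ok & tab$z > z_threshold & tab$q < q_threshold] <- "PLS_PLUS"
  tab$set[ok & tab$z < -z_threshold & tab$q < q_threshold] <- "PLS_MINUS"
  ord <- function(sel) {
    d <- tab[sel, , drop = FALSE]
    d$gene[order(-abs(d$z))]
  }
  list(plus = ord(tab$set == "PLS_PLUS"),
       minus = ord(tab$set == "PLS_MINUS"),
       table = tab)
}
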