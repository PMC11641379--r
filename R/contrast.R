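#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR, clipped to at most 1.
#' Thin wrapper over `stats::p.adjust(method = "BH")` that validates its
#' input; exposed because every stage of the pipeline adjusts within its own
#' test family.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))
bh_fdr <- function(p) {
  .check_prob(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted group contrast of one region's morphometric similarity
#'
#' Fits ordinary least squares of the regional MS values on group membership
#' (POS_POS coded 1, NEG_NEG 0) plus age, gender (M = 1, F = 0), education
#' and MMSE, and returns the group coefficient with its t-statistic and
#' two-sided p-value. A positive t means higher regional MS in the
#' biomarker-positive group.
#'
#' @param ms Numeric vector of per-subject regional MS values for one region.
#' @param subjects Data frame of subject records aligned with `ms`
#'   (columns `group`, and unless `covariates = FALSE` also `age`, `gender`,
#'   `education`, `mmse`). `EXCLUDED` subjects must be removed beforehand.
#' @param covariates If `FALSE`, fit the group term only (a two-sample
#'   comparison); default `TRUE`.
#' @return List with `beta_group`, `se`, `t`, `p`, `df`.
#' @export
fit_roi_model <- function(ms, subjects, covariates = TRUE) {
  if (length(ms) != nrow(subjects)) {
    stop("ms and subjects must be aligned", call. = FALSE)
  }
  if (!all(subjects$group %in% c("NEG_NEG", "POS_POS"))) {
    stop("subjects must be NEG_NEG or POS_POS (drop EXCLUDED first)",
         call. = FALSE)
  }
  grp <- as.numeric(subjects$group == "POS_POS")
  if (length(unique(grp)) < 2) stop("both groups must be represented", call. = FALSE)
  dat <- if (covariates) {
    data.frame(ms = ms, group = grp, age = subjects$age,
               gender = .gender_numeric(subjects$gender),
               education = subjects$education, mmse = subjects$mmse)
  } else {
    data.frame(ms = ms, group = grp)
  }
  if (nrow(dat) < ncol(dat) + 1) stop("too few subjects for the model", call. = FALSE)
  if (stats::sd(ms) == 0) {  # constant response: no effect by definition
    return(list(beta_group = 0, se = 0, t = 0, p = 1,
                df = nrow(dat) - ncol(dat) - 1))
  }
  fit <- stats::lm(ms ~ ., data = dat)
  if (anyNA(stats::coef(fit))) stop("design matrix is rank deficient", call. = FALSE)
  s <- summary(fit)$coefficients
  tval <- unname(s["group", "t value"])
  pval <- unname(s["group", "Pr(>|t|)"])
  if (is.nan(tval)) {  # zero residual variance and zero effect
    tval <- 0
    pval <- 1
  }
  list(beta_group = unname(s["group", "Estimate"]),
       se = unname(s["group", "Std. Error"]),
       t = tval, p = pval, df = fit$df.residual)
}

#' Regional-MS group contrast map with FDR adjustment
#'
#' Runs the covariate-adjusted group model of [fit_roi_model()] for every
#' region (all regions share one design matrix, solved jointly), and adjusts
#' the two-sided p-values across regions by Benjamini-Hochberg. The
#' t-statistics form the response map for the downstream transcriptomic
#' association.
#'
#' @param ms_table Subjects-by-regions matrix of regional MS values with
#'   subject ids as row names (see [regional_ms_table()]).
#' @param subjects Data frame of subject records with `subject_id`; rows are
#'   matched to `ms_table` by id, and `EXCLUDED` subjects are dropped.
#' @return Data frame with columns `roi`, `t`, `p`, `q`, `direction`
#'   (`"up"` where t > 0), plus attributes `n_subjects` and `model_df`.
#' @export
contrast_map <- function(ms_table, subjects) {
  if (is.null(rownames(ms_table))) stop("ms_table must have subject row names",
                                        call. = FALSE)
  subjects <- subjects[subjects$group != "EXCLUDED", , drop = FALSE]
  idx <- match(subjects$subject_id, rownames(ms_table))
  if (anyNA(idx)) {
    stop("subject id(s) missing from ms_table: ",
         paste(subjects$subject_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  y <- ms_table[idx, , drop = FALSE]
  x <- cbind(intercept = 1,
             group = as.numeric(subjects$group == "POS_POS"),
             age = subjects$age,
             gender = .gender_numeric(subjects$gender),
             education = subjects$education,
             mmse = subjects$mmse)
  if (length(unique(x[, "group"])) < 2) {
    stop("both groups must be represented", call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  if (n < k + 2) stop("too few subjects for the model", call. = FALSE)
  xtx <- crossprod(x)
  xtx_inv <- tryCatch(chol2inv(chol(xtx)),
                      error = function(e) stop("design matrix is rank deficient",
                                               call. = FALSE))
  beta <- xtx_inv %*% crossprod(x, y)
  res <- y - x %*% beta
  sigma2 <- colSums(res^2) / (n - k)
  se_g <- sqrt(xtx_inv[2, 2] * sigma2)
  tval <- beta[2, ] / se_g
  tval[is.nan(tval)] <- 0  # zero residual variance and zero effect
  p <- 2 * stats::pt(-abs(tval), df = n - k)
  out <- data.frame(roi = colnames(ms_table), t = unname(tval), p = unname(p),
                    q = bh_fdr(unname(p)),
                    direction = ifelse(tval > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "n_subjects") <- n
  attr(out, "model_df") <- n - k
  out
}
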