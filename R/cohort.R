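#' Classify a subject's biomarker status from CSF amyloid-beta and tau
#'
#' Applies the cerebrospinal-fluid thresholds used to define the biomarker
#' groups: a subject is amyloid- and tau-negative (`"NEG_NEG"`) when
#' CSF amyloid-beta is at or above `abeta_threshold` and CSF tau at or below
#' `tau_threshold`; amyloid- and tau-positive (`"POS_POS"`) when both
#' comparisons go the other way (strictly). Mixed profiles (one marker
#' positive, the other negative) are labelled `"EXCLUDED"` and dropped from
#' downstream group analyses.
#'
#' @param abeta CSF amyloid-beta concentration(s) in pg/mL; finite, positive.
#' @param tau CSF tau concentration(s) in pg/mL; finite, positive.
#' @param abeta_threshold Amyloid threshold in pg/mL (default 980).
#' @param tau_threshold Tau threshold in pg/mL (default 24).
#' @return Character vector with values `"NEG_NEG"`, `"POS_POS"` or
#'   `"EXCLUDED"`, vectorized over the inputs.
#' @export
#' @examples
#' classify_csf_status(1000, 20)  # "NEG_NEG"
#' classify_csf_status(900, 30)   # "POS_POS"
#' classify_csf_status(1000, 30)  # "EXCLUDED"
classify_csf_status <- function(abeta, tau, abeta_threshold = 980,
                                tau_threshold = 24) {
  if (!is.numeric(abeta) || !is.numeric(tau)) {
    stop("abeta and tau must be numeric", call. = FALSE)
  }
  if (length(abeta) != length(tau)) {
    stop("abeta and tau must have the same length", call. = FALSE)
  }
  if (anyNA(abeta) || anyNA(tau) || any(!is.finite(abeta)) ||
      any(!is.finite(tau)) || any(abeta <= 0) || any(tau <= 0)) {
    stop("CSF concentrations must be finite and positive", call. = FALSE)
  }
  ifelse(abeta >= abeta_threshold & tau <= tau_threshold, "NEG_NEG",
         ifelse(abeta < abeta_threshold & tau > tau_threshold, "POS_POS",
                "EXCLUDED"))
}

#' Read a subject covariate table and assign biomarker groups
#'
#' The table must be tab-separated with a header and columns `subject_id`,
#' `age`, `gender` (M/F), `education`, `mmse`, and either a `group` column
#' or both `abeta` and `tau` (pg/mL), from which the group is derived with
#' [classify_csf_status()].
#'
#' @param path Path to a TSV file.
#' @param abeta_threshold,tau_threshold Passed to [classify_csf_status()]
#'   when the group must be derived.
#' @return A data frame of subject records with a `group` column; attribute
#'   `n_excluded` counts mixed-profile subjects retained in the table but
#'   flagged `"EXCLUDED"`.
#' @export
load_covariate_table <- function(path, abeta_threshold = 980,
                                 tau_threshold = 24) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("subject_id", "age", "gender", "education", "mmse")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("covariate table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  has_group <- "group" %in% names(df)
  has_csf <- all(c("abeta", "tau") %in% names(df))
  if (!has_group && !has_csf) {
    stop("covariate table needs either a 'group' column or both 'abeta' and 'tau'",
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in c("age", "education", "mmse", intersect(c("abeta", "tau"), names(df)))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      if (anyNA(v)) stop("unparseable numeric in column '", col, "'", call. = FALSE)
      df[[col]] <- v
    }
    if (anyNA(df[[col]])) stop("missing values in column '", col, "'", call. = FALSE)
  }
  if (any(df$mmse < 0 | df$mmse > 30)) {
    stop("mmse must lie in [0, 30]", call. = FALSE)
  }
  if (!all(df$gender %in% c("M", "F"))) {
    stop("gender must be 'M' or 'F'", call. = FALSE)
  }
  derived <- if (has_csf) classify_csf_status(df$abeta, df$tau,
                                              abeta_threshold, tau_threshold)
             else NULL
  if (has_group) {
    if (!all(df$group %in% c("NEG_NEG", "POS_POS", "EXCLUDED"))) {
      stop("group must be NEG_NEG, POS_POS or EXCLUDED", call. = FALSE)
    }
    if (has_csf && any(df$group != derived)) {
      bad <- df$subject_id[df$group != derived]
      stop("group label inconsistent with CSF values for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    df$group <- derived
  }
  n_excl <- sum(df$group == "EXCLUDED")
  if (n_excl > 0) {
    message(n_excl, " subject(s) with mixed CSF profiles labelled EXCLUDED")
  }
  attr(df, "n_excluded") <- n_excl
  df
}

#' Write a subject covariate table
#'
#' Inverse of [load_covariate_table()]; round-trips all columns.
#'
#' @param subjects Data frame of subject records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_covariate_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# numeric gender coding used by the group-contrast design matrix: M = 1, F = 0
.gender_numeric <- function(gender) {
  if (!all(gender %in% c("M", "F"))) stop("gender must be 'M' or 'F'", call. = FALSE)
  as.numeric(gender == "M")
}
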