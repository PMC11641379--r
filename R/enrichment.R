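#' Read a GMT gene-set file
#'
#' Each line holds a set name, a description, and one or more tab-separated
#' gene ids. Duplicate genes within a line are collapsed with a message;
#' lines with fewer than three fields are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene sets); set descriptions in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, ": fewer than 3 fields",
                            call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      message("duplicate genes deduplicated in set '", f[1], "'")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors; optional `descriptions`
#'   attribute (defaults to the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a background
#'
#' Builds a collection whose sets are all subsets of the supplied background
#' (genes outside it are removed); sets left empty are dropped with a
#' message.
#'
#' @param sets Named list of character vectors.
#' @param background Character vector of background gene ids.
#' @return List with `sets` (restricted, non-empty) and `background`.
#' @export
gene_set_collection <- function(sets, background) {
  background <- unique(background)
  restricted <- lapply(sets, function(g) intersect(unique(g), background))
  empty <- lengths(restricted) == 0
  if (any(empty)) {
    message(sum(empty), " empty set(s) dropped after background restriction: ",
            paste(names(restricted)[empty], collapse = ", "))
  }
  list(sets = restricted[!empty], background = background)
}

#' Merge study-specific cell-type gene lists into one collection
#'
#' Unions the gene lists per cell-type label across studies, removes
#' unwanted labels (e.g. cell types reported by a single study or neuron
#' lists without an excitatory/inhibitory split), and restricts every set to
#' the expression background.
#'
#' @param study_lists Data frame with columns `study_id`, `cell_label`,
#'   `gene`.
#' @param background Background gene ids.
#' @param drop_labels Cell-type labels to exclude (default none).
#' @return A collection as from [gene_set_collection()].
#' @export
compile_cell_type_sets <- function(study_lists, background,
                                   drop_labels = character(0)) {
  keep <- !(study_lists$cell_label %in% drop_labels)
  merged <- lapply(split(study_lists$gene[keep], study_lists$cell_label[keep]),
                   unique)
  gene_set_collection(merged, background)
}

#' Merge disease gene lists into one background-restricted set
#'
#' @param source_lists List of character vectors (one per source).
#' @param background Background gene ids.
#' @return Character vector: the deduplicated union intersected with the
#'   background. Empty result is an error.
#' @export
compile_disease_set <- function(source_lists, background) {
  if (length(source_lists) == 0) stop("no source lists", call. = FALSE)
  out <- intersect(unique(unlist(source_lists)), unique(background))
  if (length(out) == 0) stop("disease set empty after background restriction",
                             call. = FALSE)
  out
}

#' Fisher overlap test of two gene sets against a background
#'
#' One-sided (enrichment) Fisher's exact test of the overlap between a query
#' list and a target set given a background universe: with
#' a = |query & target| the p-value is the hypergeometric upper tail
#' P(X >= a). The reported odds ratio is the sample estimate
#' a*d / (b*c) from the 2x2 table (not the conditional-MLE some tools
#' print), with `Inf` when b*c = 0 and a*d > 0, and 0 when a = 0.
#'
#' @param query,target Character vectors, both subsets of `background`.
#' @param background Background gene universe.
#' @param query_name,target_name Labels carried into the output row.
#' @return One-row data frame: `query`, `set`, `n_query`, `n_set`,
#'   `n_background`, `n_overlap`, `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(query, target, background,
                               query_name = "query", target_name = "target") {
  query <- unique(query)
  target <- unique(target)
  background <- unique(background)
  if (!all(query %in% background) || !all(target %in% background)) {
    stop("query and target must be subsets of the background", call. = FALSE)
  }
  N <- length(background)
  a <- length(intersect(query, target))
  b <- length(query) - a
  cc <- length(target) - a
  d <- N - a - b - cc
  p <- stats::phyper(a - 1, length(target), N - length(target), length(query),
                     lower.tail = FALSE)
  or <- if (a == 0) 0
        else if (b * cc == 0) Inf
        else (a * d) / (b * cc)
  data.frame(query = query_name, set = target_name,
             n_query = length(query), n_set = length(target),
             n_background = N, n_overlap = a, odds_ratio = or, p = p,
             stringsAsFactors = FALSE)
}

#' Overrepresentation table for query gene lists against a collection
#'
#' Tests every (query, set) pair by [overlap_enrichment()] and adjusts the
#' p-values by Benjamini-Hochberg within each query across the sets of this
#' collection (never pooled across collections). Query genes outside the
#' background are dropped with a message.
#'
#' @param queries Named list of character vectors (e.g. the positive and
#'   negative PLS gene lists).
#' @param collection Collection from [gene_set_collection()].
#' @return Data frame with one row per query x set, columns of
#'   [overlap_enrichment()] plus `q` and `significant` (q < 0.05).
#' @export
enrichment_table <- function(queries, collection) {
  bg <- collection$background
  rows <- lapply(names(queries), function(qn) {
    qg <- unique(queries[[qn]])
    out <- setdiff(qg, bg)
    if (length(out) > 0) {
      message(length(out), " query gene(s) outside the background dropped (",
              qn, ")")
      qg <- intersect(qg, bg)
    }
    recs <- do.call(rbind, lapply(names(collection$sets), function(sn) {
      overlap_enrichment(qg, collection$sets[[sn]], bg, qn, sn)
    }))
    recs$q <- bh_fdr(recs$p)
    recs
  })
  out <- do.call(rbind, rows)
  out$significant <- out$q < 0.05
  out
}
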