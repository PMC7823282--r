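#' Two-condition RNA-seq count matrix
#'
#' Container for a gene-by-sample matrix of non-negative integer read counts
#' together with a two-level sample-to-condition design. This is the single
#' input object consumed by the filtering, calling, concordance and
#' evaluation layers.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). Values must be
#'   non-negative and integral; small rounding error (|x - round(x)| <= 1e-6)
#'   from preprocessed public matrices is tolerated and rounded.
#' @param design Named character vector (or two-column data.frame with
#'   columns `sample_id`, `condition`) mapping every sample identifier to one
#'   of exactly two condition labels.
#' @return An object of class `count_matrix` with elements `counts` (integer
#'   storage) and `design` (named character vector).
#' @examples
#' m <- matrix(rpois(8, 10), 2, 4,
#'             dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
#' cm <- count_matrix(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
#' conditions(cm)
#' @export
count_matrix <- function(counts, design) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    cdeg_stop("`counts` must be a numeric matrix", "validation_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    cdeg_stop("`counts` must have gene rownames and sample colnames",
              "validation_error")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    cdeg_stop(sprintf("duplicated gene ids: %s",
                      paste(utils::head(dup, 5), collapse = ", ")),
              "validation_error")
  }
  if (anyDuplicated(colnames(counts))) {
    cdeg_stop("duplicated sample ids in count matrix", "validation_error")
  }
  if (is.data.frame(design)) {
    if (!all(c("sample_id", "condition") %in% names(design))) {
      cdeg_stop("design data.frame needs columns sample_id and condition",
                "design_error")
    }
    design <- stats::setNames(as.character(design$condition),
                              as.character(design$sample_id))
  }
  if (is.null(names(design)) || anyDuplicated(names(design))) {
    cdeg_stop("design must map unique sample ids to conditions",
              "design_error")
  }
  design <- stats::setNames(as.character(design), names(design))
  miss_in_design <- setdiff(colnames(counts), names(design))
  miss_in_counts <- setdiff(names(design), colnames(counts))
  if (length(miss_in_design) || length(miss_in_counts)) {
    cdeg_stop(sprintf(
      "samples must match between counts and design (missing in design: %s; missing in counts: %s)",
      paste(miss_in_design, collapse = ",") , paste(miss_in_counts, collapse = ",")),
      "design_error")
  }
  lev <- sort(unique(design))
  if (length(lev) != 2L) {
    cdeg_stop(sprintf("design must have exactly 2 condition levels, found %d (%s)",
                      length(lev), paste(lev, collapse = ", ")), "design_error")
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    cdeg_stop(sprintf("negative or non-finite count for gene '%s', sample '%s'",
                      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
              "validation_error")
  }
  off <- abs(counts - round(counts))
  if (any(off > 1e-6)) {
    bad <- which(off > 1e-6, arr.ind = TRUE)
    cdeg_stop(sprintf("non-integer count %.6g for gene '%s', sample '%s'",
                      counts[bad[1, , drop = FALSE]],
                      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
              "validation_error")
  }
  storage <- round(counts)
  design <- design[colnames(storage)]
  structure(list(counts = storage, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$design)
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Condition levels of a count matrix
#'
#' Returns the two condition labels in sorted order. The first level is the
#' fold-change numerator ("condition A") throughout the package.
#'
#' @param x A `count_matrix`.
#' @return Character vector of length 2.
#' @export
conditions <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  sort(unique(x$design))
}

#' Gene and sample identifiers
#' @param x A `count_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset a count matrix
#'
#' @param x A `count_matrix`.
#' @param genes,samples Character vectors of identifiers to retain (order
#'   preserved as given). `NULL` keeps all.
#' @return A `count_matrix`.
#' @export
subset_count_matrix <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  g <- genes %||% gene_ids(x)
  s <- samples %||% sample_ids(x)
  if (!all(g %in% gene_ids(x))) {
    cdeg_stop("unknown gene ids in subset", "validation_error")
  }
  if (!all(s %in% sample_ids(x))) {
    cdeg_stop("unknown sample ids in subset", "validation_error")
  }
  cts <- x$counts[g, s, drop = FALSE]
  # a subset used for a single hold-out pair keeps its two-level design even
  # when one condition ends up with a single sample
  count_matrix(cts, x$design[s])
}

# samples belonging to each condition, as a named list(A = ..., B = ...)
.condition_samples <- function(x) {
  lev <- conditions(x)
  list(A = names(x$design)[x$design == lev[1]],
       B = names(x$design)[x$design == lev[2]])
}

# library sizes (column sums of raw counts)
.library_sizes <- function(x) colSums(x$counts)
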