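# Pairwise Jaccard concordance between per-method DEG sets within a filter
# region, the symmetric concordance matrix, and its median summary.

#' Jaccard index between two gene sets
#'
#' `|M n N| / |M u N|`. When both sets are empty the index is undefined
#' (`NA`): no predictions were made, so concordance cannot be assessed.
#' When exactly one set is empty the index is a defined 0.
#'
#' @param m,n Character vectors of gene ids (duplicates ignored).
#' @return A value in `[0, 1]`, or `NA` when both sets are empty.
#' @export
jaccard_index <- function(m, n) {
  m <- unique(as.character(m))
  n <- unique(as.character(n))
  u <- length(union(m, n))
  if (u == 0L) return(NA_real_)
  length(intersect(m, n)) / u
}

#' Pairwise concordance matrix for one region
#'
#' Computes the Jaccard index for every unordered pair of methods (each pair
#' once, mirrored into a symmetric matrix), the region median over the
#' defined pair values, and per-method medians (diagnostic only).
#'
#' @param deg_sets List of >= 2 [deg_set()] objects for one region.
#' @return Object of class `concordance_matrix`: list with `region_id`,
#'   `methods`, `matrix` (symmetric; diagonal 1 for non-empty sets, `NA`
#'   for empty ones), `pairs` (long data.frame `method_a`, `method_b`,
#'   `jaccard`), `median`, `per_method_median`.
#' @export
concordance_matrix <- function(deg_sets) {
  if (!is.list(deg_sets) || length(deg_sets) < 2L) {
    cdeg_stop("concordance needs >= 2 method DEG sets", "config_error")
  }
  stopifnot(all(vapply(deg_sets, inherits, logical(1), "deg_set")))
  ids <- vapply(deg_sets, function(s) s$method_id, character(1))
  if (anyDuplicated(ids)) {
    cdeg_stop("duplicate method ids in concordance input", "config_error")
  }
  k <- length(ids)
  mat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  pairs <- utils::combn(k, 2L)
  pa <- character(ncol(pairs)); pb <- character(ncol(pairs))
  pj <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    v <- jaccard_index(deg_sets[[i]]$genes, deg_sets[[j]]$genes)
    mat[i, j] <- v
    mat[j, i] <- v
    pa[c] <- ids[i]; pb[c] <- ids[j]; pj[c] <- v
  }
  for (i in seq_len(k)) {
    mat[i, i] <- if (length(deg_sets[[i]]$genes) > 0L) 1 else NA_real_
  }
  per_method <- vapply(seq_len(k), function(i) {
    offdiag <- mat[i, -i]
    if (all(is.na(offdiag))) NA_real_ else stats::median(offdiag, na.rm = TRUE)
  }, numeric(1))
  names(per_method) <- ids
  structure(list(
    region_id = deg_sets[[1L]]$region_id,
    methods = ids,
    matrix = mat,
    pairs = data.frame(method_a = pa, method_b = pb, jaccard = pj,
                       stringsAsFactors = FALSE),
    median = if (all(is.na(pj))) NA_real_ else stats::median(pj, na.rm = TRUE),
    per_method_median = per_method
  ), class = "concordance_matrix")
}

#' Region median concordance
#'
#' Median over the defined unordered pairwise Jaccard values (each pair
#' counted once); `NA` if every pair is undefined.
#'
#' @param x A `concordance_matrix`.
#' @return A value in `[0, 1]` or `NA`.
#' @export
median_concordance <- function(x) {
  stopifnot(inherits(x, "concordance_matrix"))
  x$median
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("concordance_matrix (%s): %d methods, %d pairs, median %s\n",
              x$region_id %||% "unlabelled", length(x$methods),
              nrow(x$pairs),
              ifelse(is.na(x$median), "undefined", format(x$median, digits = 3))))
  invisible(x)
}

#' Export a concordance grid in long format
#'
#' Writes one row per (cutoff, window, method pair) with its Jaccard value;
#' undefined entries are written as empty fields, mirroring the blank/white
#' cells of the heatmap rendering.
#'
#' @param grid Output of [concordance_grid()].
#' @param path Output TSV path.
#' @return Invisibly, the long data.frame.
#' @export
export_concordance_grid <- function(grid, path) {
  stopifnot(inherits(grid, "concordance_grid"))
  utils::write.table(grid$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(grid$pairs)
}

#' Heatmap-grid rendering of pairwise concordances
#'
#' One heatmap tile per method pair, faceted by expression cutoff and
#' fold-change window; undefined cells (no predictions by either method)
#' are blank. Requires ggplot2.
#'
#' @param grid Output of [concordance_grid()].
#' @return A ggplot object.
#' @export
plot_concordance_grid <- function(grid) {
  stopifnot(inherits(grid, "concordance_grid"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    cdeg_stop("ggplot2 is required for plotting", "capability_error")
  }
  d <- grid$pairs
  d$pair <- paste(d$method_a, d$method_b, sep = " / ")
  d$cutoff_f <- factor(d$cutoff, levels = sort(unique(d$cutoff)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cutoff_f, y = .data$pair,
                                  fill = .data$jaccard)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::facet_wrap(~window, nrow = 1) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = "expression cutoff", y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal()
}
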