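# Per-gene expression summaries, fold changes on the oriented (>= 1) scale,
# low-expression cutoffs and fold-change windows. Together these define the
# gene universe of every cell in the concordance grid.

#' Default fold-change windows and expression cutoffs
#'
#' The standard experimental grid: five symmetric fold-change windows
#' (interpreted on the oriented scale, half-open `[lower, upper)`, the last
#' open-ended) and six minimum average-count cutoffs, i.e. 30 grid cells.
#'
#' @return `default_fc_windows()`: a data.frame with columns `lower`,
#'   `upper`. `default_expression_cutoffs()`: a numeric vector.
#' @export
default_fc_windows <- function() {
  data.frame(lower = c(1, 1.1, 1.2, 1.3, 1.5),
             upper = c(1.1, 1.2, 1.3, 1.5, Inf))
}

#' @rdname default_fc_windows
#' @export
default_expression_cutoffs <- function() c(0, 5, 10, 20, 30, 50)

.validate_windows <- function(windows) {
  if (!is.data.frame(windows) || !all(c("lower", "upper") %in% names(windows))) {
    cdeg_stop("fc windows must be a data.frame with columns lower, upper",
              "config_error")
  }
  if (nrow(windows) == 0L) cdeg_stop("empty fc window list", "config_error")
  o <- order(windows$lower)
  w <- windows[o, , drop = FALSE]
  if (any(w$lower < 1)) {
    cdeg_stop("fc window bounds are on the oriented scale and must be >= 1",
              "config_error")
  }
  if (any(w$upper <= w$lower)) {
    cdeg_stop("each fc window needs lower < upper", "config_error")
  }
  if (nrow(w) > 1L && any(w$upper[-nrow(w)] > w$lower[-1L] + 1e-12)) {
    cdeg_stop("fc windows overlap on the oriented scale", "config_error")
  }
  rownames(w) <- NULL
  w
}

.window_label <- function(lower, upper) {
  up <- ifelse(is.infinite(upper), "Inf", format(upper))
  sprintf("[%s,%s)", format(lower), up)
}

#' Per-gene condition means
#'
#' Computes, per gene, the arithmetic mean of (optionally library-size
#' scaled) counts within each condition, plus the overall mean of raw counts
#' across all samples. The first sorted condition level is "A" (the
#' fold-change numerator). With `scaling = "total_count"` each sample is
#' scaled to the mean library size before the condition means are taken; the
#' overall mean is always computed on raw counts because it feeds the
#' low-expression cutoff, which is defined on raw average counts.
#'
#' @param x A `count_matrix`.
#' @param scaling `"total_count"` (default) or `"none"`.
#' @return data.frame with columns `gene_id`, `mean_a`, `mean_b`,
#'   `overall_mean`.
#' @export
condition_summary <- function(x, scaling = c("total_count", "none")) {
  stopifnot(inherits(x, "count_matrix"))
  scaling <- match.arg(scaling)
  cs <- .condition_samples(x)
  cts <- x$counts
  scaled <- if (scaling == "total_count") {
    lib <- .library_sizes(x)
    sf <- lib / mean(lib)
    sf[sf == 0] <- 1  # all-zero sample: leave untouched rather than divide by 0
    sweep(cts, 2L, sf, "/")
  } else cts
  data.frame(
    gene_id = gene_ids(x),
    mean_a = rowMeans(scaled[, cs$A, drop = FALSE]),
    mean_b = rowMeans(scaled[, cs$B, drop = FALSE]),
    overall_mean = rowMeans(cts),
    stringsAsFactors = FALSE
  )
}

#' Per-gene fold changes on the oriented scale
#'
#' The fold change of a gene is the ratio of its condition-A mean to its
#' condition-B mean. Up- and down-regulation are not distinguished when
#' windowing: down-regulated genes (ratio < 1) are mapped to their
#' reciprocal, so `oriented_fc = max(fc, 1/fc) >= 1` and windows are
#' symmetric about 1. When either mean is zero and `pseudocount > 0`, the
#' pseudocount is added to both means; with `pseudocount = 0` a gene with
#' both means zero has no defined fold change (`undefined = TRUE`) and is
#' excluded from every window.
#'
#' @param summary Output of [condition_summary()].
#' @param pseudocount Non-negative value added to both means when either is
#'   zero (default 0.5).
#' @return The summary data.frame with columns `fc`, `oriented_fc`,
#'   `direction` (`"up"`/`"down"`) and `undefined` appended.
#' @export
fold_changes <- function(summary, pseudocount = 0.5) {
  stopifnot(is.data.frame(summary),
            all(c("mean_a", "mean_b") %in% names(summary)))
  if (pseudocount < 0) cdeg_stop("pseudocount must be >= 0", "config_error")
  a <- summary$mean_a
  b <- summary$mean_b
  zero <- a == 0 | b == 0
  fc <- a / b
  if (pseudocount > 0) {
    fc[zero] <- (a[zero] + pseudocount) / (b[zero] + pseudocount)
    undefined <- rep(FALSE, length(fc))
  } else {
    undefined <- a == 0 & b == 0
    fc[undefined] <- NA_real_
  }
  oriented <- pmax(fc, 1 / fc)
  summary$fc <- fc
  summary$oriented_fc <- oriented
  summary$direction <- ifelse(is.na(fc), NA_character_,
                              ifelse(fc >= 1, "up", "down"))
  summary$undefined <- undefined
  summary
}

#' Low-expression filter
#'
#' Retains exactly the genes whose average raw count across all samples
#' (both conditions pooled) is at least `cutoff`; genes whose average falls
#' under the threshold are removed and their count reported via `message()`.
#'
#' @param x A `count_matrix`.
#' @param cutoff Non-negative minimum average count.
#' @param quiet Suppress the removal message.
#' @return Character vector of retained gene ids (possibly empty).
#' @export
filter_low_expression <- function(x, cutoff, quiet = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0) {
    cdeg_stop("cutoff must be a single non-negative number", "config_error")
  }
  om <- rowMeans(x$counts)
  keep <- om >= cutoff
  if (!quiet && any(!keep)) {
    message(sprintf("expression cutoff %g removed %d of %d genes",
                    cutoff, sum(!keep), length(keep)))
  }
  gene_ids(x)[keep]
}

#' Assign oriented fold changes to fold-change windows
#'
#' Windows are half-open `[lower, upper)` on the oriented scale and must not
#' overlap; an infinite upper bound additionally captures infinite oriented
#' fold changes (one condition mean zero at pseudocount 0). Values covered
#' by no window, and undefined fold changes, get `NA`.
#'
#' @param oriented_fc Numeric vector of oriented fold changes (>= 1 or NA).
#' @param windows data.frame with columns `lower`, `upper`.
#' @return Integer vector of window row indices (into the sorted window
#'   table), `NA` where unassigned.
#' @export
assign_fc_window <- function(oriented_fc, windows = default_fc_windows()) {
  w <- .validate_windows(windows)
  idx <- rep(NA_integer_, length(oriented_fc))
  for (i in seq_len(nrow(w))) {
    inwin <- !is.na(oriented_fc) & oriented_fc >= w$lower[i] &
      (oriented_fc < w$upper[i] |
         (is.infinite(w$upper[i]) & is.infinite(oriented_fc)))
    idx[inwin] <- i
  }
  idx
}

#' The experimental grid of filter regions
#'
#' One region per (expression cutoff, fold-change window) combination.
#'
#' @param cutoffs Strictly ascending non-negative cutoffs.
#' @param windows Fold-change windows (see [assign_fc_window()]).
#' @return data.frame with columns `region_id`, `cutoff`, `fc_lower`,
#'   `fc_upper`, `window` (label).
#' @export
filter_regions <- function(cutoffs = default_expression_cutoffs(),
                           windows = default_fc_windows()) {
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    cdeg_stop("expression cutoffs must be strictly ascending", "config_error")
  }
  w <- .validate_windows(windows)
  grid <- expand.grid(win = seq_len(nrow(w)), cutoff = cutoffs,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    cutoff = grid$cutoff,
    fc_lower = w$lower[grid$win],
    fc_upper = w$upper[grid$win],
    stringsAsFactors = FALSE
  )
  out$window <- .window_label(out$fc_lower, out$fc_upper)
  out$region_id <- sprintf("cutoff%g_fc%s", out$cutoff, out$window)
  out[, c("region_id", "cutoff", "fc_lower", "fc_upper", "window")]
}
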