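# Grid search over (expression cutoff, fold-change window) combinations.
# DEG calling runs once per cutoff on that cutoff's filtered universe (with
# Benjamini-Hochberg adjustment over exactly that universe); the windows
# then stratify the significant sets. The search stops at the FIRST region
# whose defined median pairwise Jaccard reaches the target.

# Evaluate everything attached to one expression cutoff: universe, per-
# method calls, fold changes, window-stratified DEG sets and concordance
# matrices. Shared by the early-stopping search and the full-grid scan.
.evaluate_cutoff <- function(x, cutoff, methods, cfg, external_tables = list()) {
  filt <- cfg$filtering
  w <- .validate_windows(filt$fc_windows)
  universe <- filter_low_expression(x, cutoff, quiet = TRUE)
  empty_cms <- function() {
    lapply(seq_len(nrow(w)), function(i) {
      sets <- c(
        lapply(methods, function(m) deg_set(m, character(),
          sprintf("cutoff%g_fc%s", cutoff, .window_label(w$lower[i], w$upper[i])))),
        lapply(external_tables, function(tb)
          deg_set(paste0("external:", attr(tb, "method_id")), character()))
      )
      concordance_matrix(sets)
    })
  }
  if (length(universe) == 0L) {
    cms <- if (length(methods) + length(external_tables) >= 2L) empty_cms() else list()
    return(list(cutoff = cutoff, universe = character(),
                matrices = cms,
                medians = vapply(cms, median_concordance, numeric(1))))
  }
  sub <- subset_count_matrix(x, genes = universe)
  results <- lapply(methods, function(m) {
    call_degs(sub, m, alpha = cfg$testing$alpha, scaling = filt$scaling,
              dispersion = cfg$testing$dispersion,
              pseudocount = filt$pseudocount)
  })
  names(results) <- methods
  fc <- fold_changes(condition_summary(sub, filt$scaling), filt$pseudocount)
  sets_by_win <- stratify_deg_sets(results, fc, w, cutoff)
  if (length(external_tables)) {
    win_of <- assign_fc_window(fc$oriented_fc, w)
    names(win_of) <- fc$gene_id
    for (i in seq_along(sets_by_win)) {
      in_win <- names(win_of)[!is.na(win_of) & win_of == i]
      ext <- lapply(external_tables, function(tb)
        adapt_external_degs(tb, in_win, cfg$testing$alpha, quiet = TRUE))
      sets_by_win[[i]] <- c(sets_by_win[[i]], ext)
    }
  }
  cms <- lapply(sets_by_win, concordance_matrix)
  list(cutoff = cutoff, universe = universe, results = results, fc = fc,
       sets_by_win = sets_by_win, matrices = cms,
       medians = vapply(cms, median_concordance, numeric(1)))
}

.grid_cells_df <- function(evals, windows) {
  w <- .validate_windows(windows)
  do.call(rbind, lapply(evals, function(ev) {
    data.frame(cutoff = ev$cutoff,
               fc_lower = w$lower, fc_upper = w$upper,
               window = .window_label(w$lower, w$upper),
               median_jaccard = ev$medians,
               n_universe = length(ev$universe),
               stringsAsFactors = FALSE)
  }))
}

#' Full concordance grid
#'
#' Evaluates every (expression cutoff, fold-change window) cell regardless
#' of any target: per-cell concordance matrices, region medians and the
#' long pair table that powers the heatmap export.
#'
#' @param x A `count_matrix` (the replicated reference samples).
#' @param methods Built-in method ids (>= 2 total including external
#'   tables).
#' @param config Run configuration, see [default_config()].
#' @param external_tables Optional list of `external_deg_table` objects to
#'   include as additional methods.
#' @return Object of class `concordance_grid`: `cells` (one row per grid
#'   cell with its median), `pairs` (one row per cell and method pair),
#'   `matrices` (named list of `concordance_matrix`).
#' @export
concordance_grid <- function(x, methods = deg_methods(),
                             config = default_config(),
                             external_tables = list()) {
  cfg <- config
  cutoffs <- cfg$filtering$expression_cutoffs
  w <- .validate_windows(cfg$filtering$fc_windows)
  if (length(methods) + length(external_tables) < 2L) {
    cdeg_stop("need >= 2 methods for concordance", "config_error")
  }
  evals <- lapply(cutoffs, function(co)
    .evaluate_cutoff(x, co, methods, cfg, external_tables))
  cells <- .grid_cells_df(evals, w)
  pairs <- do.call(rbind, lapply(evals, function(ev) {
    do.call(rbind, lapply(seq_along(ev$matrices), function(i) {
      p <- ev$matrices[[i]]$pairs
      if (nrow(p) == 0L) return(NULL)
      cbind(data.frame(cutoff = ev$cutoff, fc_lower = w$lower[i],
                       fc_upper = w$upper[i],
                       window = .window_label(w$lower[i], w$upper[i]),
                       stringsAsFactors = FALSE), p)
    }))
  }))
  mats <- unlist(lapply(evals, function(ev) ev$matrices), recursive = FALSE)
  names(mats) <- sprintf("cutoff%g_fc%s",
                         rep(cutoffs, each = nrow(w)),
                         rep(.window_label(w$lower, w$upper), length(cutoffs)))
  structure(list(cells = cells, pairs = pairs, matrices = mats,
                 cutoffs = cutoffs, windows = w),
            class = "concordance_grid")
}

#' Early-stopping grid search for the reference-standard region
#'
#' Iterates the grid with cutoffs ascending (outer loop) and fold-change
#' windows ascending by lower bound (inner loop), so the first hit is the
#' least destructive parameter combination; returns the first region whose
#' defined median pairwise Jaccard index is at least `target`. Undefined
#' medians (no predictions by any pair) never satisfy the target. The
#' search is deterministic: identical inputs give identical results.
#'
#' @param x A `count_matrix` (the replicated reference samples).
#' @param methods Built-in method ids.
#' @param target Minimum median Jaccard index to attain, in (0, 1].
#' @param config Run configuration, see [default_config()].
#' @param external_tables Optional list of `external_deg_table` objects.
#' @param keep_grid Also return the medians of all cells visited before the
#'   stop (the full grid when the target is never attained).
#' @return Object of class `optimizer_result`: `attained`, `cutoff`,
#'   `fc_lower`, `fc_upper`, `region_id`, `achieved_median`, `target`,
#'   `grid` (visited cells), `message`.
#' @export
optimize_concordance <- function(x, methods = deg_methods(), target = 0.75,
                                 config = default_config(),
                                 external_tables = list(),
                                 keep_grid = TRUE) {
  if (!is.numeric(target) || length(target) != 1L || target <= 0) {
    cdeg_stop("target must be a single value in (0, 1] (or above to force failure)",
              "config_error")
  }
  cfg <- config
  cutoffs <- cfg$filtering$expression_cutoffs
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    cdeg_stop("expression cutoffs must be strictly ascending", "config_error")
  }
  w <- .validate_windows(cfg$filtering$fc_windows)
  if (length(methods) + length(external_tables) < 2L) {
    cdeg_stop("need >= 2 methods for concordance", "config_error")
  }
  visited <- list()
  for (co in cutoffs) {
    ev <- .evaluate_cutoff(x, co, methods, cfg, external_tables)
    visited[[length(visited) + 1L]] <- ev
    for (i in seq_len(nrow(w))) {
      med <- ev$medians[i]
      if (!is.na(med) && med >= target) {
        grid <- if (keep_grid) {
          g <- .grid_cells_df(visited, w)
          # cells after the stopping one in the last cutoff were evaluated
          # as a by-product; keep them for reporting
          g
        } else NULL
        return(structure(list(
          attained = TRUE, cutoff = co,
          fc_lower = w$lower[i], fc_upper = w$upper[i],
          region_id = sprintf("cutoff%g_fc%s", co,
                              .window_label(w$lower[i], w$upper[i])),
          achieved_median = med, target = target, grid = grid,
          message = "target attained"
        ), class = "optimizer_result"))
      }
    }
  }
  structure(list(
    attained = FALSE, cutoff = NA_real_,
    fc_lower = NA_real_, fc_upper = NA_real_, region_id = NA_character_,
    achieved_median = NA_real_, target = target,
    grid = if (keep_grid) .grid_cells_df(visited, w) else NULL,
    message = "No threshold achieved target Jaccard Index"
  ), class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  if (x$attained) {
    cat(sprintf(
      "optimizer_result: attained target %.3g at cutoff %g, FC window [%g, %g) (median %.3f)\n",
      x$target, x$cutoff, x$fc_lower, x$fc_upper, x$achieved_median))
  } else {
    cat(sprintf("optimizer_result: %s (target %.3g)\n", x$message, x$target))
  }
  invisible(x)
}
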