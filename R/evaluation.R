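# Hold-out evaluation: build the reference standard on replicated reference
# samples, predict single-subject DEGs on disjoint 1-vs-1 sample pairs, and
# score predictions by precision and recall against the consensus standard.

#' Plan a reference / prediction split
#'
#' Randomly (but reproducibly, given `seed`) selects
#' `n_reference_per_condition` samples per condition for reference-standard
#' construction and `n_pairs` disjoint single-subject prediction pairs (one
#' remaining sample from each condition per pair).
#'
#' @param x A `count_matrix`.
#' @param n_reference_per_condition Reference samples per condition.
#' @param n_pairs Number of disjoint hold-out pairs.
#' @param seed Integer seed for the random assignment.
#' @return Object of class `holdout_plan`: `reference` (list `A`, `B`),
#'   `pairs` (data.frame `pair_id`, `sample_a`, `sample_b`), `seed`.
#' @export
make_holdout_plan <- function(x, n_reference_per_condition = 4L,
                              n_pairs = 3L, seed) {
  stopifnot(inherits(x, "count_matrix"))
  cs <- .condition_samples(x)
  need <- n_reference_per_condition + n_pairs
  if (need > length(cs$A) || need > length(cs$B)) {
    cdeg_stop(sprintf(
      "need %d + %d samples per condition, have %d (A) and %d (B)",
      n_reference_per_condition, n_pairs, length(cs$A), length(cs$B)),
      "sizing_error")
  }
  with_local_seed(seed, {
    refA <- sample(cs$A, n_reference_per_condition)
    refB <- sample(cs$B, n_reference_per_condition)
    predA <- sample(setdiff(cs$A, refA), n_pairs)
    predB <- sample(setdiff(cs$B, refB), n_pairs)
    structure(list(
      reference = list(A = sort(refA), B = sort(refB)),
      pairs = data.frame(pair_id = seq_len(n_pairs),
                         sample_a = predA, sample_b = predB,
                         stringsAsFactors = FALSE),
      seed = as.integer(seed)
    ), class = "holdout_plan")
  })
}

#' Precision and recall of a prediction set against a reference standard
#'
#' Predicted genes outside the standard's universe are dropped first (their
#' count is reported). Precision is undefined (`NA`) when nothing remains
#' predicted; recall is undefined when the standard has no positives.
#'
#' @param predicted Character vector of predicted gene ids.
#' @param rs A `reference_standard`.
#' @param quiet Suppress the dropped-gene message.
#' @return List: `precision`, `recall`, `tp`, `n_predicted`,
#'   `n_reference_positive`, `n_universe`, `n_dropped`.
#' @export
precision_recall <- function(predicted, rs, quiet = FALSE) {
  stopifnot(inherits(rs, "reference_standard"))
  predicted <- unique(as.character(predicted))
  dropped <- setdiff(predicted, rs$universe)
  if (length(dropped) && !quiet) {
    message(sprintf("precision_recall: dropped %d predicted gene(s) outside the universe",
                    length(dropped)))
  }
  pred <- intersect(predicted, rs$universe)
  tp <- length(intersect(pred, rs$positives))
  npos <- length(rs$positives)
  list(
    precision = if (length(pred) == 0L) NA_real_ else tp / length(pred),
    recall = if (npos == 0L) NA_real_ else tp / npos,
    tp = tp,
    n_predicted = length(pred),
    n_reference_positive = npos,
    n_universe = length(rs$universe),
    n_dropped = length(dropped)
  )
}

# Predict single-subject DEGs on one 1-vs-1 pair, optionally applying the
# same region filters (expression cutoff on the pair's average raw counts,
# fold-change window on the pair's oriented fold change) before scoring.
.predict_pair <- function(x, sample_a, sample_b, method, region, cfg,
                          dispersion, filter_predictions) {
  pair <- subset_count_matrix(x, samples = c(sample_a, sample_b))
  filt <- cfg$filtering
  if (filter_predictions && region$cutoff > 0) {
    keep <- filter_low_expression(pair, region$cutoff, quiet = TRUE)
    if (length(keep) == 0L) return(character())
    pair <- subset_count_matrix(pair, genes = keep)
  }
  res <- call_degs(pair, method, alpha = cfg$testing$alpha,
                   scaling = filt$scaling, dispersion = dispersion,
                   pseudocount = filt$pseudocount)
  hits <- res$gene_id[res$significant]
  if (filter_predictions) {
    fc <- fold_changes(condition_summary(pair, filt$scaling), filt$pseudocount)
    win <- data.frame(lower = region$fc_lower, upper = region$fc_upper)
    inwin <- !is.na(assign_fc_window(fc$oriented_fc, win))
    hits <- intersect(hits, fc$gene_id[inwin])
  }
  hits
}

#' Evaluate a single-subject prediction method against a consensus standard
#'
#' Implements the hold-out protocol: the reference standard is built once
#' from the plan's replicated reference samples (expression cutoff, DEG
#' calling by every contributing method, fold-change window stratification,
#' consensus rule); then, for each disjoint hold-out pair, the prediction
#' method is run on that single 1-vs-1 pair, the same region filters are
#' applied to its calls (unless `filter_predictions = FALSE`), and
#' precision/recall are computed against the standard. Averages are taken
#' over the pairs where each metric is defined.
#'
#' The prediction method must not contribute to the reference standard:
#' evaluating a method against a standard built (in part) by itself is an
#' isomorphic evaluation that replicates the method's own artifacts, and is
#' refused with a `bias_guard_error`.
#'
#' Methods that require replicates cannot predict on a 1-vs-1 pair; the
#' negative-binomial dispersion needed by `nb_wald`/`zlogfc` in that
#' setting is estimated once from the reference samples and fixed.
#'
#' @param x A `count_matrix` with enough samples for the plan.
#' @param plan A [make_holdout_plan()] result.
#' @param prediction_method Method id generating the single-subject calls.
#' @param rs_methods Candidate reference-standard methods.
#' @param rs_exclude Methods excluded from the standard; defaults to the
#'   prediction method.
#' @param rs_rule `"intersection"` or `"majority"`.
#' @param region List with `cutoff`, `fc_lower`, `fc_upper` (a single grid
#'   region, e.g. from an `optimizer_result`).
#' @param config Run configuration.
#' @param filter_predictions Apply the region's filters to the hold-out
#'   predictions before scoring (the alternative scores the unfiltered
#'   1-vs-1 calls against the same standard).
#' @return Object of class `evaluation_report`.
#' @export
evaluate_prediction_method <- function(x, plan, prediction_method,
                                       rs_methods = deg_methods(),
                                       rs_exclude = prediction_method,
                                       rs_rule = c("intersection", "majority"),
                                       region, config = default_config(),
                                       filter_predictions = TRUE) {
  rs_rule <- match.arg(rs_rule)
  stopifnot(inherits(plan, "holdout_plan"))
  contributing <- setdiff(rs_methods, rs_exclude)
  if (prediction_method %in% contributing) {
    cdeg_stop(sprintf(
      "prediction method '%s' contributes to the reference standard (isomorphic evaluation); exclude it",
      prediction_method), "bias_guard_error")
  }
  if (!all(c("cutoff", "fc_lower", "fc_upper") %in% names(region))) {
    cdeg_stop("region needs cutoff, fc_lower, fc_upper", "config_error")
  }
  cfg <- config
  ref_cm <- subset_count_matrix(x, samples = c(plan$reference$A, plan$reference$B))
  ev <- .evaluate_cutoff(ref_cm, region$cutoff, contributing, cfg)
  if (length(ev$universe) == 0L) {
    cdeg_stop("reference universe is empty at this cutoff", "config_error")
  }
  w <- .validate_windows(cfg$filtering$fc_windows)
  win_idx <- which(abs(w$lower - region$fc_lower) < 1e-9 &
                     (w$upper == region$fc_upper |
                        (is.infinite(w$upper) & is.infinite(region$fc_upper))))
  sets <- if (length(win_idx) == 1L) {
    ev$sets_by_win[[win_idx]]
  } else {
    # region window not on the configured grid: stratify ad hoc
    win <- data.frame(lower = region$fc_lower, upper = region$fc_upper)
    inwin <- !is.na(assign_fc_window(ev$fc$oriented_fc, win))
    genes_in <- ev$fc$gene_id[inwin]
    lapply(ev$results, function(res)
      deg_set(attr(res, "method_id"),
              intersect(res$gene_id[res$significant], genes_in)))
  }
  rs <- build_reference_standard(sets, rs_rule, exclude = NULL,
                                 universe = ev$universe,
                                 region = region)
  rs$excluded <- rs_exclude
  dispersion <- tryCatch(
    stats::median(estimate_dispersion(ref_cm)),
    consensusDEG_error = function(e) cfg$testing$dispersion %||% 0.05
  )
  per_pair <- lapply(seq_len(nrow(plan$pairs)), function(i) {
    row <- plan$pairs[i, ]
    pred <- .predict_pair(x, row$sample_a, row$sample_b, prediction_method,
                          region, cfg, dispersion, filter_predictions)
    pr <- precision_recall(pred, rs, quiet = TRUE)
    c(list(pair_id = row$pair_id, sample_a = row$sample_a,
           sample_b = row$sample_b), pr)
  })
  pairs_df <- do.call(rbind, lapply(per_pair, function(p)
    data.frame(p, stringsAsFactors = FALSE)))
  prec <- pairs_df$precision
  rec <- pairs_df$recall
  structure(list(
    pairs = pairs_df,
    average_precision = if (all(is.na(prec))) NA_real_ else mean(prec, na.rm = TRUE),
    average_recall = if (all(is.na(rec))) NA_real_ else mean(rec, na.rm = TRUE),
    n_pairs_undefined_precision = sum(is.na(prec)),
    n_pairs_undefined_recall = sum(is.na(rec)),
    reference_standard = rs_sizes(rs),
    provenance = list(
      rule = rs_rule,
      rs_methods = contributing,
      excluded = rs_exclude,
      prediction_method = prediction_method,
      region = region[c("cutoff", "fc_lower", "fc_upper")],
      alpha = cfg$testing$alpha,
      filter_predictions = filter_predictions,
      dispersion = dispersion,
      seed = plan$seed
    )
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: %s predicted vs %s-of-{%s} standard\n",
    x$provenance$prediction_method, x$provenance$rule,
    paste(x$provenance$rs_methods, collapse = ", ")))
  cat(sprintf("  region: cutoff %g, FC [%g, %g)\n",
              x$provenance$region$cutoff, x$provenance$region$fc_lower,
              x$provenance$region$fc_upper))
  cat(sprintf("  average precision %.3f, average recall %.3f over %d pair(s)\n",
              x$average_precision, x$average_recall, nrow(x$pairs)))
  invisible(x)
}

#' Write / read an evaluation report
#'
#' Serialises the full report (per-pair metrics, averages, reference
#' standard sizes and provenance, including the hold-out seed) as a single
#' JSON document. A report without seed provenance is refused. Writing then
#' reading returns an identical report.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, the report.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  if (is.null(report$provenance$seed) || is.na(report$provenance$seed)) {
    cdeg_stop("refusing to write a report without seed provenance", "io_error")
  }
  # JSON has no Inf: the open-ended window bound is stored as "inf"
  doc <- unclass(report)
  up <- doc$provenance$region$fc_upper
  if (!is.null(up) && is.infinite(up)) doc$provenance$region$fc_upper <- "inf"
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         dataframe = "rows")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cdeg_stop(sprintf("cannot write report to '%s'", path), "io_error")
  invisible(report)
}

#' @rdname write_evaluation_report
#' @export
read_evaluation_report <- function(path) {
  if (!file.exists(path)) cdeg_stop(sprintf("no such report: %s", path), "io_error")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$pairs <- as.data.frame(raw$pairs, stringsAsFactors = FALSE)
  raw$reference_standard <- as.data.frame(raw$reference_standard,
                                          stringsAsFactors = FALSE)
  for (col in c("precision", "recall")) {
    raw$pairs[[col]] <- as.numeric(raw$pairs[[col]])
  }
  raw$average_precision <- as.numeric(raw$average_precision %||% NA_real_)
  raw$average_recall <- as.numeric(raw$average_recall %||% NA_real_)
  for (nm in c("fc_upper")) {
    v <- raw$provenance$region[[nm]]
    if (is.character(v)) raw$provenance$region[[nm]] <- as.numeric(v)
  }
  structure(raw, class = "evaluation_report")
}
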