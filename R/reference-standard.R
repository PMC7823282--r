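# Consensus reference standards: intersection or strict-majority vote over
# per-method DEG sets, with the evaluated method excluded so that the
# standard never shares the prediction method's systematic artifacts
# (heteromorphic evaluation).

#' Build a consensus reference standard
#'
#' `rule = "intersection"`: consensus positives are the genes called by ALL
#' contributing methods. `rule = "majority"`: genes called by strictly more
#' than half of the contributing methods (3 of 4 when four contribute; 2 of
#' 4 is not a majority). Positives are intersected with the universe — the
#' expression-filtered gene set of the region the DEG sets came from — and
#' the negatives are the remaining universe members.
#'
#' @param deg_sets List of [deg_set()] objects (one per method).
#' @param rule `"intersection"` or `"majority"`.
#' @param exclude Method id to leave out (the method under evaluation), or
#'   `NULL`.
#' @param universe Character vector of gene ids (the region's filtered
#'   universe).
#' @param region Optional provenance list, e.g.
#'   `list(cutoff = 30, fc_lower = 1.5, fc_upper = Inf)`.
#' @return Object of class `reference_standard` with elements `rule`,
#'   `methods`, `excluded`, `positives`, `universe`, `region`.
#' @export
build_reference_standard <- function(deg_sets,
                                     rule = c("intersection", "majority"),
                                     exclude = NULL, universe,
                                     region = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.list(deg_sets),
            all(vapply(deg_sets, inherits, logical(1), "deg_set")))
  ids <- vapply(deg_sets, function(s) s$method_id, character(1))
  keep <- if (is.null(exclude)) rep(TRUE, length(ids)) else !(ids %in% exclude)
  contributing <- deg_sets[keep]
  if (length(contributing) < 2L) {
    cdeg_stop(sprintf(
      "reference standard needs >= 2 contributing methods (have %d after exclusion)",
      length(contributing)), "config_error")
  }
  universe <- unique(as.character(universe))
  gene_lists <- lapply(contributing, function(s) unique(s$genes))
  positives <- if (rule == "intersection") {
    Reduce(intersect, gene_lists)
  } else {
    counts <- table(unlist(gene_lists))
    names(counts)[counts > length(gene_lists) / 2]
  }
  structure(list(
    rule = rule,
    methods = ids[keep],
    excluded = exclude,
    positives = sort(intersect(positives, universe)),
    universe = sort(universe),
    region = region
  ), class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat(sprintf(
    "reference_standard (%s of %s%s): %d positives / %d universe\n",
    x$rule, paste(x$methods, collapse = ", "),
    if (!is.null(x$excluded)) paste0("; excluding ", paste(x$excluded, collapse = ", ")) else "",
    length(x$positives), length(x$universe)))
  invisible(x)
}

#' Union of per-region reference standards
#'
#' Composes a multi-region standard by uniting the positives (and
#' universes) of several single-region standards, e.g. the union of a
#' moderate fold-change region at no expression cutoff with the open-ended
#' fold-change region at a high cutoff.
#'
#' @param rs_list List of `reference_standard` objects.
#' @return A `reference_standard` with rule `"union"` and the component
#'   provenances under `region`.
#' @export
combine_reference_standards <- function(rs_list) {
  stopifnot(is.list(rs_list), length(rs_list) >= 1L,
            all(vapply(rs_list, inherits, logical(1), "reference_standard")))
  excl <- unique(unlist(lapply(rs_list, function(r) r$excluded)))
  structure(list(
    rule = "union",
    methods = unique(unlist(lapply(rs_list, function(r) r$methods))),
    excluded = if (length(excl)) excl else NULL,
    positives = sort(unique(unlist(lapply(rs_list, function(r) r$positives)))),
    universe = sort(unique(unlist(lapply(rs_list, function(r) r$universe)))),
    region = lapply(rs_list, function(r) list(rule = r$rule, region = r$region))
  ), class = "reference_standard")
}

#' Size report for reference-standard variants
#'
#' @param rs_variants A `reference_standard` or list of them.
#' @return data.frame with one row per variant: `rule`, `excluded`,
#'   `n_positive`, `n_negative`, `n_universe`.
#' @export
rs_sizes <- function(rs_variants) {
  if (inherits(rs_variants, "reference_standard")) {
    rs_variants <- list(rs_variants)
  }
  do.call(rbind, lapply(rs_variants, function(r) {
    data.frame(
      rule = r$rule,
      excluded = if (is.null(r$excluded)) NA_character_
                 else paste(r$excluded, collapse = ","),
      n_positive = length(r$positives),
      n_negative = length(r$universe) - length(r$positives),
      n_universe = length(r$universe),
      stringsAsFactors = FALSE
    )
  }))
}
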