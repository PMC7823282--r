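# Layered run configuration: package defaults <- YAML config file <- caller
# overrides (e.g. command-line flags). A frozen snapshot of the merged
# configuration is written next to every output by the command-line layer.

#' Default run configuration
#'
#' * `filtering`: pseudocount 0.5 (added to both condition means only when
#'   either is zero), total-count scaling for means/ranks, the standard
#'   fold-change windows and expression cutoffs.
#' * `testing`: alpha 0.05 on BH-adjusted p-values (0.001 is the common
#'   stricter preset), all four built-in methods.
#' * `optimizer`: target median Jaccard 0.75.
#' * `holdout`: 4 reference replicates per condition, 3 hold-out pairs.
#' * `reference_standard`: intersection rule.
#'
#' @return Nested list of settings.
#' @export
default_config <- function() {
  list(
    filtering = list(
      pseudocount = 0.5,
      scaling = "total_count",
      fc_windows = default_fc_windows(),
      expression_cutoffs = default_expression_cutoffs()
    ),
    testing = list(
      alpha = 0.05,
      methods = deg_methods(),
      dispersion = NULL
    ),
    optimizer = list(target = 0.75),
    holdout = list(n_reference = 4L, n_pairs = 3L),
    reference_standard = list(rule = "intersection")
  )
}

# windows may arrive from YAML/JSON as a list of [lower, upper] pairs with
# "inf"/".inf" upper bounds
.parse_fc_windows <- function(x) {
  if (is.data.frame(x)) return(.validate_windows(x))
  if (is.list(x)) {
    lo <- vapply(x, function(p) as.numeric(p[[1]]), numeric(1))
    up <- vapply(x, function(p) {
      v <- p[[2]]
      if (is.character(v) && tolower(v) %in% c("inf", ".inf", "infinity")) Inf
      else as.numeric(v)
    }, numeric(1))
    return(.validate_windows(data.frame(lower = lo, upper = up)))
  }
  cdeg_stop("cannot parse fc_windows", "config_error")
}

.merge_config <- function(base, extra) {
  if (is.null(extra)) return(base)
  for (nm in names(extra)) {
    if (is.list(extra[[nm]]) && !is.data.frame(extra[[nm]]) &&
        is.list(base[[nm]]) && !is.data.frame(base[[nm]]) &&
        !is.null(names(extra[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], extra[[nm]])
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  base
}

#' Load a layered run configuration
#'
#' Precedence, lowest to highest: [default_config()], then the YAML file at
#' `path` (if any), then `overrides`. Fold-change windows given as
#' `[[1, 1.1], [1.1, 1.2], ..., [1.5, "inf"]]` are normalised to the
#' internal window table.
#'
#' @param path Optional YAML file.
#' @param overrides Optional nested list of final overrides.
#' @return Merged configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      cdeg_stop(sprintf("config file not found: %s", path), "io_error")
    }
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- .merge_config(cfg, overrides)
  cfg$filtering$fc_windows <- .parse_fc_windows(cfg$filtering$fc_windows)
  cfg$filtering$expression_cutoffs <-
    as.numeric(unlist(cfg$filtering$expression_cutoffs))
  if (is.unsorted(cfg$filtering$expression_cutoffs, strictly = TRUE)) {
    cdeg_stop("expression cutoffs must be strictly ascending", "config_error")
  }
  cfg
}

# serialisable snapshot (windows as pair lists, Inf as "inf")
.config_snapshot <- function(cfg, seed = NULL) {
  snap <- cfg
  w <- cfg$filtering$fc_windows
  snap$filtering$fc_windows <- lapply(seq_len(nrow(w)), function(i) {
    list(w$lower[i], if (is.infinite(w$upper[i])) "inf" else w$upper[i])
  })
  if (!is.null(seed)) snap$seed <- seed
  snap
}
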