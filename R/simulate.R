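# Negative-binomial two-condition count simulator with planted differential
# expression. Emulates the structure of isogenic two-condition RNA-seq
# benchmark designs: two conditions, several biological replicates each,
# log-normal baseline expression, low biological dispersion, and a minority
# of genes carrying true fold changes spread over the standard fold-change
# windows.

#' Simulation configuration
#'
#' Defaults emulate a replicated isogenic benchmark design: 20,000 measured
#' genes, 7 biological replicates per condition, log-normal baseline means,
#' constant dispersion 0.05 (cell-line-like biological variability), ~12%
#' of genes differentially expressed with oriented fold changes drawn from
#' the standard windows in proportions resembling an empirical effect-size
#' spectrum (weights 85:175:700:1100:365 over the five windows), random
#' up/down direction, and mild log-normal library-size variation.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Biological replicates per condition.
#' @param deg_fraction Fraction of genes with a planted fold change.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean
#'   parameters (raw count scale).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param dispersion_model `"constant"`, or `"trend"` for a stress-test
#'   mean-dependent dispersion `dispersion + 2 / baseline`.
#' @param window_weights Mixture weights (normalised internally) over
#'   `fc_windows` for the planted oriented fold changes.
#' @param fc_windows Fold-change windows to draw effects from.
#' @param fc_cap Upper bound used in place of an infinite window bound when
#'   drawing effect sizes.
#' @param libsize_sdlog Log-normal sd of per-sample library-size factors.
#' @param seed Mandatory integer seed; there is no global random state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000L, n_replicates = 7L,
                       deg_fraction = 0.12,
                       baseline_meanlog = log(60), baseline_sdlog = 1.5,
                       dispersion = 0.05,
                       dispersion_model = c("constant", "trend"),
                       window_weights = c(85, 175, 700, 1100, 365),
                       fc_windows = default_fc_windows(),
                       fc_cap = 5, libsize_sdlog = 0.15, seed) {
  dispersion_model <- match.arg(dispersion_model)
  if (missing(seed)) cdeg_stop("sim_config requires an explicit seed", "config_error")
  if (deg_fraction < 0 || deg_fraction > 1) {
    cdeg_stop("deg_fraction must be in [0,1]", "config_error")
  }
  w <- .validate_windows(fc_windows)
  if (length(window_weights) != nrow(w)) {
    cdeg_stop("window_weights must match the number of fc windows", "config_error")
  }
  if (dispersion < 0 || libsize_sdlog < 0) {
    cdeg_stop("dispersion and libsize_sdlog must be >= 0", "config_error")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    deg_fraction = deg_fraction,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, dispersion_model = dispersion_model,
    window_weights = window_weights / sum(window_weights),
    fc_windows = w, fc_cap = fc_cap,
    libsize_sdlog = libsize_sdlog, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-condition count matrix with planted truth
#'
#' Per gene and sample, counts are drawn from a negative binomial with mean
#' `baseline * fc_applied * library_factor` and the configured dispersion,
#' where `fc_applied` multiplies the condition-A mean for up-regulated
#' genes and the condition-B mean for down-regulated ones (so the true A/B
#' ratio equals the signed fold change). Fully reproducible from the
#' config's seed.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (a [count_matrix()] with conditions `"A"`,
#'   `"B"`), `truth` (data.frame `gene_id`, `is_deg`, `true_fc` (A/B),
#'   `oriented_fc`, `direction`, `window`, `baseline`, `dispersion`).
#' @export
simulate_two_condition_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    ng <- cfg$n_genes
    nr <- cfg$n_replicates
    baseline <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
    phi <- switch(cfg$dispersion_model,
                  constant = rep(cfg$dispersion, ng),
                  trend = cfg$dispersion + 2 / baseline)
    n_deg <- round(cfg$deg_fraction * ng)
    is_deg <- rep(FALSE, ng)
    if (n_deg > 0) is_deg[sample.int(ng, n_deg)] <- TRUE
    w <- cfg$fc_windows
    win <- rep(NA_integer_, ng)
    oriented <- rep(1, ng)
    direction <- rep(NA_character_, ng)
    if (n_deg > 0) {
      widx <- sample.int(nrow(w), n_deg, replace = TRUE,
                         prob = cfg$window_weights)
      lo <- w$lower[widx]
      hi <- pmin(w$upper[widx], cfg$fc_cap)
      oriented[is_deg] <- stats::runif(n_deg, lo, hi)
      direction[is_deg] <- sample(c("up", "down"), n_deg, replace = TRUE)
      win[is_deg] <- widx
    }
    true_fc <- ifelse(is_deg,
                      ifelse(direction == "up", oriented, 1 / oriented), 1)
    lib <- stats::rlnorm(2 * nr, 0, cfg$libsize_sdlog)
    lib <- lib / exp(mean(log(lib)))
    muA <- baseline * ifelse(is_deg & direction == "up", oriented, 1)
    muB <- baseline * ifelse(is_deg & direction == "down", oriented, 1)
    mu <- cbind(matrix(muA, ng, nr), matrix(muB, ng, nr))
    mu <- sweep(mu, 2L, lib, "*")
    counts <- matrix(0L, ng, 2L * nr)
    pois <- phi < 1e-12
    if (any(pois)) {
      counts[pois, ] <- stats::rpois(sum(pois) * 2L * nr, mu[pois, ])
    }
    if (any(!pois)) {
      counts[!pois, ] <- stats::rnbinom(sum(!pois) * 2L * nr,
                                        mu = mu[!pois, ],
                                        size = 1 / phi[!pois])
    }
    gid <- sprintf("gene%05d", seq_len(ng))
    sid <- c(sprintf("A%02d", seq_len(nr)), sprintf("B%02d", seq_len(nr)))
    dimnames(counts) <- list(gid, sid)
    design <- stats::setNames(rep(c("A", "B"), each = nr), sid)
    truth <- data.frame(
      gene_id = gid, is_deg = is_deg, true_fc = true_fc,
      oriented_fc = oriented, direction = direction,
      window = NA_character_,
      baseline = baseline, dispersion = phi,
      stringsAsFactors = FALSE
    )
    ok <- !is.na(win)
    if (any(ok)) {
      truth$window[ok] <- .window_label(w$lower[win[ok]], w$upper[win[ok]])
    }
    list(counts = count_matrix(counts, design), truth = truth)
  })
}

#' Precision and recall against the planted truth
#'
#' Ground-truth analogue of [precision_recall()]: positives are the planted
#' differentially expressed genes (optionally restricted to a universe).
#'
#' @param genes Character vector of called gene ids (a DEG set or the
#'   positives of a reference standard).
#' @param truth Truth table from [simulate_two_condition_counts()].
#' @param universe Optional universe restriction applied to both sides.
#' @return List: `precision`, `recall`, `tp`, `n_called`, `n_true`.
#' @export
truth_metrics <- function(genes, truth, universe = NULL) {
  stopifnot(is.data.frame(truth), all(c("gene_id", "is_deg") %in% names(truth)))
  genes <- unique(as.character(genes))
  pos <- truth$gene_id[truth$is_deg]
  if (!is.null(universe)) {
    genes <- intersect(genes, universe)
    pos <- intersect(pos, universe)
  }
  tp <- length(intersect(genes, pos))
  list(
    precision = if (length(genes) == 0L) NA_real_ else tp / length(genes),
    recall = if (length(pos) == 0L) NA_real_ else tp / length(pos),
    tp = tp, n_called = length(genes), n_true = length(pos)
  )
}

#' Write simulation outputs
#'
#' @param sim Output of [simulate_two_condition_counts()].
#' @param counts_path,design_path,truth_path Output TSV paths.
#' @return Invisibly, `sim`.
#' @export
write_simulation <- function(sim, counts_path, design_path, truth_path) {
  write_count_matrix(sim$counts, counts_path, design_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sim)
}
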