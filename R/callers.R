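# Built-in two-condition differential-expression callers. These span the
# distributional families commonly used for RNA-seq counts (exact
# conditional on pooled counts, negative-binomial Wald, exact rank-based,
# and a delta-method z-test on log ratios) so that their disagreement
# pattern resembles that of heterogeneous production tools; results from
# real external tools enter through adapt_external_degs() instead.

#' Registered built-in caller identifiers
#'
#' * `pooled_exact` — counts are pooled per condition and each gene is
#'   tested by the exact conditional test on the 2x2 table (gene count vs
#'   rest of library, condition A vs B); two-sided by summing the
#'   probabilities of all tables no more likely than the observed one.
#'   Valid without replicates.
#' * `nb_wald` — per-gene negative binomial with a method-of-moments
#'   dispersion shrunk toward the mean-dispersion trend across genes; Wald
#'   test on the log fold change with library-size offsets, referred to a t
#'   distribution on the residual degrees of freedom (normal when the
#'   dispersion is supplied rather than estimated). Needs >= 2 replicates
#'   per condition unless a fixed dispersion is supplied.
#' * `rank_sum` — exact two-sample rank-sum test on library-size scaled
#'   counts (normal approximation with tie correction when counts tie);
#'   needs >= 3 replicates per condition.
#' * `zlogfc` — z-test on the log2 ratio of scaled condition means with a
#'   delta-method variance from a Poisson-plus-dispersion model. Needs >= 2
#'   replicates per condition unless a fixed dispersion is supplied.
#'
#' @return Character vector of method ids.
#' @export
deg_methods <- function() c("pooled_exact", "nb_wald", "rank_sum", "zlogfc")

# (min replicates per condition without a fixed dispersion,
#  min replicates with one)
.caller_min_reps <- list(
  pooled_exact = c(1L, 1L),
  nb_wald      = c(2L, 1L),
  rank_sum     = c(3L, 3L),
  zlogfc       = c(2L, 1L)
)

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over exactly the supplied
#' p-values (the calling layer applies it within each expression-filtered
#' universe). Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    cdeg_stop("p-values must lie in [0,1] with no missing values",
              "validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes with a built-in method
#'
#' Runs one registered caller on (a filtered universe of) a two-condition
#' count matrix. P-values are adjusted by Benjamini-Hochberg over exactly
#' the genes present in `x`; `significant` is `adjusted_p < alpha`.
#'
#' @param x A `count_matrix`, typically restricted to an expression-filtered
#'   universe.
#' @param method One of [deg_methods()].
#' @param alpha Significance level applied to adjusted p-values.
#' @param scaling Library-size scaling for means/ranks (`"total_count"` or
#'   `"none"`); callers that model library sizes explicitly (pooled_exact,
#'   nb_wald) always work from raw counts and offsets.
#' @param dispersion Optional fixed negative-binomial dispersion. Required
#'   to run `nb_wald`/`zlogfc` on a single sample per condition (e.g. a
#'   hold-out pair, with the dispersion estimated on the replicated
#'   reference samples).
#' @param pseudocount Added to both condition means when either is zero, for
#'   reported log2 fold changes.
#' @return data.frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`,
#'   `significant`; attribute `method_id`.
#' @export
call_degs <- function(x, method, alpha = 0.05,
                      scaling = c("total_count", "none"),
                      dispersion = NULL, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  scaling <- match.arg(scaling)
  if (!method %in% deg_methods()) {
    cdeg_stop(sprintf("unknown method '%s' (registered: %s)", method,
                      paste(deg_methods(), collapse = ", ")), "config_error")
  }
  if (alpha <= 0 || alpha > 1) cdeg_stop("alpha must be in (0,1]", "config_error")
  cs <- .condition_samples(x)
  minrep <- .caller_min_reps[[method]][if (is.null(dispersion)) 1L else 2L]
  if (min(length(cs$A), length(cs$B)) < minrep) {
    cdeg_stop(sprintf(
      "method '%s' needs >= %d replicate(s) per condition%s (have %d vs %d)",
      method, minrep,
      if (is.null(dispersion) && .caller_min_reps[[method]][1L] >
          .caller_min_reps[[method]][2L]) " without a fixed dispersion" else "",
      length(cs$A), length(cs$B)), "capability_error")
  }
  if (nrow(x$counts) == 0L) {
    return(structure(data.frame(gene_id = character(), log2fc = numeric(),
                                pvalue = numeric(), padj = numeric(),
                                significant = logical()),
                     method_id = method))
  }
  res <- switch(method,
    pooled_exact = .call_pooled_exact(x),
    nb_wald      = .call_nb_wald(x, dispersion),
    rank_sum     = .call_rank_sum(x, scaling),
    zlogfc       = .call_zlogfc(x, scaling, dispersion, pseudocount)
  )
  sm <- fold_changes(condition_summary(x, scaling), pseudocount)
  res$log2fc <- ifelse(is.na(res$log2fc), log2(sm$fc), res$log2fc)
  res$pvalue <- pmin(pmax(res$pvalue, 0), 1)
  res$padj <- bh_adjust(res$pvalue)
  res$significant <- res$padj < alpha
  out <- data.frame(gene_id = gene_ids(x), log2fc = res$log2fc,
                    pvalue = res$pvalue, padj = res$padj,
                    significant = res$significant,
                    stringsAsFactors = FALSE)
  structure(out, method_id = method)
}

## --- pooled exact conditional test -------------------------------------

# Two-sided exact p for the 2x2 table (a, libA - a | b, libB - b),
# conditioning on both margins: sum over the hypergeometric support of all
# outcome probabilities <= the observed one (with the customary relative
# tolerance to absorb floating-point ties).
.hyper_twosided <- function(a, libA, libB, total) {
  support <- max(0L, total - libB):min(total, libA)
  pr <- stats::dhyper(support, libA, libB, total)
  obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

.call_pooled_exact <- function(x) {
  cs <- .condition_samples(x)
  a <- rowSums(x$counts[, cs$A, drop = FALSE])
  b <- rowSums(x$counts[, cs$B, drop = FALSE])
  libA <- sum(a)
  libB <- sum(b)
  n <- length(a)
  p <- numeric(n)
  if (libA == 0 || libB == 0) {
    p[] <- 1
  } else {
    tot <- a + b
    for (i in seq_len(n)) {
      p[i] <- if (tot[i] == 0) 1 else .hyper_twosided(a[i], libA, libB, tot[i])
    }
  }
  list(log2fc = NA_real_, pvalue = p)
}

## --- negative-binomial Wald test ----------------------------------------

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per-gene negative-binomial dispersion from scaled counts: within each
#' condition the unbiased sample variance is pooled, and the
#' method-of-moments estimate `(var - mean) / mean^2` is shrunk halfway
#' toward a lowess trend of dispersion on log mean fitted across all genes.
#' Used by the `nb_wald` and `zlogfc` callers and by the hold-out
#' evaluation, which estimates dispersion once on the replicated reference
#' samples and fixes it for the single-subject pair.
#'
#' @param x A `count_matrix` with >= 2 replicates per condition.
#' @return Named numeric vector of per-gene dispersions (floored at 1e-8).
#' @export
estimate_dispersion <- function(x) {
  cs <- .condition_samples(x)
  if (min(length(cs$A), length(cs$B)) < 2L) {
    cdeg_stop("dispersion estimation needs >= 2 replicates per condition",
              "capability_error")
  }
  lib <- .library_sizes(x)
  sf <- lib / mean(lib)
  sf[sf == 0] <- 1
  z <- sweep(x$counts, 2L, sf, "/")
  nA <- length(cs$A); nB <- length(cs$B)
  vA <- .row_vars(z[, cs$A, drop = FALSE])
  vB <- .row_vars(z[, cs$B, drop = FALSE])
  v <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  m <- rowMeans(z)
  raw <- rep(NA_real_, length(m))
  pos <- m > 0
  raw[pos] <- (v[pos] - m[pos]) / m[pos]^2
  # the trend is fitted on the UNCLIPPED moment estimates: clipping negative
  # values first would bias the trend (and hence every shrunk estimate) up
  raw <- pmin(raw, 10)
  fit_ok <- pos & !is.na(raw)
  trend <- rep(0, length(m))
  if (sum(fit_ok) >= 10L) {
    lw <- stats::lowess(log(m[fit_ok]), raw[fit_ok], f = 0.5)
    trend[pos] <- stats::approx(lw$x, lw$y, xout = log(m[pos]), rule = 2)$y
    trend <- pmax(trend, 0)
  } else if (any(fit_ok)) {
    trend[] <- max(stats::median(raw[fit_ok]), 0)
  }
  phi <- 0.5 * pmax(ifelse(is.na(raw), trend, raw), 0) + 0.5 * trend
  phi <- pmax(phi, 1e-8)
  names(phi) <- gene_ids(x)
  phi
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Vectorised Newton solve of the per-group NB mean on the log scale with
# library-size offsets and fixed per-gene dispersion phi. Returns the MLE
# beta = log(mu) and the expected Fisher information per gene.
.nb_group_fit <- function(y, s, phi) {
  tot <- rowSums(y)
  S <- sum(s)
  mu <- tot / S
  zero <- tot == 0
  mu[zero] <- 0.5 / S  # half-count continuity for empty groups
  beta <- log(mu)
  active <- !zero
  if (any(active)) {
    for (it in 1:50) {
      mu <- exp(beta)
      smu <- mu %o% s                 # genes x samples
      w <- 1 + phi * smu              # phi recycles down columns
      score <- rowSums((y - smu) / w)
      curv <- mu * rowSums(sweep((1 + phi * y) / w^2, 2L, s, "*"))
      step <- score / pmax(curv, 1e-12)
      step <- pmin(pmax(step, -4), 4)
      step[!active] <- 0
      beta <- beta + step
      if (max(abs(step)) < 1e-12) break
    }
  }
  mu <- exp(beta)
  smu <- mu %o% s
  info <- rowSums(smu / (1 + phi * smu))
  list(beta = beta, info = pmax(info, 1e-12))
}

.call_nb_wald <- function(x, dispersion = NULL) {
  cs <- .condition_samples(x)
  phi <- if (is.null(dispersion)) {
    unname(estimate_dispersion(x))
  } else rep(dispersion, nrow(x$counts))
  lib <- .library_sizes(x)
  sf <- lib / mean(lib)
  sf[sf == 0] <- 1
  fA <- .nb_group_fit(x$counts[, cs$A, drop = FALSE], sf[cs$A], phi)
  fB <- .nb_group_fit(x$counts[, cs$B, drop = FALSE], sf[cs$B], phi)
  delta <- fA$beta - fB$beta
  se <- sqrt(1 / fA$info + 1 / fB$info)
  z <- delta / se
  both_zero <- rowSums(x$counts) == 0
  z[both_zero] <- 0
  p <- .wald_reference(z, length(cs$A) + length(cs$B) - 2L, dispersion)
  list(log2fc = delta / log(2), pvalue = p)
}

# Reference distribution for Wald-type statistics. When the dispersion is
# estimated, the normal reference is anticonservative at small n; a
# moderated t is used instead, with prior df equal to the residual df
# because half of the shrunk dispersion's weight comes from the
# genome-wide mean-dispersion trend (whose effective df is large). With a
# fixed externally supplied dispersion there is no estimation noise and
# the normal reference applies.
.wald_reference <- function(z, residual_df, dispersion) {
  if (is.null(dispersion) && residual_df >= 1L) {
    2 * stats::pt(-abs(z), df = 2L * residual_df)
  } else {
    2 * stats::pnorm(-abs(z))
  }
}

## --- exact rank-sum test -------------------------------------------------

.call_rank_sum <- function(x, scaling) {
  cs <- .condition_samples(x)
  nA <- length(cs$A); nB <- length(cs$B)
  z <- if (scaling == "total_count") {
    lib <- .library_sizes(x)
    sf <- lib / mean(lib)
    sf[sf == 0] <- 1
    sweep(x$counts, 2L, sf, "/")
  } else x$counts
  az <- z[, cs$A, drop = FALSE]
  bz <- z[, cs$B, drop = FALSE]
  n <- nA + nB
  p <- apply(cbind(az, bz), 1L, function(v) {
    r <- rank(v)
    u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- table(v)
    if (all(ties == 1L)) {
      if (u > nA * nB / 2) {
        min(1, 2 * (1 - stats::pwilcox(u - 1, nA, nB)))
      } else {
        min(1, 2 * stats::pwilcox(u, nA, nB))
      }
    } else {
      # mid-rank normal approximation with tie correction and continuity
      # correction, as is standard when exact enumeration is unavailable
      mu <- nA * nB / 2
      sigma2 <- nA * nB / 12 *
        ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      zz <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(-abs(zz)))
    }
  })
  list(log2fc = NA_real_, pvalue = unname(p))
}

## --- delta-method z-test on the log2 ratio of scaled means ---------------

.call_zlogfc <- function(x, scaling, dispersion = NULL, pseudocount = 0.5) {
  cs <- .condition_samples(x)
  nA <- length(cs$A); nB <- length(cs$B)
  phi <- if (is.null(dispersion)) {
    unname(estimate_dispersion(x))
  } else rep(dispersion, nrow(x$counts))
  lib <- .library_sizes(x)
  sf <- lib / mean(lib)
  sf[sf == 0] <- 1
  z <- if (scaling == "total_count") sweep(x$counts, 2L, sf, "/") else x$counts
  mA <- rowMeans(z[, cs$A, drop = FALSE])
  mB <- rowMeans(z[, cs$B, drop = FALSE])
  pc <- pseudocount
  zero <- mA == 0 | mB == 0
  mA2 <- ifelse(zero, mA + pc, mA)
  mB2 <- ifelse(zero, mB + pc, mB)
  # var(log mean) by the delta method under var(count) = mu*s + phi*(mu*s)^2
  invsA <- mean(1 / sf[cs$A]); invsB <- mean(1 / sf[cs$B])
  vlA <- invsA / (nA * mA2) + phi / nA
  vlB <- invsB / (nB * mB2) + phi / nB
  se <- sqrt(vlA + vlB)
  lr <- log(mA2 / mB2)
  zstat <- ifelse(se > 0, lr / se, 0)
  zstat[mA == 0 & mB == 0 & pc == 0] <- 0
  p <- .wald_reference(zstat, nA + nB - 2L, dispersion)
  list(log2fc = lr / log(2), pvalue = p)
}

## --- external tables, DEG sets and window stratification -----------------

#' One method's significant-gene set within a filter region
#'
#' @param method_id Method label.
#' @param genes Character vector of significant gene ids.
#' @param region_id Region label (or `NA` for an unstratified set).
#' @return Object of class `deg_set`.
#' @export
deg_set <- function(method_id, genes, region_id = NA_character_) {
  structure(list(method_id = method_id,
                 genes = unique(as.character(genes)),
                 region_id = region_id),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set '%s' (%s): %d genes\n", x$method_id,
              x$region_id %||% "unstratified", length(x$genes)))
  invisible(x)
}

#' Adapt an external DEG table to a filtered universe
#'
#' Selects the genes of the universe whose externally adjusted p-value is
#' below `alpha`. No re-adjustment is performed: the external tool's own
#' multiple-testing correction is authoritative. Universe genes absent from
#' the table are treated as untested (excluded; a message reports their
#' count).
#'
#' @param table An `external_deg_table` from [read_deg_table()].
#' @param universe Character vector of gene ids defining the universe.
#' @param alpha Significance level on the table's `padj`.
#' @param quiet Suppress the missing-gene message.
#' @return A [deg_set()] with method id `"external:<method_id>"`.
#' @export
adapt_external_degs <- function(table, universe, alpha = 0.05, quiet = FALSE) {
  stopifnot(inherits(table, "external_deg_table"))
  mid <- paste0("external:", attr(table, "method_id"))
  missing <- setdiff(universe, table$gene_id)
  if (length(missing) && !quiet) {
    message(sprintf("%s: %d universe gene(s) absent from table, excluded",
                    mid, length(missing)))
  }
  hit <- table$gene_id[table$padj < alpha]
  deg_set(mid, intersect(universe, hit))
}

#' Stratify significant calls by fold-change window
#'
#' DEG calling is run once per expression cutoff on the full filtered
#' universe; the fold-change windows then stratify each method's significant
#' set by the gene's oriented fold change (they do not trigger re-testing).
#'
#' @param results Named list of [call_degs()] outputs (one per method).
#' @param fc Output of [fold_changes()] for the same universe.
#' @param windows Fold-change window table.
#' @param cutoff Expression cutoff of the region (used only for labels).
#' @return List (windows) of lists (methods) of [deg_set()] objects.
#' @export
stratify_deg_sets <- function(results, fc, windows = default_fc_windows(),
                              cutoff = NA_real_) {
  w <- .validate_windows(windows)
  win_of <- assign_fc_window(fc$oriented_fc, w)
  names(win_of) <- fc$gene_id
  lapply(seq_len(nrow(w)), function(i) {
    in_win <- names(win_of)[!is.na(win_of) & win_of == i]
    rid <- sprintf("cutoff%g_fc%s", cutoff, .window_label(w$lower[i], w$upper[i]))
    lapply(results, function(res) {
      mid <- attr(res, "method_id") %||% "unknown"
      deg_set(mid, intersect(res$gene_id[res$significant], in_win), rid)
    })
  })
}
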