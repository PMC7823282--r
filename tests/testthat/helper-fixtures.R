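# Shared fixtures, built in code at test time.

# 4-gene x 4-sample toy matrix: g1 has condition means 11 (A) and 9 (B) and
# overall raw mean 10; overall means are (10, 0.5, 55, 5).
toy_count_matrix <- function() {
  m <- rbind(
    g1 = c(10, 12, 8, 10),
    g2 = c(1, 1, 0, 0),
    g3 = c(60, 50, 55, 55),
    g4 = c(5, 5, 5, 5)
  )
  colnames(m) <- c("s1", "s2", "s3", "s4")
  count_matrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
}

# small reproducible simulated dataset for integration-style tests
small_sim <- function(seed = 42, n_genes = 800, n_replicates = 7,
                      deg_fraction = 0.12, dispersion = 0.05) {
  simulate_two_condition_counts(sim_config(
    n_genes = n_genes, n_replicates = n_replicates,
    deg_fraction = deg_fraction, dispersion = dispersion, seed = seed))
}

random_gene_sets <- function(k, universe, p = 0.3) {
  lapply(seq_len(k), function(i) {
    deg_set(sprintf("m%d", i), universe[stats::runif(length(universe)) < p])
  })
}

# independent two-sided exact p for a 2x2 table conditioned on both margins,
# by explicit enumeration with log-binomial coefficients (no dhyper)
enum_hyper_p <- function(a, libA, libB, total) {
  support <- max(0, total - libB):min(total, libA)
  logp <- lchoose(libA, support) + lchoose(libB, total - support) -
    lchoose(libA + libB, total)
  pr <- exp(logp)
  obs <- pr[support == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
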