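# independent oracle: order the exhaustive grid by the traversal (cutoffs
# ascending, windows ascending by lower bound) and take the first cell with
# a defined median >= target
first_qualifying_cell <- function(grid_cells, target) {
  o <- order(grid_cells$cutoff, grid_cells$fc_lower)
  g <- grid_cells[o, ]
  hit <- which(!is.na(g$median_jaccard) & g$median_jaccard >= target)
  if (length(hit) == 0L) return(NULL)
  g[hit[1L], ]
}

test_that("a single qualifying cell is found and reported", {
  sim <- small_sim(seed = 14, n_genes = 400)
  cfg <- default_config()
  cfg$filtering$expression_cutoffs <- 30
  cfg$filtering$fc_windows <- data.frame(lower = 1.5, upper = Inf)
  res <- optimize_concordance(sim$counts, c("pooled_exact", "zlogfc"),
                              target = 0.05, config = cfg)
  expect_true(res$attained)
  expect_equal(res$cutoff, 30)
  expect_equal(res$fc_lower, 1.5)
  expect_gte(res$achieved_median, 0.05)
})

test_that("an unattainable target reports failure, not a cell", {
  sim <- small_sim(seed = 14, n_genes = 300)
  res <- optimize_concordance(sim$counts, c("pooled_exact", "zlogfc"),
                              target = 1.01)
  expect_false(res$attained)
  expect_match(res$message, "No threshold achieved target")
  expect_true(is.na(res$cutoff))
  expect_equal(nrow(res$grid), 30L)  # full grid evaluated before giving up
})

test_that("early stopping returns the exhaustive search's first hit", {
  methods <- c("pooled_exact", "zlogfc")
  for (i in 1:4) {
    sim <- small_sim(seed = 100 + i, n_genes = 400)
    target <- c(0.3, 0.6, 0.9, 1.01)[i]
    res <- optimize_concordance(sim$counts, methods, target = target)
    grid <- concordance_grid(sim$counts, methods)
    oracle <- first_qualifying_cell(grid$cells, target)
    if (is.null(oracle)) {
      expect_false(res$attained)
    } else {
      expect_true(res$attained)
      expect_equal(res$cutoff, oracle$cutoff)
      expect_equal(res$fc_lower, oracle$fc_lower)
      expect_equal(res$achieved_median, oracle$median_jaccard)
    }
  }
})

test_that("the grid is exhaustive and consistent with the optimizer", {
  sim <- small_sim(seed = 23, n_genes = 400)
  methods <- c("pooled_exact", "nb_wald", "zlogfc")
  grid <- concordance_grid(sim$counts, methods)
  expect_equal(nrow(grid$cells), 30L)
  expect_length(grid$matrices, 30L)
  res <- optimize_concordance(sim$counts, methods, target = 0.4)
  if (res$attained) {
    cell <- grid$cells[grid$cells$cutoff == res$cutoff &
                         grid$cells$fc_lower == res$fc_lower, ]
    expect_equal(cell$median_jaccard, res$achieved_median)
  }
  # empty universe at an absurd cutoff: all-undefined medians
  cfg <- default_config()
  cfg$filtering$expression_cutoffs <- c(0, 1e7)
  g2 <- concordance_grid(sim$counts, methods, cfg)
  expect_true(all(is.na(g2$cells$median_jaccard[g2$cells$cutoff == 1e7])))
  expect_equal(g2$cells$n_universe[g2$cells$cutoff == 1e7], rep(0L, 5))
})

test_that("the search is deterministic and ignores undefined medians", {
  sim <- small_sim(seed = 4, n_genes = 300)
  r1 <- optimize_concordance(sim$counts, c("pooled_exact", "zlogfc"),
                             target = 0.5)
  r2 <- optimize_concordance(sim$counts, c("pooled_exact", "zlogfc"),
                             target = 0.5)
  expect_identical(r1[c("attained", "cutoff", "fc_lower", "achieved_median")],
                   r2[c("attained", "cutoff", "fc_lower", "achieved_median")])
  # a cell whose pairs are all undefined must never satisfy any target:
  # with an empty universe (huge first cutoff) nothing is returned there
  cfg <- default_config()
  cfg$filtering$expression_cutoffs <- c(1e7, 1e8)
  r3 <- optimize_concordance(sim$counts, c("pooled_exact", "zlogfc"),
                             target = 0.001, config = cfg)
  expect_false(r3$attained)
})

test_that("identical DEG sets everywhere hit the first non-empty cell", {
  # two external tables with the same calls act as two perfectly agreeing
  # methods; the optimizer must return the first traversal cell whose
  # window holds at least one of their significant genes
  sim <- small_sim(seed = 60, n_genes = 300)
  x <- sim$counts
  res <- call_degs(x, "zlogfc")
  tab <- data.frame(gene_id = res$gene_id, log2fc = res$log2fc,
                    pvalue = res$pvalue, padj = res$padj)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  t1 <- read_deg_table(f, "copy1")
  t2 <- read_deg_table(f, "copy2")
  r <- optimize_concordance(x, methods = character(), target = 1,
                            external_tables = list(t1, t2))
  g <- concordance_grid(x, methods = character(),
                        external_tables = list(t1, t2))
  nonempty <- !is.na(g$cells$median_jaccard)
  oracle <- first_qualifying_cell(g$cells, 1)
  expect_true(r$attained)
  expect_equal(r$cutoff, oracle$cutoff)
  expect_equal(r$fc_lower, oracle$fc_lower)
  expect_equal(r$achieved_median, 1)
  expect_true(any(nonempty))
})
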