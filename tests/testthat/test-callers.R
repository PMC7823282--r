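test_that("Benjamini-Hochberg step-up matches hand-derived values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # step-up on a mixed vector, worked by hand:
  # sorted (0.005, 0.01, 0.04, 0.8); q4=0.8, q3=min(.04*4/3,.8)=.0533..,
  # q2=min(.01*2, .0533)=.02, q1=min(.005*4/1,.02)=.02
  expect_equal(bh_adjust(c(0.04, 0.005, 0.8, 0.01)),
               c(0.04 * 4 / 3, 0.02, 0.8, 0.02))
  set.seed(3)
  p <- stats::runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))               # pointwise no smaller
  expect_true(all(bh_adjust(q) >= q))    # re-adjusting never decreases
  expect_error_class(bh_adjust(c(0.1, 1.2)), "validation_error")
  expect_error_class(bh_adjust(c(0.1, NA)), "validation_error")
})

test_that("pooled exact test agrees with margin-conditioned enumeration", {
  # all 2x2 tables with both library margins <= 12
  for (libA in c(1, 5, 12)) {
    for (libB in c(1, 7, 12)) {
      for (total in seq_len(libA + libB)) {
        support <- max(0, total - libB):min(total, libA)
        for (a in support) {
          expect_equal(consensusDEG:::.hyper_twosided(a, libA, libB, total),
                       enum_hyper_p(a, libA, libB, total), tolerance = 1e-12)
        }
      }
    }
  }
  # 10 of 1000 vs 0 of 1000, against the enumeration oracle
  expect_equal(consensusDEG:::.hyper_twosided(10, 1000, 1000, 10),
               enum_hyper_p(10, 1000, 1000, 10), tolerance = 1e-12)
  # matches the exact conditional test as implemented by fisher.test
  ft <- stats::fisher.test(matrix(c(10, 990, 0, 1000), 2))$p.value
  expect_equal(consensusDEG:::.hyper_twosided(10, 1000, 1000, 10), ft,
               tolerance = 1e-10)
})

test_that("pooled exact caller gives p = 1 under identical pooled proportions", {
  m <- rbind(gk = c(5, 5, 5, 5), rest = c(495, 495, 495, 495))
  colnames(m) <- paste0("s", 1:4)
  cm <- count_matrix(m, stats::setNames(c("A", "A", "B", "B"), colnames(m)))
  res <- call_degs(cm, "pooled_exact")
  expect_equal(res$pvalue[res$gene_id == "gk"], 1)
  expect_false(any(res$significant))
})

test_that("rank-sum caller is exact without ties and needs 3 replicates", {
  # 3 vs 3, maximal separation, no ties: every A value above every B value.
  # Exhaustive enumeration over the choose(6,3) = 20 equally likely rank
  # assignments gives two-sided p = 2/20 = 0.1.
  m <- rbind(g = c(100, 110, 120, 10, 20, 30), filler = c(50, 60, 55, 52, 58, 61))
  colnames(m) <- paste0("s", 1:6)
  cm <- count_matrix(m, stats::setNames(rep(c("A", "B"), each = 3), colnames(m)))
  res <- call_degs(cm, "rank_sum", scaling = "none")
  expect_equal(res$pvalue[res$gene_id == "g"], 0.1)

  # agreement with the standard exact implementation on random tie-free data
  set.seed(8)
  vals <- matrix(sample.int(10000, 5 * 10), 5, 10)
  dimnames(vals) <- list(paste0("g", 1:5), paste0("s", 1:10))
  cmr <- count_matrix(vals, stats::setNames(rep(c("A", "B"), each = 5),
                                            colnames(vals)))
  mine <- call_degs(cmr, "rank_sum", scaling = "none")
  ref <- apply(vals, 1, function(v)
    stats::wilcox.test(v[1:5], v[6:10], exact = TRUE)$p.value)
  expect_equal(mine$pvalue, unname(ref), tolerance = 1e-12)

  expect_error_class(
    call_degs(subset_count_matrix(cmr, samples = c("s1", "s2", "s6", "s7")),
              "rank_sum"),
    "capability_error")
})

test_that("NB Wald caller is null-centred at equal means and honours offsets", {
  m <- rbind(g1 = rep(c(40, 42, 38, 41, 39), 2),
             g2 = rep(c(7, 9, 8, 8, 8), 2))
  colnames(m) <- paste0("s", 1:10)
  cm <- count_matrix(m, stats::setNames(rep(c("A", "B"), each = 5), colnames(m)))
  res <- call_degs(cm, "nb_wald")
  expect_equal(res$log2fc, c(0, 0), tolerance = 1e-8)
  expect_equal(res$pvalue, c(1, 1), tolerance = 1e-6)

  # a 1-vs-1 pair requires a fixed dispersion
  pair <- subset_count_matrix(cm, samples = c("s1", "s6"))
  expect_error_class(call_degs(pair, "nb_wald"), "capability_error")
  res1 <- call_degs(pair, "nb_wald", dispersion = 0.05)
  expect_equal(nrow(res1), 2L)
  expect_true(all(res1$pvalue >= 0 & res1$pvalue <= 1))
})

test_that("zlogfc recovers the sign and scale of planted fold changes", {
  sim <- small_sim(seed = 31, n_genes = 600)
  res <- call_degs(sim$counts, "zlogfc")
  strong <- sim$truth$is_deg & sim$truth$oriented_fc >= 2 &
    sim$truth$baseline >= 100
  expect_gt(sum(strong), 3)
  expect_equal(sign(res$log2fc[strong]),
               sign(log(sim$truth$true_fc[strong])))
  expect_true(all(res$significant == (res$padj < 0.05)))
})

test_that("significance is exactly the adjusted-p threshold rule", {
  sim <- small_sim(seed = 12, n_genes = 400)
  for (alpha in c(0.05, 0.001)) {
    res <- call_degs(sim$counts, "pooled_exact", alpha = alpha)
    expect_identical(res$significant, res$padj < alpha)
  }
})

test_that("external DEG tables adapt to a universe without re-adjustment", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj",
               "g1\t2\t0.0001\t0.001",
               "g2\t0.1\t0.1\t0.2",
               "g3\t1\t0.001\t0.04"), f)
  tab <- read_deg_table(f, "edger_run")
  ds <- adapt_external_degs(tab, universe = c("g1", "g2"), alpha = 0.05,
                            quiet = TRUE)
  expect_s3_class(ds, "deg_set")
  expect_equal(ds$genes, "g1")          # g3 significant but outside universe
  expect_equal(ds$method_id, "external:edger_run")
  expect_message(
    adapt_external_degs(tab, universe = c("g1", "g9"), alpha = 0.05),
    "absent")
  expect_length(adapt_external_degs(tab, character(), quiet = TRUE)$genes, 0L)
})

test_that("window stratification splits significant sets without re-testing", {
  sim <- small_sim(seed = 21, n_genes = 500)
  x <- sim$counts
  res <- list(pe = call_degs(x, "pooled_exact"), zl = call_degs(x, "zlogfc"))
  fc <- fold_changes(condition_summary(x), 0.5)
  strata <- stratify_deg_sets(res, fc, cutoff = 0)
  expect_length(strata, 5L)
  # union over windows == significant genes with a windowed fold change
  for (nm in seq_along(res)) {
    sig <- res[[nm]]$gene_id[res[[nm]]$significant]
    strat_union <- unlist(lapply(strata, function(s) s[[nm]]$genes))
    expect_setequal(strat_union, intersect(sig, fc$gene_id[!fc$undefined]))
    expect_false(anyDuplicated(strat_union) > 0)  # windows partition
  }
})
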