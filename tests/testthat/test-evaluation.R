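test_that("hold-out plans are disjoint, reproducible, and size-checked", {
  sim <- small_sim(seed = 2, n_genes = 100, n_replicates = 7)
  plan <- make_holdout_plan(sim$counts, 4, 3, seed = 5)
  expect_length(plan$reference$A, 4L)
  expect_length(plan$reference$B, 4L)
  expect_equal(nrow(plan$pairs), 3L)
  all_ref <- c(plan$reference$A, plan$reference$B)
  all_pred <- c(plan$pairs$sample_a, plan$pairs$sample_b)
  expect_length(intersect(all_ref, all_pred), 0L)
  expect_false(anyDuplicated(all_pred) > 0)
  # one sample from each condition per pair
  expect_true(all(sim$counts$design[plan$pairs$sample_a] == "A"))
  expect_true(all(sim$counts$design[plan$pairs$sample_b] == "B"))

  plan2 <- make_holdout_plan(sim$counts, 4, 3, seed = 5)
  expect_identical(plan, plan2)
  plan3 <- make_holdout_plan(sim$counts, 4, 3, seed = 6)
  expect_false(identical(plan$pairs, plan3$pairs))

  expect_error_class(make_holdout_plan(sim$counts, 4, 4, seed = 1),
                     "sizing_error")
})

test_that("precision and recall match hand counts and conventions", {
  u <- letters[1:10]
  rs <- build_reference_standard(
    list(deg_set("m1", c("a", "b", "e")), deg_set("m2", c("a", "b", "e"))),
    "intersection", universe = u)
  pr <- precision_recall(c("a", "b", "c", "d"), rs)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 2 / 3)
  expect_equal(pr$tp, 2L)

  ident <- precision_recall(rs$positives, rs)
  expect_equal(c(ident$precision, ident$recall), c(1, 1))

  none <- precision_recall(character(), rs)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  # genes outside the universe are dropped (and counted)
  expect_message(out <- precision_recall(c("a", "zz"), rs), "dropped 1")
  expect_equal(out$n_dropped, 1L)
  expect_equal(out$precision, 1)

  # no positives: recall undefined
  rs0 <- build_reference_standard(
    list(deg_set("m1", character()), deg_set("m2", character())),
    "intersection", universe = u)
  expect_true(is.na(precision_recall("a", rs0)$recall))
})

test_that("metrics are invariant under a consistent gene relabelling", {
  set.seed(44)
  u <- sprintf("g%03d", 1:50)
  pred <- sample(u, 15)
  rs <- build_reference_standard(
    list(deg_set("m1", sample(u, 20)), deg_set("m2", sample(u, 20))),
    "majority", universe = u)
  map <- stats::setNames(sprintf("X%03d", sample(50)), u)
  rs2 <- rs
  rs2$positives <- sort(unname(map[rs$positives]))
  rs2$universe <- sort(unname(map[rs$universe]))
  p1 <- precision_recall(pred, rs, quiet = TRUE)
  p2 <- precision_recall(unname(map[pred]), rs2, quiet = TRUE)
  expect_equal(p1[c("precision", "recall", "tp")],
               p2[c("precision", "recall", "tp")])
})

test_that("evaluation refuses isomorphic configurations", {
  sim <- small_sim(seed = 19, n_genes = 150)
  plan <- make_holdout_plan(sim$counts, 4, 3, seed = 1)
  expect_error_class(
    evaluate_prediction_method(sim$counts, plan, "pooled_exact",
                               rs_methods = deg_methods(),
                               rs_exclude = character(),
                               region = list(cutoff = 0, fc_lower = 1,
                                             fc_upper = Inf)),
    "bias_guard_error")
})

test_that("the report composes per-pair precision_recall calls", {
  sim <- small_sim(seed = 28, n_genes = 400)
  x <- sim$counts
  plan <- make_holdout_plan(x, 4, 3, seed = 9)
  region <- list(cutoff = 10, fc_lower = 1.5, fc_upper = Inf)
  rep <- evaluate_prediction_method(
    x, plan, "pooled_exact", rs_methods = c("nb_wald", "zlogfc"),
    rs_rule = "majority", region = region)
  expect_equal(nrow(rep$pairs), 3L)
  # averages are the arithmetic mean of the defined per-pair values
  expect_equal(rep$average_precision,
               mean(rep$pairs$precision, na.rm = TRUE))
  expect_equal(rep$average_recall, mean(rep$pairs$recall, na.rm = TRUE))
  expect_equal(rep$provenance$seed, 9L)
  expect_false(rep$provenance$prediction_method %in% rep$provenance$rs_methods)

  # recomposing the protocol by hand gives the same numbers: rebuild the
  # standard from the reference samples, predict each pair, score, average
  cfg <- default_config()
  ref_cm <- subset_count_matrix(x, samples = c(plan$reference$A,
                                               plan$reference$B))
  ev <- consensusDEG:::.evaluate_cutoff(ref_cm, region$cutoff,
                                        c("nb_wald", "zlogfc"), cfg)
  rs <- build_reference_standard(ev$sets_by_win[[5L]], "majority",
                                 universe = ev$universe)
  phi <- stats::median(estimate_dispersion(ref_cm))
  hand <- vapply(seq_len(3), function(i) {
    pred <- consensusDEG:::.predict_pair(
      x, plan$pairs$sample_a[i], plan$pairs$sample_b[i], "pooled_exact",
      region, cfg, phi, TRUE)
    pr <- precision_recall(pred, rs, quiet = TRUE)
    c(pr$precision, pr$recall)
  }, numeric(2))
  expect_equal(rep$pairs$precision, unname(hand[1, ]))
  expect_equal(rep$pairs$recall, unname(hand[2, ]))
  expect_equal(rep$reference_standard$n_positive, length(rs$positives))
})

test_that("truth-built standards agree with direct truth metrics", {
  sim <- small_sim(seed = 33, n_genes = 300)
  u <- gene_ids(sim$counts)
  truth_pos <- sim$truth$gene_id[sim$truth$is_deg]
  rs <- build_reference_standard(
    list(deg_set("oracle1", truth_pos), deg_set("oracle2", truth_pos)),
    "intersection", universe = u)
  set.seed(1)
  pred <- sample(u, 40)
  a <- precision_recall(pred, rs, quiet = TRUE)
  b <- truth_metrics(pred, sim$truth)
  expect_equal(a$precision, b$precision)
  expect_equal(a$recall, b$recall)
})
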