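# Kernel classifier protocols, multiclass extension, tiered scheme.

test_that("build_features is the log2 ratio matrix, column-stable", {
  expr <- tiny_expr()
  panel <- manual_panel(c("PGK1", "HRAS"), c("POU6F1", "TBP"), c(1, 1))
  f <- build_features(expr, panel)
  expect_equal(dim(f), c(8L, 2L))
  # hand computation on the tiny fixture's exact CTs: log2(num/den) =
  # ct_den - ct_num
  tab <- make_fixture("tiny")
  expect_equal(unname(f[, "PGK1/POU6F1"]),
               unname(tab$ct[, "POU6F1"] - tab$ct[, "PGK1"]))
  # permuting panel order permutes columns identically
  panel_rev <- manual_panel(c("HRAS", "PGK1"), c("TBP", "POU6F1"), c(1, 1))
  f2 <- build_features(expr, panel_rev)
  expect_equal(f2, f[, 2:1])
  expect_error(build_features(expr, manual_panel("NOPE", "TBP", 1)), "NOPE")
})

test_that("subset-grid protocol separates separable blobs with 0 errors", {
  d <- blob_data(n_per = 15, sep = 6)
  cfg <- train_config("subset_grid", 0.6, n_random_subsets = 5L,
                      grid = small_grid(), seed = 3)
  clf <- train_subset_grid(d$x, d$labels, cfg, positive_label = "B")
  expect_equal(clf$tuning$total_errors, 0)
  expect_equal(unname(predict(clf, d$x)), d$labels)
  # decision scores are invariant to subject order
  perm <- sample(nrow(d$x))
  expect_equal(decision_scores(clf, d$x[perm, ]),
               decision_scores(clf, d$x)[perm])
})

test_that("both protocols are deterministic given (data, config, seed)", {
  d <- blob_data(n_per = 12, sep = 3, seed = 8)
  cfg <- train_config("subset_grid", 0.6, n_random_subsets = 4L,
                      grid = small_grid(), seed = 11)
  a <- train_subset_grid(d$x, d$labels, cfg, positive_label = "B")
  b <- train_subset_grid(d$x, d$labels, cfg, positive_label = "B")
  expect_identical(decision_scores(a, d$x), decision_scores(b, d$x))
  cfg2 <- train_config("cv_holdout", 0.6, n_folds = 5L,
                       grid = small_grid(), seed = 11)
  r1 <- train_cv_holdout(d$x, d$labels, cfg2, positive_label = "B")
  r2 <- train_cv_holdout(d$x, d$labels, cfg2, positive_label = "B")
  expect_identical(r1$report, r2$report)
})

test_that("cv-holdout report satisfies the Tc + Ti = TOTAL layout", {
  d <- blob_data(n_per = 20, sep = 5, seed = 4)
  for (fam in c("radial_basis", "polynomial")) {
    cfg <- train_config("cv_holdout", 0.6, n_folds = 5L, family = fam,
                        grid = if (fam == "radial_basis") small_grid() else
                          list(width_or_degree = 1:3,
                               soft_margin_C = 2 ^ c(-2, 0, 2)),
                        seed = 21)
    res <- train_cv_holdout(d$x, d$labels, cfg, positive_label = "B")
    rep <- res$report
    expect_equal(rep$set, c("total", "training", "validation"))
    expect_equal(rep$Tc + rep$Ti, rep$TOTAL)
    expect_equal(rep$TOTAL[1], nrow(d$x))
    expect_equal(rep$TOTAL[2] + rep$TOTAL[3], rep$TOTAL[1])
    expect_equal(rep$pct_I, trunc(100 * rep$Ti / rep$TOTAL + 0.5))
    # separable data: no training errors
    expect_equal(rep$Ti[rep$set == "training"], 0)
  }
})

test_that("the two protocols agree on nearly all calls given identical features", {
  eff <- list(effect_spec("G1", "up", 6, 0.8), effect_spec("G2", "down", 6, 0.8))
  expr <- ct_to_relative(small_cohort(25, 25, eff, seed = 14))
  fit <- fit_ratioscore(expr, "CD", "CTRL", reps = 20, top_k = 20, seed = 15)
  f <- build_features(expr, fit$panel)
  labs <- unname(expr$groups)
  c1 <- train_subset_grid(f, labs, train_config(
    "subset_grid", 0.6, n_random_subsets = 10L, grid = small_grid(),
    seed = 5), positive_label = "CD")
  c2 <- train_cv_holdout(f, labs, train_config(
    "cv_holdout", 0.6, n_folds = 5L, grid = small_grid(), seed = 5),
    positive_label = "CD")$classifier
  agree <- mean(predict(c1, f) == predict(c2, f))
  expect_gte(agree, 0.9)
})

test_that("multiclass union mode deduplicates and enlarges the feature set", {
  expr <- ct_to_relative(make_fixture("paperlike", seed = 77))
  cfg <- train_config("subset_grid", 0.6, n_random_subsets = 5L,
                      grid = small_grid(), seed = 5)
  m_cc <- train_multiclass(expr, c("CTRL", "UC", "CD"), "case_vs_control",
                           reps = 15, top_k = 30, config = cfg, seed = 42)
  m_un <- train_multiclass(expr, c("CTRL", "UC", "CD"), "union",
                           reps = 15, top_k = 30, config = cfg, seed = 42)
  key <- paste(m_un$ratios$numerator, m_un$ratios$denominator)
  expect_false(anyDuplicated(key) > 0)
  expect_gte(nrow(m_un$ratios), nrow(m_cc$ratios))
  # disjoint CD-only signature (ANAPC1/RANGAP1/TP53 down): the union mode
  # should classify at least as well on average
  expect_gte(mean(m_un$train_recall), mean(m_cc$train_recall) - 0.02)
  expect_error(train_multiclass(expr, c("CTRL", "UC", "CeD"),
                                config = cfg, seed = 1), "CeD")
})

test_that("tiered classification routes IBD-positives to stage 2", {
  expr <- ct_to_relative(make_fixture("paperlike", seed = 31))
  cfg <- train_config("subset_grid", 0.6, n_random_subsets = 5L,
                      grid = small_grid(), seed = 9)
  # stage 1: IBD vs IBS
  rows1 <- which(expr$groups %in% c("CD", "UC", "IBS"))
  f1 <- fit_ratioscore(expr, c("CD", "UC"), "IBS", reps = 15, top_k = 30,
                       seed = 71)
  subj1 <- rownames(expr$levels)[rows1]
  labs1 <- ifelse(expr$groups[subj1] %in% c("CD", "UC"), "IBD", "IBS")
  s1 <- train_subset_grid(build_features(expr, f1$panel, subjects = subj1),
                          labs1, cfg, positive_label = "IBD",
                          panel = f1$panel)
  # stage 2: CD vs UC
  f2 <- fit_ratioscore(expr, "CD", "UC", reps = 15, top_k = 30, seed = 72)
  rows2 <- which(expr$groups %in% c("CD", "UC"))
  subj2 <- rownames(expr$levels)[rows2]
  s2 <- train_subset_grid(build_features(expr, f2$panel, subjects = subj2),
                          unname(expr$groups[subj2]), cfg,
                          positive_label = "CD", panel = f2$panel)
  out <- tiered_classify(expr, s1, s2, subjects = subj1)
  expect_setequal(unique(out), intersect(c("IBS", "CD", "UC"), out))
  # IBS-assigned subjects never receive a stage-2 label
  p1 <- classify_expr(s1, expr, subjects = subj1)
  expect_true(all(out[p1 == "IBS"] == "IBS"))
  # stage-2 labels only among stage-1 IBD calls
  expect_true(all(out[p1 == "IBD"] %in% c("CD", "UC")))
  # composition sanity: overall recall on CD+UC close to the product of
  # the stage recalls
  truth <- expr$groups[subj1]
  rec1 <- mean(p1[truth %in% c("CD", "UC")] == "IBD")
  p2 <- classify_expr(s2, expr, subjects = subj2)
  rec2 <- mean(p2 == expr$groups[subj2])
  rec_tiered <- mean(out[truth %in% c("CD", "UC")] ==
                       truth[truth %in% c("CD", "UC")])
  expect_gte(rec_tiered, rec1 * rec2 - 0.1)
})

test_that("classifiers round-trip through JSON serialization", {
  d <- blob_data(n_per = 10, sep = 4, seed = 2)
  panel <- manual_panel("PGK1", "POU6F1", 1.5)
  cfg <- train_config("subset_grid", 0.6, n_random_subsets = 3L,
                      grid = small_grid(), seed = 6)
  clf <- train_subset_grid(d$x, d$labels, cfg, positive_label = "B",
                           panel = panel)
  f <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, f)
  back <- read_classifier(f)
  expect_equal(decision_scores(back, d$x), decision_scores(clf, d$x),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$panel)$numerator, "PGK1")
})

test_that("kernel and config validation", {
  expect_error(kernel_spec("radial_basis", -1, 1), "positive")
  expect_error(kernel_spec("radial_basis", 1, 0), "positive")
  expect_error(train_config("subset_grid", 1.2, seed = 1), "train_fraction")
  expect_error(train_config("cv_holdout", 0.6, n_folds = 1, seed = 1),
               "n_folds")
  expect_error(train_config("subset_grid", 0.6,
                            grid = list(width_or_degree = numeric(0),
                                        soft_margin_C = 1), seed = 1),
               "empty")
  d <- blob_data(n_per = 5)
  cfg <- train_config("subset_grid", 0.6, n_random_subsets = 2L,
                      grid = small_grid(), seed = 1)
  expect_error(train_subset_grid(d$x, rep("A", 10), cfg), "exactly 2")
})
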