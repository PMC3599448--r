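# The ratioscore method: separation counts, resampled search, greedy panel
# assembly, scoring.

test_that("separation_count counts strict exceedances of the control max", {
  expect_equal(separation_count(c(2.5, 3.5, 4.0), c(1.0, 2.0, 3.0)), 2)
  expect_equal(separation_count(c(1.5, 2.0), c(1.0, 3.0)), 0)
  expect_error(separation_count(c(1, 2), numeric(0)), "empty control")
  # brute-force oracle on random draws
  set.seed(99)
  for (i in 1:20) {
    cs <- runif(10); ct <- runif(10)
    oracle <- sum(vapply(cs, function(v) all(v > ct), logical(1)))
    expect_equal(separation_count(cs, ct), oracle)
  }
})

test_that("a planted dominant ratio is selected in every repetition", {
  # numerator up x8, denominator down x8, penetrance 1: log2 ratio shifts
  # by 6 cycles, far beyond the 0.35-cycle noise
  eff <- list(effect_spec("G1", "up", 8, 1), effect_spec("G2", "down", 8, 1))
  expr <- ct_to_relative(small_cohort(15, 15, eff, seed = 21))
  cand <- search_candidates(expr, "CD", "CTRL", reps = 25, top_k = 10,
                            seed = 31)
  top <- cand[1, ]
  expect_equal(top$numerator, "G1")
  expect_equal(top$denominator, "G2")
  expect_equal(top$selection_frequency, 1.0)
  expect_equal(top$separation_count, 15L)
})

test_that("search equals exhaustive enumeration when subsampling is the whole group", {
  # at resample_frac = 1 every repetition sees the full groups and the
  # search reduces to plain enumeration by separation count
  eff <- list(effect_spec("G1", "up", 8, 1), effect_spec("G2", "down", 4, 1))
  expr <- ct_to_relative(small_cohort(5, 5, eff, seed = 61,
                                      panel = c("GAPDH", paste0("G", 1:4))))
  cand <- search_candidates(expr, "CD", "CTRL", resample_frac = 1,
                            reps = 3, top_k = 2, seed = 5)
  probes <- colnames(expr$levels)
  case <- expr$levels[expr$groups == "CD", , drop = FALSE]
  ctrl <- expr$levels[expr$groups == "CTRL", , drop = FALSE]
  seps <- list()
  for (num in probes) for (den in probes) if (num != den) {
    seps[[paste(num, den, sep = "/")]] <-
      separation_count(case[, num] / case[, den], ctrl[, num] / ctrl[, den])
  }
  seps <- unlist(seps)
  best <- sort(seps, decreasing = TRUE)[1:2]
  keys <- paste(cand$numerator, cand$denominator, sep = "/")
  # retained candidates carry the exhaustively computed separation counts
  expect_equal(cand$separation_count, unname(seps[keys]))
  # and the retained set is exactly a top-2 by separation count
  expect_equal(sort(cand$separation_count, decreasing = TRUE), unname(best))
  expect_true(all(cand$selection_frequency == 1))
})

test_that("search is deterministic given the seed and requires one", {
  expr <- ct_to_relative(small_cohort(10, 10, list(), seed = 1))
  a <- search_candidates(expr, "CD", "CTRL", reps = 5, top_k = 5, seed = 2)
  b <- search_candidates(expr, "CD", "CTRL", reps = 5, top_k = 5, seed = 2)
  expect_identical(a, b)
  expect_error(search_candidates(expr, "CD", "CTRL"), "seed")
  expect_error(search_candidates(subset_expr(expr, 1:8), "CD", "CTRL",
                                 seed = 1), "at least 5")
})

test_that("panel thresholds are training-control maxima; training controls score 0", {
  eff <- list(effect_spec("G1", "up", 8, 0.7), effect_spec("G2", "down", 8, 0.7))
  expr <- ct_to_relative(small_cohort(20, 20, eff, seed = 77))
  fit <- fit_ratioscore(expr, "CD", "CTRL", reps = 20, top_k = 20, seed = 8)
  ctrl <- expr$levels[expr$groups == "CTRL", , drop = FALSE]
  for (i in seq_len(nrow(fit$panel))) {
    expect_equal(fit$panel$threshold[i],
                 max(ctrl[, fit$panel$numerator[i]] /
                       ctrl[, fit$panel$denominator[i]]))
  }
  ctrl_scores <- fit$scores[fit$scores$group == "CTRL", ]
  expect_true(all(ctrl_scores$ratioscore == 0L))
  expect_true(all(ctrl_scores$call == "negative"))
  expect_equal(fit$control_specificity, 1.0)
  # greedy dominance: panel coverage >= best single candidate's coverage
  expect_gte(fit$case_coverage,
             max(fit$candidates$separation_count) /
               sum(expr$groups == "CD"))
})

test_that("scoring produces the indicator tuple, score and call", {
  lv <- matrix(c(4, 2, 1, 8), 1, 4,
               dimnames = list("S1", c("A", "B", "C", "D")))
  expr <- expr_from_levels(lv, "CD")
  # ratios A/B=2, A/C=4, B/D=0.25 with thresholds 1.5, 8, 1
  panel <- manual_panel(c("A", "A", "B"), c("B", "C", "D"), c(1.5, 8, 1))
  sc <- score_subjects(panel, expr)
  expect_equal(sc$tuple, "100")
  expect_equal(sc$ratioscore, 1L)
  expect_equal(sc$call, "positive")
  # all below threshold -> all-zero tuple, negative
  panel0 <- manual_panel(c("A", "A"), c("B", "C"), c(10, 10))
  sc0 <- score_subjects(panel0, expr)
  expect_equal(sc0$tuple, "00")
  expect_equal(sc0$call, "negative")
  expect_error(score_subjects(manual_panel("A", "Z", 1), expr), "Z")
})

test_that("adding control subjects can only shrink case exceedance sets", {
  set.seed(13)
  expr <- ct_to_relative(small_cohort(20, 10, list(), seed = 3))
  case <- expr$levels[expr$groups == "CD", "G1"] /
    expr$levels[expr$groups == "CD", "G2"]
  ctrl <- expr$levels[expr$groups == "CTRL", "G1"] /
    expr$levels[expr$groups == "CTRL", "G2"]
  for (k in c(5, 10, 15, 20)) {
    small <- case > max(ctrl[1:k])
    full <- case > max(ctrl)
    expect_true(all(small | !full))  # exceed-full implies exceed-subset
  }
})

test_that("coverage is the fraction of positive calls", {
  df <- data.frame(group = rep("CD", 50),
                   ratioscore = c(rep(1L, 47), rep(0L, 3)))
  expect_equal(coverage(df), 0.94)
  df$ratioscore <- 0L
  expect_equal(coverage(df), 0)
  df$ratioscore <- 5L
  expect_equal(coverage(df), 1)
})

test_that("panels serialize to JSON and back", {
  panel <- manual_panel(c("PGK1", "HRAS"), c("POU6F1", "TBP"),
                        c(1.25, 2.5), case_label = c("CD", "UC"))
  f <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, f)
  back <- read_panel(f)
  expect_equal(as.data.frame(back), as.data.frame(panel))
  expect_equal(attr(back, "case_label"), c("CD", "UC"))
})

test_that("selected panels contain planted probes at full penetrance", {
  # parameter recovery: with effects in known genes at penetrance 1, every
  # covered case owes its coverage to a ratio touching a planted probe
  eff <- list(effect_spec("G1", "up", 6, 1), effect_spec("G4", "down", 6, 1))
  expr <- ct_to_relative(small_cohort(15, 15, eff, seed = 17))
  fit <- fit_ratioscore(expr, "CD", "CTRL", reps = 20, top_k = 20, seed = 19)
  panel_probes <- unique(c(fit$panel$numerator, fit$panel$denominator))
  expect_true(any(c("G1", "G4") %in% panel_probes))
  ind <- attr(fit$scores, "indicators")
  case_rows <- fit$scores$group == "CD"
  touched <- grepl("G1|G4", colnames(ind))
  covered <- rowSums(ind[case_rows, , drop = FALSE]) > 0
  covered_by_planted <-
    rowSums(ind[case_rows, touched, drop = FALSE]) > 0
  expect_true(all(covered_by_planted[covered]))
})
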