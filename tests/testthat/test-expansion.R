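crit <- expansion_criteria()

test_that("criteria validate and round-trip through JSON", {
  expect_equal(crit$new_min_freq, 2.5e-4)
  expect_equal(crit$increased_min_fold, 10)
  expect_equal(crit$increased_min_freq, 1e-4)
  expect_error(expansion_criteria(new_min_freq = 0),
    class = "clonotrack_value_error")
  expect_error(expansion_criteria(increased_min_fold = -1),
    class = "clonotrack_value_error")

  tf <- withr::local_tempfile(fileext = ".json")
  write_criteria_json(crit, tf)
  parsed <- jsonlite::read_json(tf)
  expect_equal(parsed$new_min_freq_pct, 0.025)
  expect_equal(parsed$increased_min_freq_pct, 0.01)
  back <- read_criteria_json(tf)
  expect_equal(back, crit, ignore_attr = TRUE)
})

test_that("pair_samples union-joins clone sets with absence as zero", {
  b <- make_sample(10, ids = "A", frequencies = TRUE)
  f <- make_sample(10, ids = "B", sample_id = "s2", timepoint_days = 30L,
    frequencies = TRUE)
  pairs <- pair_samples(b, f)
  expect_equal(nrow(pairs), 2)
  a_row <- pairs[pairs$rearrangement == "A", ]
  expect_equal(a_row$baseline_templates, 10L)
  expect_equal(a_row$followup_templates, 0L)
  expect_equal(a_row$followup_freq, 0)
  b_row <- pairs[pairs$rearrangement == "B", ]
  expect_equal(b_row$baseline_templates, 0L)
  expect_equal(b_row$followup_templates, 10L)

  ident <- pair_samples(b, make_sample(10, ids = "A", sample_id = "s2",
    timepoint_days = 30L, frequencies = TRUE))
  expect_equal(ident$baseline_freq, ident$followup_freq)

  empty_fu <- make_sample(integer(0), ids = character(0),
    status = character(0), sample_id = "s2")
  empty_fu$frequency <- numeric(0)
  pairs0 <- pair_samples(b, empty_fu)
  expect_true(all(pairs0$followup_templates == 0))
})

test_that("pairing samples from different subjects needs an override", {
  b <- make_sample(10, ids = "A", frequencies = TRUE)
  f <- make_sample(10, ids = "A", sample_id = "s2", subject_id = "p2",
    timepoint_days = 30L, frequencies = TRUE)
  expect_error(pair_samples(b, f), class = "clonotrack_value_error")
  expect_equal(nrow(pair_samples(b, f, check_subject = FALSE)), 1)
})

test_that("classification applies the strict frequency and fold thresholds", {
  # followup frequencies built as templates/2e5 so percentages are exact
  cases <- tibble::tribble(
    ~baseline_templates, ~baseline_total, ~followup_templates, ~expected,
    0L,   2e5, 60L, "new",       # absent -> 0.03% > 0.025%
    0L,   2e5, 40L, "none",      # absent -> 0.02% below the new rule
    2L,   2e5, 40L, "increased", # 0.001% -> 0.02%, 20-fold
    10L,  2e5, 80L, "none",      # 0.005% -> 0.04%, only 8-fold
    4L,   2e5, 40L, "none"       # 0.002% -> 0.02%, exactly tenfold: strict
  )
  pairs <- tibble::tibble(
    rearrangement = sprintf("C%d", seq_len(nrow(cases))),
    baseline_templates = cases$baseline_templates,
    baseline_freq = cases$baseline_templates / cases$baseline_total,
    followup_templates = cases$followup_templates,
    followup_freq = cases$followup_templates / 2e5,
    baseline_total = cases$baseline_total,
    followup_total = 2e5
  )
  out <- classify_expansion(pairs, crit)
  expect_equal(as.character(out$category), cases$expected)
  expect_true(is.na(out$fold_change[1]))
  expect_equal(out$fold_change[3], 20)
})

test_that("decision boundaries sit exactly at the thresholds", {
  # new: scan follow-up template counts at total 2e5 with absent baseline
  ks <- 0:200
  pairs <- make_pair(rep(0L, length(ks)), ks,
    ids = sprintf("K%03d", ks))
  cat_new <- classify_expansion(pairs, crit)$category
  boundary_new <- max(ks[cat_new == "none"])
  expect_identical(boundary_new, 50L) # 50/2e5 = 0.025%
  expect_true(all(cat_new[ks > 50] == "new"))

  # increased frequency floor: baseline tiny so fold is astronomically met
  pairs_inc <- tibble::tibble(
    rearrangement = sprintf("K%03d", ks),
    baseline_templates = 1L, baseline_freq = 1e-9,
    followup_templates = ks, followup_freq = ks / 2e5,
    baseline_total = 1e9, followup_total = 2e5
  )
  cat_inc <- classify_expansion(pairs_inc, crit)$category
  expect_identical(max(ks[cat_inc == "none"]), 20L) # 20/2e5 = 0.01%
  expect_true(all(cat_inc[ks > 20] == "increased"))

  # fold boundary: follow-up frequency fixed far above the floor
  folds <- seq(8, 12, by = 0.5)
  pairs_fold <- tibble::tibble(
    rearrangement = sprintf("F%02d", seq_along(folds)),
    baseline_templates = 100L,
    baseline_freq = 1e-3 / folds,
    followup_templates = 200L,
    followup_freq = 1e-3,
    baseline_total = 2e5, followup_total = 2e5
  )
  cat_fold <- classify_expansion(pairs_fold, crit)$category
  expect_equal(as.character(cat_fold), ifelse(folds > 10, "increased", "none"))
})

test_that("raising the follow-up frequency never cancels a call", {
  withr::local_seed(5)
  rank_cat <- function(x) ifelse(x == "none", 0, 1)
  for (i in 1:20) {
    base_t <- sample(0:50, 1)
    fus <- sort(sample(0:300, 40))
    pairs <- tibble::tibble(
      rearrangement = sprintf("C%02d", seq_along(fus)),
      baseline_templates = base_t,
      baseline_freq = base_t / 2e5,
      followup_templates = fus,
      followup_freq = fus / 2e5,
      baseline_total = 2e5, followup_total = 2e5
    )
    cats <- rank_cat(classify_expansion(pairs, crit)$category)
    expect_true(all(diff(cats) >= 0),
      info = sprintf("baseline_templates=%d", base_t))
  }
})

test_that("call_expansions summarises categories and exposes tidy/glance", {
  # 5-clone baseline (total 10000, clone C0 at 0.1%); follow-up plants one
  # new clone at 0.1% and rises C0 by 25-fold to 2.5%
  b <- make_sample(c(4000, 3000, 2000, 990, 10),
    ids = c("C1", "C2", "C3", "C4", "C0"), frequencies = TRUE)
  f <- make_sample(c(3740, 3000, 2000, 1000, 250, 10),
    ids = c("C1", "C2", "C3", "C4", "C0", "NEW1"), sample_id = "s2",
    timepoint_days = 30L, frequencies = TRUE)

  calls <- call_expansions(b, f, crit)
  g <- glance(calls)
  expect_equal(g$n_new, 1L)
  expect_equal(g$n_increased, 1L)
  expect_equal(g$n_clonotypes, 6L)
  cc <- tidy(calls)
  expect_equal(cc$category[cc$rearrangement == "NEW1"], factor("new",
    levels = c("new", "increased", "none")))
  expect_equal(cc$category[cc$rearrangement == "C0"], factor("increased",
    levels = c("new", "increased", "none")))
  expect_setequal(names(cc),
    c("rearrangement", "baseline_freq", "followup_freq", "fold_change",
      "category"))

  same <- call_expansions(b, make_sample(c(4000, 3000, 2000, 990, 10),
    ids = c("C1", "C2", "C3", "C4", "C0"), sample_id = "s2",
    timepoint_days = 30L, frequencies = TRUE), crit)
  expect_equal(glance(same)$n_expanded, 0L)
})

test_that("resampling the same repertoire at depth yields no calls", {
  cfg <- simulation_config(n_clones = 2e4, depth = 2e5, seed = 101)
  base <- generate_baseline(cfg)
  c1 <- sample_counts(base$true_freq, cfg$depth, seed = 102)
  c2 <- sample_counts(base$true_freq, cfg$depth, seed = 103)
  pairs <- tibble::tibble(
    rearrangement = base$rearrangement,
    baseline_templates = c1, baseline_freq = c1 / sum(c1),
    followup_templates = c2, followup_freq = c2 / sum(c2),
    baseline_total = sum(c1), followup_total = sum(c2)
  )
  cats <- classify_expansion(pairs, crit)$category
  expect_equal(sum(cats != "none"), 0L)
})

test_that("calibration returns the least stringent admissible criteria", {
  quiet <- make_pair(c(100L, 50L), c(101L, 49L))
  sel <- calibrate_criteria(list(quiet), max_false_positives = 0)
  grid <- default_criteria_grid()
  expect_equal(sel$new_min_freq, grid$new_min_freq[1])
  expect_equal(sel$increased_min_freq, grid$increased_min_freq[1])
  expect_equal(sel$increased_min_fold, grid$increased_min_fold[1])

  # one clone jumping from absent to 0.02%: candidates above 0.02% pass,
  # 0.015% does not, at zero tolerated false positives
  jump <- make_pair(0L, 40L, ids = "J") # 40/2e5 = 0.02%
  small_grid <- tibble::tibble(
    new_min_freq = c(0.015, 0.025) / 100,
    increased_min_freq = 0.01 / 100,
    increased_min_fold = 10
  )
  sel2 <- calibrate_criteria(list(jump), grid = small_grid,
    max_false_positives = 0)
  expect_equal(sel2$new_min_freq, 2.5e-4)

  only_low <- small_grid[1, ]
  expect_error(
    calibrate_criteria(list(jump), grid = only_low,
      max_false_positives = 0),
    class = "clonotrack_value_error", regexp = "best achievable"
  )

  sel3 <- calibrate_criteria(list(jump), grid = small_grid,
    max_false_positives = 5)
  expect_equal(sel3$new_min_freq, 1.5e-4)
})
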