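crit <- expansion_criteria()

# One subject's samples: baseline day -7, follow-ups day 30/90, biopsy.
# Totals are 10000 so frequencies are round percentages.
make_timeline <- function(subject = "p1", with_biopsy = TRUE,
                          with_d90 = TRUE) {
  base <- make_sample(c(4000, 3000, 2000, 990, 10),
    ids = c("C1", "C2", "C3", "C4", "C0"), subject_id = subject,
    sample_id = paste0(subject, "_base"), frequencies = TRUE)
  d30 <- make_sample(c(3740, 3000, 2000, 1000, 250, 10),
    ids = c("C1", "C2", "C3", "C4", "C0", "NEW1"), subject_id = subject,
    sample_id = paste0(subject, "_d30"), timepoint_days = 30L,
    frequencies = TRUE)
  parts <- list(base, d30)
  if (with_d90) {
    # C0 stays 25-fold up; NEW1 drops below the new threshold (2/10000)
    d90 <- make_sample(c(3748, 3000, 2000, 1000, 250, 2),
      ids = c("C1", "C2", "C3", "C4", "C0", "NEW1"), subject_id = subject,
      sample_id = paste0(subject, "_d90"), timepoint_days = 90L,
      frequencies = TRUE)
    parts <- c(parts, list(d90))
  }
  if (with_biopsy) {
    biopsy <- make_sample(c(50, 30), ids = c("C0", "C9"),
      subject_id = subject, sample_id = paste0(subject, "_bx"),
      compartment = "tumor_biopsy", frequencies = TRUE)
    parts <- c(parts, list(biopsy))
  }
  dplyr::bind_rows(parts)
}

test_that("TIL status is biopsy membership, unknown without a biopsy", {
  biopsy <- make_sample(c(3, 1), ids = c("C0", "C9"),
    compartment = "tumor_biopsy")
  expect_true(classify_til("C0", biopsy))
  expect_false(classify_til("C1", biopsy))
  expect_identical(classify_til(c("C0", "C1"), NULL), c(NA, NA))
})

test_that("trajectories track the blood union against one baseline", {
  traj <- build_trajectories(make_timeline(), crit)
  union_ids <- c("C1", "C2", "C3", "C4", "C0", "NEW1")
  expect_setequal(unique(traj$rearrangement), union_ids)
  # conservation: one row per clone per blood timepoint, no duplicates
  expect_equal(nrow(traj), length(union_ids) * 3)
  expect_false(any(duplicated(traj[c("rearrangement", "timepoint_days")])))

  # baseline rows carry no expansion category
  expect_true(all(is.na(traj$category[traj$timepoint_days == -7])))

  # NEW1 is new at day 30, below threshold at day 90; C0 increased at both
  at <- function(id, day) traj[traj$rearrangement == id &
    traj$timepoint_days == day, ]
  expect_equal(as.character(at("NEW1", 30)$category), "new")
  expect_equal(as.character(at("NEW1", 90)$category), "none")
  expect_equal(as.character(at("C0", 30)$category), "increased")
  expect_equal(as.character(at("C0", 90)$category), "increased")
  expect_equal(at("NEW1", -7)$frequency, 0)

  # TIL labels come from the biopsy; biopsy-only clone C9 is not tracked
  expect_true(all(at("C0", 30)$is_til))
  expect_false(any(at("C1", 30)$is_til))
  expect_false("C9" %in% traj$rearrangement)
})

test_that("trajectories agree with direct expansion calls per follow-up", {
  samples <- make_timeline()
  traj <- build_trajectories(samples, crit)
  base <- dplyr::filter(samples, sample_id == "p1_base")
  for (day in c(30, 90)) {
    fu <- dplyr::filter(samples, timepoint_days == day,
      compartment == "blood")
    direct <- tidy(call_expansions(base, fu, crit))
    merged <- merge(direct,
      traj[traj$timepoint_days == day, c("rearrangement", "category")],
      by = "rearrangement")
    expect_equal(as.character(merged$category.x),
      as.character(merged$category.y))
  }
})

test_that("a baseline-only timeline yields trajectories without calls", {
  base_only <- dplyr::filter(make_timeline(with_d90 = FALSE),
    timepoint_days < 0 | compartment == "tumor_biopsy")
  traj <- build_trajectories(base_only, crit)
  expect_equal(unique(traj$timepoint_days), -7L)
  expect_true(all(is.na(traj$category)))
})

test_that("without a biopsy every TIL flag is unknown", {
  traj <- build_trajectories(make_timeline(with_biopsy = FALSE), crit)
  expect_true(all(is.na(traj$is_til)))
})

test_that("persistence requires expansion at both follow-ups", {
  traj <- build_trajectories(make_timeline(), crit)
  pers <- persistent_expansions(traj, 30, 90)
  expect_setequal(unique(pers$rearrangement), "C0") # NEW1 faded by day 90

  # subset relation: persistent clones are expanded at the early timepoint
  early <- traj$rearrangement[traj$timepoint_days == 30 &
    traj$category != "none"]
  expect_true(all(unique(pers$rearrangement) %in% early))

  expect_error(persistent_expansions(traj, 30, 180),
    class = "clonotrack_value_error")
  expect_equal(nrow(persistent_expansions(traj[0, ], 30, 90)), 0)
})

test_that("per-patient summaries reproduce per-pair calls and TIL splits", {
  # three patients with 2, 0 and 1 expansions planted at day 30
  p1 <- make_timeline("p1") # NEW1 + C0 -> 2 expansions
  p2_base <- make_sample(c(5000, 5000), ids = c("A1", "A2"),
    subject_id = "p2", sample_id = "p2_base", frequencies = TRUE)
  p2_d30 <- make_sample(c(5001, 4999), ids = c("A1", "A2"),
    subject_id = "p2", sample_id = "p2_d30", timepoint_days = 30L,
    frequencies = TRUE)
  p3_base <- make_sample(c(9990, 10), ids = c("B1", "B0"),
    subject_id = "p3", sample_id = "p3_base", frequencies = TRUE)
  p3_d30 <- make_sample(c(9750, 250), ids = c("B1", "B0"),
    subject_id = "p3", sample_id = "p3_d30", timepoint_days = 30L,
    frequencies = TRUE)
  cohort <- dplyr::bind_rows(p1, p2_base, p2_d30, p3_base, p3_d30)

  summ <- summarize_expansion_by_patient(cohort, crit, at = 30)
  expect_equal(nrow(summ), 3)
  expect_equal(summ$n_expanded[summ$subject_id == "p1"], 2L)
  expect_equal(summ$n_expanded[summ$subject_id == "p2"], 0L)
  expect_equal(summ$n_expanded[summ$subject_id == "p3"], 1L)

  g <- glance(summ)
  expect_equal(g$median_expanded, 1)
  expect_equal(g$min_expanded, 0L)
  expect_equal(g$max_expanded, 2L)
  expect_equal(g$n_patients, 3L)

  # consistency with call_expansions, patient by patient
  for (sid in c("p1", "p2", "p3")) {
    sub <- dplyr::filter(cohort, subject_id == sid)
    base <- dplyr::filter(sub, timepoint_days < 0, compartment == "blood")
    fu <- dplyr::filter(sub, timepoint_days == 30, compartment == "blood")
    direct <- glance(call_expansions(base, fu, crit))
    expect_equal(summ$n_new[summ$subject_id == sid], direct$n_new)
    expect_equal(summ$n_increased[summ$subject_id == sid],
      direct$n_increased)
  }

  # TIL partition holds for the patient with a biopsy, is NA otherwise
  p1_row <- summ[summ$subject_id == "p1", ]
  expect_equal(p1_row$n_til_expanded + p1_row$n_nontil_expanded,
    p1_row$n_expanded)
  expect_true(is.na(summ$n_til_expanded[summ$subject_id == "p2"]))

  # a single-patient cohort's median is its own count
  solo <- summarize_expansion_by_patient(p1, crit, at = 30)
  expect_equal(glance(solo)$median_expanded, 2)

  # patients lacking the timepoint are skipped with a warning each
  w <- capture_warnings(
    s90 <- summarize_expansion_by_patient(cohort, crit, at = 90))
  expect_length(w, 2)
  expect_match(w, "skipped", all = TRUE)
  expect_equal(s90$subject_id, "p1")
  expect_error(
    suppressWarnings(summarize_expansion_by_patient(cohort, crit,
      at = 180)),
    class = "clonotrack_value_error")
})

test_that("the pairwise scatter table is in percent with one row per clone", {
  samples <- make_timeline()
  base <- dplyr::filter(samples, sample_id == "p1_base")
  fu <- dplyr::filter(samples, sample_id == "p1_d30")
  tab <- export_pairwise_scatter(base, fu, crit)
  expect_equal(nrow(tab), 6) # union clonotype count
  expect_equal(tab$followup_pct[tab$rearrangement == "NEW1"], 0.1)
  expect_equal(tab$baseline_pct[tab$rearrangement == "NEW1"], 0)
  expect_equal(as.character(tab$category[tab$rearrangement == "NEW1"]),
    "new")

  same <- export_pairwise_scatter(base,
    dplyr::mutate(base, sample_id = "p1_rep", timepoint_days = 30L), crit)
  expect_true(all(same$category == "none"))
})
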