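#' Tumor-infiltrating lymphocyte (TIL) membership
#'
#' A clonotype is classified as a TIL when it is detected — at least one
#' productive template — in the patient's pre-procedure tumor-biopsy
#' repertoire. When the patient has no biopsy sample, TIL status is unknown
#' (`NA`), never coerced to `FALSE`.
#'
#' @param rearrangement Character vector of clonotype identities.
#' @param biopsy The patient's productive-filtered biopsy repertoire tibble,
#'   or `NULL` when no biopsy was collected.
#' @return A logical vector along `rearrangement` (`NA` throughout when
#'   `biopsy` is `NULL`).
#' @export
classify_til <- function(rearrangement, biopsy) {
  if (is.null(biopsy)) {
    return(rep(NA, length(rearrangement)))
  }
  check_repertoire(biopsy)
  detected <- unique(biopsy$rearrangement[
    biopsy$status == "productive" & biopsy$templates >= 1])
  rearrangement %in% detected
}

# Split one subject's long repertoire tibble into baseline / follow-up /
# biopsy pieces, validating the timeline structure.
split_timeline <- function(samples, call = rlang::caller_env()) {
  check_repertoire(samples)
  needed <- c("subject_id", "compartment", "timepoint_days")
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    abort(sprintf("Timeline tibble is missing column(s): %s.",
      paste(missing, collapse = ", ")),
      class = "clonotrack_format_error", call = call)
  }
  if (length(unique(samples$subject_id)) != 1) {
    abort("A timeline holds samples of exactly one subject.",
      class = "clonotrack_value_error", call = call)
  }
  blood <- filter(samples, .data$compartment == "blood")
  biopsy <- filter(samples, .data$compartment == "tumor_biopsy")
  baseline_ids <- unique(blood$sample_id[blood$timepoint_days <= 0])
  if (length(baseline_ids) != 1) {
    abort(sprintf(
      "Expected exactly one pre-procedure (timepoint_days <= 0) blood sample, found %d.",
      length(baseline_ids)
    ), class = "clonotrack_value_error", call = call)
  }
  list(
    baseline = filter(blood, .data$sample_id == baseline_ids),
    followups = filter(blood, .data$sample_id != baseline_ids),
    biopsy = if (nrow(biopsy) > 0) biopsy else NULL
  )
}

#' Build per-clonotype frequency trajectories for one patient
#'
#' Tracks every clonotype seen in any of a patient's blood samples across
#' the full timeline: its frequency at each timepoint (0 when undetected),
#' its TIL status from the pre-procedure biopsy (unknown when no biopsy
#' exists), and its expansion category at each follow-up. Expansion at every
#' follow-up is judged against the same pre-procedure baseline, not the
#' previous draw. Biopsy repertoires never contribute clonotypes to the
#' tracked union; they only label TIL status.
#'
#' @param samples A long repertoire tibble holding all of one subject's
#'   productive-filtered samples with computed frequencies: exactly one
#'   pre-procedure (`timepoint_days <= 0`) blood sample, any number of
#'   follow-up blood samples, and optionally a tumor biopsy.
#' @param criteria An [expansion_criteria()] object.
#' @return A long tibble of class `tcr_trajectories`: `subject_id`,
#'   `rearrangement`, `timepoint_days`, `frequency`, `is_til`, `category`
#'   (`NA` at the baseline timepoint). One row per tracked clonotype per
#'   blood timepoint.
#' @export
build_trajectories <- function(samples, criteria = expansion_criteria()) {
  tl <- split_timeline(samples)
  if (!"frequency" %in% names(samples)) {
    abort("All samples need computed frequencies; run compute_frequencies().",
      class = "clonotrack_value_error")
  }
  blood <- bind_rows(tl$baseline, tl$followups)
  union_clones <- unique(blood$rearrangement)
  timepoints <- sort(unique(blood$timepoint_days))
  baseline_day <- unique(tl$baseline$timepoint_days)

  skeleton <- tidyr::expand_grid(
    rearrangement = union_clones,
    timepoint_days = timepoints
  )
  traj <- skeleton |>
    left_join(
      select(blood, "rearrangement", "timepoint_days", "frequency"),
      by = c("rearrangement", "timepoint_days")
    ) |>
    mutate(
      subject_id = unique(blood$subject_id),
      frequency = tidyr::replace_na(.data$frequency, 0),
      is_til = classify_til(.data$rearrangement, tl$biopsy)
    )

  categories <- purrr::map(
    split(tl$followups, tl$followups$sample_id),
    function(fu) {
      call_expansions(tl$baseline, fu, criteria) |>
        as_tibble() |>
        mutate(timepoint_days = unique(fu$timepoint_days),
          category = as.character(.data$category)) |>
        select("rearrangement", "timepoint_days", "category")
    }
  ) |>
    bind_rows()
  if (nrow(categories) == 0) {
    categories <- tibble(rearrangement = character(),
      timepoint_days = integer(), category = character())
  }

  traj <- traj |>
    left_join(categories, by = c("rearrangement", "timepoint_days")) |>
    mutate(category = factor(
      dplyr::if_else(.data$timepoint_days == baseline_day,
        NA_character_,
        tidyr::replace_na(.data$category, "none")),
      levels = c("new", "increased", "none"))) |>
    select("subject_id", "rearrangement", "timepoint_days",
      "frequency", "is_til", "category") |>
    arrange(.data$rearrangement, .data$timepoint_days)

  structure(traj,
    class = c("tcr_trajectories", class(tibble())),
    criteria = criteria, baseline_day = baseline_day)
}

#' Clonotypes that remain expanded at a later follow-up
#'
#' A clonotype "remains expanded" when it meets the expansion criteria
#' versus the pre-procedure baseline at both an earlier and a later
#' follow-up. A clone first qualifying only at the later timepoint is
#' expanded there but not persistent.
#'
#' @param trajectories A `tcr_trajectories` tibble from
#'   [build_trajectories()].
#' @param t_early,t_late Follow-up timepoints (days) present in the
#'   trajectories.
#' @return The trajectory rows of the persistent clonotypes (same class as
#'   the input; possibly zero rows).
#' @export
persistent_expansions <- function(trajectories, t_early, t_late) {
  stopifnot(inherits(trajectories, "tcr_trajectories"))
  if (nrow(trajectories) == 0) {
    return(trajectories)
  }
  tps <- unique(trajectories$timepoint_days)
  for (t in c(t_early, t_late)) {
    if (!t %in% tps) {
      abort(sprintf("Timepoint %s is not present in the trajectories.", t),
        class = "clonotrack_value_error")
    }
  }
  expanded_at <- function(t) {
    trajectories$rearrangement[
      trajectories$timepoint_days == t &
        !is.na(trajectories$category) & trajectories$category != "none"]
  }
  keep <- intersect(expanded_at(t_early), expanded_at(t_late))
  out <- filter(trajectories, .data$rearrangement %in% keep)
  structure(out, class = class(trajectories),
    criteria = attr(trajectories, "criteria"),
    baseline_day = attr(trajectories, "baseline_day"))
}

#' Per-patient expansion counts and cohort summary
#'
#' For every patient with a blood sample at the requested follow-up
#' timepoint, counts the clonotypes called new and increased versus that
#' patient's pre-procedure baseline, split by TIL status where a biopsy
#' exists. Patients lacking the timepoint are skipped with a warning, so
#' cohort summaries are computed over exactly the patients sampled then.
#'
#' @param samples A long repertoire tibble holding several subjects'
#'   productive-filtered samples with frequencies (see
#'   [build_trajectories()] for the per-subject structure).
#' @param criteria An [expansion_criteria()] object.
#' @param at Follow-up timepoint in days (e.g. 30 for the 1-month draw).
#' @return A tibble of class `tcr_expansion_summary` with one row per
#'   patient: `subject_id`, `n_new`, `n_increased`, `n_expanded`,
#'   `n_til_expanded`, `n_nontil_expanded` (the TIL split is `NA` for
#'   patients without a biopsy). [glance()] gives the cohort median, range
#'   and IQR of `n_expanded`.
#' @export
summarize_expansion_by_patient <- function(samples,
                                           criteria = expansion_criteria(),
                                           at) {
  check_repertoire(samples)
  subjects <- unique(samples$subject_id)
  rows <- purrr::map(subjects, function(sid) {
    tl <- split_timeline(filter(samples, .data$subject_id == sid))
    fu <- filter(tl$followups, .data$timepoint_days == at)
    if (nrow(fu) == 0) {
      warn(sprintf("Subject %s has no blood sample at day %s; skipped.",
        sid, at))
      return(NULL)
    }
    calls <- call_expansions(tl$baseline, fu, criteria)
    expanded <- filter(as_tibble(calls), .data$category != "none")
    til <- classify_til(expanded$rearrangement, tl$biopsy)
    tibble(
      subject_id = sid,
      n_new = sum(calls$category == "new"),
      n_increased = sum(calls$category == "increased"),
      n_expanded = nrow(expanded),
      n_til_expanded = if (is.null(tl$biopsy)) NA_integer_ else
        sum(til),
      n_nontil_expanded = if (is.null(tl$biopsy)) NA_integer_ else
        sum(!til)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort(sprintf("No subject has a blood sample at day %s.", at),
      class = "clonotrack_value_error")
  }
  structure(out,
    class = c("tcr_expansion_summary", class(tibble())),
    at = at)
}

#' @method glance tcr_expansion_summary
#' @export
glance.tcr_expansion_summary <- function(x, ...) {
  tibble(
    n_patients = nrow(x),
    median_expanded = median(x$n_expanded),
    min_expanded = min(x$n_expanded),
    max_expanded = max(x$n_expanded),
    iqr_expanded = IQR(x$n_expanded)
  )
}

#' Plot-ready before/after frequency table
#'
#' One row per union clonotype of a baseline/follow-up pair with both
#' frequencies in percent and the expansion category — the data layer of a
#' pairwise clonal-frequency scatter plot.
#'
#' @inheritParams call_expansions
#' @return A tibble: `rearrangement`, `baseline_pct`, `followup_pct`,
#'   `category`.
#' @export
export_pairwise_scatter <- function(baseline, followup,
                                    criteria = expansion_criteria(),
                                    check_subject = TRUE) {
  call_expansions(baseline, followup, criteria,
    check_subject = check_subject) |>
    as_tibble() |>
    mutate(baseline_pct = 100 * .data$baseline_freq,
      followup_pct = 100 * .data$followup_freq) |>
    select("rearrangement", "baseline_pct", "followup_pct", "category")
}
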