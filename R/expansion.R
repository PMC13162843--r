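#' Expansion-calling criteria
#'
#' Threshold criteria for calling clonal expansion between a pre-procedure
#' baseline and a follow-up blood sample, calibrated against no-treatment
#' negative-control sample pairs. A clonotype is called:
#'
#' * **new** — undetected at baseline (zero templates) with a follow-up
#'   frequency strictly above `new_min_freq` (default 0.025%);
#' * **increased** — detected at baseline, with over `increased_min_fold`
#'   fold increase in frequency (strictly; default 10) and a follow-up
#'   frequency strictly above `increased_min_freq` (default 0.01%);
#' * **none** — otherwise.
#'
#' All frequencies are fractions in \[0, 1\]; thresholds quoted in percent
#' must be converted once at construction (0.025% is `2.5e-4`).
#'
#' @param new_min_freq Minimum follow-up frequency (fraction) for a "new"
#'   call; strict.
#' @param increased_min_fold Minimum frequency fold change for an
#'   "increased" call; strict.
#' @param increased_min_freq Minimum follow-up frequency (fraction) for an
#'   "increased" call; strict.
#' @return An object of class `expansion_criteria`.
#' @examples
#' expansion_criteria() # the calibrated defaults
#' @export
expansion_criteria <- function(new_min_freq = 2.5e-4,
                               increased_min_fold = 10,
                               increased_min_freq = 1e-4) {
  vals <- c(new_min_freq, increased_min_fold, increased_min_freq)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All criteria must be strictly positive and finite.",
      class = "clonotrack_value_error")
  }
  structure(
    list(new_min_freq = new_min_freq,
      increased_min_fold = increased_min_fold,
      increased_min_freq = increased_min_freq),
    class = "expansion_criteria"
  )
}

#' @export
print.expansion_criteria <- function(x, ...) {
  cat("Expansion criteria (strict thresholds):\n")
  cat(sprintf("  new:       baseline undetected, follow-up frequency > %g%%\n",
    x$new_min_freq * 100))
  cat(sprintf("  increased: > %g-fold rise and follow-up frequency > %g%%\n",
    x$increased_min_fold, x$increased_min_freq * 100))
  invisible(x)
}

#' Read / write expansion criteria as JSON
#'
#' The on-disk schema quotes frequencies in percent:
#' `{"new_min_freq_pct": 0.025, "increased_min_fold": 10,
#' "increased_min_freq_pct": 0.01}`.
#'
#' @param path JSON file path.
#' @return `read_criteria_json()` returns an [expansion_criteria()] object
#'   (percent fields converted to fractions once, on parse);
#'   `write_criteria_json()` returns `path` invisibly.
#' @export
read_criteria_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("new_min_freq_pct", "increased_min_fold", "increased_min_freq_pct")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Criteria file is missing field(s): %s.",
      paste(missing, collapse = ", ")), class = "clonotrack_format_error")
  }
  expansion_criteria(
    new_min_freq = x$new_min_freq_pct / 100,
    increased_min_fold = x$increased_min_fold,
    increased_min_freq = x$increased_min_freq_pct / 100
  )
}

#' @rdname read_criteria_json
#' @param criteria An [expansion_criteria()] object.
#' @export
write_criteria_json <- function(criteria, path) {
  stopifnot(inherits(criteria, "expansion_criteria"))
  jsonlite::write_json(
    list(
      new_min_freq_pct = criteria$new_min_freq * 100,
      increased_min_fold = criteria$increased_min_fold,
      increased_min_freq_pct = criteria$increased_min_freq * 100
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Pair a baseline and a follow-up sample clone by clone
#'
#' Builds the union join underlying pairwise before/after comparisons: one
#' row per clonotype present in either sample, with absence encoded as zero
#' templates and zero frequency on that side.
#'
#' @param baseline,followup Productive-filtered repertoire tibbles with
#'   frequencies, one sample each, from the same subject.
#' @param check_subject Error if the two samples carry different
#'   `subject_id`s (set to `FALSE` to pair across subjects deliberately).
#' @return A tibble of clone pairs: `rearrangement`, `baseline_templates`,
#'   `baseline_freq`, `followup_templates`, `followup_freq`,
#'   `baseline_total`, `followup_total`.
#' @export
pair_samples <- function(baseline, followup, check_subject = TRUE) {
  for (s in list(baseline, followup)) {
    check_repertoire(s)
    if (!"frequency" %in% names(s)) {
      abort("Both samples need computed frequencies; run compute_frequencies().",
        class = "clonotrack_value_error")
    }
    if (length(unique(s$sample_id)) > 1) {
      abort("pair_samples() takes exactly one sample on each side.",
        class = "clonotrack_value_error")
    }
  }
  if (check_subject &&
      nrow(baseline) > 0 && nrow(followup) > 0 &&
      !identical(unique(baseline$subject_id), unique(followup$subject_id))) {
    abort(sprintf(
      "Samples come from different subjects ('%s' vs '%s'); set check_subject = FALSE to override.",
      unique(baseline$subject_id), unique(followup$subject_id)
    ), class = "clonotrack_value_error")
  }
  n1 <- sum(baseline$templates)
  n2 <- sum(followup$templates)
  full_join(
    select(baseline, "rearrangement",
      baseline_templates = "templates", baseline_freq = "frequency"),
    select(followup, "rearrangement",
      followup_templates = "templates", followup_freq = "frequency"),
    by = "rearrangement"
  ) |>
    mutate(
      baseline_templates = tidyr::replace_na(.data$baseline_templates, 0L),
      baseline_freq = tidyr::replace_na(.data$baseline_freq, 0),
      followup_templates = tidyr::replace_na(.data$followup_templates, 0L),
      followup_freq = tidyr::replace_na(.data$followup_freq, 0),
      baseline_total = n1,
      followup_total = n2
    ) |>
    arrange(.data$rearrangement)
}

#' Classify clone pairs as new / increased / none
#'
#' Applies the strict threshold rules of [expansion_criteria()] to each
#' clone pair. A clone absent at baseline is only ever eligible for "new"
#' (its fold change is undefined); fold change is computed on frequencies,
#' not raw template counts, so differing sequencing depths cancel.
#'
#' @param pairs A clone-pair tibble from [pair_samples()].
#' @param criteria An [expansion_criteria()] object.
#' @return `pairs` with `fold_change` (`NA` when baseline is absent) and
#'   `category` (factor: `new`, `increased`, `none`) columns added.
#' @examples
#' pairs <- tibble::tibble(
#'   rearrangement = c("A", "B"),
#'   baseline_templates = c(0L, 2L), baseline_freq = c(0, 1e-5),
#'   followup_templates = c(60L, 40L), followup_freq = c(3e-4, 2e-4),
#'   baseline_total = 2e5, followup_total = 2e5
#' )
#' classify_expansion(pairs, expansion_criteria())$category # new, increased
#' @export
classify_expansion <- function(pairs, criteria = expansion_criteria()) {
  stopifnot(inherits(criteria, "expansion_criteria"))
  check_pairs(pairs)
  pairs |>
    mutate(
      fold_change = dplyr::if_else(.data$baseline_templates > 0,
        .data$followup_freq / .data$baseline_freq, NA_real_),
      category = factor(dplyr::case_when(
        .data$baseline_templates == 0 &
          .data$followup_freq > criteria$new_min_freq ~ "new",
        .data$baseline_templates > 0 &
          .data$fold_change > criteria$increased_min_fold &
          .data$followup_freq > criteria$increased_min_freq ~ "increased",
        TRUE ~ "none"
      ), levels = c("new", "increased", "none"))
    )
}

#' Call clonal expansions between a baseline and a follow-up sample
#'
#' End-to-end expansion calling: union-joins the two samples
#' ([pair_samples()]), classifies every clone pair against the criteria
#' ([classify_expansion()]), and attaches the per-category summary counts.
#' Deterministic given its inputs.
#'
#' @inheritParams pair_samples
#' @inheritParams classify_expansion
#' @return A tibble of class `tcr_expansion_calls` (one row per union
#'   clonotype, with `category` and `fold_change`). [glance()] extracts the
#'   summary counts `n_new`, `n_increased`, `n_clonotypes`; [autoplot()]
#'   draws the before/after frequency scatter.
#' @export
call_expansions <- function(baseline, followup,
                            criteria = expansion_criteria(),
                            check_subject = TRUE) {
  calls <- pair_samples(baseline, followup, check_subject = check_subject) |>
    classify_expansion(criteria)
  new_tcr_expansion_calls(calls, criteria)
}

new_tcr_expansion_calls <- function(calls, criteria) {
  structure(calls,
    class = c("tcr_expansion_calls", class(tibble())),
    criteria = criteria)
}

#' @method tidy tcr_expansion_calls
#' @export
tidy.tcr_expansion_calls <- function(x, ...) {
  as_tibble(x) |>
    select("rearrangement", "baseline_freq", "followup_freq",
      "fold_change", "category")
}

#' @method glance tcr_expansion_calls
#' @export
glance.tcr_expansion_calls <- function(x, ...) {
  tibble(
    n_new = sum(x$category == "new"),
    n_increased = sum(x$category == "increased"),
    n_expanded = sum(x$category != "none"),
    n_clonotypes = nrow(x)
  )
}

check_pairs <- function(pairs, call = rlang::caller_env()) {
  needed <- c("rearrangement", "baseline_templates", "baseline_freq",
    "followup_templates", "followup_freq", "baseline_total", "followup_total")
  missing <- setdiff(needed, names(pairs))
  if (length(missing) > 0) {
    abort(sprintf("Not a clone-pair tibble: missing column(s) %s.",
      paste(missing, collapse = ", ")),
      class = "clonotrack_format_error", call = call)
  }
  invisible(pairs)
}
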