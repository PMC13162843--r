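#' Default criteria grid for negative-control calibration
#'
#' Candidate expansion criteria spanning the plausible stringency range:
#' `new_min_freq` in \{0.005, 0.01, 0.025, 0.05\}%, `increased_min_freq` in
#' \{0.005, 0.01, 0.025\}% and fold thresholds \{5, 10, 20\}.
#'
#' @return A tibble with columns `new_min_freq`, `increased_min_freq`,
#'   `increased_min_fold` (frequencies as fractions), ordered from least to
#'   most stringent (lexicographically by `new_min_freq`, then
#'   `increased_min_freq`, then `increased_min_fold`).
#' @export
default_criteria_grid <- function() {
  tidyr::expand_grid(
    new_min_freq = c(0.005, 0.01, 0.025, 0.05) / 100,
    increased_min_freq = c(0.005, 0.01, 0.025) / 100,
    increased_min_fold = c(5, 10, 20)
  ) |>
    arrange(.data$new_min_freq, .data$increased_min_freq,
      .data$increased_min_fold)
}

#' Calibrate expansion criteria against negative controls
#'
#' Chooses expansion-calling thresholds from no-treatment control sample
#' pairs: every call the threshold rules make on a control pair is by
#' construction a false positive, so the calibration returns the
#' least-stringent candidate criteria whose total calls across all control
#' sets do not exceed `max_false_positives`. "Least stringent" is resolved
#' deterministically by lexicographic order: lowest `new_min_freq`, then
#' lowest `increased_min_freq`, then lowest fold threshold.
#'
#' @param control_pair_sets A list of clone-pair tibbles ([pair_samples()]),
#'   one per negative-control sample pair.
#' @param grid Candidate criteria, as from [default_criteria_grid()].
#' @param max_false_positives Maximum tolerated total expansion calls across
#'   all control sets (default 0).
#' @return The selected [expansion_criteria()]. Errors if no grid point
#'   satisfies the constraint, reporting the best achievable count.
#' @export
calibrate_criteria <- function(control_pair_sets,
                               grid = default_criteria_grid(),
                               max_false_positives = 0) {
  if (!is.list(control_pair_sets) || length(control_pair_sets) == 0 ||
      is.data.frame(control_pair_sets)) {
    abort("`control_pair_sets` must be a non-empty list of clone-pair tibbles.",
      class = "clonotrack_value_error")
  }
  purrr::walk(control_pair_sets, check_pairs)
  if (nrow(grid) == 0) {
    abort("`grid` must contain at least one candidate.",
      class = "clonotrack_value_error")
  }
  grid <- arrange(grid, .data$new_min_freq, .data$increased_min_freq,
    .data$increased_min_fold)
  fp <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    crit <- expansion_criteria(
      new_min_freq = grid$new_min_freq[i],
      increased_min_fold = grid$increased_min_fold[i],
      increased_min_freq = grid$increased_min_freq[i]
    )
    fp[i] <- sum(purrr::map_int(control_pair_sets, function(pairs) {
      sum(classify_expansion(pairs, crit)$category != "none")
    }))
    if (fp[i] <= max_false_positives) {
      return(crit)
    }
  }
  abort(sprintf(
    "No candidate criteria achieve <= %d control calls; best achievable is %d.",
    max_false_positives, min(fp)
  ), class = "clonotrack_value_error")
}
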