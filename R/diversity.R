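#' Simpson dominance index
#'
#' The Simpson Dominance Index of a repertoire is the sum of squared clone
#' frequencies, the probability that two templates drawn with replacement
#' come from the same clonotype. It ranges from 1/N for a uniform repertoire
#' of N clonotypes up to 1 for a monoclonal one.
#'
#' @param frequencies Numeric vector of clone frequencies summing to 1
#'   (within 1e-9).
#' @return The dominance, a value in (0, 1\].
#' @examples
#' simpson_dominance(c(0.6, 0.2, 0.1, 0.1)) # 0.42
#' @export
simpson_dominance <- function(frequencies) {
  if (length(frequencies) == 0) {
    abort("Cannot compute dominance of an empty frequency vector.",
      class = "clonotrack_value_error")
  }
  if (any(!is.finite(frequencies)) || any(frequencies < 0)) {
    abort("Frequencies must be finite and non-negative.",
      class = "clonotrack_value_error")
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    abort(sprintf("Frequencies must sum to 1 (got %.12g).", sum(frequencies)),
      class = "clonotrack_value_error")
  }
  sum(frequencies^2)
}

#' Simpson clonality per sample
#'
#' Simpson clonality — the square root of the Simpson Dominance Index — is
#' the diversity summary used for bulk TCR-beta repertoires: values near 0
#' indicate a polyclonal repertoire, values near 1 a monoclonal/oligoclonal
#' one. It is computed on productive clone frequencies without any
#' small-sample (unseen species) correction, matching the plain sum of
#' squared frequencies definition, so values are directly comparable to
#' platform-reported Simpson clonality.
#'
#' @param x A productive-filtered repertoire tibble with frequencies
#'   ([compute_frequencies()]); may contain several samples.
#' @return A tibble with one row per sample: `sample_id`, `richness`
#'   (number of distinct productive clonotypes), `simpson_dominance` and
#'   `simpson_clonality`.
#' @examples
#' rep <- tibble::tibble(
#'   sample_id = "s", subject_id = "p", compartment = "blood",
#'   timepoint_days = -7L, rearrangement = c("AA", "CC", "GG", "TT"),
#'   cdr3_aa = "C", v_gene = "v", j_gene = "j", status = "productive",
#'   templates = c(6L, 2L, 1L, 1L)
#' )
#' simpson_clonality(compute_frequencies(filter_productive(rep)))
#' @export
simpson_clonality <- function(x) {
  check_repertoire(x)
  if (!"frequency" %in% names(x)) {
    abort("Run compute_frequencies() before simpson_clonality().",
      class = "clonotrack_value_error")
  }
  if (nrow(x) == 0) {
    abort("Cannot compute clonality of an empty repertoire.",
      class = "clonotrack_degenerate_error")
  }
  x |>
    group_by(.data$sample_id) |>
    summarise(
      richness = n(),
      simpson_dominance = simpson_dominance(.data$frequency),
      simpson_clonality = sqrt(.data$simpson_dominance),
      .groups = "drop"
    )
}

#' Compare clonality between two groups of samples
#'
#' Group comparisons of Simpson clonality use the two-tailed Wilcoxon
#' rank-sum test (signed-rank when `paired = TRUE`): clonality values are
#' bounded, skewed and typically non-normal, which a Shapiro-Wilk p-value is
#' reported alongside to document — it never gates the choice of test. The
#' exact null distribution is used when both groups have at most 12
#' observations and there are no ties; otherwise the normal approximation
#' with mid-rank tie correction and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors of clonality values (each of
#'   length >= 2; equal lengths required when `paired = TRUE`).
#' @param paired Treat the two groups as paired per-subject measurements.
#' @return A one-row tibble: `statistic` (rank-sum W, or signed-rank V),
#'   `p_value`, `method` and `normality_p` (Shapiro-Wilk on the pooled
#'   values; `NA` if not computable).
#' @examples
#' compare_clonality(c(0.026, 0.031, 0.015), c(0.063, 0.047, 0.22))
#' @export
compare_clonality <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group must contain at least 2 values.",
      class = "clonotrack_value_error")
  }
  pooled <- c(group_a, group_b)
  exact <- length(group_a) <= 12 && length(group_b) <= 12 &&
    !any(duplicated(pooled))
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
      paired = paired, exact = exact, correct = TRUE)
  )
  normality_p <- tryCatch(shapiro.test(pooled)$p.value,
    error = function(e) NA_real_)
  tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = if (paired) "wilcoxon_signed_rank_two_tailed" else
      "wilcoxon_rank_sum_two_tailed",
    normality_p = normality_p
  )
}
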