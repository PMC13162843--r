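#' Drop non-productive rearrangements
#'
#' Non-productive TCR-beta rearrangements — those encoding a premature stop
#' codon or an out-of-frame (frameshifted) junction — do not make a surface
#' receptor and are excluded before any repertoire analysis. All downstream
#' frequency, clonality and expansion computations in this package operate on
#' the productive repertoire only.
#'
#' @param x A repertoire tibble from [read_repertoire_tsv()]; may contain
#'   several samples (distinguished by `sample_id`).
#' @return The rows of `x` with `status == "productive"`, with the
#'   `productive_filtered` attribute set. A warning is emitted for any sample
#'   left with zero productive records.
#' @examples
#' rep <- tibble::tibble(
#'   sample_id = "s", subject_id = "p", compartment = "blood",
#'   timepoint_days = -7L,
#'   rearrangement = c("AA", "CC", "GG"), cdr3_aa = c("CA", "", ""),
#'   v_gene = "v", j_gene = "j",
#'   status = c("productive", "stop", "frameshift"), templates = c(5L, 2L, 1L)
#' )
#' filter_productive(rep)
#' @export
filter_productive <- function(x) {
  check_repertoire(x)
  out <- filter(x, .data$status == "productive")
  empty <- setdiff(unique(x$sample_id), unique(out$sample_id))
  if (length(empty) > 0) {
    warn(sprintf(
      "No productive records remain for sample(s): %s.",
      paste(empty, collapse = ", ")
    ))
  }
  attr(out, "productive_filtered") <- TRUE
  out
}

#' Compute clonal frequencies
#'
#' The clonal frequency of a clonotype is its template count divided by the
#' total number of productive templates in the same sample, so frequencies
#' sum to one within each sample. [filter_productive()] must be applied
#' first: the denominator is the post-filter productive total.
#'
#' @param x A productive-filtered repertoire tibble; may contain several
#'   samples.
#' @return `x` with a `frequency` column added (fractions in \[0, 1\]).
#' @examples
#' rep <- tibble::tibble(
#'   sample_id = "s", subject_id = "p", compartment = "blood",
#'   timepoint_days = -7L, rearrangement = c("AA", "CC"),
#'   cdr3_aa = "C", v_gene = "v", j_gene = "j",
#'   status = "productive", templates = c(5L, 15L)
#' )
#' compute_frequencies(filter_productive(rep))$frequency  # 0.25 0.75
#' @export
compute_frequencies <- function(x) {
  check_repertoire(x)
  if (!isTRUE(attr(x, "productive_filtered")) &&
      any(x$status != "productive")) {
    abort("Apply filter_productive() before compute_frequencies().",
      class = "clonotrack_value_error")
  }
  totals <- x |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$templates), .groups = "drop")
  degenerate <- totals$sample_id[totals$total == 0]
  if (length(degenerate) > 0) {
    abort(sprintf(
      "Sample(s) %s have zero productive templates; frequencies are undefined.",
      paste(degenerate, collapse = ", ")
    ), class = "clonotrack_degenerate_error")
  }
  out <- x |>
    group_by(.data$sample_id) |>
    mutate(frequency = .data$templates / sum(.data$templates)) |>
    ungroup()
  attr(out, "productive_filtered") <- TRUE
  out
}

#' Total productive templates per sample
#'
#' @param x A repertoire tibble.
#' @return A tibble with `sample_id` and `total_templates`.
#' @export
total_templates <- function(x) {
  check_repertoire(x)
  x |>
    group_by(.data$sample_id) |>
    summarise(total_templates = sum(.data$templates), .groups = "drop")
}

#' Aggregate clonotypes by CDR3 amino-acid sequence
#'
#' Clonotype identity throughout this package is the exact nucleotide
#' rearrangement. This optional view collapses records to the amino-acid
#' level (summing templates over synonymous rearrangements); it is never
#' applied implicitly.
#'
#' @param x A repertoire tibble.
#' @return A tibble keyed by (`sample_id`, `cdr3_aa`) with summed `templates`
#'   (and summed `frequency` when present).
#' @export
aggregate_by_cdr3 <- function(x) {
  check_repertoire(x)
  has_freq <- "frequency" %in% names(x)
  out <- x |>
    group_by(.data$sample_id, .data$subject_id, .data$compartment,
      .data$timepoint_days, .data$cdr3_aa) |>
    summarise(
      n_rearrangements = n(),
      templates = sum(.data$templates),
      frequency = if (has_freq) sum(.data$frequency) else NA_real_,
      .groups = "drop"
    )
  if (!has_freq) out$frequency <- NULL
  out
}

check_repertoire <- function(x, call = rlang::caller_env()) {
  needed <- c("sample_id", "rearrangement", "status", "templates")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "Not a repertoire tibble: missing column(s) %s.",
      paste(missing, collapse = ", ")
    ), class = "clonotrack_format_error", call = call)
  }
  if (any(x$templates < 0)) {
    abort("Template counts must be non-negative.",
      class = "clonotrack_value_error", call = call)
  }
  invisible(x)
}
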