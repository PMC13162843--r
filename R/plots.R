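category_palette <- c(new = "#E69F00", increased = "#7B3294",
  none = "grey60")

#' Before/after clonal-frequency scatter
#'
#' One point per clonotype of a baseline/follow-up pair, follow-up
#' frequency (percent) on the x axis against baseline frequency (percent)
#' on the y axis on log-like square-root scales, coloured by expansion
#' category (new clones sit on the x axis since they are undetected at
#' baseline).
#'
#' @param calls A `tcr_expansion_calls` object ([call_expansions()]).
#' @return A ggplot object.
#' @export
plot_pairwise_scatter <- function(calls) {
  stopifnot(inherits(calls, "tcr_expansion_calls"))
  df <- as_tibble(calls) |>
    mutate(baseline_pct = 100 * .data$baseline_freq,
      followup_pct = 100 * .data$followup_freq)
  ggplot2::ggplot(df, ggplot2::aes(.data$followup_pct, .data$baseline_pct,
    colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_sqrt() +
    ggplot2::scale_y_sqrt() +
    ggplot2::scale_colour_manual(values = category_palette) +
    ggplot2::labs(
      x = "Clonal frequency at follow-up (%)",
      y = "Clonal frequency at baseline (%)",
      colour = "Expansion"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot tcr_expansion_calls
#' @export
autoplot.tcr_expansion_calls <- function(object, ...) {
  plot_pairwise_scatter(object)
}

#' Clonotype frequency trajectories
#'
#' One line per tracked clonotype across a patient's blood timepoints;
#' by default restricted to clonotypes expanded at some follow-up, with
#' TIL clonotypes drawn in red and non-TILs in black (patients without a
#' biopsy have unknown TIL status, drawn in grey).
#'
#' @param trajectories A `tcr_trajectories` tibble
#'   ([build_trajectories()]).
#' @param expanded_only Keep only clonotypes with an expansion call at at
#'   least one follow-up.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, expanded_only = TRUE) {
  stopifnot(inherits(trajectories, "tcr_trajectories"))
  df <- as_tibble(trajectories)
  if (expanded_only) {
    keep <- df |>
      filter(!is.na(.data$category) & .data$category != "none") |>
      pull("rearrangement") |>
      unique()
    df <- filter(df, .data$rearrangement %in% keep)
  }
  df <- mutate(df, til = dplyr::case_when(
    is.na(.data$is_til) ~ "unknown",
    .data$is_til ~ "TIL",
    TRUE ~ "non-TIL"
  ))
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint_days,
    100 * .data$frequency, group = .data$rearrangement,
    colour = .data$til)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_manual(values = c(
      "TIL" = "#C0392B", "non-TIL" = "black", "unknown" = "grey55")) +
    ggplot2::labs(x = "Days from procedure", y = "Clonal frequency (%)",
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot tcr_trajectories
#' @export
autoplot.tcr_trajectories <- function(object, ...) {
  plot_trajectories(object, ...)
}

#' Clonality comparison boxplot
#'
#' Box-and-dot plot of per-sample Simpson clonality by group (e.g. biopsy
#' vs baseline blood, or blood timepoints).
#'
#' @param clonality A tibble with a `simpson_clonality` column
#'   ([simpson_clonality()]) and a grouping column.
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_clonality <- function(clonality, group) {
  ggplot2::ggplot(clonality, ggplot2::aes(.data[[group]],
    .data$simpson_clonality)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Simpson clonality") +
    ggplot2::theme_minimal()
}
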