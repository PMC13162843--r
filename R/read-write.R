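#' Read a clonotype table into a tidy repertoire tibble
#'
#' Ingests one sequenced sample (blood draw or tumor biopsy) from a
#' tab-separated clonotype export: one row per unique TCR-beta rearrangement
#' with its CDR3 amino-acid translation, V/J gene calls, productivity status
#' and template count. Rows sharing an identical nucleotide rearrangement are
#' merged by summing their template counts, so rearrangement strings are
#' unique in the result.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param dialect Column dialect; see [repertoire_dialect()].
#' @param sample_id,subject_id Identifiers attached to every row; `sample_id`
#'   defaults to the file name without extension, `subject_id` to `sample_id`.
#' @param compartment `"blood"` or `"tumor_biopsy"`.
#' @param timepoint_days Integer day of the draw relative to the procedure
#'   day (0); negative values are pre-procedure.
#'
#' @return A tibble with one row per unique rearrangement and columns
#'   `sample_id`, `subject_id`, `compartment`, `timepoint_days`,
#'   `rearrangement`, `cdr3_aa`, `v_gene`, `j_gene`, `status`
#'   (`"productive"`, `"stop"` or `"frameshift"`) and `templates`
#'   (non-negative integer). Frequencies are added later by
#'   [compute_frequencies()].
#' @seealso [filter_productive()], [compute_frequencies()],
#'   [write_repertoire_tsv()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' demo <- tibble::tibble(
#'   rearrangement = c("TGTGCC", "TGTGCG"),
#'   cdr3_aa = c("CASSF", "CASAF"), v_gene = "TCRBV05-01",
#'   j_gene = "TCRBJ02-01", status = "productive", templates = c(5L, 3L)
#' )
#' write_repertoire_tsv(demo, tf)
#' read_repertoire_tsv(tf, sample_id = "demo")
#' @export
read_repertoire_tsv <- function(path, dialect = "immunoseq",
                                sample_id = NULL, subject_id = NULL,
                                compartment = c("blood", "tumor_biopsy"),
                                timepoint_days = NA_integer_) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "clonotrack_io_error")
  }
  compartment <- match.arg(compartment)
  dl <- repertoire_dialect(dialect)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  subject_id <- subject_id %||% sample_id

  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
    progress = FALSE)

  required <- c("rearrangement", "templates", "status")
  for (field in required) {
    if (!dl[[field]] %in% names(raw)) {
      abort(sprintf(
        "Required column '%s' (field '%s') is missing from '%s'.",
        dl[[field]], field, path
      ), class = "clonotrack_format_error")
    }
  }
  get_col <- function(field, default = NA_character_) {
    if (dl[[field]] %in% names(raw)) raw[[dl[[field]]]] else
      rep(default, nrow(raw))
  }

  templates_chr <- get_col("templates")
  templates_num <- suppressWarnings(as.numeric(templates_chr))
  bad <- which(is.na(templates_num) | templates_num < 0 |
    templates_num != round(templates_num))
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid template count '%s' at data row %d of '%s': counts must be non-negative integers.",
      templates_chr[bad[1]], bad[1], path
    ), class = "clonotrack_value_error")
  }

  status_raw <- get_col("status")
  status <- unname(dl$status_map[status_raw])
  unknown <- which(is.na(status))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unrecognised sequence status '%s' at data row %d of '%s' for this dialect.",
      status_raw[unknown[1]], unknown[1], path
    ), class = "clonotrack_value_error")
  }

  out <- tibble(
    sample_id = sample_id,
    subject_id = subject_id,
    compartment = compartment,
    timepoint_days = as.integer(timepoint_days),
    rearrangement = get_col("rearrangement"),
    cdr3_aa = get_col("cdr3_aa"),
    v_gene = get_col("v_gene", "unresolved"),
    j_gene = get_col("j_gene", "unresolved"),
    status = status,
    templates = as.integer(round(templates_num))
  )

  # identical rearrangements collapse to one clonotype; annotation from the
  # first occurrence, counts summed
  out |>
    group_by(.data$sample_id, .data$subject_id, .data$compartment,
      .data$timepoint_days, .data$rearrangement) |>
    summarise(
      cdr3_aa = dplyr::first(.data$cdr3_aa),
      v_gene = dplyr::first(.data$v_gene),
      j_gene = dplyr::first(.data$j_gene),
      status = dplyr::first(.data$status),
      templates = sum(.data$templates),
      .groups = "drop"
    )
}

#' Write a repertoire tibble as a tab-separated clonotype table
#'
#' Writes the canonical columns (`rearrangement`, `cdr3_aa`, `v_gene`,
#' `j_gene`, `status`, `templates`, and `frequency` when present) under the
#' column names of the chosen dialect, so that
#' `read_repertoire_tsv(write_repertoire_tsv(x))` round-trips records,
#' counts and identities exactly.
#'
#' @param x A repertoire tibble (one sample).
#' @param path Output file path.
#' @inheritParams read_repertoire_tsv
#' @return `path`, invisibly.
#' @export
write_repertoire_tsv <- function(x, path, dialect = "immunoseq") {
  dl <- repertoire_dialect(dialect)
  inv_status <- setNames(names(dl$status_map), dl$status_map)
  get <- function(col, default) {
    if (col %in% names(x)) x[[col]] else rep(default, nrow(x))
  }
  # column order must follow canonical_fields: the dialect names are
  # assigned positionally below
  out <- tibble(
    rearrangement = as.character(get("rearrangement", NA_character_)),
    cdr3_aa = as.character(get("cdr3_aa", NA_character_)),
    templates = get("templates", NA_integer_),
    status = unname(inv_status[as.character(get("status", NA_character_))]),
    v_gene = as.character(get("v_gene", "unresolved")),
    j_gene = as.character(get("j_gene", "unresolved"))
  )
  names(out) <- unlist(dl[canonical_fields], use.names = FALSE)
  if ("frequency" %in% names(x)) out$frequency <- x$frequency
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
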