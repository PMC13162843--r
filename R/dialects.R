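#' Column dialects for clonotype tables
#'
#' Bulk TCR-beta clonotype exports differ in column naming between platforms.
#' A dialect is a named list mapping the canonical fields used throughout this
#' package (`rearrangement`, `cdr3_aa`, `templates`, `status`, `v_gene`,
#' `j_gene`) to the column names found in the file, plus a `status_map`
#' translating the platform's frame/productivity labels to the canonical
#' `"productive"`, `"stop"`, `"frameshift"` categories.
#'
#' Two dialects are built in:
#'
#' * `"immunoseq"` — Adaptive immunoSEQ exports: `rearrangement`,
#'   `aminoAcid`, `count (templates/estimate)`, `sequenceStatus`
#'   (`In`/`Out`/`Stop`), `vGeneName`, `jGeneName`.
#' * `"airr"` — AIRR Rearrangement standard: `junction`, `junction_aa`,
#'   `duplicate_count`, `productive` (`T`/`F` or `true`/`false`; non-productive
#'   rows are mapped to `frameshift` since AIRR does not separate the two
#'   failure modes), `v_call`, `j_call`.
#'
#' @param dialect Either a dialect name (`"immunoseq"` or `"airr"`) or a named
#'   list with the fields described above (a partial list overrides the
#'   immunoseq defaults).
#'
#' @return A named list with elements `rearrangement`, `cdr3_aa`, `templates`,
#'   `status`, `v_gene`, `j_gene` (column names) and `status_map` (named
#'   character vector).
#' @examples
#' repertoire_dialect("immunoseq")$templates
#' repertoire_dialect("airr")$rearrangement
#' @export
repertoire_dialect <- function(dialect = "immunoseq") {
  builtin <- list(
    immunoseq = list(
      rearrangement = "rearrangement",
      cdr3_aa       = "aminoAcid",
      templates     = "count (templates/estimate)",
      status        = "sequenceStatus",
      v_gene        = "vGeneName",
      j_gene        = "jGeneName",
      status_map    = c(In = "productive", Out = "frameshift", Stop = "stop")
    ),
    airr = list(
      rearrangement = "junction",
      cdr3_aa       = "junction_aa",
      templates     = "duplicate_count",
      status        = "productive",
      v_gene        = "v_call",
      j_gene        = "j_call",
      status_map    = c(
        "T" = "productive", "TRUE" = "productive", "true" = "productive",
        "F" = "frameshift", "FALSE" = "frameshift", "false" = "frameshift"
      )
    )
  )
  if (is.character(dialect) && length(dialect) == 1) {
    if (!dialect %in% names(builtin)) {
      abort(sprintf(
        "Unknown dialect '%s'; built-in dialects are %s.",
        dialect, paste0("'", names(builtin), "'", collapse = ", ")
      ), class = "clonotrack_format_error")
    }
    return(builtin[[dialect]])
  }
  if (!is.list(dialect)) {
    abort("`dialect` must be a dialect name or a named list.",
      class = "clonotrack_format_error")
  }
  out <- utils::modifyList(builtin$immunoseq, dialect)
  out
}

canonical_fields <- c("rearrangement", "cdr3_aa", "templates", "status",
  "v_gene", "j_gene")
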