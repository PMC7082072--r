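#' Cell tables: the shared per-cone schema
#'
#' A cell table is a tibble with one row per cone and the columns
#' `cell_id`, `x_um`, `y_um`, `area_um2`, `s_intensity`, `m_intensity`,
#' `class_label`, `fate_truth`. The dorsal edge is at `y_um = 0` and `y_um`
#' increases ventrally. `class_label` (one of `S_ONLY`, `M_ONLY`,
#' `COEXPRESSING`, `NONE`) is assigned by [classify_cells()]; `fate_truth`
#' (`S_ONLY`, `CEC`, `UNKNOWN`) is ground truth carried by synthetic and
#' simulated tables. Experiment-like, synthetic, and simulated cells all share
#' this schema so every profiling operation applies to each identically.
#'
#' Strip dimensions and provenance travel in the `meta` attribute, a list with
#' at least `source` (`"experimental"`, `"synthetic"` or `"simulated"`),
#' `strip_length_um` and `strip_width_um`.
#'
#' @param data A data frame with the schema columns.
#' @param meta A named list of metadata (source tag, strip dimensions, pixel
#'   size for image-derived tables, alignment shifts, ...).
#' @return A `cell_table` tibble.
#' @export
cell_table <- function(data, meta = list()) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cell table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- data[, union(CELL_TABLE_COLUMNS, names(data))]
  validate_cell_table(data, meta)
  attr(data, "meta") <- meta
  class(data) <- c("cell_table", class(data))
  data
}

validate_cell_table <- function(data, meta = cell_meta(data)) {
  if (anyDuplicated(data$cell_id) > 0) abort("cell_id values must be unique")
  ok_int <- stats::complete.cases(data$s_intensity, data$m_intensity)
  if (!all(ok_int)) abort("intensities must be non-missing")
  if (any(data$s_intensity < 0) || any(data$m_intensity < 0)) {
    abort("intensities must be >= 0")
  }
  len <- meta$strip_length_um
  if (!is.null(len) && is.null(meta$y_shift_um) &&
    (any(data$y_um < 0) || any(data$y_um > len))) {
    abort("y_um must lie within [0, strip_length_um]")
  }
  invisible(data)
}

#' @rdname cell_table
#' @param table A cell table.
#' @export
cell_meta <- function(table) {
  attr(table, "meta") %||% list()
}

#' @export
print.cell_table <- function(x, ...) {
  meta <- cell_meta(x)
  cat(sprintf(
    "# A cell_table: %d cells (source: %s, strip %s x %s um)\n",
    nrow(x), meta$source %||% "unknown",
    format(meta$strip_length_um %||% NA), format(meta$strip_width_um %||% NA)
  ))
  NextMethod()
}

# Strip length with a fallback to the observed coordinate range.
strip_length <- function(table) {
  cell_meta(table)$strip_length_um %||% max(table$y_um)
}
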