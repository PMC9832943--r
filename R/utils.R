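# Internal helpers: classed conditions and well-name arithmetic.

stop_buildplanr <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "buildplanr_error"), ...)
}

#' @noRd
parse_error <- function(section, message = NULL) {
  stop_buildplanr(
    "buildplanr_parse_error",
    message %||% sprintf("design file section not usable: %s", section),
    section = section
  )
}

reference_error <- function(identifier, message = NULL) {
  stop_buildplanr(
    "buildplanr_reference_error",
    message %||% sprintf("unresolvable cross-reference: %s", identifier),
    identifier = identifier
  )
}

`%||%` <- rlang::`%||%`

#' Well names of a rectangular labware in column-major order
#'
#' Wells are named `"A1"`, `"B1"`, ..., filling rows top-down within a
#' column before moving to the next column (1-based column numbers).
#'
#' @param n_rows,n_cols labware dimensions.
#' @return character vector of length `n_rows * n_cols`.
#' @keywords internal
#' @noRd
wells_column_major <- function(n_rows, n_cols) {
  as.vector(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0))
}

# "B6" -> list(row = 2L, col = 6L)
split_well <- function(well) {
  row <- match(substr(well, 1, 1), LETTERS)
  col <- as.integer(substring(well, 2))
  list(row = row, col = col)
}

well_name <- function(row, col) paste0(LETTERS[row], col)

# Round-half-up to one decimal on a 0.1 degC grid without FP drift.
round_tenth <- function(x) round(x * 10) / 10

# Deterministic number formatting for rendered artifacts.
fmt_num <- function(x, digits = 2) {
  formatC(x, format = "f", digits = digits)
}
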