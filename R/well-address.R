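#' Well addresses
#'
#' Plate coordinates follow plate-reader convention: letter rows and 1-based
#' numeric columns, e.g. `"B17"`. The 384-well format spans rows A-P and
#' columns 1-24; the 96-well format rows A-H and columns 1-12.
#'
#' @param row Character vector of row letters (`"A"`..`"P"`).
#' @param column Integer vector of 1-based column indices.
#' @param plate_format Number of wells on the plate, `384` or `96`.
#'
#' @return `well_address()` returns the string form (e.g. `"B17"`);
#'   `parse_well_address()` returns a tibble with columns `row_letter` and
#'   `column`.
#'
#' @examples
#' well_address("B", 17)
#' parse_well_address(c("A1", "P24"))
#' @export
well_address <- function(row, column, plate_format = 384) {
  dims <- plate_dims(plate_format)
  row <- toupper(as.character(row))
  column <- as.integer(column)
  bad_row <- !row %in% LETTERS[seq_len(dims$n_rows)]
  bad_col <- is.na(column) | column < 1L | column > dims$n_cols
  if (any(bad_row)) {
    abort(sprintf("Row(s) out of range for %d-well format: %s",
                  plate_format, paste(unique(row[bad_row]), collapse = ", ")))
  }
  if (any(bad_col)) {
    abort(sprintf("Column(s) out of range for %d-well format: %s",
                  plate_format,
                  paste(unique(column[bad_col]), collapse = ", ")))
  }
  paste0(row, column)
}

#' @param x Character vector of well strings such as `"B17"`.
#' @rdname well_address
#' @export
parse_well_address <- function(x, plate_format = 384) {
  m <- regmatches(x, regexec("^([A-Pa-p])([0-9]{1,2})$", as.character(x)))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    abort(sprintf("Malformed well address(es): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  row <- toupper(vapply(m, `[`, character(1), 2L))
  column <- as.integer(vapply(m, `[`, character(1), 3L))
  # re-validate ranges against the plate format
  well_address(row, column, plate_format)
  tibble(row_letter = row, column = column)
}

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
    "384" = list(n_rows = 16L, n_cols = 24L),
    "96"  = list(n_rows = 8L, n_cols = 12L),
    abort("`plate_format` must be 384 or 96.")
  )
}

#' All well addresses of a plate in row-major order
#'
#' @inheritParams well_address
#' @return Character vector of length `plate_format`.
#' @export
plate_wells <- function(plate_format = 384) {
  dims <- plate_dims(plate_format)
  grid <- expand.grid(column = seq_len(dims$n_cols),
                      row = LETTERS[seq_len(dims$n_rows)],
                      stringsAsFactors = FALSE)
  # row-major: A1, A2, ..., A24, B1, ...
  paste0(grid$row, grid$column)
}

well_roles <- c("blank", "dmso", "hemin", "cddo", "test", "empty")
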