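#' Read a plate-reader matrix export
#'
#' Parses the matrix dialect of a luminescence export: a comma-separated
#' grid with a header row of column indices and a leading column of row
#' letters, 16 x 24 for 384-well plates (8 x 12 for 96-well). Roles are not
#' known at this stage; every well is returned with `role = "empty"` until a
#' layout is applied.
#'
#' @param path Path to the CSV file.
#' @param plate_id Plate identifier to stamp on every record.
#' @param replicate Replicate number (integer >= 1).
#' @param plate_format 384 (default) or 96.
#'
#' @return A tibble of well records with columns `plate_id`, `replicate`,
#'   `well`, `row_letter`, `column`, `role`, `compound_id`,
#'   `concentration_um`, `raw_lum`, `corrected_lum` (all `corrected_lum`
#'   `NA` until [blank_correct()]).
#' @seealso [parse_plate_long()], [write_plate_matrix()]
#' @export
parse_plate_matrix <- function(path, plate_id, replicate = 1L,
                               plate_format = 384) {
  dims <- plate_dims(plate_format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) != dims$n_rows + 1L) {
    abort(sprintf(
      "Expected %d data rows plus header in %s, found %d lines.",
      dims$n_rows, path, length(lines)))
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) != dims$n_cols + 1L) {
    abort(sprintf("Expected %d columns plus row-letter column, found %d.",
                  dims$n_cols, length(header) - 1L))
  }
  rows <- cells[-1L]
  row_letters <- vapply(rows, `[`, character(1), 1L)
  expected_letters <- LETTERS[seq_len(dims$n_rows)]
  if (!identical(toupper(row_letters), expected_letters)) {
    abort(sprintf("Row letters must be %s-%s in order; got: %s",
                  expected_letters[1], expected_letters[dims$n_rows],
                  paste(head(row_letters, 5), collapse = ", ")))
  }
  bad_len <- vapply(rows, length, integer(1)) != dims$n_cols + 1L
  if (any(bad_len)) {
    abort(sprintf("Row(s) %s have the wrong number of columns.",
                  paste(row_letters[bad_len], collapse = ", ")))
  }
  values <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(dims$n_cols)))
  # values is n_cols x n_rows; locate non-numeric cells by address
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)
    addr <- paste0(expected_letters[idx[, 2L]], idx[, 1L])
    abort(sprintf("Non-numeric value(s) at well(s): %s",
                  paste(addr, collapse = ", ")))
  }
  tibble(
    plate_id = as.character(plate_id),
    replicate = as.integer(replicate),
    well = plate_wells(plate_format),
    row_letter = rep(expected_letters, each = dims$n_cols),
    column = rep(seq_len(dims$n_cols), times = dims$n_rows),
    role = "empty",
    compound_id = NA_character_,
    concentration_um = NA_real_,
    raw_lum = as.vector(values),  # column-major over (col, row) = row-major wells
    corrected_lum = NA_real_
  )
}

#' Write a plate matrix CSV
#'
#' Inverse of [parse_plate_matrix()]: one plate/replicate of well records is
#' written back as the matrix dialect.
#'
#' @param wells Well records for a single `(plate_id, replicate)`.
#' @param path Output path.
#' @inheritParams parse_plate_matrix
#' @return `path`, invisibly.
#' @export
write_plate_matrix <- function(wells, path, plate_format = 384) {
  dims <- plate_dims(plate_format)
  stopifnot(nrow(wells) == dims$n_rows * dims$n_cols)
  if (nrow(dplyr::distinct(wells, plate_id, replicate)) != 1L) {
    abort("`wells` must contain exactly one plate/replicate.")
  }
  ord <- order(match(wells$row_letter, LETTERS), wells$column)
  vals <- matrix(wells$raw_lum[ord], nrow = dims$n_rows,
                 ncol = dims$n_cols, byrow = TRUE)
  txt <- apply(vals, 1, function(v)
    paste(format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE),
          collapse = ","))
  header <- paste(c("", seq_len(dims$n_cols)), collapse = ",")
  writeLines(c(header, paste(LETTERS[seq_len(dims$n_rows)], txt, sep = ",")),
             path)
  invisible(path)
}

#' Read / write the long (annotated) plate dialect
#'
#' The long dialect is the canonical interchange format: one row per well
#' with columns `plate_id, replicate, well, role, compound_id,
#' concentration_uM, raw_lum`. Roles must be one of blank, dmso, hemin,
#' cddo, test, empty; a test well must name its compound; each
#' `(plate_id, replicate, well)` may appear only once.
#'
#' @param path Path to the CSV file.
#' @param plate_format 384 (default) or 96; used to validate addresses.
#' @return A tibble of well records (see [parse_plate_matrix()] for columns).
#' @export
parse_plate_long <- function(path, plate_format = 384) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      replicate = readr::col_integer(),
      well = readr::col_character(),
      role = readr::col_character(),
      compound_id = readr::col_character(),
      concentration_uM = readr::col_double(),
      raw_lum = readr::col_double()
    ),
    progress = FALSE
  )
  validate_well_records(
    tibble(
      plate_id = df$plate_id,
      replicate = df$replicate,
      well = df$well,
      role = df$role,
      compound_id = df$compound_id,
      concentration_um = df$concentration_uM,
      raw_lum = df$raw_lum
    ),
    plate_format = plate_format
  )
}

validate_well_records <- function(df, plate_format = 384) {
  addr <- parse_well_address(df$well, plate_format)
  bad_role <- !df$role %in% well_roles
  if (any(bad_role)) {
    abort(sprintf("Unknown role(s): %s",
                  paste(unique(df$role[bad_role]), collapse = ", ")))
  }
  orphan <- df$role == "test" & (is.na(df$compound_id) | df$compound_id == "")
  if (any(orphan)) {
    abort(sprintf("Test well(s) without compound_id: %s",
                  paste(head(df$well[orphan], 10), collapse = ", ")))
  }
  tagged <- df$role == "blank" & !is.na(df$compound_id)
  if (any(tagged)) {
    abort(sprintf("Blank well(s) must not carry a compound: %s",
                  paste(head(df$well[tagged], 10), collapse = ", ")))
  }
  key <- paste(df$plate_id, df$replicate, df$well, sep = "/")
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (plate, replicate, well): %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  tibble(
    plate_id = df$plate_id,
    replicate = as.integer(df$replicate),
    well = df$well,
    row_letter = addr$row_letter,
    column = addr$column,
    role = df$role,
    compound_id = dplyr::if_else(df$compound_id == "", NA_character_,
                                 df$compound_id),
    concentration_um = df$concentration_um,
    raw_lum = df$raw_lum,
    corrected_lum = if ("corrected_lum" %in% names(df)) df$corrected_lum
                    else NA_real_
  )
}

#' @param wells Well records as returned by the parsers.
#' @rdname parse_plate_long
#' @export
write_plate_long <- function(wells, path) {
  out <- tibble(
    plate_id = wells$plate_id,
    replicate = wells$replicate,
    well = wells$well,
    role = wells$role,
    compound_id = wells$compound_id,
    concentration_uM = wells$concentration_um,
    raw_lum = wells$raw_lum
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Load compound-library manifests
#'
#' Each manifest CSV lists `compound_id,name,library_tag`; several files are
#' merged into one manifest. Compound ids must be unique across files.
#'
#' @param paths Character vector of manifest CSV paths (may be empty).
#' @param screen_concentration Single-dose screening concentration in uM.
#' @return A tibble with columns `compound_id`, `name`, `library_tag` and
#'   attribute `screen_concentration`.
#' @seealso [manifest_totals()]
#' @export
load_manifest <- function(paths, screen_concentration = 10) {
  if (length(paths) == 0) {
    m <- tibble(compound_id = character(), name = character(),
                library_tag = character())
  } else {
    m <- purrr::map(paths, function(p) {
      readr::read_csv(p, col_types = readr::cols(
        compound_id = readr::col_character(),
        name = readr::col_character(),
        library_tag = readr::col_character()
      ), progress = FALSE)
    })
    m <- dplyr::bind_rows(m)
  }
  dup <- unique(m$compound_id[duplicated(m$compound_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate compound_id across manifests: %s",
                  paste(head(dup, 10), collapse = ", ")))
  }
  attr(m, "screen_concentration") <- screen_concentration
  m
}

#' Manifest totals per library and overall
#'
#' @param manifest A manifest tibble from [load_manifest()].
#' @return A tibble with one row per `library_tag` plus a `total` row.
#' @examples
#' m <- tibble::tibble(compound_id = c("a", "b", "c"), name = NA_character_,
#'                     library_tag = c("CLOUD", "TOCRI1", "TOCRI1"))
#' manifest_totals(m)
#' @export
manifest_totals <- function(manifest) {
  per_tag <- dplyr::count(manifest, library_tag, name = "n")
  dplyr::bind_rows(per_tag,
                   tibble(library_tag = "total", n = nrow(manifest)))
}

#' Define a screen plate layout
#'
#' The default 384-well screening layout reserves one full column for blanks
#' (media only) and one full 16-well column for each control (DMSO negative,
#' hemin positive, CDDO non-specific inducer); the remaining 320 wells take
#' test compounds.
#'
#' @param plate_format 384 (default) or 96.
#' @param blank_columns Integer vector of blank column indices.
#' @param control_columns Named integer vector mapping `dmso`, `hemin`,
#'   `cddo` to column indices.
#' @return An object of class `screen_layout`.
#' @export
screen_layout <- function(plate_format = 384,
                          blank_columns = 1L,
                          control_columns = c(dmso = 2L, hemin = 3L,
                                              cddo = 4L)) {
  dims <- plate_dims(plate_format)
  stopifnot(all(c("dmso", "hemin", "cddo") %in% names(control_columns)))
  reserved <- c(blank_columns, unname(control_columns))
  if (anyDuplicated(reserved)) {
    abort("Blank and control columns must be disjoint.")
  }
  if (any(reserved < 1L | reserved > dims$n_cols)) {
    abort("Reserved columns outside plate range.")
  }
  all_wells <- plate_wells(plate_format)
  col_of <- rep(seq_len(dims$n_cols), times = dims$n_rows)
  role <- rep("test", length(all_wells))
  role[col_of %in% blank_columns] <- "blank"
  for (ctrl in names(control_columns)) {
    role[col_of == control_columns[[ctrl]]] <- ctrl
  }
  structure(
    list(plate_format = plate_format,
         blank_columns = as.integer(blank_columns),
         control_columns = control_columns,
         wells = all_wells,
         roles = role,
         capacity = sum(role == "test")),
    class = "screen_layout"
  )
}

#' @export
print.screen_layout <- function(x, ...) {
  cat(sprintf("<screen_layout> %d-well; blanks in col %s; %s; capacity %d\n",
              x$plate_format, paste(x$blank_columns, collapse = ","),
              paste(sprintf("%s=col %d", names(x$control_columns),
                            x$control_columns), collapse = ", "),
              x$capacity))
  invisible(x)
}

#' Randomly place library compounds onto assay plates
#'
#' Compounds are dispensed into random test wells; replicate placements use
#' different permutations (seed + replicate - 1) so that every compound
#' occupies a different well in each replicate with near certainty. Plates
#' are filled to capacity; leftover wells on the last plate stay
#' `role = "empty"` and are excluded from all statistics.
#'
#' @param manifest Manifest tibble from [load_manifest()].
#' @param layout A [screen_layout()].
#' @param n_replicates Number of independent replicates (default 2).
#' @param seed Integer seed; placement is deterministic given the seed.
#' @return A tibble of well records (raw_lum `NA`) covering
#'   `ceiling(nrow(manifest) / capacity)` plates times `n_replicates`.
#' @export
assign_layout <- function(manifest, layout = screen_layout(),
                          n_replicates = 2L, seed = 1L) {
  if (layout$capacity < 1L) abort("Layout has no test capacity.")
  n <- nrow(manifest)
  n_plates <- max(1L, as.integer(ceiling(n / layout$capacity)))
  conc <- attr(manifest, "screen_concentration") %||% 10
  addr <- parse_well_address(layout$wells, layout$plate_format)

  one_replicate <- function(rep_i) {
    base <- tibble(
      plate_id = rep(sprintf("P%d", seq_len(n_plates)),
                     each = length(layout$wells)),
      replicate = as.integer(rep_i),
      well = rep(layout$wells, times = n_plates),
      row_letter = rep(addr$row_letter, times = n_plates),
      column = rep(addr$column, times = n_plates),
      role = rep(layout$roles, times = n_plates),
      compound_id = NA_character_,
      concentration_um = NA_real_,
      raw_lum = NA_real_,
      corrected_lum = NA_real_
    )
    slots <- which(base$role == "test")
    placed <- withr::with_seed(seed + rep_i - 1L, sample(slots, n))
    base$compound_id[placed] <- manifest$compound_id
    base$concentration_um[placed] <- conc
    base$role[base$role == "test" & is.na(base$compound_id)] <- "empty"
    base
  }
  dplyr::bind_rows(purrr::map(seq_len(n_replicates), one_replicate))
}
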