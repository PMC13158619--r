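# Independent formula oracles (deliberately not using stats::mad or the
# package's own functions) and small fixture builders.

oracle_raw_mad <- function(v) median(abs(v - median(v)))

oracle_rz <- function(pos, neg) {
  1 - 3 * (oracle_raw_mad(pos) + oracle_raw_mad(neg)) /
    (median(pos) - median(neg))
}

oracle_sb <- function(pos, neg) {
  (sum(pos) / length(pos)) / (sum(neg) / length(neg))
}

# Build a minimal plate of well records directly (no file round trip).
# Each argument is a numeric vector of raw luminescence for that role.
mini_plate <- function(blank = c(50, 50, 48, 52),
                       dmso = c(100, 110, 90, 105),
                       hemin = NULL, cddo = NULL, test = NULL,
                       test_ids = NULL,
                       plate_id = "P1", replicate = 1L) {
  roles <- c(rep("blank", length(blank)), rep("dmso", length(dmso)),
             rep("hemin", length(hemin)), rep("cddo", length(cddo)),
             rep("test", length(test)))
  n <- length(roles)
  stopifnot(n <= 384)
  wells <- plate_wells(384)[seq_len(n)]
  ids <- rep(NA_character_, n)
  if (length(test)) {
    ids[roles == "test"] <- test_ids %||%
      sprintf("T%03d", seq_along(test))
  }
  tibble::tibble(
    plate_id = plate_id, replicate = as.integer(replicate),
    well = wells,
    row_letter = substr(wells, 1, 1),
    column = as.integer(sub("^[A-P]", "", wells)),
    role = roles,
    compound_id = ids,
    concentration_um = ifelse(roles == "test", 10, NA_real_),
    raw_lum = c(blank, dmso, hemin, cddo, test),
    corrected_lum = NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless Hill curve sampled on a grid, as a dose-response data frame.
hill_points <- function(bottom, top, ec50, hill,
                        grid = default_conc_grid()) {
  data.frame(concentration_um = grid,
             fc = bottom + (top - bottom) * grid^hill /
               (ec50^hill + grid^hill))
}

# Write a tiny manifest CSV with n auto-named compounds; returns the path.
write_test_manifest <- function(n, tag, prefix, dir = tempdir()) {
  path <- file.path(dir, paste0(prefix, ".csv"))
  df <- data.frame(compound_id = sprintf("%s%04d", prefix, seq_len(n)),
                   name = sprintf("%s compound %d", tag, seq_len(n)),
                   library_tag = tag)
  readr::write_csv(df, path, progress = FALSE)
  path
}
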