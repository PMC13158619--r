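test_that("matrix dialect parses, errors on bad cells, and round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "plate.csv")

  grid <- matrix(100, nrow = 16, ncol = 24)
  writeLines(c(paste(c("", 1:24), collapse = ","),
               paste(LETTERS[1:16], apply(grid, 1, paste, collapse = ","),
                     sep = ",")), path)
  rec <- parse_plate_matrix(path, plate_id = "P1", replicate = 1)
  expect_equal(nrow(rec), 384)
  expect_true(all(rec$raw_lum == 100))
  expect_true(all(rec$role == "empty"))
  expect_equal(rec$well[1:3], c("A1", "A2", "A3"))

  # write -> parse round trip is byte-identical
  out <- file.path(dir, "out.csv")
  rec2 <- rec
  rec2$raw_lum <- seq_len(384) * 1.5
  write_plate_matrix(rec2, out)
  expect_identical(parse_plate_matrix(out, "P1", 1)$raw_lum, rec2$raw_lum)
  out2 <- file.path(dir, "out2.csv")
  write_plate_matrix(parse_plate_matrix(out, "P1", 1), out2)
  expect_identical(readLines(out), readLines(out2))

  # non-numeric cell is reported by its address
  grid2 <- matrix(100, nrow = 16, ncol = 24)
  lines <- c(paste(c("", 1:24), collapse = ","),
             paste(LETTERS[1:16], apply(grid2, 1, paste, collapse = ","),
                   sep = ","))
  cells <- strsplit(lines[3], ",")[[1]]  # row B
  cells[4] <- "NA"                       # column 3 -> well B3
  lines[3] <- paste(cells, collapse = ",")
  writeLines(lines, path)
  expect_error(parse_plate_matrix(path, "P1", 1), "B3")

  # wrong grid dimensions
  writeLines(lines[1:10], path)
  expect_error(parse_plate_matrix(path, "P1", 1), "16 data rows")
})

test_that("long dialect maps fields and enforces validation rules", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "long.csv")
  hdr <- "plate_id,replicate,well,role,compound_id,concentration_uM,raw_lum"

  writeLines(c(hdr, "P1,1,A1,blank,,,52"), path)
  rec <- parse_plate_long(path)
  expect_equal(rec$role, "blank")
  expect_equal(rec$well, "A1")
  expect_equal(rec$raw_lum, 52)
  expect_true(is.na(rec$compound_id))

  writeLines(c(hdr, "P1,1,A1,blank,,,52", "P1,1,A1,dmso,,,60"), path)
  expect_error(parse_plate_long(path), "Duplicate")

  writeLines(c(hdr, "P1,1,C5,test,,10,900"), path)
  expect_error(parse_plate_long(path), "without compound_id")

  # records -> write -> parse round trip
  plate <- mini_plate(hemin = c(1300, 1250), test = c(900, 410))
  out <- file.path(dir, "rt.csv")
  write_plate_long(plate, out)
  back <- parse_plate_long(out)
  expect_equal(back, dplyr::mutate(plate, corrected_lum = NA_real_))
})

test_that("manifests merge with library totals and unique compound ids", {
  dir <- withr::local_tempdir()
  paths <- c(write_test_manifest(263, "CLOUD", "CL", dir),
             write_test_manifest(1280, "TOCRI1", "T1", dir),
             write_test_manifest(503, "TOCRI2", "T2", dir))
  m <- load_manifest(paths)
  tot <- manifest_totals(m)
  expect_equal(tot$n[tot$library_tag == "total"], 2046)
  expect_equal(sum(tot$n[tot$library_tag %in% c("TOCRI1", "TOCRI2")]), 1783)

  expect_equal(nrow(load_manifest(character())), 0)
  expect_equal(manifest_totals(load_manifest(character()))$n, 0)

  expect_error(load_manifest(c(paths[1], paths[1])), "Duplicate compound_id")
})

test_that("random placement fills the right number of plates bijectively", {
  dir <- withr::local_tempdir()
  layout <- screen_layout()
  expect_equal(layout$capacity, 320)

  m1280 <- load_manifest(write_test_manifest(1280, "TOCRI1", "T1", dir))
  w <- assign_layout(m1280, layout, n_replicates = 2, seed = 7)
  expect_equal(dplyr::n_distinct(w$plate_id), 4)

  m503 <- load_manifest(write_test_manifest(503, "TOCRI2", "T2", dir))
  w503 <- assign_layout(m503, layout, n_replicates = 2, seed = 7)
  expect_equal(dplyr::n_distinct(w503$plate_id), 2)

  # bijection: every compound exactly once per replicate, no well reused
  for (r in 1:2) {
    placed <- w[w$replicate == r & w$role == "test", ]
    expect_setequal(placed$compound_id, m1280$compound_id)
    expect_equal(anyDuplicated(placed$compound_id), 0)
    expect_equal(anyDuplicated(paste(placed$plate_id, placed$well)), 0)
  }
  # leftover wells on the last plate are empty and carry no compound
  empties <- w503[w503$role == "empty", ]
  expect_equal(nrow(empties), 2 * (2 * 320 - 503))
  expect_true(all(is.na(empties$compound_id)))

  # determinism and replicate decorrelation
  w_again <- assign_layout(m1280, layout, n_replicates = 2, seed = 7)
  expect_identical(w, w_again)
  w_other <- assign_layout(m1280, layout, n_replicates = 2, seed = 8)
  expect_false(identical(w, w_other))
  pl1 <- w[w$replicate == 1 & w$role == "test", c("compound_id", "plate_id", "well")]
  pl2 <- w[w$replicate == 2 & w$role == "test", c("compound_id", "plate_id", "well")]
  j <- dplyr::inner_join(pl1, pl2, by = "compound_id")
  same_well <- mean(j$plate_id.x == j$plate_id.y & j$well.x == j$well.y)
  expect_lt(same_well, 0.05)
})

test_that("well addresses validate ranges and malformed strings", {
  expect_equal(well_address("B", 17), "B17")
  expect_error(well_address("Q", 1, 384), "out of range")
  expect_error(well_address("A", 25, 384), "out of range")
  expect_error(well_address("J", 5, 96), "out of range")
  addr <- parse_well_address(c("A1", "P24"))
  expect_equal(addr$row_letter, c("A", "P"))
  expect_equal(addr$column, c(1L, 24L))
  expect_error(parse_well_address("17B"), "Malformed")
})
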