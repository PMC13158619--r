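test_that("blank correction subtracts the per-plate blank median", {
  plate <- mini_plate(blank = c(50, 50, 48, 52), dmso = c(100, 110, 90, 105),
                      test = 150)
  cor <- blank_correct(plate, quiet = TRUE)
  expect_equal(cor$corrected_lum[cor$role == "test"], 100)
  # blanks themselves centre on zero
  expect_equal(median(cor$corrected_lum[cor$role == "blank"]), 0)

  # all-zero plate stays zero
  zero <- mini_plate(blank = c(0, 0), dmso = c(0, 0))
  expect_true(all(blank_correct(zero, quiet = TRUE)$corrected_lum == 0))

  # values below the blank stay negative (flagged via message, not clamped)
  neg <- mini_plate(blank = c(50, 50), dmso = c(100, 100), test = 40)
  expect_message(out <- blank_correct(neg), "below the blank median")
  expect_equal(out$corrected_lum[out$role == "test"], -10)

  expect_error(blank_correct(mini_plate(blank = numeric(0), dmso = 100)),
               "No blank wells")
})

test_that("fold change normalises to the DMSO median and is scale invariant", {
  plate <- mini_plate(blank = rep(0, 4), dmso = c(100, 110, 90, 105),
                      test = c(1025, 102.5))
  fc <- fold_change_normalise(blank_correct(plate, quiet = TRUE))
  expect_equal(sort(fc$fold_change[fc$role == "test"]), c(1.0, 10.0))
  expect_equal(median(fc$fold_change[fc$role == "dmso"]), 1)

  scaled <- dplyr::mutate(plate, raw_lum = raw_lum * 3.7)
  fc2 <- fold_change_normalise(blank_correct(scaled, quiet = TRUE))
  expect_equal(fc2$fold_change, fc$fold_change)

  dead <- mini_plate(blank = c(100, 100), dmso = c(50, 60))
  expect_error(fold_change_normalise(blank_correct(dead, quiet = TRUE)),
               "DMSO median <= 0")
  expect_error(fold_change_normalise(mini_plate()), "not blank-corrected")
})

test_that("robust Z-prime matches hand arithmetic and its limits", {
  pos <- c(20, 22, 24, 26, 28)
  neg <- c(1, 1, 2, 1, 1)
  expect_equal(robust_zprime(pos, neg), 1 - 3 * (2 + 0) / (24 - 1))

  # noiseless limit is exactly 1
  expect_equal(robust_zprime(c(10, 10, 10), c(1, 1, 1)), 1)

  expect_error(robust_zprime(c(5, 5, 5), c(5, 5, 5)), "undefined")
  expect_error(robust_zprime(7, c(1, 2)), "at least 2")
})

test_that("rZ' and SB agree with direct formula evaluation on random vectors", {
  withr::with_seed(42, {
    for (i in 1:200) {
      pos <- rnorm(sample(3:16, 1), mean = 20, sd = 3)
      neg <- rnorm(sample(3:16, 1), mean = 2, sd = 0.5)
      expect_equal(robust_zprime(pos, neg), oracle_rz(pos, neg))
      expect_equal(signal_to_background(pos, neg), oracle_sb(pos, neg))
      expect_lte(robust_zprime(pos, neg), 1)
    }
  })
})

test_that("signal-to-background is the ratio of control means", {
  expect_equal(signal_to_background(c(20, 22, 24, 26, 28), c(1, 1, 2, 1, 1)),
               20)
  expect_equal(signal_to_background(c(3, 4), c(3, 4)), 1)
  expect_error(signal_to_background(c(3, 4), c(-1, 1)), "undefined")
})

test_that("plate QC flags plates on both statistics with reasons", {
  plate <- mini_plate(blank = rep(50, 16),
                      dmso = 50 + c(95, 100, 105, 98, 102, 99, 101, 100),
                      hemin = 50 + 100 * c(12.8, 13.1, 13.0, 12.9, 13.2,
                                           13.0, 12.7, 13.1))
  qc <- plate_qc(blank_correct(plate, quiet = TRUE))
  expect_s3_class(qc, "plate_qc")
  expect_true(qc$pass_qc)
  expect_equal(qc$rz_prime,
               oracle_rz(plate$raw_lum[plate$role == "hemin"] - 50,
                         plate$raw_lum[plate$role == "dmso"] - 50))

  # a plate just under the rZ' gate fails
  qc_fail <- plate_qc(blank_correct(plate, quiet = TRUE),
                      rz_min = qc$rz_prime + 1e-6)
  expect_false(qc_fail$pass_qc)
  expect_match(qc_fail$reason, "rZ'")

  # hemin identical to DMSO: rZ' undefined -> fail with reason, no error
  flat <- mini_plate(blank = rep(0, 4), dmso = rep(100, 8),
                     hemin = rep(100, 8))
  qc_flat <- plate_qc(blank_correct(flat, quiet = TRUE))
  expect_false(qc_flat$pass_qc)
  expect_match(qc_flat$reason, "undefined")

  no_ctrl <- mini_plate(blank = c(1, 1), dmso = c(100, 100))
  expect_error(plate_qc(blank_correct(no_ctrl, quiet = TRUE)), "hemin")
})

test_that("active wells use a strict cut-off and recover planted spike-ins", {
  plate <- mini_plate(blank = rep(0, 4), dmso = rep(100, 8),
                      test = c(100, 250, 260),
                      test_ids = c("a", "b", "c"))
  fc <- fold_change_normalise(blank_correct(plate, quiet = TRUE))
  act <- flag_active_wells(fc, 2.5)
  expect_equal(act$compound_id, "c")  # FC 2.5 itself is not active

  expect_equal(nrow(flag_active_wells(fc[0, ], 2.5)), 0)

  # blind spike-in: 5 wells at FC ~8 among nulls at FC ~1
  withr::with_seed(99, {
    n <- 100
    fcs <- rlnorm(n, 0, 0.05)
    spike <- sample(n, 5)
    fcs[spike] <- 8 * rlnorm(5, 0, 0.05)
  })
  plate2 <- mini_plate(blank = rep(0, 4), dmso = rep(100, 8),
                       test = 100 * fcs,
                       test_ids = sprintf("S%03d", seq_along(fcs)))
  fc2 <- fold_change_normalise(blank_correct(plate2, quiet = TRUE))
  found <- flag_active_wells(fc2, 2.5)
  expect_setequal(found$compound_id, sprintf("S%03d", spike))
  expect_equal(found$fold_change, sort(found$fold_change, decreasing = TRUE))
})
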