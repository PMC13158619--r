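test_that("noiseless Hill data are recovered within 1 percent", {
  d <- hill_points(bottom = 1, top = 15, ec50 = 2, hill = 1)
  fit <- fit_hill(d)
  expect_equal(fit$method, "hill")
  expect_equal(fit$bottom, 1, tolerance = 0.01)
  expect_equal(fit$top, 15, tolerance = 0.01)
  expect_equal(fit$ec50, 2, tolerance = 0.01)
  expect_equal(fit$hill, 1, tolerance = 0.01)
  expect_lt(fit$rss, 1e-4)

  td <- tidy(fit)
  expect_equal(td$term, c("bottom", "top", "ec50", "hill"))
  expect_equal(td$estimate[3], 2, tolerance = 0.01)
  expect_equal(glance(fit)$method, "hill")
  expect_false(glance(fit)$degenerate)
})

test_that("degenerate and undersized series are handled", {
  flat <- data.frame(concentration_um = default_conc_grid(),
                     fc = rep(1, 8))
  fit <- fit_hill(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$bottom, 1)
  expect_equal(fit$top, 1)
  expect_true(is.na(min_effective_concentration(fit, 7.8)))

  expect_error(fit_hill(data.frame(concentration_um = c(1, 3, 10),
                                   fc = c(1, 2, 3))),
               ">= 4 distinct")

  # replicate columns are averaged before fitting
  d <- hill_points(1, 15, 2, 1)
  d2 <- rbind(transform(d, fc = fc * 1.1, replicate = 1),
              transform(d, fc = fc * 0.9, replicate = 2))
  fit2 <- fit_hill(d2)
  expect_equal(fit2$ec50, 2, tolerance = 0.05)
})

test_that("minimal effective concentration inverts the fitted curve", {
  # hand inversion: 1 + 14 c / (2 + c) = 7.8  =>  c = 13.6 / 7.2
  d <- hill_points(1, 15, 2, 1)
  fit <- fit_hill(d)
  expect_equal(min_effective_concentration(fit, 7.8), 13.6 / 7.2,
               tolerance = 1e-3)

  # curve never reaching the benchmark
  low <- fit_hill(hill_points(1, 5, 2, 1))
  expect_true(is.na(min_effective_concentration(low, 7.8)))

  # benchmark at/below bottom clamps to the smallest tested concentration
  expect_equal(min_effective_concentration(fit, 1), 0.01)
  expect_equal(min_effective_concentration(fit, 0.5), 0.01)

  # analytic inversion agrees with a dense grid search over concentration
  grid <- 10^seq(log10(0.01), log10(30), length.out = 5000)
  for (bench in c(3, 7.8, 12)) {
    c_grid <- grid[which(hill_response(grid, fit$bottom, fit$top, fit$ec50,
                                       fit$hill) >= bench)[1]]
    expect_equal(min_effective_concentration(fit, bench), c_grid,
                 tolerance = 0.01)
  }

  # mec is non-decreasing in the benchmark
  benches <- seq(1.5, 16, by = 0.5)
  mecs <- vapply(benches, function(b) min_effective_concentration(fit, b),
                 numeric(1))
  reached <- !is.na(mecs)
  expect_true(all(diff(mecs[reached]) >= 0))
  # once unreachable, stays unreachable
  expect_true(all(diff(reached) <= 0))
})

test_that("interpolation fallback decides mec from the points", {
  pts <- tibble::tibble(concentration_um = c(1, 10),
                        fc = c(0.9, NA))
  # exercise the piecewise path through the internal constructor
  f <- screenfunnel:::new_hill_fit(
    bottom = 1, top = 9, ec50 = NA_real_, hill = NA_real_, rss = NA_real_,
    points = tibble::tibble(concentration_um = c(0.1, 1, 10, 30),
                            fc = c(1, 2, 9, 9.5)),
    method = "interpolation")
  # crossing between 1 and 10 on the log scale: f = (7.8-2)/(9-2)
  expect_equal(min_effective_concentration(f, 7.8),
               10^(0 + (5.8 / 7) * 1), tolerance = 1e-6)
  expect_equal(min_effective_concentration(f, 0.5), 0.1)
  expect_true(is.na(min_effective_concentration(f, 20)))
})

test_that("efficacy filter keeps compounds reaching the benchmark by 10 uM", {
  cohort <- dplyr::bind_rows(
    dplyr::mutate(hill_points(1, 15, 2, 1), compound_id = "fast"),
    dplyr::mutate(hill_points(1, 15, 25, 1), compound_id = "slow"),
    dplyr::mutate(hill_points(1, 5, 2, 1), compound_id = "weak"))
  fits <- fit_hill_all(cohort)
  out <- efficacy_filter(fits, benchmark = 7.8, max_conc = 10)
  expect_equal(out$pass_efficacy[out$compound_id == "fast"], TRUE)
  expect_equal(out$pass_efficacy[out$compound_id == "slow"], FALSE)
  expect_equal(out$pass_efficacy[out$compound_id == "weak"], FALSE)
  expect_true(is.na(out$mec[out$compound_id == "weak"]))

  # boundary: needing exactly 10 uM passes; only "more than 10" is removed
  # (benchmark 8 is the curve's exact midpoint response at ec50 = 10)
  f10 <- screenfunnel:::new_hill_fit(
    bottom = 1, top = 15, ec50 = 10, hill = 1, rss = 0,
    points = hill_points(1, 15, 10, 1), method = "hill")
  expect_identical(min_effective_concentration(f10, 8), 10)
  fits10 <- tibble::tibble(compound_id = "edge", bottom = 1, top = 15,
                           ec50 = 10, hill = 1, rss = 0,
                           method = "hill", fit = list(f10))
  expect_true(efficacy_filter(fits10, 8, max_conc = 10)$pass_efficacy)
  expect_false(efficacy_filter(fits10, 8, max_conc = 9.99)$pass_efficacy)

  # planted cohort of 34 with 13 potent actives: exactly those 13 pass
  mk <- function(id, top, ec50) dplyr::mutate(hill_points(1, top, ec50, 1),
                                              compound_id = id)
  cohort34 <- dplyr::bind_rows(
    purrr::map(sprintf("potent%02d", 1:13), mk, top = 15, ec50 = 2),
    purrr::map(sprintf("weak%02d", 1:21), mk, top = 5, ec50 = 2))
  out34 <- efficacy_filter(fit_hill_all(cohort34), 7.8, 10)
  expect_equal(sum(out34$pass_efficacy), 13)
  expect_true(all(grepl("^potent", out34$compound_id[out34$pass_efficacy])))
})

test_that("ec50 is recovered within 10 percent under 5 percent CV noise", {
  truth_row <- tibble::tibble(compound_id = "x", true_top = 15,
                              true_ec50 = 2, true_hill = 1,
                              tox_ic50 = NA_real_, tox_hill = NA_real_)
  errs <- vapply(1:100, function(s) {
    d <- simulate_dose_response(truth_row, n_rep = 3, cv = 0.05, seed = s)
    abs(fit_hill(d)$ec50 - 2) / 2
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})
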