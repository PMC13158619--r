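#' Blank-correct a screen
#'
#' Subtracts, per plate and replicate, the median raw luminescence of the
#' blank (media-only) wells from every well on that plate, including the
#' blanks themselves (their corrected values centre on zero). Negative
#' corrected values are retained — clamping would bias the DMSO median — and
#' their count is reported via a message.
#'
#' @param wells Well records (see [parse_plate_long()]); every
#'   `(plate_id, replicate)` group must contain at least one blank well.
#' @param quiet Suppress the negative-value message.
#' @return The input tibble with `corrected_lum` filled in.
#' @export
blank_correct <- function(wells, quiet = FALSE) {
  out <- wells |>
    dplyr::group_by(plate_id, replicate) |>
    dplyr::group_modify(function(df, key) {
      blanks <- df$raw_lum[df$role == "blank"]
      blanks <- blanks[!is.na(blanks)]
      if (length(blanks) == 0) {
        abort(sprintf("No blank wells on plate %s replicate %s.",
                      key$plate_id, key$replicate))
      }
      df$corrected_lum <- df$raw_lum - median(blanks)
      df
    }) |>
    dplyr::ungroup()
  n_neg <- sum(out$corrected_lum < 0 & out$role != "blank" &
                 out$role != "empty", na.rm = TRUE)
  if (n_neg > 0 && !quiet) {
    inform(sprintf("blank_correct: %d non-blank well(s) fell below the blank median (kept, not clamped).",
                   n_neg))
  }
  out
}

#' Plate-normalised fold change
#'
#' Divides each well's blank-corrected luminescence by the median of the
#' blank-corrected DMSO control wells on the same plate and replicate. By
#' construction the median DMSO fold change on every plate is exactly 1, and
#' the table is invariant under any per-plate rescaling of the raw signal.
#'
#' @param wells Blank-corrected well records (run [blank_correct()] first).
#' @return A fold-change tibble with columns `plate_id`, `replicate`,
#'   `well`, `role`, `compound_id`, `fold_change` (empty wells dropped).
#' @export
fold_change_normalise <- function(wells) {
  if (all(is.na(wells$corrected_lum))) {
    abort("Wells are not blank-corrected; run blank_correct() first.")
  }
  wells |>
    dplyr::filter(role != "empty") |>
    dplyr::group_by(plate_id, replicate) |>
    dplyr::group_modify(function(df, key) {
      dmso <- df$corrected_lum[df$role == "dmso"]
      dmso <- dmso[!is.na(dmso)]
      if (length(dmso) == 0) {
        abort(sprintf("No DMSO wells on plate %s replicate %s.",
                      key$plate_id, key$replicate))
      }
      dm <- median(dmso)
      if (dm <= 0) {
        abort(sprintf("DMSO median <= 0 on plate %s replicate %s; plate unusable.",
                      key$plate_id, key$replicate))
      }
      tibble(well = df$well, role = df$role, compound_id = df$compound_id,
             fold_change = df$corrected_lum / dm)
    }) |>
    dplyr::ungroup()
}

#' Robust Z-prime factor
#'
#' Plate-quality statistic on control wells:
#' `1 - 3 * (MAD(pos) + MAD(neg)) / (median(pos) - median(neg))`, where MAD
#' is the raw median absolute deviation (consistency constant 1 by default,
#' not the 1.4826 normal-consistency scaling; configurable). Values approach
#' 1 for a perfectly separated, noiseless assay and can be arbitrarily
#' negative; the statistic never exceeds 1.
#'
#' @param pos Numeric vector of positive-control values (>= 2 values).
#' @param neg Numeric vector of negative-control values (>= 2 values).
#' @param mad_constant Scale constant passed to [stats::mad()]; default 1.
#' @return A single number <= 1.
#' @examples
#' robust_zprime(c(20, 22, 24, 26, 28), c(1, 1, 2, 1, 1))
#' @export
robust_zprime <- function(pos, neg, mad_constant = 1) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 2 || length(neg) < 2) {
    abort("Need at least 2 values per control group.")
  }
  sep <- median(pos) - median(neg)
  if (sep == 0) {
    abort("Control medians are equal; robust Z-prime undefined.")
  }
  1 - 3 * (mad(pos, constant = mad_constant) +
             mad(neg, constant = mad_constant)) / sep
}

#' Signal-to-background ratio
#'
#' Mean of the positive-control values over the mean of the
#' negative-control values, both blank-corrected.
#'
#' @inheritParams robust_zprime
#' @return A single number.
#' @examples
#' signal_to_background(c(20, 22, 24, 26, 28), c(1, 1, 2, 1, 1))
#' @export
signal_to_background <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 1 || length(neg) < 1) abort("Empty control group.")
  mn <- mean(neg)
  if (mn == 0) abort("Negative-control mean is zero; SB undefined.")
  mean(pos) / mn
}

#' Per-plate quality-control report
#'
#' Computes robust Z-prime and signal-to-background per plate and replicate
#' on blank-corrected luminescence, with hemin as the positive control and
#' DMSO as the negative control, and flags plates passing
#' `rz_prime >= rz_min` and `sb >= sb_min`. A plate whose rZ' is undefined
#' (equal control medians) fails with a reason rather than erroring.
#'
#' @param wells Blank-corrected well records containing `hemin` and `dmso`
#'   roles on every plate.
#' @param rz_min Minimum robust Z-prime to pass (default 0.5).
#' @param sb_min Minimum signal-to-background to pass (default 5).
#' @param mad_constant MAD scale constant (default 1, the raw MAD).
#' @return A tibble of class `plate_qc` with one row per plate/replicate:
#'   control medians and MADs, `rz_prime`, `sb`, `pass_qc`, `reason`.
#' @export
plate_qc <- function(wells, rz_min = 0.5, sb_min = 5, mad_constant = 1) {
  if (all(is.na(wells$corrected_lum))) {
    abort("Wells are not blank-corrected; run blank_correct() first.")
  }
  rep <- wells |>
    dplyr::group_by(plate_id, replicate) |>
    dplyr::group_modify(function(df, key) {
      for (need in c("hemin", "dmso")) {
        if (!any(df$role == need)) {
          abort(sprintf("Plate %s replicate %s is missing control role '%s'.",
                        key$plate_id, key$replicate, need))
        }
      }
      blanks <- df$raw_lum[df$role == "blank"]
      pos <- df$corrected_lum[df$role == "hemin"]
      neg <- df$corrected_lum[df$role == "dmso"]
      rz <- tryCatch(robust_zprime(pos, neg, mad_constant = mad_constant),
                     error = function(e) NA_real_)
      sb <- tryCatch(signal_to_background(pos, neg),
                     error = function(e) NA_real_)
      pass <- !is.na(rz) && !is.na(sb) && rz >= rz_min && sb >= sb_min
      reason <- if (is.na(rz)) "rZ' undefined (no control separation)"
        else if (is.na(sb)) "SB undefined (zero DMSO mean)"
        else if (!pass) sprintf("rZ' %.3f (min %.2f), SB %.2f (min %.2f)",
                                rz, rz_min, sb, sb_min)
        else ""
      tibble(
        blank_median = if (length(blanks)) median(blanks) else NA_real_,
        dmso_median = median(neg), dmso_mad = mad(neg, constant = mad_constant),
        hemin_median = median(pos), hemin_mad = mad(pos, constant = mad_constant),
        rz_prime = rz, sb = sb, pass_qc = pass, reason = reason
      )
    }) |>
    dplyr::ungroup()
  class(rep) <- c("plate_qc", class(rep))
  rep
}

#' Wells exceeding an activity cut-off
#'
#' Returns the test wells whose plate-normalised fold change is strictly
#' greater than `cutoff`, sorted by decreasing fold change. Used both for
#' per-well hit flags and for blind spike-in recovery checks.
#'
#' @param fc A fold-change tibble from [fold_change_normalise()].
#' @param cutoff Positive fold-change cut-off; strict `>` applies.
#' @return The qualifying rows of `fc`, ordered by descending `fold_change`.
#' @export
flag_active_wells <- function(fc, cutoff) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  fc |>
    dplyr::filter(role == "test", fold_change > cutoff) |>
    dplyr::arrange(dplyr::desc(fold_change))
}
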