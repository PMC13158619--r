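#' Normalise viability to the DMSO control
#'
#' Raw fluorescence readings (e.g. resazurin reduction) are expressed as a
#' fraction of the mean DMSO-control reading. Values slightly above 1 are
#' normal measurement scatter and are kept.
#'
#' @param raw_fluor Numeric vector of treated-well readings.
#' @param dmso_fluor Numeric vector of DMSO-control readings; the mean must
#'   be positive.
#' @return Viability fractions, same length as `raw_fluor`.
#' @examples
#' normalise_viability(500, c(1000, 1000))
#' @export
normalise_viability <- function(raw_fluor, dmso_fluor) {
  dmso_fluor <- dmso_fluor[!is.na(dmso_fluor)]
  if (length(dmso_fluor) == 0 || mean(dmso_fluor) <= 0) {
    abort("DMSO control mean must be positive.")
  }
  raw_fluor / mean(dmso_fluor)
}

#' Viability at a given concentration
#'
#' Linear interpolation of a compound's viability series on log10
#' concentration; exact at tested points. Queries outside the tested range
#' are an error — no extrapolation.
#'
#' @param series Data frame with columns `concentration_um` and `viability`
#'   (replicates, if present, are averaged per concentration).
#' @param conc Query concentration in uM, within the tested range.
#' @return Interpolated viability fraction.
#' @examples
#' s <- data.frame(concentration_um = c(1, 10), viability = c(0.9, 0.5))
#' viability_at(s, 3)
#' @export
viability_at <- function(series, conc) {
  pts <- series |>
    dplyr::group_by(concentration_um) |>
    dplyr::summarise(viability = mean(viability), .groups = "drop") |>
    dplyr::arrange(concentration_um)
  if (any(pts$concentration_um <= 0)) abort("Concentrations must be > 0.")
  rng <- range(pts$concentration_um)
  if (conc < rng[1] || conc > rng[2]) {
    abort(sprintf("Concentration %g uM outside tested range [%g, %g]; no extrapolation.",
                  conc, rng[1], rng[2]))
  }
  approx(log10(pts$concentration_um), pts$viability,
         xout = log10(conc), ties = mean)$y
}

#' Viability gate at each compound's effective concentration
#'
#' The counter-screen: a candidate is excluded when the concentration it
#' needs to reach the efficacy benchmark leaves fewer than `min_viability`
#' of cells alive relative to DMSO. Exactly `min_viability` passes — only
#' strictly lower viability excludes. Candidates without a minimal
#' effective concentration (already failed efficacy) are not evaluated.
#'
#' @param candidates Data frame with columns `compound_id` and `mec` (uM).
#' @param viability_data Long viability table: `compound_id`,
#'   `concentration_um`, `viability` (fractions of DMSO control); every
#'   candidate with a finite `mec` needs a series covering it.
#' @param min_viability Minimum surviving fraction (default 0.70).
#' @return `candidates` with `viability_at_mec` and logical `final_pass`
#'   columns.
#' @export
toxicity_filter <- function(candidates, viability_data, min_viability = 0.70) {
  ev <- candidates |>
    dplyr::mutate(
      viability_at_mec = purrr::map2_dbl(compound_id, mec, function(id, m) {
        if (is.na(m)) return(NA_real_)
        s <- dplyr::filter(viability_data, compound_id == id)
        if (nrow(s) == 0) {
          abort(sprintf("No viability series for compound %s.", id))
        }
        viability_at(s, m)
      }),
      final_pass = !is.na(mec) & viability_at_mec >= min_viability
    )
  ev
}
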