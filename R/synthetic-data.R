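#' Synthetic-screen generator configuration
#'
#' Defines the study conditions for the simulated screen: a 2046-compound
#' library on 7 assay plates (320 test wells each) in two independent
#' replicates, with one blank column and 16-well DMSO / hemin / CDDO control
#' columns per plate, multiplicative plate effects and log-normal well
#' noise. Planted compound classes mirror the selection funnel: most
#' compounds are inactive; a small set activates the reporter at NRF2 level
#' only (below the hit cut-off, like CDDO); `bach1_like` compounds induce
#' the reporter above the cut-off, a `potent` subset reaching the
#' hemin-level benchmark below 10 uM; `cytotoxic_inducer` compounds induce
#' the reporter through cellular stress but never reach the benchmark; and
#' `toxic_active` compounds reach the benchmark but kill cells at their
#' effective concentration. Control fold-change distributions are normal on
#' the fold-change scale, with hemin mean 13 and SD 5.2/3 so that
#' `mean - 3*sd = 7.8`, and CDDO mean 2.5 — making the control-derived
#' thresholds land on the conventional 2.5 / 7.8 values.
#'
#' @param n_inactive,n_nrf2_like,n_bach1_like,n_cytotoxic,n_toxic_active
#'   Compounds per class (defaults 1992 / 20 / 15 / 10 / 9; total 2046).
#' @param n_bach1_potent How many `bach1_like` compounds reach the benchmark
#'   below 10 uM and stay non-toxic (default 4).
#' @param dmso_mean_lum Mean DMSO-well luminescence in RLU.
#' @param blank_mean Mean media-only background in RLU.
#' @param plate_effect_sd SD of the per-plate log-normal scale effect.
#' @param well_cv Log-normal coefficient of variation of well noise
#'   (default 0.08).
#' @param hemin_fc_mean,hemin_fc_sd Hemin-well fold-change distribution.
#' @param cddo_fc_mean,cddo_fc_sd CDDO-well fold-change distribution.
#' @param screen_conc Single-dose screening concentration in uM.
#' @param dr_cv Log-normal CV of dose-response wells (default 0.05).
#' @param viability_cv Log-normal CV of viability wells (default 0.03).
#' @param seed Integer seed behind all generator randomness.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_inactive = 1992L, n_nrf2_like = 20L,
                             n_bach1_like = 15L, n_bach1_potent = 4L,
                             n_cytotoxic = 10L, n_toxic_active = 9L,
                             dmso_mean_lum = 2000, blank_mean = 100,
                             plate_effect_sd = 0.1, well_cv = 0.08,
                             hemin_fc_mean = 13, hemin_fc_sd = 5.2 / 3,
                             cddo_fc_mean = 2.5, cddo_fc_sd = 0.25,
                             screen_conc = 10, dr_cv = 0.05,
                             viability_cv = 0.03, seed = 1L) {
  stopifnot(n_bach1_potent <= n_bach1_like)
  structure(as.list(environment()), class = "generator_config")
}

class_params <- list(
  inactive          = list(top = 1,  ec50 = 1, hill = 1,
                           tox_ic50 = NA_real_, tox_hill = NA_real_),
  nrf2_like         = list(top = 2,  ec50 = 1, hill = 1,
                           tox_ic50 = NA_real_, tox_hill = NA_real_),
  bach1_weak        = list(top = 5,  ec50 = 2, hill = 1,
                           tox_ic50 = NA_real_, tox_hill = NA_real_),
  bach1_potent      = list(top = 15, ec50 = 2, hill = 1,
                           tox_ic50 = NA_real_, tox_hill = NA_real_),
  cytotoxic_inducer = list(top = 6,  ec50 = 3, hill = 1,
                           tox_ic50 = 5, tox_hill = 2),
  toxic_active      = list(top = 15, ec50 = 2, hill = 1,
                           tox_ic50 = 1.5, tox_hill = 2)
)

#' Generate a compound library with planted ground truth
#'
#' Produces a manifest (CLOUD / TOCRI1 / TOCRI2 tags sized 263 / 1280 / 503
#' when the library totals 2046) and a truth table giving each compound's
#' class and true concentration-response parameters: reporter response is
#' `Hill(bottom = 1, true_top, true_ec50, true_hill)` and toxicity a
#' descending Hill on viability with midpoint `tox_ic50`. Per-compound
#' parameters get a small seeded jitter so compounds are not carbon copies.
#'
#' @param config A [generator_config()].
#' @return A list with elements `manifest` (tibble; attribute
#'   `screen_concentration`) and `truth` (tibble with `compound_id`,
#'   `class`, `potent`, `true_top`, `true_ec50`, `true_hill`, `tox_ic50`,
#'   `tox_hill`).
#' @export
generate_truth_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  archetype <- c(
    rep("inactive", config$n_inactive),
    rep("nrf2_like", config$n_nrf2_like),
    rep("bach1_potent", config$n_bach1_potent),
    rep("bach1_weak", config$n_bach1_like - config$n_bach1_potent),
    rep("cytotoxic_inducer", config$n_cytotoxic),
    rep("toxic_active", config$n_toxic_active)
  )
  n <- length(archetype)
  if (n == 0) {
    truth <- tibble(compound_id = character(), class = character(),
                    potent = logical(), true_top = numeric(),
                    true_ec50 = numeric(), true_hill = numeric(),
                    tox_ic50 = numeric(), tox_hill = numeric())
    manifest <- tibble(compound_id = character(), name = character(),
                       library_tag = character())
    attr(manifest, "screen_concentration") <- config$screen_conc
    return(list(manifest = manifest, truth = truth))
  }
  withr::with_seed(config$seed, {
    archetype <- sample(archetype)
    p <- purrr::map(archetype, function(a) class_params[[a]])
    top <- vapply(p, `[[`, numeric(1), "top")
    jit_top <- ifelse(top >= 10, stats::runif(n, 0.97, 1.03),
                      stats::runif(n, 0.95, 1.05))
    truth <- tibble(
      compound_id = sprintf("C%04d", seq_len(n)),
      class = sub("^bach1_(weak|potent)$", "bach1_like", archetype),
      potent = archetype %in% c("bach1_potent", "toxic_active"),
      true_top = ifelse(top == 1, 1, 1 + (top - 1) * jit_top),
      true_ec50 = vapply(p, `[[`, numeric(1), "ec50") *
        stats::runif(n, 0.8, 1.25),
      true_hill = vapply(p, `[[`, numeric(1), "hill"),
      tox_ic50 = vapply(p, `[[`, numeric(1), "tox_ic50"),
      tox_hill = vapply(p, `[[`, numeric(1), "tox_hill")
    )
  })
  tags <- if (n == 2046) {
    rep(c("CLOUD", "TOCRI1", "TOCRI2"), times = c(263, 1280, 503))
  } else {
    rep("CLOUD", n)
  }
  manifest <- tibble(compound_id = truth$compound_id,
                     name = truth$compound_id, library_tag = tags)
  attr(manifest, "screen_concentration") <- config$screen_conc
  list(manifest = manifest, truth = truth)
}

#' True reporter response and viability of planted compounds
#'
#' @param truth Truth tibble from [generate_truth_library()] (or rows of it).
#' @param conc Concentration in uM (scalar or one per truth row).
#' @return `true_fold_change()`: the noiseless reporter fold change;
#'   `true_viability()`: the noiseless surviving fraction (1 for compounds
#'   without a toxicity midpoint).
#' @export
true_fold_change <- function(truth, conc) {
  1 + (truth$true_top - 1) * conc^truth$true_hill /
    (truth$true_ec50^truth$true_hill + conc^truth$true_hill)
}

#' @rdname true_fold_change
#' @export
true_viability <- function(truth, conc) {
  ifelse(is.na(truth$tox_ic50), 1,
         1 / (1 + (conc / truth$tox_ic50)^truth$tox_hill))
}

#' Planted stage counts of a truth table
#'
#' The counts a perfect pipeline run should recover: every reporter-inducing
#' class (bach1_like, cytotoxic_inducer, toxic_active) is a primary hit at
#' the screening concentration; benchmark-reaching compounds (potent
#' bach1_like and toxic_active) pass efficacy; potent non-toxic bach1_like
#' compounds are the final candidates.
#'
#' @param truth Truth tibble from [generate_truth_library()].
#' @return Named integer vector `screened`, `primary_hits`, `efficacy_pass`,
#'   `final_candidates`.
#' @export
planted_counts <- function(truth) {
  c(screened = nrow(truth),
    primary_hits = sum(truth$class %in%
                         c("bach1_like", "cytotoxic_inducer", "toxic_active")),
    efficacy_pass = sum(truth$potent),
    final_candidates = sum(truth$potent & truth$class == "bach1_like"))
}

#' Simulate the primary screen
#'
#' Places the library at random (different wells per replicate) and draws
#' raw luminescence for every well: an additive media background, a
#' per-plate multiplicative scale effect, and log-normal well noise on the
#' signal. Control wells draw their fold change from the configured normal
#' control distributions; test wells respond at their true fold change at
#' the screening concentration. The reporter is read before substantial
#' cell loss occurs, so by default toxicity does not attenuate the screen
#' signal; set `acute_tox_attenuation = TRUE` to multiply toxic compounds'
#' signal by their end-point viability at the screening concentration.
#'
#' @param truth Truth tibble from [generate_truth_library()].
#' @param config A [generator_config()].
#' @param layout A [screen_layout()].
#' @param n_replicates Number of independent replicates (default 2).
#' @param acute_tox_attenuation Attenuate reporter signal by end-point
#'   viability (default `FALSE`; see Details).
#' @return A tibble of well records with `raw_lum` drawn; feed to
#'   [blank_correct()].
#' @export
simulate_screen <- function(truth, config = generator_config(),
                            layout = screen_layout(), n_replicates = 2L,
                            acute_tox_attenuation = FALSE) {
  manifest <- tibble(compound_id = truth$compound_id,
                     name = truth$compound_id,
                     library_tag = "SIM")
  attr(manifest, "screen_concentration") <- config$screen_conc
  wells <- assign_layout(manifest, layout, n_replicates = n_replicates,
                         seed = config$seed)
  fc_true <- setNames(true_fold_change(truth, config$screen_conc),
                      truth$compound_id)
  if (acute_tox_attenuation) {
    fc_true <- fc_true * setNames(true_viability(truth, config$screen_conc),
                                  truth$compound_id)
  }
  sdlog <- sqrt(log(1 + config$well_cv^2))
  withr::with_seed(config$seed + 101L, {
    pe <- wells |>
      dplyr::distinct(plate_id, replicate) |>
      dplyr::mutate(plate_effect = rlnorm(dplyr::n(), 0, config$plate_effect_sd))
    wells <- dplyr::left_join(wells, pe, by = c("plate_id", "replicate"))
    n <- nrow(wells)
    bg <- config$blank_mean * rlnorm(n, -sdlog^2 / 2, sdlog)
    scale <- config$dmso_mean_lum * wells$plate_effect
    fc_well <- numeric(n)
    is <- wells$role == "dmso"
    fc_well[is] <- rlnorm(sum(is), -sdlog^2 / 2, sdlog)
    is <- wells$role == "hemin"
    fc_well[is] <- pmax(rnorm(sum(is), config$hemin_fc_mean,
                              config$hemin_fc_sd), 0.05)
    is <- wells$role == "cddo"
    fc_well[is] <- pmax(rnorm(sum(is), config$cddo_fc_mean,
                              config$cddo_fc_sd), 0.05)
    is <- wells$role == "test"
    fc_well[is] <- fc_true[wells$compound_id[is]] *
      rlnorm(sum(is), -sdlog^2 / 2, sdlog)
    wells$raw_lum <- bg + ifelse(wells$role %in% c("blank", "empty"),
                                 0, scale * fc_well)
    wells$raw_lum[wells$role == "empty"] <- NA_real_
  })
  dplyr::select(wells, -plate_effect)
}

#' Default follow-up concentration grid
#'
#' Eight log-spaced concentrations spanning 0.01-30 uM.
#' @return Numeric vector of concentrations in uM.
#' @export
default_conc_grid <- function() c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30)

#' Simulate follow-up dose-response measurements
#'
#' Reporter fold change at each concentration is the compound's true Hill
#' response times log-normal noise; deterministic for a fixed seed.
#'
#' @param truth Truth tibble (or subset of rows) to simulate.
#' @param compounds Optional character vector restricting to some compounds.
#' @param grid Concentration grid in uM (default [default_conc_grid()]).
#' @param n_rep Replicates per concentration (default 3).
#' @param cv Log-normal CV (default from `config` would be 0.05).
#' @param seed Integer seed.
#' @return Long tibble: `compound_id`, `concentration_um`, `replicate`, `fc`.
#' @export
simulate_dose_response <- function(truth, compounds = NULL,
                                   grid = default_conc_grid(), n_rep = 3L,
                                   cv = 0.05, seed = 1L) {
  stopifnot(length(grid) > 0)
  if (!is.null(compounds)) {
    truth <- dplyr::filter(truth, compound_id %in% compounds)
  }
  d <- tidyr::expand_grid(compound_id = truth$compound_id,
                          concentration_um = grid,
                          replicate = seq_len(n_rep))
  d <- dplyr::left_join(
    d, dplyr::select(truth, compound_id, true_top, true_ec50, true_hill),
    by = "compound_id")
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed + 211L, {
    d$fc <- true_fold_change(d, d$concentration_um) *
      rlnorm(nrow(d), -sdlog^2 / 2, sdlog)
  })
  dplyr::select(d, compound_id, concentration_um, replicate, fc)
}

#' Simulate viability counter-screen measurements
#'
#' Viability at each concentration is the compound's true surviving
#' fraction (a descending Hill with midpoint `tox_ic50`; 1 for clean
#' compounds) times log-normal noise.
#'
#' @inheritParams simulate_dose_response
#' @param grid Concentration grid in uM (default 0.1-30).
#' @return Long tibble: `compound_id`, `concentration_um`, `replicate`,
#'   `viability`.
#' @export
simulate_viability <- function(truth, compounds = NULL,
                               grid = c(0.1, 0.3, 1, 3, 10, 30),
                               n_rep = 3L, cv = 0.03, seed = 1L) {
  stopifnot(length(grid) > 0)
  if (!is.null(compounds)) {
    truth <- dplyr::filter(truth, compound_id %in% compounds)
  }
  d <- tidyr::expand_grid(compound_id = truth$compound_id,
                          concentration_um = grid,
                          replicate = seq_len(n_rep))
  d <- dplyr::left_join(
    d, dplyr::select(truth, compound_id, tox_ic50, tox_hill),
    by = "compound_id")
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed + 307L, {
    d$viability <- true_viability(d, d$concentration_um) *
      rlnorm(nrow(d), -sdlog^2 / 2, sdlog)
  })
  dplyr::select(d, compound_id, concentration_um, replicate, viability)
}

#' Simulate a qPCR Ct table for signature testing
#'
#' Given per-condition true fold changes of target genes, draws Ct values
#' with the housekeeping gene flat across conditions: a gene induced
#' f-fold under treatment has its Ct lowered by log2(f) cycles relative to
#' the control condition.
#'
#' @param fc_by_condition Named list: condition -> named numeric vector of
#'   true fold changes per gene.
#' @param housekeeping Housekeeping gene name (default `"HPRT1"`).
#' @param base_ct Control-condition Ct of every target gene (default 25).
#' @param hk_ct Housekeeping Ct (default 18).
#' @param n_rep Technical replicates (default 3).
#' @param noise_sd Ct noise SD in cycles (default 0.1).
#' @param seed Integer seed.
#' @return Long Ct tibble: `sample_id`, `condition`, `gene`, `replicate`,
#'   `ct` (control condition named `"DMSO"`).
#' @export
simulate_ct <- function(fc_by_condition, housekeeping = "HPRT1",
                        base_ct = 25, hk_ct = 18, n_rep = 3L,
                        noise_sd = 0.1, seed = 1L) {
  genes <- unique(unlist(purrr::map(fc_by_condition, names)))
  conds <- c("DMSO", names(fc_by_condition))
  grid <- tidyr::expand_grid(condition = conds,
                             gene = c(genes, housekeeping),
                             replicate = seq_len(n_rep))
  withr::with_seed(seed + 401L, {
    grid$ct <- purrr::pmap_dbl(grid, function(condition, gene, replicate) {
      mu <- if (gene == housekeeping) hk_ct
        else if (condition == "DMSO") base_ct
        else base_ct - log2(fc_by_condition[[condition]][[gene]])
      rnorm(1, mu, noise_sd)
    })
  })
  dplyr::mutate(grid, sample_id = condition, .before = 1)
}
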