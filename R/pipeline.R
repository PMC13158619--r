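#' Run the staged selection funnel end-to-end
#'
#' Orchestrates the complete screen analysis: blank correction, per-plate
#' QC (fatal on failure unless `allow_qc_fail`), fold-change normalisation,
#' control-derived thresholds, replicate aggregation and primary-hit
#' calling, concentration-response fitting with the efficacy filter, and
#' the viability gate. By default the inputs are simulated from `config`
#' with planted ground truth; alternatively supply measured tables via
#' `data` (elements `wells` — raw well records covering both replicates —
#' plus `dose` and `viability` long tables for the follow-up assays).
#'
#' @param config A [generator_config()]; drives the simulation and seeds.
#' @param layout A [screen_layout()] used when simulating.
#' @param data Optional list with elements `wells`, `dose`, `viability`
#'   (and optionally `truth`) replacing the simulation.
#' @param thresholds Optional [threshold_set()] pinning the activation
#'   cut-off and benchmark instead of deriving them from control wells.
#' @param rz_min,sb_min Plate QC gates (defaults 0.5 and 5).
#' @param max_conc Efficacy limit in uM (default 10).
#' @param min_viability Viability gate (default 0.70).
#' @param allow_qc_fail Continue past failing plates (default `FALSE`:
#'   any failing plate aborts with its QC report attached).
#' @param quiet Suppress progress messages.
#' @return An object of class `stage_ledger`: stage counts, thresholds, QC
#'   report, per-compound hit table, fits, final candidates, and the truth
#'   table when simulated.
#' @export
run_screen_pipeline <- function(config = generator_config(),
                                layout = screen_layout(),
                                data = NULL, thresholds = NULL,
                                rz_min = 0.5, sb_min = 5, max_conc = 10,
                                min_viability = 0.70,
                                allow_qc_fail = FALSE, quiet = TRUE) {
  truth <- NULL
  if (is.null(data)) {
    lib <- generate_truth_library(config)
    truth <- lib$truth
    wells <- simulate_screen(truth, config, layout)
  } else {
    wells <- data$wells
    truth <- data$truth
  }
  n_screened <- length(unique(wells$compound_id[wells$role == "test"]))

  wells <- blank_correct(wells, quiet = quiet)
  qc <- plate_qc(wells, rz_min = rz_min, sb_min = sb_min)
  if (!all(qc$pass_qc)) {
    failing <- qc[!qc$pass_qc, ]
    if (!allow_qc_fail) {
      cond <- rlang::error_cnd(
        "screenfunnel_qc_failure",
        message = sprintf(
          "%d plate(s) failed QC (first: plate %s rep %d — %s). Use allow_qc_fail = TRUE to continue.",
          nrow(failing), failing$plate_id[1], failing$replicate[1],
          failing$reason[1]),
        qc = qc)
      rlang::cnd_signal(cond)
    }
    if (!quiet) inform(sprintf("Continuing past %d failing plate(s).",
                               nrow(failing)))
  }

  fc <- fold_change_normalise(wells)
  if (is.null(thresholds)) thresholds <- derive_thresholds(fc)

  fc1 <- dplyr::filter(fc, replicate == 1L)
  fc2 <- dplyr::filter(fc, replicate == 2L)
  hit_rows <- aggregate_replicates(fc1, fc2)
  hits <- call_primary_hits(hit_rows, thresholds)
  hit_ids <- hits$compound_id[hits$is_hit]

  fits <- NULL; candidates <- NULL
  n_eff <- 0L; n_final <- 0L
  if (length(hit_ids) > 0) {
    dose <- if (is.null(data)) {
      simulate_dose_response(truth, compounds = hit_ids,
                             cv = config$dr_cv, seed = config$seed)
    } else {
      if (is.null(data$dose)) abort("`data$dose` is required: the screen produced primary hits.")
      dplyr::filter(data$dose, compound_id %in% hit_ids)
    }
    missing_dose <- setdiff(hit_ids, unique(dose$compound_id))
    if (length(missing_dose)) {
      abort(sprintf("No dose-response data for hit(s): %s",
                    paste(head(missing_dose, 10), collapse = ", ")))
    }
    fits <- fit_hill_all(dose) |>
      efficacy_filter(benchmark = thresholds$benchmark, max_conc = max_conc)
    eff_ids <- fits$compound_id[fits$pass_efficacy]
    n_eff <- length(eff_ids)

    if (n_eff > 0) {
      viab <- if (is.null(data)) {
        simulate_viability(truth, compounds = eff_ids,
                           cv = config$viability_cv, seed = config$seed)
      } else {
        if (is.null(data$viability)) abort("`data$viability` is required: compounds passed the efficacy filter.")
        data$viability
      }
      candidates <- fits |>
        dplyr::filter(pass_efficacy) |>
        dplyr::select(compound_id, mec) |>
        toxicity_filter(viab, min_viability = min_viability)
      n_final <- sum(candidates$final_pass)
    }
  }

  structure(
    list(
      counts = c(screened = n_screened,
                 primary_hits = length(hit_ids),
                 efficacy_pass = n_eff,
                 final_candidates = n_final),
      thresholds = thresholds, qc = qc, hits = hits, fits = fits,
      candidates = candidates, truth = truth,
      settings = list(rz_min = rz_min, sb_min = sb_min,
                      max_conc = max_conc, min_viability = min_viability)
    ),
    class = "stage_ledger")
}

#' Human-readable funnel summary
#'
#' Formats a [run_screen_pipeline()] ledger as text: the four funnel
#' stages with their thresholds and provenance, and per-plate QC
#' statistics.
#'
#' @param ledger A `stage_ledger`.
#' @return Character vector of report lines, invisibly printed by
#'   `print.stage_ledger()`.
#' @export
stage_report <- function(ledger) {
  stopifnot(inherits(ledger, "stage_ledger"))
  n <- ledger$counts
  if (n[["screened"]] == 0) return("no compounds screened")
  th <- ledger$thresholds
  s <- ledger$settings
  lines <- c(
    sprintf("screened:          %d compounds", n[["screened"]]),
    sprintf("primary hits:      %d (mean FC > %.3f, CDDO-derived)",
            n[["primary_hits"]], th$activator_cutoff),
    sprintf("efficacy pass:     %d (reach %.3f-fold at <= %g uM)",
            n[["efficacy_pass"]], th$benchmark, s$max_conc),
    sprintf("final candidates:  %d (viability >= %.0f%% at effective conc.)",
            n[["final_candidates"]], 100 * s$min_viability),
    sprintf("thresholds:        %s", th$provenance),
    "plate QC (rZ' / SB):")
  qc_lines <- sprintf("  %s rep %d: rZ' = %.3f, SB = %.2f [%s]",
                      ledger$qc$plate_id, ledger$qc$replicate,
                      ledger$qc$rz_prime, ledger$qc$sb,
                      ifelse(ledger$qc$pass_qc, "pass", "FAIL"))
  c(lines, qc_lines)
}

#' @export
print.stage_ledger <- function(x, ...) {
  cat(stage_report(x), sep = "\n")
  invisible(x)
}

#' Serialise a stage ledger to JSON
#'
#' @param ledger A `stage_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_ledger <- function(ledger, path) {
  out <- list(
    counts = as.list(ledger$counts),
    thresholds = list(
      activator_cutoff = ledger$thresholds$activator_cutoff,
      benchmark = ledger$thresholds$benchmark,
      provenance = ledger$thresholds$provenance),
    settings = ledger$settings,
    qc = ledger$qc[, c("plate_id", "replicate", "rz_prime", "sb", "pass_qc")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
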