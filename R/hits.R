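#' Control-derived activation thresholds
#'
#' The primary-hit cut-off is anchored to the non-specific NRF2-activator
#' control (CDDO): its arithmetic mean fold change across all control wells
#' of the screen. The efficacy benchmark is anchored to the reference
#' BACH1-inhibitor control (hemin): the lower edge of its fold-change
#' distribution at `k` standard deviations below the mean (sample SD). With
#' the default control behaviour these land near 2.5 and 7.8 respectively.
#'
#' @param cddo_fc Numeric vector of CDDO-well fold changes (>= 2 values).
#' @return `derive_activator_cutoff()`: the mean CDDO fold change.
#' @examples
#' derive_activator_cutoff(c(2.0, 3.0))
#' derive_benchmark(c(10, 12, 14))
#' @export
derive_activator_cutoff <- function(cddo_fc) {
  cddo_fc <- cddo_fc[!is.na(cddo_fc)]
  if (length(cddo_fc) < 2) abort("Need >= 2 CDDO fold changes.")
  mean(cddo_fc)
}

#' @param hemin_fc Numeric vector of hemin-well fold changes (>= 2 values).
#' @param k Number of standard deviations from the mean (default 3).
#' @param direction `"lower"` (default) takes `mean - k*sd`; `"upper"`
#'   takes `mean + k*sd`.
#' @return `derive_benchmark()`: the hemin-derived efficacy benchmark.
#' @rdname derive_activator_cutoff
#' @export
derive_benchmark <- function(hemin_fc, k = 3, direction = c("lower", "upper")) {
  direction <- match.arg(direction)
  hemin_fc <- hemin_fc[!is.na(hemin_fc)]
  if (length(hemin_fc) < 2) abort("Need >= 2 hemin fold changes.")
  s <- sd(hemin_fc)
  if (direction == "lower") mean(hemin_fc) - k * s else mean(hemin_fc) + k * s
}

#' Derive both thresholds from a screen's control wells
#'
#' Pools the CDDO and hemin fold changes across all plates and replicates of
#' a fold-change table and applies [derive_activator_cutoff()] and
#' [derive_benchmark()].
#'
#' @param fc A fold-change tibble from [fold_change_normalise()] (both
#'   replicates bound together).
#' @inheritParams derive_activator_cutoff
#' @inheritParams derive_benchmark
#' @return A list of class `threshold_set` with elements `activator_cutoff`,
#'   `benchmark`, `provenance`.
#' @export
derive_thresholds <- function(fc, k = 3, direction = "lower") {
  cutoff <- derive_activator_cutoff(fc$fold_change[fc$role == "cddo"])
  bench <- derive_benchmark(fc$fold_change[fc$role == "hemin"],
                            k = k, direction = direction)
  threshold_set(
    cutoff, bench,
    provenance = sprintf(
      "activator_cutoff = mean(CDDO FC) over %d wells; benchmark = mean %s %g*sd(hemin FC) over %d wells",
      sum(fc$role == "cddo"), if (direction == "lower") "-" else "+", k,
      sum(fc$role == "hemin")))
}

#' @param activator_cutoff Fold-change cut-off for primary hits.
#' @param benchmark Fold-change efficacy benchmark.
#' @param provenance Free-text description of how the values were obtained.
#' @rdname derive_thresholds
#' @export
threshold_set <- function(activator_cutoff, benchmark,
                          provenance = "user-specified") {
  if (!(benchmark > activator_cutoff && activator_cutoff > 1)) {
    warn(sprintf(
      "Expected benchmark > activator_cutoff > 1; got %.3g and %.3g.",
      benchmark, activator_cutoff))
  }
  structure(list(activator_cutoff = activator_cutoff, benchmark = benchmark,
                 provenance = provenance),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> activator_cutoff = %.3f, benchmark = %.3f\n  %s\n",
              x$activator_cutoff, x$benchmark, x$provenance))
  invisible(x)
}

#' Aggregate per-compound fold changes across the two screen replicates
#'
#' Each compound occupies one (randomly placed) well per replicate; the
#' per-compound screen fold change is the arithmetic mean of the two
#' plate-normalised values (geometric mean optional, since fold changes are
#' ratio-scaled).
#'
#' @param fc_rep1,fc_rep2 Fold-change tibbles for the two replicates; the
#'   same compound set must appear in both.
#' @param method `"arithmetic"` (default) or `"geometric"` mean.
#' @return A tibble with columns `compound_id`, `fc_rep1`, `fc_rep2`,
#'   `mean_fc`.
#' @export
aggregate_replicates <- function(fc_rep1, fc_rep2,
                                 method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  one <- function(fc, col) {
    fc |>
      dplyr::filter(role == "test", !is.na(compound_id)) |>
      dplyr::select(compound_id, !!col := fold_change)
  }
  a <- one(fc_rep1, "fc_rep1")
  b <- one(fc_rep2, "fc_rep2")
  orphans <- c(setdiff(a$compound_id, b$compound_id),
               setdiff(b$compound_id, a$compound_id))
  if (length(orphans)) {
    abort(sprintf("Compound(s) present in only one replicate: %s",
                  paste(head(sort(orphans), 10), collapse = ", ")))
  }
  dplyr::inner_join(a, b, by = "compound_id") |>
    dplyr::mutate(mean_fc = if (method == "arithmetic") (fc_rep1 + fc_rep2) / 2
                  else sqrt(fc_rep1 * fc_rep2))
}

#' Replicate concordance of screen fold changes
#'
#' Pearson correlation between the two replicates' per-compound fold
#' changes, computed on the log2 scale because fold changes are
#' ratio-scaled. Pairs with a non-positive fold change in either replicate
#' (possible after blank correction of a dead well) are dropped with a
#' message.
#'
#' @inheritParams aggregate_replicates
#' @param log2_scale Correlate log2 fold changes (default) or raw values.
#' @return The Pearson correlation coefficient.
#' @export
replicate_concordance <- function(fc_rep1, fc_rep2, log2_scale = TRUE) {
  pairs <- aggregate_replicates(fc_rep1, fc_rep2)
  if (nrow(pairs) < 3) abort("Need >= 3 shared compounds.")
  x <- pairs$fc_rep1; y <- pairs$fc_rep2
  if (log2_scale) {
    ok <- x > 0 & y > 0
    if (!all(ok)) {
      inform(sprintf("replicate_concordance: dropped %d non-positive pair(s) before log transform.",
                     sum(!ok)))
    }
    x <- log2(x[ok]); y <- log2(y[ok])
    if (length(x) < 3) abort("Fewer than 3 positive pairs remain.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in a replicate; correlation undefined.")
  }
  cor(x, y, method = "pearson")
}

#' Call primary hits
#'
#' A compound is a primary hit when its mean fold change across the two
#' replicates is strictly greater than the activator cut-off.
#'
#' @param hit_rows Tibble from [aggregate_replicates()].
#' @param thresholds A [threshold_set()].
#' @return `hit_rows` with a logical `is_hit` column.
#' @export
call_primary_hits <- function(hit_rows, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  dplyr::mutate(hit_rows, is_hit = mean_fc > thresholds$activator_cutoff)
}
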