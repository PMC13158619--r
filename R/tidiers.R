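#' Tidy a Hill fit
#'
#' @param x A [fit_hill()] object.
#' @param ... Unused.
#' @return One row per parameter with columns `term` and `estimate`.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("bottom", "top", "ec50", "hill"),
         estimate = c(x$bottom, x$top, x$ec50, x$hill))
}

#' One-row summary of a Hill fit
#'
#' @param x A [fit_hill()] object.
#' @param ... Unused.
#' @return A one-row tibble with fit diagnostics: residual sum of squares,
#'   residual standard error, number of averaged points, method and flags.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  n <- nrow(x$points)
  tibble(rss = x$rss,
         sigma = if (!is.na(x$rss) && n > 4) sqrt(x$rss / (n - 4)) else NA_real_,
         nobs = n, method = x$method,
         degenerate = x$degenerate, unreliable = x$unreliable)
}

#' Tidy a stage ledger
#'
#' @param x A `stage_ledger` from [run_screen_pipeline()].
#' @param ... Unused.
#' @return A tibble with one row per funnel stage (`stage`, `count`).
#' @method tidy stage_ledger
#' @export
tidy.stage_ledger <- function(x, ...) {
  tibble(stage = factor(names(x$counts), levels = names(x$counts)),
         count = unname(x$counts))
}

#' One-row summary of a stage ledger
#'
#' @param x A `stage_ledger`.
#' @param ... Unused.
#' @return A one-row tibble: stage counts, thresholds, QC extremes.
#' @method glance stage_ledger
#' @export
glance.stage_ledger <- function(x, ...) {
  tibble(screened = x$counts[["screened"]],
         primary_hits = x$counts[["primary_hits"]],
         efficacy_pass = x$counts[["efficacy_pass"]],
         final_candidates = x$counts[["final_candidates"]],
         activator_cutoff = x$thresholds$activator_cutoff,
         benchmark = x$thresholds$benchmark,
         min_rz_prime = min(x$qc$rz_prime),
         min_sb = min(x$qc$sb),
         all_plates_pass_qc = all(x$qc$pass_qc))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
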