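#' Plot a fitted concentration-response curve
#'
#' Averaged dose-response points with the fitted 4PL curve on a log10
#' concentration axis; an optional horizontal line marks the efficacy
#' benchmark.
#'
#' @param object A [fit_hill()] object.
#' @param benchmark Optional fold-change benchmark to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, benchmark = NULL, ...) {
  pts <- object$points
  grid <- 10^seq(log10(object$conc_range[1]), log10(object$conc_range[2]),
                 length.out = 200)
  curve <- tibble(
    concentration_um = grid,
    fc = if (object$method == "hill")
      hill_response(grid, object$bottom, object$top, object$ec50, object$hill)
    else approx(log10(pts$concentration_um), pts$fc, xout = log10(grid))$y)
  p <- ggplot2::ggplot(pts, ggplot2::aes(concentration_um, fc)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)", y = "fold change (vs DMSO)")
  if (!is.null(benchmark)) {
    p <- p + ggplot2::geom_hline(yintercept = benchmark, linetype = "dashed")
  }
  p
}

#' Plot the selection funnel
#'
#' Bar chart of the four stage counts of a pipeline run.
#'
#' @param object A `stage_ledger` from [run_screen_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stage_ledger
#' @export
autoplot.stage_ledger <- function(object, ...) {
  d <- tidy.stage_ledger(object)
  ggplot2::ggplot(d, ggplot2::aes(stage, count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "compounds")
}

#' Control fold-change distributions
#'
#' Density of plate-normalised fold changes by well role, the visual check
#' that DMSO, CDDO and hemin wells separate cleanly.
#'
#' @param fc A fold-change tibble from [fold_change_normalise()].
#' @param roles Roles to include.
#' @return A ggplot object.
#' @export
plot_control_distributions <- function(fc, roles = c("dmso", "cddo", "hemin")) {
  d <- dplyr::filter(fc, role %in% roles)
  ggplot2::ggplot(d, ggplot2::aes(fold_change, fill = role)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "fold change (vs DMSO median)", y = "density")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
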