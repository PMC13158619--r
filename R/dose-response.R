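#' Four-parameter logistic (Hill) response
#'
#' `hill_response()` evaluates
#' `FC(c) = bottom + (top - bottom) * c^h / (ec50^h + c^h)` — the standard
#' 4PL concentration-response curve with Hill coefficient `h`.
#'
#' @param conc Concentrations in uM (> 0).
#' @param bottom,top Lower/upper fold-change asymptotes.
#' @param ec50 Half-maximal concentration in uM.
#' @param hill Hill coefficient (> 0).
#' @return Fold change at each concentration.
#' @export
hill_response <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) * conc^hill / (ec50^hill + conc^hill)
}

#' Fit a concentration-response curve
#'
#' Bounded least-squares fit of the 4PL curve on log10 concentration, with a
#' deterministic multi-start grid (Hill coefficient in {0.5, 1, 2} crossed
#' with three EC50 starting points spanning the tested range). Replicate
#' measurements at the same concentration are averaged before fitting. If
#' no start converges, the fit degrades to monotone linear interpolation on
#' log10 concentration, which still supports a minimal-effective-
#' concentration decision.
#'
#' @param data Data frame with columns `concentration_um` and `fc`
#'   (optionally `replicate`); at least 4 distinct concentrations, all > 0.
#' @return An object of class `hill_fit`: parameters `bottom`, `top`,
#'   `ec50`, `hill`, residual sum of squares `rss`, the averaged points,
#'   and flags `method` ("hill" or "interpolation"), `degenerate`,
#'   `unreliable` (EC50 outside `[min(conc)/10, max(conc)*10]`).
#' @examples
#' d <- data.frame(concentration_um = c(0.01, 0.1, 1, 3, 10, 30),
#'                 fc = hill_response(c(0.01, 0.1, 1, 3, 10, 30), 1, 15, 2, 1))
#' fit_hill(d)
#' @export
fit_hill <- function(data) {
  pts <- data |>
    dplyr::group_by(concentration_um) |>
    dplyr::summarise(fc = mean(fc), .groups = "drop") |>
    dplyr::arrange(concentration_um)
  if (nrow(pts) < 4) abort("Need >= 4 distinct concentrations.")
  if (any(pts$concentration_um <= 0)) abort("Concentrations must be > 0.")
  conc <- pts$concentration_um
  y <- pts$fc
  span <- diff(range(y))

  if (span == 0) {
    fit <- new_hill_fit(bottom = y[1], top = y[1],
                        ec50 = exp(mean(log(range(conc)))), hill = 1,
                        rss = 0, points = pts, method = "hill",
                        degenerate = TRUE)
    return(fit)
  }

  lc <- log10(conc)
  obj <- function(p) {
    pred <- hill_response(conc, p[1], p[2], 10^p[3], p[4])
    sum((y - pred)^2)
  }
  lower <- c(min(y) - span, min(y) - span, min(lc) - 1, 0.1)
  upper <- c(max(y) + span, max(y) + span, max(lc) + 1, 10)
  starts <- expand.grid(
    h = c(0.5, 1, 2),
    l50 = stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(min(y), max(y), starts$l50[i], starts$h[i])
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    # interpolation fallback: keeps every compound decidable
    return(new_hill_fit(bottom = min(y), top = max(y), ec50 = NA_real_,
                        hill = NA_real_, rss = NA_real_, points = pts,
                        method = "interpolation"))
  }
  p <- best$par
  if (p[1] > p[2]) p <- p[c(2, 1, 3, 4)]  # enforce bottom <= top
  ec50 <- 10^p[3]
  new_hill_fit(
    bottom = p[1], top = p[2], ec50 = ec50, hill = p[4],
    rss = best$value, points = pts, method = "hill",
    unreliable = ec50 < min(conc) / 10 || ec50 > max(conc) * 10
  )
}

new_hill_fit <- function(bottom, top, ec50, hill, rss, points, method,
                         degenerate = FALSE, unreliable = FALSE) {
  structure(
    list(bottom = bottom, top = top, ec50 = ec50, hill = hill, rss = rss,
         points = points, conc_range = range(points$concentration_um),
         method = method, degenerate = degenerate, unreliable = unreliable),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit (%s)> bottom %.3g, top %.3g, ec50 %.3g uM, hill %.3g, rss %.3g%s\n",
    x$method, x$bottom, x$top, x$ec50, x$hill, x$rss,
    if (x$degenerate) " [degenerate]" else if (x$unreliable) " [unreliable]"
    else ""))
  invisible(x)
}

#' Minimal effective concentration
#'
#' Smallest concentration at which the fitted response reaches the efficacy
#' benchmark. For a Hill fit this is the analytic inversion
#' `c = ec50 * ((b - bottom) / (top - b))^(1/hill)`, clamped to the tested
#' concentration range; for an interpolation fallback it is the first
#' crossing of the piecewise-linear curve on log10 concentration. `NA` means
#' the response never reaches the benchmark (`top < benchmark`); if the
#' benchmark is at or below the bottom asymptote the smallest tested
#' concentration is returned.
#'
#' @param fit A [fit_hill()] object.
#' @param benchmark Fold-change benchmark (e.g. the hemin-derived value).
#' @return Concentration in uM, or `NA_real_` if unreachable.
#' @examples
#' d <- data.frame(concentration_um = c(0.01, 0.1, 1, 3, 10, 30),
#'                 fc = hill_response(c(0.01, 0.1, 1, 3, 10, 30), 1, 15, 2, 1))
#' min_effective_concentration(fit_hill(d), 7.8)  # ~1.889 uM
#' @export
min_effective_concentration <- function(fit, benchmark) {
  stopifnot(inherits(fit, "hill_fit"))
  lo <- fit$conc_range[1]; hi <- fit$conc_range[2]
  if (fit$method == "interpolation") {
    return(mec_from_points(fit$points, benchmark))
  }
  if (benchmark <= fit$bottom) return(lo)
  if (fit$top < benchmark || fit$top == fit$bottom) return(NA_real_)
  if (fit$top == benchmark) return(NA_real_)  # asymptote only reached at c = Inf
  c_star <- fit$ec50 *
    ((benchmark - fit$bottom) / (fit$top - benchmark))^(1 / fit$hill)
  min(max(c_star, lo), hi)
}

mec_from_points <- function(points, benchmark) {
  conc <- points$concentration_um
  y <- points$fc
  if (y[1] >= benchmark) return(conc[1])
  above <- which(y >= benchmark)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  # linear crossing on log10 concentration between points i-1 and i
  f <- (benchmark - y[i - 1]) / (y[i] - y[i - 1])
  10^(log10(conc[i - 1]) + f * (log10(conc[i]) - log10(conc[i - 1])))
}

#' Fit curves and apply the efficacy filter over a cohort
#'
#' `fit_hill_all()` fits every compound in a long dose-response table.
#' `efficacy_filter()` computes each compound's minimal effective
#' concentration at the benchmark and keeps those reaching it at or below
#' `max_conc` (compounds needing more, or never reaching it, fail).
#'
#' @param data Long dose-response table: `compound_id`, `concentration_um`,
#'   optionally `replicate`, `fc`.
#' @return `fit_hill_all()`: tibble with per-compound parameters and a
#'   `fit` list-column.
#' @export
fit_hill_all <- function(data) {
  data |>
    dplyr::group_by(compound_id) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_hill(df)
      tibble(bottom = f$bottom, top = f$top, ec50 = f$ec50, hill = f$hill,
             rss = f$rss, method = f$method, fit = list(f))
    }) |>
    dplyr::ungroup()
}

#' @param fits Tibble from [fit_hill_all()].
#' @param benchmark Fold-change efficacy benchmark.
#' @param max_conc Maximum acceptable effective concentration in uM
#'   (default 10); `mec == max_conc` passes — only compounds needing *more*
#'   are removed.
#' @return `efficacy_filter()`: `fits` with `mec` and `pass_efficacy`
#'   columns (the `fit` list-column dropped).
#' @rdname fit_hill_all
#' @export
efficacy_filter <- function(fits, benchmark, max_conc = 10) {
  fits |>
    dplyr::mutate(
      mec = purrr::map_dbl(fit, min_effective_concentration,
                           benchmark = benchmark),
      pass_efficacy = !is.na(mec) & mec <= max_conc
    ) |>
    dplyr::select(-fit)
}
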