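#' Geometric mean
#'
#' Helper for collapsing per-event fluorescence to a per-well summary.
#'
#' @param x positive values.
#' @return The geometric mean of `x`.
#' @export
geomean <- function(x) {
  if (any(x <= 0)) sr_error("screenrank_invalid_argument",
                            "geometric mean requires positive values")
  exp(mean(log(x)))
}

#' Vehicle-normalized reporter stability
#'
#' Each well's eGFP geometric mean is normalized to its mCherry geometric
#' mean, and drug-treated wells are compared to the vehicle (DMSO) controls:
#' the returned value is `(gfp/mcherry) / mean(vehicle gfp/mcherry)`, i.e.
#' the fraction of reporter remaining relative to vehicle.
#'
#' @param wells data frame with columns `gfp_geomean` and `mcherry_geomean`
#'   (and typically `condition`, `concentration`, `replicate`).
#' @param vehicle logical vector marking vehicle wells, or `NULL` to use
#'   `wells$concentration == 0`.
#' @return `wells` with a `stability` column (fraction of vehicle).
#' @export
reporter_ratio <- function(wells, vehicle = NULL) {
  if (any(wells$gfp_geomean <= 0) || any(wells$mcherry_geomean <= 0)) {
    sr_error("screenrank_invalid_argument",
             "geometric means must be positive")
  }
  if (is.null(vehicle)) {
    if (is.null(wells$concentration)) {
      sr_error("screenrank_invalid_argument",
               "no vehicle flag and no concentration column")
    }
    vehicle <- wells$concentration == 0
  }
  if (!any(vehicle)) {
    sr_error("screenrank_invalid_argument", "at least one vehicle well needed")
  }
  ratio <- wells$gfp_geomean / wells$mcherry_geomean
  wells$stability <- ratio / mean(ratio[vehicle])
  wells
}

#' LOESS display curve on log10 concentration
#'
#' Local-linear smoothing with the tricube kernel, used for dose-dependent
#' degradation and TR-FRET display curves. The fit is computed on log10
#' concentration and evaluated both at the input doses and on a dense
#' display grid.
#'
#' @param concentrations positive doses (molar); at least 5 distinct values.
#' @param responses responses at those doses.
#' @param span smoothing span in (0, 1]; default 0.75.
#' @param n_grid size of the dense display grid; default 200.
#' @return List with `fitted` (at the input doses), `grid` (data frame of
#'   `concentration`, `fitted` on the display grid), and `span`.
#' @export
fit_loess <- function(concentrations, responses, span = 0.75, n_grid = 200) {
  if (span <= 0 || span > 1) {
    sr_error("screenrank_invalid_argument", "span must be in (0, 1]")
  }
  if (any(concentrations <= 0)) {
    sr_error("screenrank_invalid_argument",
             "LOESS smoothing runs on log10 concentration; doses must be > 0")
  }
  if (length(unique(concentrations)) < 5) {
    sr_error("screenrank_invalid_argument",
             "need at least 5 distinct concentrations")
  }
  lx <- log10(concentrations)
  fit <- stats::loess(responses ~ lx, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  gx <- seq(min(lx), max(lx), length.out = n_grid)
  list(
    fitted = unname(stats::predict(fit, data.frame(lx = lx))),
    grid = data.frame(concentration = 10^gx,
                      fitted = unname(stats::predict(fit, data.frame(lx = gx)))),
    span = span
  )
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = d + (a - d) / (1 + (x/c)^b)` (see
#' [fourpl()]) by bounded Levenberg-Marquardt from four quantile-based
#' starts, with the inflection parameter on the log scale; 4PL residual
#' surfaces are multimodal on sparse grids, so the best of the converged
#' starts is kept. Derived quantities: `dc50 = c` (the concentration of
#' half-maximal response, since `f(c) = (a + d)/2`) and
#' `dmax = (1 - d/a) * 100`, the maximal depth of degradation in percent;
#' an empirical alternative `dmax_empirical = (1 - min(response)) * 100` is
#' carried alongside. Vehicle wells (`concentration == 0`) are excluded from
#' the fit. Flat data (response range below `flat_tol`) return
#' `converged = FALSE` with `dc50 = NA` rather than an error.
#'
#' @param concentrations doses (molar); at least 4 distinct nonzero values.
#' @param responses responses (typically vehicle-normalized stability).
#' @param flat_tol minimum response range considered fittable; default 1e-6.
#' @return A `fourpl` object with fields `coefficients` (`a`, `b`, `c`,
#'   `d`), `dc50`, `dmax`, `dmax_empirical`, `converged`, `residual`.
#' @examples
#' dr <- simulate_dose_response(1, 1.2, 1e-9, 0.05,
#'                              10^seq(-11, -7.5, by = 0.5))
#' fit_4pl(dr$concentration, dr$response)
#' @export
fit_4pl <- function(concentrations, responses, flat_tol = 1e-6) {
  keep <- concentrations > 0
  x <- concentrations[keep]
  y <- responses[keep]
  empty <- structure(list(
    coefficients = c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_),
    dc50 = NA_real_, dmax = NA_real_,
    dmax_empirical = (1 - min(responses)) * 100,
    converged = FALSE, residual = NA_real_,
    data = data.frame(concentration = x, response = y)
  ), class = "fourpl")
  if (length(unique(x)) < 4) {
    sr_error("screenrank_invalid_argument",
             "need at least 4 distinct nonzero concentrations")
  }
  if (diff(range(y)) < flat_tol) return(empty)

  lx <- log(x)
  # heuristic starts: asymptotes from the dose extremes, slope sign from the
  # response trend, inflection from log-dose quantiles
  ord <- order(x)
  a0 <- mean(y[ord][seq_len(max(1, length(y) %/% 4))])
  d0 <- mean(rev(y[ord])[seq_len(max(1, length(y) %/% 4))])
  b_sign <- if (a0 >= d0) 1 else -1
  if (a0 == d0) { a0 <- max(y); d0 <- min(y) }
  starts <- expand.grid(
    logc = stats::quantile(lx, c(0.2, 0.4, 0.6, 0.8), names = FALSE),
    b = b_sign * c(0.8, 2)
  )
  yrange <- diff(range(y))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d + (a - d) / (1 + exp(b * (lx - logc))),
        start = list(a = a0, d = d0, b = starts$b[i], logc = starts$logc[i]),
        lower = c(a = min(y) - 2 * yrange, d = min(y) - 2 * yrange,
                  b = -50, logc = min(lx) - 10),
        upper = c(a = max(y) + 2 * yrange, d = max(y) + 2 * yrange,
                  b = 50, logc = max(lx) + 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(empty)
  cf <- stats::coef(best$fit)
  a <- unname(cf["a"]); d <- unname(cf["d"])
  b <- unname(cf["b"]); cc <- exp(unname(cf["logc"]))
  structure(list(
    coefficients = c(a = a, b = b, c = cc, d = d),
    dc50 = cc,
    dmax = if (a > 0) (1 - d / a) * 100 else NA_real_,
    dmax_empirical = (1 - min(responses)) * 100,
    converged = TRUE,
    residual = best$rss,
    data = data.frame(concentration = x, response = y)
  ), class = "fourpl")
}

#' @export
print.fourpl <- function(x, ...) {
  if (!x$converged) {
    cat("fourpl: fit did not converge (flat or degenerate data); DC50 undefined\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("fourpl fit: a = %.4g, b = %.4g, c = %.4g, d = %.4g\n",
              cf["a"], cf["b"], cf["c"], cf["d"]))
  cat(sprintf("DC50 = %.4g M, Dmax = %.1f%% (empirical %.1f%%), RSS = %.3g\n",
              x$dc50, x$dmax, x$dmax_empirical, x$residual))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' Predict 4PL responses at new concentrations
#'
#' @param object a `fourpl` fit.
#' @param newdata numeric concentrations, or a data frame with a
#'   `concentration` column; default the fitted doses.
#' @param ... unused.
#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  if (!object$converged) {
    sr_error("screenrank_invalid_argument", "cannot predict from a non-converged fit")
  }
  x <- if (is.null(newdata)) object$data$concentration
       else if (is.data.frame(newdata)) newdata$concentration
       else newdata
  cf <- object$coefficients
  unname(fourpl(x, cf["a"], cf["b"], cf["c"], cf["d"]))
}

#' @export
residuals.fourpl <- function(object, ...) {
  object$data$response - predict(object)
}

#' Plot a 4PL fit with its data
#'
#' @param x a `fourpl` fit.
#' @param ... passed to [plot()].
#' @export
plot.fourpl <- function(x, ...) {
  d <- x$data
  plot(d$concentration, d$response, log = "x",
       xlab = "concentration (M)", ylab = "response", pch = 16, ...)
  if (x$converged) {
    g <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
                length.out = 200)
    graphics::lines(g, predict(x, g), col = "red3")
    graphics::abline(v = x$dc50, lty = 2, col = "grey50")
  }
  invisible(x)
}

#' Fit dose-response curves for a table of wells
#'
#' Normalizes each condition's wells to the vehicle controls
#' ([reporter_ratio()]), then fits a 4PL curve per condition.
#'
#' @param wells data frame with columns `condition`, `concentration` (molar,
#'   0 for vehicle), `gfp_geomean`, `mcherry_geomean`, `replicate`. Vehicle
#'   wells are shared across conditions if labelled with
#'   `condition == "vehicle"`, otherwise each condition's own
#'   zero-concentration wells are used.
#' @param span LOESS span for the display curve.
#' @return Data frame, one row per condition: the 4PL parameters, `dc50_M`,
#'   `dmax_pct`, `dmax_empirical_pct`, `converged`, `residual`.
#' @export
dose_response_analysis <- function(wells, span = 0.75) {
  conditions <- setdiff(unique(wells$condition), "vehicle")
  shared_vehicle <- wells[wells$condition == "vehicle" | wells$concentration == 0, ]
  out <- lapply(conditions, function(cond) {
    w <- rbind(wells[wells$condition == cond & wells$concentration > 0, ],
               shared_vehicle)
    w <- reporter_ratio(w)
    fit <- fit_4pl(w$concentration, w$stability)
    cf <- fit$coefficients
    data.frame(condition = cond, a = cf["a"], b = cf["b"], c = cf["c"],
               d = cf["d"], dc50_M = fit$dc50, dmax_pct = fit$dmax,
               dmax_empirical_pct = fit$dmax_empirical,
               converged = fit$converged, residual = fit$residual,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Normalized competition-growth trajectories
#'
#' For marker-based competition assays (fraction of BFP+ or RFP+ cells over
#' time): each arm's marker fraction is normalized to its own day-0 value.
#'
#' @param trajectories data frame with columns `arm`, `day`, `fraction`
#'   (in \[0, 1\]).
#' @return `trajectories` with a `normalized` column (fraction relative to
#'   day 0), ordered by arm then day.
#' @export
summarize_competition <- function(trajectories) {
  if (any(trajectories$fraction < 0 | trajectories$fraction > 1)) {
    sr_error("screenrank_invalid_argument", "fractions must lie in [0, 1]")
  }
  out <- lapply(split(trajectories, trajectories$arm), function(tr) {
    tr <- tr[order(tr$day), ]
    f0 <- tr$fraction[tr$day == 0]
    if (length(f0) != 1) {
      sr_error("screenrank_invalid_argument",
               "arm %s lacks a unique day-0 fraction", tr$arm[1])
    }
    tr$normalized <- tr$fraction / f0
    tr
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
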