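#' TR-FRET ratio
#'
#' The time-resolved FRET signal of a data point is the 520 nm (acceptor)
#' over 490 nm (terbium donor) emission ratio; a common gain factor on both
#' channels cancels.
#'
#' @param em520 nonnegative acceptor emission.
#' @param em490 positive donor emission.
#' @return `em520 / em490`, vectorized.
#' @export
fret_ratio <- function(em520, em490) {
  if (any(em490 <= 0)) {
    sr_error("screenrank_invalid_argument", "donor emission (490 nm) must be > 0")
  }
  em520 / em490
}

#' Locate the hook peak of a dose-dependent ternary-complex curve
#'
#' Ternary-complex readouts (TR-FRET of a degrader titration) rise, peak and
#' fall again at high compound concentration as binary complexes saturate
#' (the hook effect). This finds the concentration of the maximal
#' LOESS-smoothed signal; when the maximum sits at the last (highest)
#' concentration the curve shows no hook yet and the `no_hook` flag is set.
#' With `smooth = FALSE` (or fewer points than the smoother needs) the raw
#' argmax is used.
#'
#' @param concentrations strictly increasing doses (molar or any consistent
#'   unit); at least 3 points.
#' @param ratios signal at those doses (e.g. [fret_ratio()] values).
#' @param smooth smooth on log10 dose before locating the peak.
#' @param span LOESS span.
#' @param n_grid display-grid size for the smoothed peak search.
#' @return List with `peak_concentration`, `peak_ratio`, `no_hook`.
#' @export
hook_peak <- function(concentrations, ratios, smooth = TRUE, span = 0.75,
                      n_grid = 200) {
  if (length(concentrations) < 3) {
    sr_error("screenrank_invalid_argument", "need at least 3 points")
  }
  if (any(diff(concentrations) <= 0)) {
    sr_error("screenrank_invalid_argument",
             "concentrations must be strictly increasing")
  }
  if (smooth && length(concentrations) >= 5 && all(concentrations > 0)) {
    curve <- fit_loess(concentrations, ratios, span = span, n_grid = n_grid)
    i <- which.max(curve$grid$fitted)
    peak_conc <- curve$grid$concentration[i]
    peak_ratio <- curve$grid$fitted[i]
    no_hook <- i == nrow(curve$grid)
  } else {
    i <- which.max(ratios)
    peak_conc <- concentrations[i]
    peak_ratio <- ratios[i]
    no_hook <- i == length(ratios)
  }
  list(peak_concentration = peak_conc, peak_ratio = peak_ratio,
       no_hook = no_hook)
}

#' Covalent labeling efficiency from peak heights
#'
#' Fraction of protein carrying the covalent adduct, from deconvoluted
#' zero-charge mass-spectrum peak heights:
#' `labeled / (labeled + unlabeled) * 100` percent. Invariant to a common
#' rescaling of both heights.
#'
#' @param labeled peak height of the labeled (adduct-bearing) protein.
#' @param unlabeled peak height of the unlabeled protein.
#' @return Labeling efficiency in percent, in \[0, 100\].
#' @examples
#' labeling_efficiency(50, 50)  # 50 percent
#' @export
labeling_efficiency <- function(labeled, unlabeled) {
  if (labeled < 0 || unlabeled < 0) {
    sr_error("screenrank_invalid_argument", "peak heights must be >= 0")
  }
  if (labeled + unlabeled == 0) {
    sr_error("screenrank_invalid_argument", "both peak heights are zero")
  }
  labeled / (labeled + unlabeled) * 100
}

#' Labeling efficiency from a deconvoluted peak table
#'
#' Identifies the unlabeled and labeled peaks in a table of deconvoluted
#' masses and applies [labeling_efficiency()]. If a `label` column marks
#' peaks as `"unlabeled"`/`"labeled"`, those are used; otherwise the tallest
#' peak is taken as the unlabeled protein and the labeled peak must satisfy
#' `|mass_labeled - mass_unlabeled - adduct_mass| <= tolerance`.
#'
#' @param peaks data frame with columns `mass` (Da), `height`, and optional
#'   `label` (`unlabeled`, `labeled`, `other`).
#' @param adduct_mass expected covalent adduct mass (Da).
#' @param tolerance mass-matching tolerance on deconvoluted masses; default
#'   2 Da.
#' @return List with `efficiency` (percent), `unlabeled_mass`,
#'   `labeled_mass`.
#' @export
labeling_efficiency_from_peaks <- function(peaks, adduct_mass, tolerance = 2) {
  stopifnot(all(c("mass", "height") %in% names(peaks)))
  if (any(peaks$height < 0)) {
    sr_error("screenrank_invalid_argument", "peak heights must be >= 0")
  }
  if (!is.null(peaks$label) && any(peaks$label == "unlabeled")) {
    un <- peaks[peaks$label == "unlabeled", ]
    if (nrow(un) != 1) {
      sr_error("screenrank_invalid_argument",
               "exactly one peak may be labelled 'unlabeled'")
    }
  } else {
    un <- peaks[which.max(peaks$height), ]
  }
  if (!is.null(peaks$label) && any(peaks$label == "labeled")) {
    lab <- peaks[peaks$label == "labeled", ]
    if (nrow(lab) != 1) {
      sr_error("screenrank_invalid_argument",
               "exactly one peak may be labelled 'labeled'")
    }
  } else {
    cand <- peaks[abs(peaks$mass - un$mass - adduct_mass) <= tolerance, ]
    if (nrow(cand) == 0) {
      sr_error("screenrank_missing_peak",
               "no labeled peak within %g Da of %g + %g Da",
               tolerance, un$mass, adduct_mass)
    }
    if (nrow(cand) > 1) {
      sr_error("screenrank_ambiguous_peak",
               "multiple candidate labeled peaks within tolerance: %s",
               paste(sprintf("%.1f Da", cand$mass), collapse = ", "))
    }
    lab <- cand
  }
  list(
    efficiency = labeling_efficiency(lab$height, un$height),
    unlabeled_mass = un$mass,
    labeled_mass = lab$mass
  )
}
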