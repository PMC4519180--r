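# Differential scanning fluorimetry (thermal shift): melt-curve processing
# and Boltzmann-sigmoid Tm estimation.
#
# The dye signal rises as the protein unfolds; the melting temperature Tm
# is the midpoint of the sigmoid between the minimum and maximum
# fluorescence.  Past the fluorescence maximum the signal decays as the
# unfolded protein aggregates, so curves are truncated at their global
# maximum before fitting (standard DSF practice).

#' Create a melt curve
#'
#' @param temperature Strictly increasing temperatures in degrees C, within
#'   20-100.
#' @param fluorescence Dye fluorescence in arbitrary units, same length.
#' @param replicate_id Optional replicate label.
#' @param background_corrected Whether a no-protein control has already been
#'   subtracted.
#' @return List of class `"melt_curve"`.
#' @export
melt_curve <- function(temperature, fluorescence, replicate_id = NA_character_,
                       background_corrected = FALSE) {
  temperature <- as.numeric(temperature); fluorescence <- as.numeric(fluorescence)
  if (length(temperature) != length(fluorescence)) {
    abort_value("temperature and fluorescence must have equal length")
  }
  if (any(diff(temperature) <= 0)) abort_value("temperatures must be strictly increasing")
  if (any(temperature < 20 | temperature > 100)) {
    abort_value("temperatures must lie within [20, 100] degrees C")
  }
  structure(list(temperature = temperature, fluorescence = fluorescence,
                 replicate_id = as.character(replicate_id),
                 background_corrected = isTRUE(background_corrected)),
            class = "melt_curve")
}

#' Subtract a no-protein background curve
#'
#' @param curve,no_protein_control [melt_curve()] objects.  Their
#'   temperature grids must match unless `interpolate = TRUE`, in which case
#'   the control is linearly interpolated onto the curve's grid.
#' @param interpolate Allow interpolation across mismatched grids.
#' @return The background-corrected [melt_curve()].
#' @export
subtract_background <- function(curve, no_protein_control, interpolate = FALSE) {
  stopifnot(inherits(curve, "melt_curve"), inherits(no_protein_control, "melt_curve"))
  same_grid <- length(curve$temperature) == length(no_protein_control$temperature) &&
    all(curve$temperature == no_protein_control$temperature)
  if (!same_grid && !interpolate) {
    abort_grid("temperature grids differ; set interpolate = TRUE to allow interpolation")
  }
  bg <- if (same_grid) no_protein_control$fluorescence
        else stats::approx(no_protein_control$temperature,
                           no_protein_control$fluorescence,
                           xout = curve$temperature, rule = 2)$y
  melt_curve(curve$temperature, curve$fluorescence - bg,
             replicate_id = curve$replicate_id, background_corrected = TRUE)
}

#' Average replicate melt curves
#'
#' Replicates (typically duplicates) are averaged pointwise after
#' background subtraction; all curves must share the temperature grid.
#'
#' @param curves List of [melt_curve()] objects.
#' @return A single averaged [melt_curve()].
#' @export
average_melt_replicates <- function(curves) {
  stopifnot(length(curves) >= 1L)
  t0 <- curves[[1L]]$temperature
  for (cv in curves) {
    if (length(cv$temperature) != length(t0) || any(cv$temperature != t0)) {
      abort_grid("replicate melt curves must share the temperature grid")
    }
  }
  f <- rowMeans(vapply(curves, function(cv) cv$fluorescence,
                       numeric(length(t0))))
  melt_curve(t0, f, replicate_id = "mean",
             background_corrected = all(vapply(curves, function(cv)
               cv$background_corrected, logical(1))))
}

#' Boltzmann sigmoid melt model
#'
#' `F(T) = f_min + (f_max - f_min) / (1 + exp((tm - T) / slope))`; at
#' `T = tm` the value is the midpoint `(f_min + f_max) / 2`.
#'
#' @param temperature Temperatures in degrees C.
#' @param f_min,f_max Lower and upper fluorescence plateaus (AU).
#' @param tm Melting temperature (degrees C).
#' @param slope Transition width (degrees C).
#' @return Fluorescence values.
#' @export
boltzmann <- function(temperature, f_min, f_max, tm, slope) {
  f_min + (f_max - f_min) / (1 + exp((tm - temperature) / slope))
}

#' Truncate a melt curve at its fluorescence maximum
#'
#' Removes the post-peak aggregation decay so the Boltzmann model (which is
#' monotone) sees only the unfolding transition.
#'
#' @param curve A [melt_curve()].
#' @return The truncated [melt_curve()].
#' @export
truncate_at_peak <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  k <- which.max(curve$fluorescence)
  melt_curve(curve$temperature[seq_len(k)], curve$fluorescence[seq_len(k)],
             replicate_id = curve$replicate_id,
             background_corrected = curve$background_corrected)
}

#' Fit the Boltzmann sigmoid to a melt curve
#'
#' Nonlinear least squares for `f_min`, `f_max`, `tm` and `slope`.  The
#' curve is truncated at its global fluorescence maximum first (see
#' [truncate_at_peak()]); at least 8 points must remain.
#'
#' @param curve A [melt_curve()] (background-corrected).
#' @param truncate Truncate at the global maximum before fitting.
#' @return List of class `"boltzmann_fit"`: `f_min`, `f_max`, `tm`,
#'   `slope`, `tm_se` (standard error of `tm`), `residual_norm`, `fitted`.
#' @export
fit_boltzmann <- function(curve, truncate = TRUE) {
  stopifnot(inherits(curve, "melt_curve"))
  if (stats::sd(curve$fluorescence) <
      sqrt(.Machine$double.eps) * max(1, abs(mean(curve$fluorescence)))) {
    abort_degenerate("flat melt curve; Tm is unidentifiable")
  }
  if (truncate) curve <- truncate_at_peak(curve)
  tt <- curve$temperature; ff <- curve$fluorescence
  if (length(tt) < 8L) abort_fit("need at least 8 points to fit a melt curve")
  half <- (min(ff) + max(ff)) / 2
  tm0 <- tt[which.min(abs(ff - half))]
  start <- list(f_min = min(ff), f_max = max(ff), tm = tm0, slope = 2)
  dat <- data.frame(tt = tt, ff = ff)
  fit <- tryCatch(
    minpack.lm::nlsLM(ff ~ f_min + (f_max - f_min) / (1 + exp((tm - tt) / slope)),
                      data = dat, start = start,
                      lower = c(-Inf, -Inf, min(tt), 1e-3),
                      upper = c(Inf, Inf, max(tt), Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort_fit(paste("Boltzmann fit failed:", conditionMessage(e))))
  cf <- stats::coef(fit)
  if (cf[["f_min"]] >= cf[["f_max"]]) {
    abort_degenerate("fitted f_min >= f_max; no unfolding transition")
  }
  if (cf[["tm"]] <= min(tt) || cf[["tm"]] >= max(tt)) {
    abort_degenerate("fitted Tm lies on the boundary of the temperature window")
  }
  se <- tryCatch(summary(fit)$coefficients["tm", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(f_min = cf[["f_min"]], f_max = cf[["f_max"]],
                 tm = cf[["tm"]], slope = cf[["slope"]], tm_se = se,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = as.numeric(stats::fitted(fit))),
            class = "boltzmann_fit")
}

#' Thermal shift between a sample and a reference fit
#'
#' @param sample_fit,reference_fit [fit_boltzmann()] results; the reference
#'   is typically the DMSO control.
#' @return `tm_sample - tm_reference` in degrees C; negative values mean
#'   the compound destabilizes the protein.
#' @export
delta_tm <- function(sample_fit, reference_fit) {
  stopifnot(inherits(sample_fit, "boltzmann_fit"),
            inherits(reference_fit, "boltzmann_fit"))
  sample_fit$tm - reference_fit$tm
}
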