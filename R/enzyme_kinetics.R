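# Kinase progress-curve reduction (ADP-fluorescence assay) and kinetic
# model fitting.
#
# Raw plate-reader fluorescence (RFU) is converted to product amounts with
# an ADP standard curve, corrected for non-enzymatic ADP production (the
# no-kinase control) and kinase autophosphorylation (the rate observed
# without substrate), normalized to the amount of kinase, and reduced to an
# initial reaction velocity from the linear portion of the progress curve.
# Velocities then feed the Michaelis-Menten fit (Km, Vmax), the activator
# saturation model Va = Vact L / (Kact + L), and the dose-response EC50 fit.

#' Build an ADP standard curve
#'
#' Ordinary least-squares line `RFU = slope * pmol + intercept` through
#' standard wells with known ADP amounts, measured under the reaction
#' conditions of the assay.
#'
#' @param points Data frame with columns `pmol` (ADP per well) and `rfu`;
#'   at least 3 points with distinct `pmol`.
#' @return List of class `"standard_curve"`: `slope` (RFU per pmol ADP),
#'   `intercept` (RFU), `r2`.
#' @export
build_standard_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("pmol", "rfu") %in% names(points)))
  if (nrow(points) < 3L) abort_value("need at least 3 standard-curve points")
  if (length(unique(points$pmol)) < 2L) {
    abort_value("standard-curve pmol values must not all be identical")
  }
  fit <- stats::lm(rfu ~ pmol, data = points)
  slope <- stats::coef(fit)[["pmol"]]
  if (slope <= 0) abort_degenerate("standard-curve slope must be positive")
  tss <- sum((points$rfu - mean(points$rfu))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  structure(list(slope = slope, intercept = stats::coef(fit)[["(Intercept)"]],
                 r2 = r2),
            class = "standard_curve")
}

#' Create a progress curve
#'
#' @param times Measurement times in minutes (typically a 5-min grid over
#'   3 h), increasing.
#' @param rfu Raw fluorescence readings (or pmol-per-ng values once
#'   corrected).
#' @param kinase_ng Kinase amount per well in ng (> 0 for enzyme wells, 0
#'   for control wells).
#' @param condition Optional named list of condition labels (substrate and
#'   ATP concentrations, activator id and concentration).
#' @return List of class `"progress_curve"`.
#' @export
progress_curve <- function(times, rfu, kinase_ng, condition = list()) {
  times <- as.numeric(times); rfu <- as.numeric(rfu)
  if (length(times) != length(rfu)) abort_value("times and rfu must have equal length")
  if (any(diff(times) <= 0)) abort_value("times must be increasing")
  if (kinase_ng < 0) abort_value("kinase_ng must be non-negative")
  structure(list(times = times, rfu = rfu, kinase_ng = kinase_ng,
                 condition = condition, corrected = FALSE),
            class = "progress_curve")
}

#' Correct a raw progress curve and convert to pmol ADP per ng kinase
#'
#' Correction order: subtract the no-enzyme control (non-enzymatic ADP
#' production; this also cancels the standard-curve intercept), subtract
#' the autophosphorylation signal (the no-substrate control minus the
#' no-enzyme control), convert RFU to pmol ADP with the standard-curve
#' slope, and normalize to the kinase amount.
#'
#' @param raw Enzyme-well [progress_curve()] (raw RFU).
#' @param no_enzyme No-kinase control [progress_curve()].
#' @param no_substrate No-substrate (autophosphorylation) control
#'   [progress_curve()].
#' @param sc A [build_standard_curve()] result.
#' @return A [progress_curve()] whose `rfu` field holds pmol ADP per ng
#'   kinase, flagged `corrected`.
#' @export
correct_progress_curve <- function(raw, no_enzyme, no_substrate, sc) {
  stopifnot(inherits(raw, "progress_curve"), inherits(sc, "standard_curve"))
  for (ctl in list(no_enzyme, no_substrate)) {
    if (length(ctl$times) != length(raw$times) || any(ctl$times != raw$times)) {
      abort_grid("control progress curves must share the enzyme well's time grid")
    }
  }
  if (raw$kinase_ng <= 0) abort_value("enzyme well must have kinase_ng > 0")
  corrected_rfu <- raw$rfu - no_enzyme$rfu - (no_substrate$rfu - no_enzyme$rfu)
  pmol_per_ng <- corrected_rfu / sc$slope / raw$kinase_ng
  out <- progress_curve(raw$times, pmol_per_ng, raw$kinase_ng, raw$condition)
  out$corrected <- TRUE
  out
}

#' Estimate the initial reaction velocity from a progress curve
#'
#' Fits the linear portion of the curve by ordinary least squares.  The
#' window is the longest prefix (at least `min_points` points) whose
#' regression r-squared is at least `r2_threshold` and whose slope differs
#' by less than `slope_tol` (relative) from the slope of the minimal
#' `min_points`-point window; a flat curve returns velocity 0 over the full
#' window.
#'
#' @param curve A corrected [progress_curve()] in pmol per ng (values in
#'   other units give a velocity in those units per minute).
#' @param min_points Minimum window length.
#' @param r2_threshold Linearity requirement for the window.
#' @param slope_tol Maximum relative slope deviation from the minimal
#'   window.
#' @return List of class `"velocity_estimate"`: `v` (units of `curve`
#'   values per minute), `window` (index range used), `window_r2`.
#' @export
estimate_velocity <- function(curve, min_points = 5L, r2_threshold = 0.99,
                              slope_tol = 0.05) {
  stopifnot(inherits(curve, "progress_curve"))
  n <- length(curve$times)
  if (n < 6L) abort_value("need at least 6 points to estimate a velocity")
  tt <- curve$times; yy <- curve$rfu
  if (stats::sd(yy) < sqrt(.Machine$double.eps) * max(1, abs(mean(yy)))) {
    return(structure(list(v = 0, window = c(1L, n), window_r2 = NA_real_),
                     class = "velocity_estimate"))
  }
  win_fit <- function(k) {
    fit <- stats::lm(yy[1:k] ~ tt[1:k])
    tss <- sum((yy[1:k] - mean(yy[1:k]))^2)
    r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
    list(slope = stats::coef(fit)[[2L]], r2 = r2)
  }
  base <- win_fit(min_points)
  if (abs(base$slope) < sqrt(.Machine$double.eps)) {
    return(structure(list(v = 0, window = c(1L, min_points),
                          window_r2 = base$r2),
                     class = "velocity_estimate"))
  }
  for (k in seq.int(n, min_points)) {
    f <- win_fit(k)
    if (f$r2 >= r2_threshold &&
        abs(f$slope - base$slope) / abs(base$slope) < slope_tol) {
      return(structure(list(v = f$slope, window = c(1L, k), window_r2 = f$r2),
                       class = "velocity_estimate"))
    }
  }
  abort_degenerate("no window satisfies the linearity threshold")
}

#' Michaelis-Menten fit
#'
#' Model: `v = vmax * S / (km + S)`.
#'
#' @param velocities Data frame with columns `conc` (substrate or ATP
#'   concentration, µM) and `v`; at least 4 concentrations spanning `km`.
#' @return List of class `"mm_fit"`: `km`, `vmax`, `km_se`, `vmax_se`,
#'   `residual_norm`.
#' @export
fit_michaelis_menten <- function(velocities) {
  stopifnot(is.data.frame(velocities), all(c("conc", "v") %in% names(velocities)))
  if (length(unique(velocities$conc)) < 4L) {
    abort_fit("need at least 4 concentrations")
  }
  if (stats::sd(velocities$v) < sqrt(.Machine$double.eps) * max(1, abs(mean(velocities$v)))) {
    abort_degenerate("velocities are constant; km is unidentifiable")
  }
  vmax0 <- max(velocities$v)
  km0 <- velocities$conc[which.min(abs(velocities$v - vmax0 / 2))]
  fit <- lm_curve_fit(
    function(p) velocities$v - p[1L] * velocities$conc / (p[2L] + velocities$conc),
    start = c(vmax = vmax0, km = max(km0, 1e-6)),
    lower = c(1e-12, 1e-12), label = "Michaelis-Menten")
  structure(list(km = fit$par[["km"]], vmax = fit$par[["vmax"]],
                 km_se = fit$se[["km"]], vmax_se = fit$se[["vmax"]],
                 residual_norm = sqrt(fit$rss)),
            class = "mm_fit")
}

#' Activator saturation fit (K_act)
#'
#' The basal rate is subtracted from the velocities measured in the
#' presence of each activator concentration L; the increments obey
#' saturation kinetics `Va = Vact * L / (Kact + L)`, where `Vact` is the
#' maximal velocity increment and `Kact` the activator concentration at
#' half-maximal enhancement.  The ratio `Vact / Kact` is reported as a
#' measure of overall enhancement.
#'
#' @param velocities Data frame with columns `conc` (activator
#'   concentration, µM) and `v` (raw, non-basal-subtracted velocities); at
#'   least 4 activator concentrations.
#' @param basal_v Basal velocity from same-plate DMSO wells.
#' @return List of class `"activation_fit"`: `basal_v`, `v_act`, `k_act`,
#'   `v_act_se`, `k_act_se`, `enhancement_ratio` (`v_act / k_act`),
#'   `no_activation` flag (when no increment is positive the parameters are
#'   `NA` and the flag is set).
#' @export
fit_activation <- function(velocities, basal_v) {
  stopifnot(is.data.frame(velocities), all(c("conc", "v") %in% names(velocities)))
  if (length(unique(velocities$conc)) < 4L) {
    abort_fit("need at least 4 activator concentrations")
  }
  inc <- data.frame(conc = velocities$conc, va = velocities$v - basal_v)
  if (all(inc$va <= 0)) {
    return(structure(list(basal_v = basal_v, v_act = NA_real_,
                          k_act = NA_real_, v_act_se = NA_real_,
                          k_act_se = NA_real_, enhancement_ratio = NA_real_,
                          no_activation = TRUE),
                     class = "activation_fit"))
  }
  vact0 <- max(inc$va)
  kact0 <- inc$conc[which.min(abs(inc$va - vact0 / 2))]
  fit <- lm_curve_fit(
    function(p) inc$va - p[1L] * inc$conc / (p[2L] + inc$conc),
    start = c(v_act = vact0, k_act = max(kact0, 1e-6)),
    lower = c(1e-12, 1e-12), label = "activation")
  structure(list(basal_v = basal_v, v_act = fit$par[["v_act"]],
                 k_act = fit$par[["k_act"]],
                 v_act_se = fit$se[["v_act"]], k_act_se = fit$se[["k_act"]],
                 enhancement_ratio = fit$par[["v_act"]] / fit$par[["k_act"]],
                 no_activation = FALSE),
            class = "activation_fit")
}

#' Dose-response EC50 fit
#'
#' Three-parameter log-logistic fit on the raw (non-basal-subtracted)
#' velocities: `v(L) = bottom + (top - bottom) * L^h / (ec50^h + L^h)` with
#' the hill slope fixed to 1 by default; `ec50` is the concentration at the
#' half-effect between `bottom` and `top`.
#'
#' @param velocities Data frame with columns `conc` (µM) and `v`; at least
#'   4 concentrations.
#' @param hill Hill slope; fixed at 1 unless `free_hill = TRUE`.
#' @param free_hill Also estimate the hill slope.
#' @return List of class `"dose_response_fit"`: `ec50`, `top`, `bottom`,
#'   `hill`, standard errors, `residual_norm`.
#' @export
fit_ec50 <- function(velocities, hill = 1, free_hill = FALSE) {
  stopifnot(is.data.frame(velocities), all(c("conc", "v") %in% names(velocities)))
  if (length(unique(velocities$conc)) < 4L) {
    abort_fit("need at least 4 concentrations")
  }
  if (stats::sd(velocities$v) < sqrt(.Machine$double.eps) * max(1, abs(mean(velocities$v)))) {
    abort_degenerate("flat dose-response; ec50 is unidentifiable")
  }
  pos <- velocities$conc[velocities$conc > 0]
  cc <- velocities$conc; vv <- velocities$v
  model <- function(p, h) p[1L] + (p[2L] - p[1L]) * cc^h / (p[3L]^h + cc^h)
  if (free_hill) {
    fit <- lm_curve_fit(function(p) vv - model(p, p[4L]),
                        start = c(bottom = min(vv), top = max(vv),
                                  ec50 = stats::median(pos), h = hill),
                        lower = c(-Inf, -Inf, 1e-12, 0.1), label = "EC50")
    hill_est <- fit$par[["h"]]
  } else {
    fit <- lm_curve_fit(function(p) vv - model(p, hill),
                        start = c(bottom = min(vv), top = max(vv),
                                  ec50 = stats::median(pos)),
                        lower = c(-Inf, -Inf, 1e-12), label = "EC50")
    hill_est <- hill
  }
  structure(list(ec50 = fit$par[["ec50"]], top = fit$par[["top"]],
                 bottom = fit$par[["bottom"]], hill = hill_est,
                 ec50_se = fit$se[["ec50"]], top_se = fit$se[["top"]],
                 bottom_se = fit$se[["bottom"]],
                 residual_norm = sqrt(fit$rss)),
            class = "dose_response_fit")
}
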