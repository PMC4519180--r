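# FP titration and competition analysis used in assay development:
# saturation of the probe FP signal with increasing target-protein amount,
# and competition of the labeled probe by unlabeled peptide or compound.
#
# Neither curve family needs more than the minimal monotone models:
# a one-site hyperbola for saturation and a three-parameter log-logistic
# (hill = 1) for competition.

#' Baseline-correct FP titration points
#'
#' Subtracts the FP signal of the zero-dose point (probe alone, no target
#' protein) from every point, so the corrected signal measures the
#' binding-induced polarization increase only.
#'
#' @param points Data frame with columns `dose` and `fp`.
#' @return The data frame with `fp` corrected and a `baseline_corrected`
#'   column set to `TRUE`; the zero-dose point maps to 0.
#' @export
baseline_correct <- function(points) {
  stopifnot(is.data.frame(points), all(c("dose", "fp") %in% names(points)))
  if (any(points$dose < 0)) abort_value("doses must be non-negative")
  zero <- which(points$dose == 0)
  if (length(zero) == 0L) {
    abort_baseline("no zero-dose point to define the FP baseline")
  }
  points$fp <- points$fp - mean(points$fp[zero])
  points$baseline_corrected <- TRUE
  points
}

#' Fit a one-site saturation hyperbola to FP titration data
#'
#' Model: `FP(d) = fp_max * d / (half_sat + d)`; `fp_max` is the plateau FP
#' increase and `half_sat` the dose (protein amount per well) at
#' half-saturation.
#'
#' @param points Data frame with columns `dose` and `fp`
#'   (baseline-corrected).
#' @return List of class `"saturation_fit"`: `fp_max`, `half_sat`,
#'   `residual_norm`, `fitted` (predictions at the input doses),
#'   `degenerate` flag.
#' @export
fit_saturation <- function(points) {
  stopifnot(is.data.frame(points), all(c("dose", "fp") %in% names(points)))
  if (nrow(points) < 4L) abort_fit("need at least 4 titration points")
  if (max(abs(points$fp)) < sqrt(.Machine$double.eps)) {
    return(structure(list(fp_max = 0, half_sat = NA_real_,
                          residual_norm = 0, fitted = rep(0, nrow(points)),
                          degenerate = TRUE),
                     class = "saturation_fit"))
  }
  start <- list(fp_max = max(points$fp),
                half_sat = max(stats::median(points$dose[points$dose > 0]), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(fp ~ fp_max * dose / (half_sat + dose),
                      data = points, start = start,
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort_fit(paste("saturation fit failed:", conditionMessage(e))))
  cf <- stats::coef(fit)
  structure(list(fp_max = unname(cf["fp_max"]), half_sat = unname(cf["half_sat"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = as.numeric(stats::fitted(fit)),
                 degenerate = FALSE),
            class = "saturation_fit")
}

#' Predict from a saturation fit
#' @param object A `"saturation_fit"`.
#' @param dose Doses at which to predict.
#' @param ... Unused.
#' @export
predict.saturation_fit <- function(object, dose, ...) {
  object$fp_max * dose / (object$half_sat + dose)
}

#' Fit a decreasing log-logistic competition curve
#'
#' Model: `FP(d) = bottom + (top - bottom) / (1 + d / ic50)` (three-parameter
#' log-logistic with hill slope 1), so the fitted FP at `d = ic50` is the
#' midpoint `(top + bottom) / 2`.
#'
#' @param points Data frame with columns `dose` (competitor concentration,
#'   µM; zero doses anchor the top plateau) and `fp` (mP).
#' @return List of class `"competition_fit"`: `top`, `bottom`, `ic50`,
#'   `residual_norm`, `fitted`, `degenerate` flag.  Non-monotone
#'   (pathological) data produce a warning, not an error.
#' @export
fit_competition <- function(points) {
  stopifnot(is.data.frame(points), all(c("dose", "fp") %in% names(points)))
  if (nrow(points) < 4L) abort_fit("need at least 4 competition points")
  if (stats::sd(points$fp) < sqrt(.Machine$double.eps)) {
    return(structure(list(top = mean(points$fp), bottom = NA_real_,
                          ic50 = NA_real_, residual_norm = 0,
                          fitted = points$fp, degenerate = TRUE),
                     class = "competition_fit"))
  }
  ord <- points[order(points$dose), , drop = FALSE]
  if (suppressWarnings(stats::cor(ord$dose, ord$fp, method = "spearman")) > 0) {
    warning("competition data are not monotone decreasing; fit may be unreliable")
  }
  pos <- points$dose[points$dose > 0]
  start <- list(top = max(points$fp), bottom = min(points$fp),
                ic50 = stats::median(pos))
  fit <- tryCatch(
    minpack.lm::nlsLM(fp ~ bottom + (top - bottom) / (1 + dose / ic50),
                      data = points, start = start,
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort_fit(paste("competition fit failed:", conditionMessage(e))))
  cf <- stats::coef(fit)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 ic50 = unname(cf["ic50"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = as.numeric(stats::fitted(fit)),
                 degenerate = FALSE),
            class = "competition_fit")
}

#' Predict from a competition fit
#' @param object A `"competition_fit"`.
#' @param dose Doses at which to predict.
#' @param ... Unused.
#' @export
predict.competition_fit <- function(object, dose, ...) {
  object$bottom + (object$top - object$bottom) / (1 + dose / object$ic50)
}
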