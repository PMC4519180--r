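# Surface plasmon resonance: closed-form 1:1 Langmuir sensorgram
# simulation and global kinetic fitting.
#
# For a 1:1 interaction with association rate ka (1/M/s), dissociation rate
# kd (1/s) and surface capacity Rmax (RU), analyte at concentration C gives
#   association  (t <= t_switch):  R(t) = Req (1 - exp(-(ka C + kd) t)),
#                                  Req  = Rmax C / (C + KD),  KD = kd / ka
#   dissociation (t >  t_switch):  R(t) = R(t_switch) exp(-kd (t - t_switch))
# which is continuous at the buffer switch.  The equilibrium constant KD is
# always derived as kd / ka, never fit independently.

#' 1:1 Langmuir kinetic parameters
#'
#' @param ka Association rate constant (1/M/s), positive.
#' @param kd Dissociation rate constant (1/s), positive.
#' @param rmax Surface binding capacity (RU), positive.
#' @return List of class `"langmuir_params"` with `ka`, `kd`, `rmax` and the
#'   derived `kD = kd / ka` (M).
#' @export
langmuir_params <- function(ka, kd, rmax) {
  if (any(c(ka, kd, rmax) <= 0)) abort_value("ka, kd and rmax must be positive")
  structure(list(ka = ka, kd = kd, rmax = rmax, kD = kd / ka),
            class = "langmuir_params")
}

#' Closed-form 1:1 Langmuir response
#'
#' @param times Times in seconds from injection start.
#' @param params A [langmuir_params()].
#' @param conc Analyte concentration (M).
#' @param t_switch Time of the association-to-dissociation buffer switch (s).
#' @return Response in RU at `times`.
#' @export
langmuir_response <- function(times, params, conc, t_switch) {
  stopifnot(inherits(params, "langmuir_params"), conc > 0, t_switch > 0)
  req <- params$rmax * conc / (conc + params$kD)
  kobs <- params$ka * conc + params$kd
  r_switch <- req * (1 - exp(-kobs * t_switch))
  ifelse(times <= t_switch,
         req * (1 - exp(-kobs * times)),
         r_switch * exp(-params$kd * (times - t_switch)))
}

#' Simulate a sensorgram
#'
#' @inheritParams langmuir_response
#' @param noise_ru Standard deviation of additive Gaussian RU noise
#'   (0 for an exact closed-form curve).
#' @return List of class `"sensorgram"`: `times`, `response`,
#'   `analyte_conc`, `t_switch`.
#' @export
simulate_sensorgram <- function(params, conc, t_switch, times, noise_ru = 0) {
  if (any(diff(times) <= 0)) abort_value("times must be increasing")
  if (t_switch <= 0 || t_switch >= max(times)) {
    abort_value("t_switch must lie strictly inside the time range")
  }
  resp <- langmuir_response(times, params, conc, t_switch)
  if (noise_ru > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_ru)
  structure(list(times = times, response = resp, analyte_conc = conc,
                 t_switch = t_switch),
            class = "sensorgram")
}

#' Reference-channel correction
#'
#' Pointwise subtraction of the reference (or buffer-blank) channel from
#' the raw sensorgram; the two must share the time grid.
#'
#' @param raw,reference `"sensorgram"` objects.
#' @return The corrected `"sensorgram"`.
#' @export
reference_correct <- function(raw, reference) {
  stopifnot(inherits(raw, "sensorgram"), inherits(reference, "sensorgram"))
  if (length(raw$times) != length(reference$times) ||
      any(raw$times != reference$times)) {
    abort_grid("sensorgram time grids differ")
  }
  raw$response <- raw$response - reference$response
  raw
}

# Deterministic initializer: kd from a log-linear regression of the
# dissociation tail of the highest-signal curve, then ka from the
# observed-rate regression k_obs = ka C + kd across curves.
langmuir_init <- function(sensorgrams) {
  best <- sensorgrams[[which.max(vapply(sensorgrams, function(s)
    max(s$response), numeric(1)))]]
  dis <- best$times > best$t_switch
  y <- best$response[dis]
  keep <- y > max(y) * 1e-3
  kd0 <- -stats::coef(stats::lm(log(y[keep]) ~ best$times[dis][keep]))[[2L]]
  kd0 <- max(kd0, 1e-6)
  kobs <- vapply(sensorgrams, function(s) {
    assoc <- s$times <= s$t_switch & s$times > 0
    req <- max(s$response[s$times <= s$t_switch]) * 1.02
    y <- req - s$response[assoc]
    keep <- y > req * 1e-3
    -stats::coef(stats::lm(log(y[keep]) ~ s$times[assoc][keep]))[[2L]]
  }, numeric(1))
  concs <- vapply(sensorgrams, function(s) s$analyte_conc, numeric(1))
  ka0 <- stats::coef(stats::lm(kobs ~ concs))[[2L]]
  if (!is.finite(ka0) || ka0 <= 0) ka0 <- max(kobs) / max(concs)
  rmax0 <- max(vapply(sensorgrams, function(s) max(s$response), numeric(1)))
  c(ka = ka0, kd = kd0, rmax = max(rmax0, 1e-6))
}

#' Global 1:1 Langmuir fit of a set of sensorgrams
#'
#' Fits one set of (ka, kd, Rmax) shared across all curves (different
#' analyte concentrations; replicate injections enter as separate curves)
#' by Levenberg-Marquardt least squares on log-parameters, with a
#' deterministic initializer (dissociation-tail log-linear regression for
#' kd; observed-rate regression `k_obs = ka C + kd` for ka).
#'
#' @param sensorgrams List of `"sensorgram"` objects (reference-corrected);
#'   at least two distinct analyte concentrations, each curve containing
#'   both phases.
#' @return A [langmuir_params()] augmented with standard errors (`ka_se`,
#'   `kd_se`, `rmax_se`, `kD_se`), `residual_norm` and `per_curve_rss`.
#' @export
fit_langmuir <- function(sensorgrams) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(length(sensorgrams) >= 1L)
  concs <- vapply(sensorgrams, function(s) s$analyte_conc, numeric(1))
  if (length(unique(concs)) < 2L) {
    abort_fit("need at least 2 analyte concentrations for a global fit")
  }
  for (s in sensorgrams) {
    if (!any(s$times <= s$t_switch) || !any(s$times > s$t_switch)) {
      abort_fit("each sensorgram must contain association and dissociation phases")
    }
  }
  if (max(vapply(sensorgrams, function(s) max(abs(s$response)), numeric(1))) <
      sqrt(.Machine$double.eps)) {
    abort_fit("all responses are zero; rmax is unidentifiable")
  }
  init <- langmuir_init(sensorgrams)
  resid_fn <- function(logp) {
    p <- langmuir_params(exp(logp[1L]), exp(logp[2L]), exp(logp[3L]))
    unlist(lapply(sensorgrams, function(s) {
      s$response - langmuir_response(s$times, p, s$analyte_conc, s$t_switch)
    }))
  }
  out <- minpack.lm::nls.lm(par = log(init), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (out$info == 0 || out$info == 5) {
    abort_fit(sprintf("Langmuir fit did not converge (info=%d; start ka=%.3g kd=%.3g rmax=%.3g)",
                      out$info, init["ka"], init["kd"], init["rmax"]))
  }
  est <- unname(exp(out$par))
  params <- langmuir_params(est[1L], est[2L], est[3L])
  # delta-method SEs on the natural scale from the log-scale covariance
  nobs <- sum(vapply(sensorgrams, function(s) length(s$times), integer(1)))
  covl <- tryCatch({
    s2 <- out$deviance / max(nobs - 3L, 1L)
    s2 * solve(out$hessian)
  }, error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(covl), 0)) * est
  kD_se <- if (all(is.finite(covl[1:2, 1:2]))) {
    # var(log kD) = var(log kd) + var(log ka) - 2 cov
    sqrt(max(covl[2, 2] + covl[1, 1] - 2 * covl[1, 2], 0)) * params$kD
  } else NA_real_
  params$ka_se <- se[1L]; params$kd_se <- se[2L]; params$rmax_se <- se[3L]
  params$kD_se <- kD_se
  params$residual_norm <- sqrt(out$deviance)
  params$per_curve_rss <- vapply(sensorgrams, function(s) {
    sum((s$response - langmuir_response(s$times, params, s$analyte_conc,
                                        s$t_switch))^2)
  }, numeric(1))
  params
}
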