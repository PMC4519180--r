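# Shared Levenberg-Marquardt driver for the package's nonlinear fits.
# Works on a residual function directly (no model-frame machinery), honors
# box constraints, and reports standard errors from the Gauss-Newton
# covariance at the optimum (NA when the Jacobian is singular there).

lm_curve_fit <- function(resid_fn, start, lower = rep(-Inf, length(start)),
                         upper = rep(Inf, length(start)), label = "curve") {
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) abort_fit(sprintf("%s fit failed: %s", label,
                                          conditionMessage(e))))
  if (out$info == 0) {
    abort_fit(sprintf("%s fit failed: improper input parameters", label))
  }
  est <- stats::setNames(as.numeric(out$par), names(start))
  se <- tryCatch({
    cf <- summary(out)$coefficients
    stats::setNames(cf[, "Std. Error"], names(start))
  }, error = function(e) stats::setNames(rep(NA_real_, length(est)),
                                         names(est)))
  list(par = est, se = se, rss = out$deviance)
}
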