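linear_curve <- function(slope_pmol_min, ng = 1, times = seq(0, 180, 5),
                         sc_slope = 100, sc_intercept = 100) {
  progress_curve(times, sc_intercept + sc_slope * slope_pmol_min * times, ng)
}

test_that("ADP standard curve is the OLS line through the points", {
  sc <- build_standard_curve(data.frame(pmol = c(0, 10, 20),
                                        rfu = c(100, 1100, 2100)))
  expect_equal(sc$slope, 100)
  expect_equal(sc$intercept, 100)
  expect_equal(sc$r2, 1)
  expect_error(build_standard_curve(data.frame(pmol = c(5, 5, 5),
                                               rfu = c(1, 2, 3))),
               class = "fpscreen_value_error")
  expect_error(build_standard_curve(data.frame(pmol = c(0, 1), rfu = c(0, 1))),
               class = "fpscreen_value_error")
})

test_that("progress-curve correction removes backgrounds and converts units", {
  times <- seq(0, 180, 5)
  sc <- build_standard_curve(data.frame(pmol = c(0, 10, 20),
                                        rfu = c(100, 1100, 2100)))
  ne <- progress_curve(times, 100 + 2 * times, 0)       # non-enzymatic drift
  ns <- progress_curve(times, 100 + 5 * times, 1)       # + autophosphorylation
  # raw = controls: corrected curve is identically zero
  raw0 <- progress_curve(times, 100 + 5 * times, 1)
  expect_equal(correct_progress_curve(raw0, ne, ns, sc)$rfu,
               rep(0, length(times)))
  # 100 RFU per min of enzymatic signal on top, slope 100 RFU/pmol, 1 ng
  raw <- progress_curve(times, 100 + 5 * times + 100 * times, 1)
  corr <- correct_progress_curve(raw, ne, ns, sc)
  expect_equal(corr$rfu, times * 1)  # 1 pmol per ng per min
  # grid mismatch
  ne_bad <- progress_curve(seq(0, 180, 10), rep(0, 19), 0)
  expect_error(correct_progress_curve(raw, ne_bad, ns, sc),
               class = "fpscreen_grid_error")
})

test_that("velocity estimation matches the closed-form slope on linear curves", {
  v <- estimate_velocity(linear_curve(7))
  expect_equal(v$v, 700)             # RFU units: 7 pmol/min * 100 RFU/pmol
  corrected <- progress_curve(seq(0, 180, 5), 7 * seq(0, 180, 5), 1)
  expect_equal(estimate_velocity(corrected)$v, 7.0)
  expect_equal(estimate_velocity(corrected)$window, c(1L, 37L))

  flat <- progress_curve(seq(0, 180, 5), rep(3, 37), 1)
  expect_equal(estimate_velocity(flat)$v, 0)

  # random linear curves: estimator equals the generating slope exactly
  set.seed(61)
  for (i in 1:20) {
    s <- stats::runif(1, -5, 5)
    cur <- progress_curve(seq(0, 120, 5), 40 + s * seq(0, 120, 5), 1)
    expect_equal(estimate_velocity(cur)$v, s, tolerance = 1e-10)
  }
})

test_that("saturating curves confine the window to the early linear region", {
  times <- seq(0, 180, 1)
  # v0 = 10 pmol/min, exponential approach with 60-min time constant
  pmol <- 10 * 60 * (1 - exp(-times / 60))
  est <- estimate_velocity(progress_curve(times, pmol, 1))
  expect_lt(est$window[2], length(times))
  # the window rule tolerates a 5% slope drift from the minimal window, so
  # recovery of the true initial velocity is bounded by twice that
  expect_equal(est$v, 10, tolerance = 0.1)
})

test_that("velocity is intercept-invariant and scales inversely with kinase", {
  times <- seq(0, 180, 5)
  for (icpt in c(0, 120, 500)) {
    sc <- build_standard_curve(data.frame(pmol = c(0, 10, 20),
                                          rfu = icpt + c(0, 850, 1700)))
    ne <- progress_curve(times, icpt + 3 * times, 0)
    ns <- progress_curve(times, icpt + 4 * times, 40)
    raw <- progress_curve(times, icpt + 4 * times + 85 * 7 * times, 40)
    v <- estimate_velocity(correct_progress_curve(raw, ne, ns, sc))$v
    expect_equal(v * 40, 7, tolerance = 1e-9)  # whole-well pmol/min
    raw2 <- progress_curve(times, icpt + 4 * times + 85 * 7 * times, 80)
    v2 <- estimate_velocity(correct_progress_curve(raw2, ne, ns, sc))$v
    expect_equal(v2, v / 2, tolerance = 1e-9)
  }
})

test_that("Michaelis-Menten fit recovers noiseless parameters", {
  conc <- c(0.2, 0.5, 1, 2, 5, 10, 20, 50, 100, 200)
  vel <- data.frame(conc = conc, v = 14 * conc / (9.78 + conc))
  fit <- fit_michaelis_menten(vel)
  expect_equal(fit$km, 9.78, tolerance = 1e-6)
  expect_equal(fit$vmax, 14, tolerance = 1e-6)
  # v at S = km is vmax / 2 under the model
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  expect_error(fit_michaelis_menten(data.frame(conc = conc, v = rep(3, 10))),
               class = "fpscreen_degenerate_error")
})

test_that("Km recovery stays within 10% median error at 5% noise", {
  set.seed(67)
  errs <- replicate(100, {
    km <- stats::runif(1, 2, 50)
    vmax <- stats::runif(1, 5, 30)
    conc <- km * c(0.05, 0.1, 0.3, 1, 3, 10, 30)
    v <- vmax * conc / (km + conc) * (1 + stats::rnorm(length(conc), 0, 0.05))
    abs(fit_michaelis_menten(data.frame(conc = conc, v = v))$km - km) / km
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("activation fit recovers K_act and flags absent activation", {
  conc <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100)
  va <- function(k_act, v_act) 7 + v_act * conc / (k_act + conc)
  f142 <- fit_activation(data.frame(conc = conc, v = va(0.4, 3.0)), basal_v = 7)
  expect_equal(f142$k_act, 0.4, tolerance = 1e-6)
  expect_equal(f142$v_act, 3.0, tolerance = 1e-6)
  expect_equal(f142$enhancement_ratio, 3.0 / 0.4, tolerance = 1e-6)
  fdph <- fit_activation(data.frame(conc = conc, v = va(1.02, 2.4)), basal_v = 7)
  expect_equal(fdph$k_act, 1.02, tolerance = 1e-6)
  # model identity: increment at L = K_act is half-maximal
  expect_equal(f142$v_act * 0.4 / (0.4 + 0.4), f142$v_act / 2)

  none <- fit_activation(data.frame(conc = conc, v = rep(7, length(conc))),
                         basal_v = 7)
  expect_true(none$no_activation)
  expect_true(is.na(none$k_act))
})

test_that("EC50 fit is self-consistent and matches K_act for hill-1 data", {
  conc <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100)
  v <- 7 + (10 - 7) * conc / (conc + 0.63)
  fit <- fit_ec50(data.frame(conc = conc, v = v))
  expect_equal(fit$ec50, 0.63, tolerance = 1e-6)
  expect_equal(fit$bottom, 7, tolerance = 1e-6)
  expect_equal(fit$top, 10, tolerance = 1e-6)

  # saturation-model data: fitted ec50 equals the generating k_act
  v2 <- 7 + 3 * conc / (0.4 + conc)
  expect_equal(fit_ec50(data.frame(conc = conc, v = v2))$ec50, 0.4,
               tolerance = 1e-6)

  expect_error(fit_ec50(data.frame(conc = conc, v = rep(5, length(conc)))),
               class = "fpscreen_degenerate_error")
})

test_that("K_act recovery stays within 10% median error at 5% noise", {
  # noise applies to the observations the saturation model actually fits:
  # the basal-subtracted velocity increments
  set.seed(71)
  errs <- replicate(100, {
    k_act <- stats::runif(1, 0.1, 5)
    v_act <- stats::runif(1, 1, 6)
    conc <- k_act * c(0.03, 0.1, 0.3, 1, 3, 10, 30, 100)
    va <- v_act * conc / (k_act + conc) *
      (1 + stats::rnorm(length(conc), 0, 0.05))
    abs(fit_activation(data.frame(conc = conc, v = 7 + va), basal_v = 7)$k_act -
          k_act) / k_act
  })
  expect_lt(stats::median(errs), 0.1)
})
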