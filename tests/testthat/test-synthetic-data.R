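test_that("generators are pure functions of configuration and seed", {
  small <- list(n_plates = 2L, compounds_per_plate = 40L,
                hits = data.frame(position = c(3L, 42L),
                                  fraction = c(0.85, 0.8),
                                  retest_fraction = c(0, 0.8),
                                  quencher = c(FALSE, TRUE)))
  cfg <- sim_config(seed = 9, screen = small)
  a <- generate_screen(cfg); b <- generate_screen(cfg)
  expect_identical(a, b)
  expect_identical(generate_sensorgrams(cfg), generate_sensorgrams(cfg))
  expect_identical(generate_melt_curves(cfg), generate_melt_curves(cfg))
  expect_identical(generate_progress_curves(cfg, "atp"),
                   generate_progress_curves(cfg, "atp"))
  # a different seed perturbs the data
  expect_false(identical(a, generate_screen(sim_config(seed = 10,
                                                       screen = small))))
})

test_that("zero-noise artifact-free screen puts compound wells at mu_pos", {
  cfg <- sim_config(seed = 1, screen = list(
    n_plates = 2L, compounds_per_plate = 30L,
    sigma_well = 0, sigma_read = 0,
    drift = 0, beta_pos = 0, gamma = 0, n_fluor = 0L,
    hits = data.frame(position = integer(), fraction = numeric(),
                      retest_fraction = numeric(), quencher = logical())))
  plates <- generate_screen(cfg)
  wm <- do.call(rbind, lapply(plates, well_means))
  expect_equal(wm$mean_fp[wm$role == "compound"],
               rep(160, sum(wm$role == "compound")))
  expect_equal(wm$mean_fp[wm$role == "neg_control"],
               rep(40, sum(wm$role == "neg_control")))
})

test_that("screen layout and spiking respect the configuration", {
  cfg <- sim_config(seed = 4)
  plates <- generate_screen(cfg)
  expect_length(plates, 4L)
  for (pl in plates) {
    roles <- vapply(pl$wells, function(w) w$role, character(1))
    expect_equal(sum(roles == "pos_control"), 28L)
    expect_equal(sum(roles == "neg_control"), 28L)
    expect_equal(sum(roles == "compound"), 300L)
  }
  expect_error(
    generate_screen(sim_config(screen = list(compounds_per_plate = 400L))),
    class = "fpscreen_config_error")
})

test_that("empirical Z-factor converges to the analytic value with plates", {
  cfg_big <- sim_config(seed = 12, screen = list(n_plates = 40L))
  expect_equal(analytic_zprime(cfg_big), 0.57, tolerance = 1e-9)
  plates <- generate_screen(cfg_big)
  wm <- do.call(rbind, lapply(plates, well_means))
  emp <- z_factor(wm$mean_fp[wm$role == "pos_control"],
                  wm$mean_fp[wm$role == "neg_control"])
  expect_equal(emp, 0.57, tolerance = 0.03)
})

test_that("noiseless sensorgram generation delegates to the closed form", {
  cfg <- sim_config(seed = 2)
  sg <- generate_sensorgrams(cfg)
  p <- langmuir_params(cfg$spr$ka, cfg$spr$kd, cfg$spr$rmax)
  for (i in seq_along(sg)) {
    expect_equal(sg[[i]]$response,
                 langmuir_response(sg[[i]]$times, p, cfg$spr$conc[i], 180))
    expect_lte(max(sg[[i]]$response), cfg$spr$rmax)
  }
})

test_that("melt-curve generator round-trips the configured thermal shift", {
  cfg <- sim_config(seed = 2)
  mc <- generate_melt_curves(cfg)
  fit_of <- function(reps) {
    corr <- lapply(reps, subtract_background,
                   no_protein_control = mc$background)
    fit_boltzmann(average_melt_replicates(corr))
  }
  ref <- fit_of(mc$reference)
  expect_equal(ref$tm, cfg$dsf$tm_ref, tolerance = 1e-6)
  for (id in names(cfg$dsf$delta_tm)) {
    expect_equal(delta_tm(fit_of(mc$samples[[id]]), ref),
                 unname(cfg$dsf$delta_tm[[id]]), tolerance = 1e-4)
  }
})

test_that("noiseless generator output returns generating parameters end-to-end", {
  cfg <- sim_config(seed = 2)
  # SPR chain
  fit <- fit_langmuir(generate_sensorgrams(cfg))
  expect_equal(fit$ka, cfg$spr$ka, tolerance = 1e-4)
  expect_equal(fit$kd, cfg$spr$kd, tolerance = 1e-4)
  # kinase chain: basal well velocity equals the configured basal rate
  bas <- generate_progress_curves(cfg, "basal")
  sc <- build_standard_curve(bas$standard)
  corr <- correct_progress_curve(bas$curves$basal, bas$no_enzyme,
                                 bas$no_substrate, sc)
  expect_equal(estimate_velocity(corr)$v * cfg$kinetics$kinase_ng,
               7, tolerance = 1e-9)
  # zero-enzyme wells carry no net signal after correction
  zero <- correct_progress_curve(
    progress_curve(bas$no_substrate$times, bas$no_substrate$rfu, 1),
    bas$no_enzyme, bas$no_substrate, sc)
  expect_equal(zero$rfu, rep(0, length(zero$times)))
})
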