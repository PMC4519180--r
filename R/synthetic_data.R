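# Seeded generators for every input the pipeline consumes, with the
# statistical structure of the original screen: a 4-plate, 1200-compound
# FP screen with 28 positive and 28 negative control wells per plate,
# control separation tuned so the analytic pooled Z-factor is 0.57, five
# spiked inhibitors, one spiked quencher; 1:1 Langmuir sensorgrams (180 s
# association / 300 s dissociation); 25-99 degC melt curves; and 5-min
# interval, 3-h kinase progress curves with non-enzymatic and
# autophosphorylation backgrounds plus ADP standard-curve wells.
#
# Real screening data are never artifact-free, and the three hit rankings
# (raw FP, per-plate NPI, per-plate Z-score) only disagree on null
# compounds when plate-level artifacts are present -- on a homogeneous
# Gaussian library the three statistics are near-monotone transforms of
# one another and the >=2-of-3 rule degenerates to the plain top fraction.
# The default screen therefore carries the classic FP-screen artifacts:
# a small whole-plate drift, a placement bias on the positive-control
# block, a per-plate compound-dispense offset, and a handful of
# auto-fluorescent library compounds on two plates.  The within-plate
# control noise is then solved numerically so that the analytic pooled
# Z-factor (between-plate components included) is exactly the target.

#' Simulation configuration
#'
#' Bundles the generating parameters for every synthetic assay.  All
#' generators are pure functions of (configuration, seed).
#'
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @param screen,spr,dsf,kinetics Named lists overriding individual
#'   defaults of the corresponding section (see Details).
#'
#' @details
#' Screen section defaults: 4 plates x 300 compounds, 28 + 28 control
#' wells per plate, `mu_pos = 160` and `mu_neg = 40` mP (arbitrary levels;
#' only separation over noise is meaningful), triplicate reads with 2 mP
#' read noise, target pooled Z-factor 0.57, plate artifact vectors
#' (`drift`, `beta_pos`, `gamma`), 10 auto-fluorescent compounds on each
#' of plates 1-2, five spiked inhibitors (positions 3, 42, 142, 487, 551)
#' of which compound 3 is non-reproducible at retest and compound 487 is a
#' fluorescence quencher.
#'
#' SPR section defaults: `ka = 3.87e3` 1/M/s, `kd = 2.70e-2` 1/s,
#' `rmax = 100` RU, four analyte concentrations `kD * (1/3, 1, 3, 9)`,
#' 180 s association, 300 s dissociation, 1 s sampling, no noise.
#'
#' DSF section defaults: 25-99 degC at 0.5 degC steps, reference
#' `tm = 55` degC, `f_min = 100`, `f_max = 1000` AU, transition width
#' 1.5 degC, duplicate curves, a linear background, no noise.
#'
#' Kinetics section defaults: ATP Km 9.78 uM (substrate Km 144.65 uM),
#' 40 ng kinase per well, basal rate 7 pmol ADP/min at the Km-fixed
#' conditions, activator parameters Kact 0.4 uM / Vact 3.0 pmol/min
#' (compound 142) and Kact 1.02 uM / Vact 2.4 pmol/min (DPH), 0-180 min
#' at 5-min intervals, ADP standard curve 85 RFU/pmol with 120 RFU
#' intercept.
#'
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, screen = list(), spr = list(), dsf = list(),
                       kinetics = list()) {
  # like modifyList, but data-frame entries (hit tables etc.) are replaced
  # wholesale rather than merged column-wise
  merge_section <- function(defaults, override) {
    dfs <- names(override)[vapply(override, is.data.frame, logical(1))]
    out <- utils::modifyList(defaults, override[setdiff(names(override), dfs)])
    for (nm in dfs) out[[nm]] <- override[[nm]]
    out
  }
  scr <- merge_section(list(
    n_plates = 4L, compounds_per_plate = 300L, n_pos = 28L, n_neg = 28L,
    mu_pos = 160, mu_neg = 40, zprime = 0.57,
    sigma_read = 2, n_reads = 3L,
    drift = c(0, -10, 0, 0),      # whole-plate additive drift (mP)
    beta_pos = c(9, -9, 0, 0),    # positive-control placement bias (mP)
    gamma = c(0, -4, 4, 4),       # compound-dispense offset (mP)
    n_fluor = c(10L, 10L, 0L, 0L),  # auto-fluorescent compounds per plate
    fluor_range = c(50, 90),      # their FP artifact magnitude (mP)
    hits = data.frame(
      position = c(3L, 42L, 142L, 487L, 551L),
      fraction = c(0.85, 0.80, 0.90, 0.85, 0.75),
      retest_fraction = c(0, 0.80, 0.90, 0.85, 0.75),
      quencher = c(FALSE, FALSE, FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    quencher_fraction = 0.6,      # probe-only FP/intensity reduction
    probe_fp = 45, probe_fp_sd = 2,
    intensity_mean = 1000, intensity_sd = 25,
    n_retest = 4L, n_retest_dmso = 4L, n_counter_dmso = 8L
  ), screen)
  # an explicit sigma_well override (e.g. a zero-noise screen) bypasses the
  # Z-factor calibration
  if (is.null(scr$sigma_well)) scr$sigma_well <- solve_sigma_well(scr)
  spr_cfg <- merge_section(list(
    ka = 3.87e3, kd = 2.70e-2, rmax = 100,
    conc = NULL,                  # NULL -> kD * c(1/3, 1, 3, 9)
    t_assoc = 180, t_dissoc = 300, dt = 1, noise_ru = 0
  ), spr)
  if (is.null(spr_cfg$conc)) {
    spr_cfg$conc <- (spr_cfg$kd / spr_cfg$ka) * c(1 / 3, 1, 3, 9)
  }
  dsf_cfg <- merge_section(list(
    t_min = 25, t_max = 99, dt = 0.5,
    f_min = 100, f_max = 1000, tm_ref = 55, slope = 1.5,
    delta_tm = c("C0142" = -2.8, "C0042" = -1.2, "C0551" = -0.8),
    bg_base = 60, bg_rate = 0.8,  # linear background: base + rate * (T - 25)
    decay_rate = 0,               # post-peak aggregation decay (AU per degC)
    noise_frac = 0, n_rep = 2L
  ), dsf)
  kin <- merge_section(list(
    km_atp = 9.78, km_sub = 144.65,
    vmax_atp = 14,                # pmol/min at saturating ATP, substrate at Km
    kinase_ng = 40, basal_v = 7,  # pmol/min at both-Km conditions
    atp_conc = c(0.2, 0.5, 1, 2, 5, 10, 20, 50, 100, 200),
    activators = data.frame(
      id = c("C0142", "DPH"),
      k_act = c(0.4, 1.02), v_act = c(3.0, 2.4),
      stringsAsFactors = FALSE),
    act_conc = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100),
    t_max = 180, dt = 5,
    r_nonenzymatic = 0.3,         # pmol/min, no-kinase background
    r_autophos = 0.01,            # pmol/min/ng, no-substrate background
    sc_slope = 85, sc_intercept = 120,
    sc_pmol = seq(0, 50, by = 10),
    noise_rfu = 0, curvature_min = Inf  # finite -> saturating curves
  ), kinetics)
  structure(list(seed = as.integer(seed), screen = scr, spr = spr_cfg,
                 dsf = dsf_cfg, kinetics = kin),
            class = "sim_config")
}

# Within-plate control SD (per-well, after read averaging) such that the
# analytic pooled Z-factor, including the between-plate variance of the
# fixed plate effects, equals the target.
solve_sigma_well <- function(scr) {
  pos_means <- scr$beta_pos + scr$drift
  bp <- mean((pos_means - mean(pos_means))^2)
  bn <- mean((scr$drift - mean(scr$drift))^2)
  sep <- abs(scr$mu_pos - scr$mu_neg)
  need <- (1 - scr$zprime) * sep / 3
  if (need^2 <= bp + bn) {
    abort_config("plate effects alone exceed the control spread allowed by the target Z-factor")
  }
  f <- function(s) sqrt(s^2 + bp) + sqrt(s^2 + bn) - need
  sig_eff <- stats::uniroot(f, c(1e-9, sep), tol = 1e-12)$root
  within <- sig_eff^2 - scr$sigma_read^2 / scr$n_reads
  if (within <= 0) {
    abort_config("read noise alone exceeds the control spread allowed by the target Z-factor")
  }
  sqrt(within)
}

#' Analytic pooled Z-factor of a screen configuration
#'
#' The Z-factor implied by the generating distributions: control wells are
#' a mixture over plates of normals with fixed plate-effect means, so the
#' pooled SD per role combines the within-plate noise with the
#' between-plate variance of the plate effects.
#'
#' @param cfg A [sim_config()].
#' @return The analytic pooled Z-factor (0.57 under the defaults).
#' @export
analytic_zprime <- function(cfg) {
  scr <- cfg$screen
  sig_eff2 <- scr$sigma_well^2 + scr$sigma_read^2 / scr$n_reads
  pos_means <- scr$beta_pos + scr$drift
  sd_pos <- sqrt(sig_eff2 + mean((pos_means - mean(pos_means))^2))
  sd_neg <- sqrt(sig_eff2 + mean((scr$drift - mean(scr$drift))^2))
  1 - 3 * (sd_pos + sd_neg) / abs(scr$mu_pos - scr$mu_neg)
}

library_compound_ids <- function(n) sprintf("C%04d", seq_len(n))

# 384-well coordinates A1..P24, row-major
well_coords <- function(n) {
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  paste0(rows, cols)[seq_len(n)]
}

#' Generate a synthetic FP screen
#'
#' Produces the full plate set: per plate, 28 positive controls
#' (wild-type target + probe + DMSO, high FP), 28 negative controls
#' (non-binding mutant + probe + DMSO, low FP) and the compound wells, with
#' triplicate reads per well.  Spiked inhibitors pull their wells toward
#' the negative-control level by the configured fraction; auto-fluorescent
#' compounds add a positive FP artifact and raised intensity.
#' Deterministic under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List of [screen_plate()] objects.
#' @export
generate_screen <- function(cfg) {
  scr <- cfg$screen
  npp <- scr$compounds_per_plate
  n_compounds <- scr$n_plates * npp
  if (npp + scr$n_pos + scr$n_neg > 384L) {
    abort_config("layout exceeds 384 wells per plate")
  }
  if (any(scr$hits$position > n_compounds)) {
    abort_config("spiked hit position outside the library")
  }
  ids <- library_compound_ids(n_compounds)
  set.seed(cfg$seed)
  sep <- scr$mu_neg - scr$mu_pos
  pl_idx <- function(p, vec) vec[(p - 1L) %% length(vec) + 1L]
  plates <- vector("list", scr$n_plates)
  for (p in seq_len(scr$n_plates)) {
    idx <- (p - 1L) * npp + seq_len(npp)
    true_fp <- stats::rnorm(npp, scr$mu_pos, scr$sigma_well)
    true_int <- stats::rnorm(npp, scr$intensity_mean, scr$intensity_sd)
    # auto-fluorescent artifacts (never on spiked positions)
    nf <- pl_idx(p, scr$n_fluor)
    if (nf > 0L) {
      free <- which(!(idx %in% scr$hits$position))
      oi <- sample(free, nf)
      art <- stats::runif(nf, scr$fluor_range[1L], scr$fluor_range[2L])
      true_fp[oi] <- true_fp[oi] + art
      true_int[oi] <- true_int[oi] + 10 * art
    }
    # spiked inhibitors
    sp <- which(idx %in% scr$hits$position)
    if (length(sp)) {
      frac <- scr$hits$fraction[match(idx[sp], scr$hits$position)]
      true_fp[sp] <- stats::rnorm(length(sp), scr$mu_pos + frac * sep,
                                  scr$sigma_well)
    }
    obs_fp <- true_fp + pl_idx(p, scr$gamma) + pl_idx(p, scr$drift)
    pos_fp <- stats::rnorm(scr$n_pos,
                           scr$mu_pos + pl_idx(p, scr$beta_pos) + pl_idx(p, scr$drift),
                           scr$sigma_well)
    neg_fp <- stats::rnorm(scr$n_neg, scr$mu_neg + pl_idx(p, scr$drift),
                           scr$sigma_well)
    all_fp <- c(pos_fp, neg_fp, obs_fp)
    roles <- c(rep("pos_control", scr$n_pos), rep("neg_control", scr$n_neg),
               rep("compound", npp))
    cids <- c(rep(NA_character_, scr$n_pos + scr$n_neg), ids[idx])
    ints <- c(stats::rnorm(scr$n_pos + scr$n_neg, scr$intensity_mean,
                           scr$intensity_sd), true_int)
    coords <- well_coords(length(all_fp))
    wells <- vector("list", length(all_fp))
    for (w in seq_along(all_fp)) {
      reads <- all_fp[w] + stats::rnorm(scr$n_reads, 0, scr$sigma_read)
      iread <- ints[w] + stats::rnorm(scr$n_reads, 0, scr$intensity_sd / 10)
      wells[[w]] <- well_record(sprintf("P%02d", p), coords[w], roles[w],
                                reads, compound_id = cids[w],
                                intensity_reads = iread)
    }
    plates[[p]] <- screen_plate(sprintf("P%02d", p), wells,
                                layout_spec = c(pos_control = scr$n_pos,
                                                neg_control = scr$n_neg))
  }
  plates
}

#' Generate quadruplicate retest data for raw hits
#'
#' Retests each compound under screening conditions against same-plate
#' DMSO control wells.  Reproducible hits keep their screen effect
#' (`retest_fraction`); a non-reproducible screen artifact retests at the
#' control level.
#'
#' @param cfg A [sim_config()].
#' @param compound_ids Character vector of compounds to retest.
#' @return List with elements `retest` (data frame `compound_id`, `fp`) and
#'   `dmso` (numeric control FP values).
#' @export
generate_retest <- function(cfg, compound_ids) {
  scr <- cfg$screen
  set.seed(cfg$seed + 1L)
  sep <- scr$mu_neg - scr$mu_pos
  ids_all <- library_compound_ids(scr$n_plates * scr$compounds_per_plate)
  hit_ids <- ids_all[scr$hits$position]
  rows <- lapply(compound_ids, function(id) {
    frac <- if (id %in% hit_ids) {
      scr$hits$retest_fraction[match(id, hit_ids)]
    } else 0
    data.frame(compound_id = id,
               fp = stats::rnorm(scr$n_retest, scr$mu_pos + frac * sep,
                                 scr$sigma_well),
               stringsAsFactors = FALSE)
  })
  list(retest = do.call(rbind, rows),
       dmso = stats::rnorm(scr$n_retest_dmso, scr$mu_pos, scr$sigma_well))
}

#' Generate probe-only counter-screen data
#'
#' Probe-only wells (no target protein) for each compound and for DMSO.  A
#' spiked quencher reduces both the baseline probe FP and the total
#' fluorescence intensity by the configured fraction.
#'
#' @param cfg A [sim_config()].
#' @param compound_ids Compounds to counter-screen.
#' @return List with data frames `compound` (`compound_id`, `fp`,
#'   `intensity`) and `dmso` (`fp`, `intensity`).
#' @export
generate_counter_screen <- function(cfg, compound_ids) {
  scr <- cfg$screen
  set.seed(cfg$seed + 2L)
  ids_all <- library_compound_ids(scr$n_plates * scr$compounds_per_plate)
  quencher_ids <- ids_all[scr$hits$position[scr$hits$quencher]]
  rows <- lapply(compound_ids, function(id) {
    f <- if (id %in% quencher_ids) 1 - cfg$screen$quencher_fraction else 1
    data.frame(compound_id = id,
               fp = stats::rnorm(scr$n_retest, scr$probe_fp * f, scr$probe_fp_sd),
               intensity = stats::rnorm(scr$n_retest, scr$intensity_mean * f,
                                        scr$intensity_sd),
               stringsAsFactors = FALSE)
  })
  list(compound = do.call(rbind, rows),
       dmso = data.frame(
         fp = stats::rnorm(scr$n_counter_dmso, scr$probe_fp, scr$probe_fp_sd),
         intensity = stats::rnorm(scr$n_counter_dmso, scr$intensity_mean,
                                  scr$intensity_sd)))
}

#' Generate 1:1 Langmuir sensorgrams
#'
#' Closed-form association/dissociation curves at the configured analyte
#' concentrations, with optional Gaussian RU noise.
#'
#' @param cfg A [sim_config()].
#' @return List of `"sensorgram"` objects (one per concentration).
#' @export
generate_sensorgrams <- function(cfg) {
  sp <- cfg$spr
  set.seed(cfg$seed + 3L)
  params <- langmuir_params(sp$ka, sp$kd, sp$rmax)
  times <- seq(0, sp$t_assoc + sp$t_dissoc, by = sp$dt)
  lapply(sp$conc, function(cc) {
    simulate_sensorgram(params, cc, sp$t_assoc, times, noise_ru = sp$noise_ru)
  })
}

#' Generate DSF melt curves
#'
#' Boltzmann melt curves on the configured temperature grid for the DMSO
#' reference and for each compound with a configured thermal shift, plus a
#' shared no-protein background curve; duplicate replicates with optional
#' multiplicative noise.
#'
#' @param cfg A [sim_config()].
#' @param compounds Compound ids to simulate (default: those with
#'   configured shifts).
#' @return List with elements `reference` (list of replicate raw
#'   [melt_curve()]s), `samples` (named list of replicate lists), and
#'   `background` (no-protein control curve).
#' @export
generate_melt_curves <- function(cfg, compounds = names(cfg$dsf$delta_tm)) {
  dc <- cfg$dsf
  set.seed(cfg$seed + 4L)
  tt <- seq(dc$t_min, dc$t_max, by = dc$dt)
  bg <- dc$bg_base + dc$bg_rate * (tt - dc$t_min)
  make <- function(tm, rep_id) {
    f <- boltzmann(tt, dc$f_min, dc$f_max, tm, dc$slope)
    if (dc$decay_rate > 0) {
      over <- tt > tm + 8 * dc$slope
      f[over] <- f[over] - dc$decay_rate * (tt[over] - (tm + 8 * dc$slope))
    }
    f <- f + bg
    if (dc$noise_frac > 0) {
      f <- f * (1 + stats::rnorm(length(f), 0, dc$noise_frac))
    }
    melt_curve(tt, f, replicate_id = rep_id)
  }
  reference <- lapply(seq_len(dc$n_rep), function(r) make(dc$tm_ref, paste0("ref_", r)))
  samples <- lapply(compounds, function(id) {
    shift <- if (id %in% names(dc$delta_tm)) dc$delta_tm[[id]] else 0
    lapply(seq_len(dc$n_rep), function(r) make(dc$tm_ref + shift, paste0(id, "_", r)))
  })
  names(samples) <- compounds
  list(reference = reference, samples = samples,
       background = melt_curve(tt, bg, replicate_id = "background"))
}

# Noise-free total RFU trajectory of a well producing ADP at rate
# v_enz (pmol/min, whole well) on top of the backgrounds.
kin_rfu <- function(kin, times, v_enz, ng, with_substrate = TRUE) {
  pmol_enz <- if (is.finite(kin$curvature_min)) {
    v_enz * kin$curvature_min * (1 - exp(-times / kin$curvature_min))
  } else v_enz * times
  pmol_bg <- kin$r_nonenzymatic * times
  pmol_auto <- if (ng > 0) kin$r_autophos * ng * times else 0
  pmol <- pmol_bg + pmol_auto + if (with_substrate) pmol_enz else 0
  kin$sc_intercept + kin$sc_slope * pmol
}

#' Generate kinase progress curves
#'
#' Produces, for a chosen experiment, the enzyme-well progress curves plus
#' the shared no-enzyme and no-substrate control curves and the ADP
#' standard-curve points, all on the configured time grid.
#'
#' * `mode = "atp"`: ATP titration at the configured concentrations with
#'   the peptide substrate fixed at its Km; velocities follow
#'   Michaelis-Menten kinetics in ATP.
#' * `mode = "activation"`: activator titration with both substrates fixed
#'   at their Km values; whole-well velocities follow
#'   `basal_v + Vact L / (Kact + L)` for the chosen activator.
#' * `mode = "basal"`: a single well at the basal rate.
#'
#' @param cfg A [sim_config()].
#' @param mode One of `"atp"`, `"activation"`, `"basal"`.
#' @param activator Activator id (for `mode = "activation"`).
#' @return List with `curves` (named list of [progress_curve()]s),
#'   `no_enzyme`, `no_substrate` (control curves), `standard` (data frame
#'   of standard-curve points) and `conc` (the titrated concentrations,
#'   where applicable).
#' @export
generate_progress_curves <- function(cfg, mode = c("atp", "activation", "basal"),
                                     activator = "C0142") {
  mode <- match.arg(mode)
  kin <- cfg$kinetics
  set.seed(cfg$seed + 5L)
  times <- seq(0, kin$t_max, by = kin$dt)
  ng <- kin$kinase_ng
  noise <- function(x) if (kin$noise_rfu > 0)
    x + stats::rnorm(length(x), 0, kin$noise_rfu) else x
  conc <- switch(mode,
                 atp = kin$atp_conc,
                 activation = kin$act_conc,
                 basal = numeric())
  vels <- switch(mode,
    atp = kin$vmax_atp * conc / (kin$km_atp + conc),
    activation = {
      a <- kin$activators[kin$activators$id == activator, , drop = FALSE]
      if (nrow(a) != 1L) abort_config(sprintf("unknown activator: %s", activator))
      kin$basal_v + a$v_act * conc / (a$k_act + conc)
    },
    basal = kin$basal_v)
  labels <- if (mode == "basal") "basal" else sprintf("%s_%g", mode, conc)
  curves <- lapply(seq_along(vels), function(i) {
    cond <- if (mode == "basal") list() else
      stats::setNames(list(conc[i]), if (mode == "atp") "atp_uM" else "activator_uM")
    progress_curve(times, noise(kin_rfu(kin, times, vels[i], ng)), ng, cond)
  })
  names(curves) <- labels
  no_enzyme <- progress_curve(times, noise(kin_rfu(kin, times, 0, 0)), 0)
  no_substrate <- progress_curve(
    times, noise(kin_rfu(kin, times, 0, ng, with_substrate = FALSE)), ng)
  standard <- data.frame(
    pmol = kin$sc_pmol,
    rfu = noise(kin$sc_intercept + kin$sc_slope * kin$sc_pmol))
  list(curves = curves, no_enzyme = no_enzyme, no_substrate = no_substrate,
       standard = standard, conc = conc)
}
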