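# End-to-end orchestration of the screen -> confirm -> counter-screen flow
# and of the secondary-assay characterization of advanced hits.

#' Run the full screen pipeline
#'
#' Generates (or accepts) the screen plates, scores every compound, applies
#' the three-ranking hit-selection rule, confirms raw hits against DMSO
#' controls in a quadruplicate retest, counter-screens confirmed hits for
#' fluorescence quenching, and assembles the QC summary (per-plate and
#' pooled Z-factors).  Optionally writes `scores.csv`, `hits.csv`,
#' `qc.json` and `run.log` to `out_dir`.
#'
#' @param cfg A [sim_config()]; its seed drives all generated data.
#' @param plates Optional list of [screen_plate()]s to analyse instead of
#'   generating them from `cfg` (retest and counter-screen data are still
#'   generated from `cfg`).
#' @param top_fraction,min_rankings Hit-selection thresholds (see
#'   [select_hits()]).
#' @param alpha,sigma_cut Confirmation thresholds (see [confirm_hits()]).
#' @param out_dir Optional output directory.
#' @return List with `scores` (ranked compound table), `raw_hits`,
#'   `confirmation` (per-compound test results), `counter`
#'   (quencher flags), `advanced` (compound ids past all stages), `qc`
#'   (per-plate and pooled Z-factors), and `hit_report` (one row per raw
#'   hit with all stage outcomes).
#' @export
run_screen_pipeline <- function(cfg = sim_config(), plates = NULL,
                                top_fraction = 0.01, min_rankings = 2L,
                                alpha = 0.05, sigma_cut = 3,
                                out_dir = NULL) {
  if (is.null(plates)) plates <- generate_screen(cfg)
  scores <- rank_compound_scores(score_compounds(plates),
                                 top_fraction = top_fraction,
                                 min_rankings = min_rankings)
  raw_hits <- sort(scores$compound_id[scores$raw_hit])

  per_plate_z <- vapply(plates, function(pl) {
    wm <- well_means(pl)
    z_factor(wm$mean_fp[wm$role == "pos_control"],
             wm$mean_fp[wm$role == "neg_control"])
  }, numeric(1))
  names(per_plate_z) <- vapply(plates, function(pl) pl$plate_id, character(1))
  all_wm <- do.call(rbind, lapply(plates, well_means))
  pooled_z <- z_factor(all_wm$mean_fp[all_wm$role == "pos_control"],
                       all_wm$mean_fp[all_wm$role == "neg_control"])
  qc <- list(per_plate_zfactor = as.list(per_plate_z),
             pooled_zfactor = pooled_z,
             n_compounds = nrow(scores), n_raw_hits = length(raw_hits))

  confirmation <- if (length(raw_hits)) {
    rt <- generate_retest(cfg, raw_hits)
    confirm_hits(rt$retest, rt$dmso, alpha = alpha, sigma_cut = sigma_cut)
  } else {
    data.frame(compound_id = character(), p_value = numeric(),
               sigma_delta = numeric(), confirmed = logical())
  }
  confirmed <- confirmation$compound_id[confirmation$confirmed]

  counter <- if (length(confirmed)) {
    cs <- generate_counter_screen(cfg, confirmed)
    counter_screen(cs$compound, cs$dmso, sigma_cut = sigma_cut)
  } else {
    data.frame(compound_id = character(), fp_flag = logical(),
               intensity_flag = logical(), quencher_flagged = logical())
  }
  advanced <- sort(setdiff(confirmed,
                           counter$compound_id[counter$quencher_flagged]))

  hit_report <- if (length(raw_hits)) {
    rep <- scores[match(raw_hits, scores$compound_id),
                  c("compound_id", "plate_id", "mean_fp", "npi", "z_score",
                    "rank_fp", "rank_npi", "rank_z", "rankings_hit_count")]
    rep$raw_hit <- TRUE
    rep$confirmed <- raw_hits %in% confirmed
    rep$quencher_flagged <- raw_hits %in%
      counter$compound_id[counter$quencher_flagged]
    rep$advanced <- raw_hits %in% advanced
    rownames(rep) <- NULL
    rep
  } else {
    data.frame(compound_id = character())
  }

  result <- list(scores = scores, raw_hits = raw_hits,
                 confirmation = confirmation, counter = counter,
                 advanced = advanced, qc = qc, hit_report = hit_report)
  if (!is.null(out_dir)) write_pipeline_outputs(result, cfg, out_dir,
                                                top_fraction, min_rankings,
                                                alpha, sigma_cut)
  result
}

write_pipeline_outputs <- function(result, cfg, out_dir, top_fraction,
                                   min_rankings, alpha, sigma_cut) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$hit_report, file.path(out_dir, "hits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    format(Sys.time(), "%Y-%m-%d %H:%M:%S run_screen_pipeline"),
    sprintf("seed=%d", cfg$seed),
    sprintf("top_fraction=%g min_rankings=%d alpha=%g sigma_cut=%g",
            top_fraction, min_rankings, alpha, sigma_cut),
    sprintf("pooled_zfactor=%.4f", result$qc$pooled_zfactor),
    sprintf("plate_zfactor %s=%.4f", names(result$qc$per_plate_zfactor),
            unlist(result$qc$per_plate_zfactor)),
    sprintf("raw_hits=%s", paste(result$raw_hits, collapse = ",")),
    sprintf("advanced=%s", paste(result$advanced, collapse = ",")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Characterize hit compounds with the secondary assays
#'
#' Reduces, per compound, whichever assay bundles are present: DSF melt
#' curves to a thermal shift, SPR sensorgrams to 1:1 Langmuir kinetics,
#' an ATP titration to a Michaelis constant, and an activator titration to
#' the saturation constant K_act and the dose-response EC50.  Missing
#' assays are reported as `NA`, not errors.
#'
#' @param bundles Named list (one element per compound); each element may
#'   contain:
#'   * `melt`: list with `sample` and `reference` replicate curve lists and
#'     a `background` curve (as produced by [generate_melt_curves()]),
#'   * `sensorgrams`: list of `"sensorgram"` objects,
#'   * `atp`: output of [generate_progress_curves()] in `"atp"` mode,
#'   * `activation`: output of [generate_progress_curves()] in
#'     `"activation"` mode plus an element `basal_v`.
#' @param out_dir Optional directory; writes `characterization.csv`.
#' @return Data frame with one row per compound: `compound_id`,
#'   `delta_tm_c`, `ka`, `kd`, `kD`, `km_atp_uM`, `k_act_uM`, `ec50_uM`.
#' @export
run_characterization <- function(bundles, out_dir = NULL) {
  rows <- lapply(names(bundles), function(id) {
    b <- bundles[[id]]
    out <- data.frame(compound_id = id, delta_tm_c = NA_real_, ka = NA_real_,
                      kd = NA_real_, kD = NA_real_, km_atp_uM = NA_real_,
                      k_act_uM = NA_real_, ec50_uM = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(b$melt)) {
      fit_of <- function(reps, bg) {
        corrected <- lapply(reps, subtract_background, no_protein_control = bg)
        fit_boltzmann(average_melt_replicates(corrected))
      }
      out$delta_tm_c <- delta_tm(fit_of(b$melt$sample, b$melt$background),
                                 fit_of(b$melt$reference, b$melt$background))
    }
    if (!is.null(b$sensorgrams)) {
      lp <- fit_langmuir(b$sensorgrams)
      out$ka <- lp$ka; out$kd <- lp$kd; out$kD <- lp$kD
    }
    if (!is.null(b$atp)) {
      vel <- reduce_to_velocities(b$atp)
      out$km_atp_uM <- fit_michaelis_menten(vel)$km
    }
    if (!is.null(b$activation)) {
      vel <- reduce_to_velocities(b$activation)
      out$k_act_uM <- fit_activation(vel, basal_v = b$activation$basal_v)$k_act
      out$ec50_uM <- fit_ec50(vel)$ec50
    }
    out
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "characterization.csv"),
                     row.names = FALSE)
  }
  report
}

#' Reduce a progress-curve experiment to per-condition velocities
#'
#' Applies the full reduction chain to each enzyme well: standard curve,
#' background corrections, per-ng normalization, linear-window velocity;
#' velocities are returned on the whole-well scale (pmol ADP per minute,
#' i.e. the per-ng velocity times the kinase amount) so they are directly
#' comparable to the basal rate.
#'
#' @param gen Output of [generate_progress_curves()] (or a list with the
#'   same shape).
#' @return Data frame with columns `conc` and `v`.
#' @export
reduce_to_velocities <- function(gen) {
  sc <- build_standard_curve(gen$standard)
  v <- vapply(gen$curves, function(cur) {
    corrected <- correct_progress_curve(cur, gen$no_enzyme, gen$no_substrate, sc)
    estimate_velocity(corrected)$v * cur$kinase_ng
  }, numeric(1))
  data.frame(conc = gen$conc, v = unname(v))
}
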