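# Plate QC, compound scoring, the three-ranking hit-selection rule,
# retest confirmation and the fluorescence-quencher counter-screen.
#
# Scoring conventions (inhibitor screen; positive controls give the high FP
# signal, negative controls the low one):
#   NPI      = (sample FP - mean FP_pos) / (mean FP_neg - mean FP_pos) * 100
#              so NPI = 0 at the positive-control mean and 100 at the
#              negative-control mean; strong inhibitors score high.
#   Z-score  = (sample FP - mean FP_samples) / sd FP_samples, computed per
#              plate over that plate's compound wells; strong inhibitors
#              score very negative.
#   Z-factor = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|.

#' Z-factor (Z') of an assay from control wells
#'
#' Screen-quality metric computed from positive- and negative-control well
#' values: `1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' standard deviations.  Values of 0.5 and above indicate a robust
#' screening assay.
#'
#' @param pos_values,neg_values Numeric vectors (mP) of per-well averaged FP
#'   for the two control roles; at least two wells each.
#' @return The Z-factor (dimensionless, at most 1).
#' @export
z_factor <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L) {
    abort_replicates("z_factor needs at least 2 wells per control role")
  }
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n) {
    abort_degenerate("control means are equal; Z-factor is undefined")
  }
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / abs(mu_p - mu_n)
}

#' Control-normalized percent inhibition (NPI)
#'
#' Affine rescaling of a well's FP value to the plate's controls: 0 percent
#' at the positive-control mean (intact probe binding) and 100 percent at
#' the negative-control mean (no binding).
#'
#' @param x FP value(s) in mP.
#' @param summary A [summarize_plate()] result, or any list with elements
#'   `mean_pos` and `mean_neg`.
#' @return NPI in percent (vectorized over `x`).
#' @export
normalized_percent_inhibition <- function(x, summary) {
  mu_p <- summary$mean_pos; mu_n <- summary$mean_neg
  if (isTRUE(all.equal(mu_p, mu_n)) || mu_p == mu_n) {
    abort_degenerate("positive and negative control means are equal")
  }
  (x - mu_p) / (mu_n - mu_p) * 100
}

#' Z-score of a well against the compound-well population
#'
#' Control-independent standardization: `(x - mean(samples)) / sd(samples)`
#' with the sample standard deviation.
#'
#' @param x FP value(s) in mP.
#' @param sample_values FP values of the compound-well population the score
#'   is taken against (at least two, with positive spread).
#' @return Dimensionless Z-score (vectorized over `x`).
#' @export
z_score <- function(x, sample_values) {
  if (length(sample_values) < 2L) {
    abort_replicates("z_score needs at least 2 sample values")
  }
  s <- stats::sd(sample_values)
  if (s == 0) abort_degenerate("sample standard deviation is zero")
  (x - mean(sample_values)) / s
}

#' Score every compound well of a screen
#'
#' Computes, for each compound well, the averaged FP signal, the
#' control-normalized percent inhibition against its own plate's controls,
#' and the Z-score against its own plate's compound-well population.
#'
#' @param plates A list of [screen_plate()] objects (or a single plate).
#' @return A data frame with columns `compound_id`, `plate_id`, `well`,
#'   `mean_fp`, `npi`, `z_score`.
#' @export
score_compounds <- function(plates) {
  if (inherits(plates, "screen_plate")) plates <- list(plates)
  out <- lapply(plates, function(pl) {
    wm <- well_means(pl)
    cmp <- wm[wm$role == "compound", , drop = FALSE]
    if (nrow(cmp) == 0L) return(NULL)
    ps <- summarize_plate(pl)
    data.frame(compound_id = cmp$compound_id, plate_id = cmp$plate_id,
               well = cmp$well, mean_fp = cmp$mean_fp,
               npi = normalized_percent_inhibition(cmp$mean_fp, ps),
               z_score = z_score(cmp$mean_fp, cmp$mean_fp),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank compounds on the three screen statistics
#'
#' Ranks the scored compounds screen-wide in order of increasing FP signal,
#' decreasing normalized percent inhibition, and increasing Z-score (rank 1
#' = most inhibitor-like in each ranking).  Ties are broken
#' deterministically by `compound_id`, so the result is invariant under
#' permutation of the input rows.
#'
#' @param scores Output of [score_compounds()].
#' @param top_fraction Fraction of compounds selected per ranking; the top
#'   `ceiling(top_fraction * N)` compounds of each ranking count as selected.
#' @param min_rankings Number of rankings a compound must be selected in to
#'   be called a raw hit.
#' @return `scores` with added columns `rank_fp`, `rank_npi`, `rank_z`,
#'   `rankings_hit_count` (0-3) and `raw_hit`.
#' @export
rank_compound_scores <- function(scores, top_fraction = 0.01, min_rankings = 2L) {
  stopifnot(nrow(scores) > 0L, top_fraction > 0, top_fraction <= 1)
  n <- nrow(scores)
  cutoff <- ceiling(top_fraction * n)
  pos_rank <- function(ord) { r <- integer(n); r[ord] <- seq_len(n); r }
  scores$rank_fp  <- pos_rank(order(scores$mean_fp, scores$compound_id))
  scores$rank_npi <- pos_rank(order(-scores$npi, scores$compound_id))
  scores$rank_z   <- pos_rank(order(scores$z_score, scores$compound_id))
  scores$rankings_hit_count <- (scores$rank_fp <= cutoff) +
    (scores$rank_npi <= cutoff) + (scores$rank_z <= cutoff)
  scores$raw_hit <- scores$rankings_hit_count >= min_rankings
  scores
}

#' Select raw hits by the three-ranking rule
#'
#' A compound is a raw hit when it falls in the selected top fraction of at
#' least `min_rankings` of the three rankings (FP signal, NPI, Z-score).
#'
#' @inheritParams rank_compound_scores
#' @return Character vector of raw-hit compound ids, sorted.
#' @export
select_hits <- function(scores, top_fraction = 0.01, min_rankings = 2L) {
  ranked <- rank_compound_scores(scores, top_fraction, min_rankings)
  sort(ranked$compound_id[ranked$raw_hit])
}

#' Confirm raw hits against DMSO controls
#'
#' Each raw hit is retested in replicate wells under screening conditions
#' and compared with same-plate DMSO control wells.  A compound is
#' confirmed when a two-tailed Welch t-test rejects equality at `alpha`
#' AND its mean FP lies at least `sigma_cut` control standard deviations
#' below the control mean.
#'
#' @param retest Data frame with columns `compound_id` and `fp` (one row per
#'   retest well), or a named list of numeric vectors.
#' @param dmso_controls Numeric vector of DMSO control FP values.
#' @param alpha Significance level of the t-test.
#' @param sigma_cut Control-SD multiple for the effect-size requirement.
#' @return A data frame with one row per compound: `compound_id`,
#'   `p_value`, `sigma_delta` (mean difference in control-SD units; negative
#'   means inhibition) and `confirmed`.
#' @export
confirm_hits <- function(retest, dmso_controls, alpha = 0.05, sigma_cut = 3) {
  if (is.data.frame(retest)) {
    retest <- split(retest$fp, retest$compound_id)
  }
  if (length(dmso_controls) < 2L) {
    abort_replicates("need at least 2 DMSO control replicates")
  }
  bad <- names(retest)[vapply(retest, length, integer(1)) < 2L]
  if (length(bad)) {
    abort_replicates(sprintf("fewer than 2 retest replicates for: %s",
                             paste(bad, collapse = ", ")))
  }
  mu_c <- mean(dmso_controls); sd_c <- stats::sd(dmso_controls)
  rows <- lapply(names(retest), function(id) {
    v <- retest[[id]]
    p <- if (stats::sd(v) == 0 && sd_c == 0 && mean(v) == mu_c) 1
         else stats::t.test(v, dmso_controls, alternative = "two.sided")$p.value
    sig <- if (sd_c > 0) (mean(v) - mu_c) / sd_c else ifelse(mean(v) == mu_c, 0, -Inf)
    data.frame(compound_id = id, p_value = p, sigma_delta = sig,
               confirmed = p < alpha && sig <= -sigma_cut,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$compound_id), , drop = FALSE]
}

#' Counter-screen for fluorescence quenchers
#'
#' Confirmed hits are retested in probe-only wells (no target protein).  A
#' compound that lowers the probe-only FP signal or the total fluorescence
#' intensity beyond `sigma_cut` standard deviations of the DMSO probe-only
#' wells is acting on the fluorophore rather than on the binding
#' interaction, and is flagged as a quencher.
#'
#' @param probe_only_with_compound Data frame with columns `compound_id`,
#'   `fp` and `intensity` (one row per well).
#' @param probe_only_dmso Data frame with columns `fp` and `intensity` for
#'   the DMSO probe-only wells (at least two rows).
#' @param sigma_cut Standard-deviation multiple defining the flag band.
#' @return A data frame with one row per compound: `compound_id`,
#'   `fp_flag`, `intensity_flag`, `quencher_flagged`.
#' @export
counter_screen <- function(probe_only_with_compound, probe_only_dmso,
                           sigma_cut = 3) {
  if (nrow(probe_only_dmso) < 2L) {
    abort_replicates("need at least 2 DMSO probe-only wells")
  }
  split_rows <- split(probe_only_with_compound,
                      probe_only_with_compound$compound_id)
  if (any(vapply(split_rows, nrow, integer(1)) < 2L)) {
    abort_replicates("need at least 2 probe-only wells per compound")
  }
  fp_cut <- mean(probe_only_dmso$fp) - sigma_cut * stats::sd(probe_only_dmso$fp)
  int_cut <- mean(probe_only_dmso$intensity) -
    sigma_cut * stats::sd(probe_only_dmso$intensity)
  rows <- lapply(names(split_rows), function(id) {
    v <- split_rows[[id]]
    fp_flag <- mean(v$fp) < fp_cut
    int_flag <- mean(v$intensity) < int_cut
    data.frame(compound_id = id, fp_flag = fp_flag, intensity_flag = int_flag,
               quencher_flagged = fp_flag || int_flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$compound_id), , drop = FALSE]
}
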