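# Shared fixtures and independent oracles, built in code.

# Minimal plate: n_pos/n_neg control wells at fixed levels plus optional
# compound wells given as a named vector of mean FP values.
toy_plate <- function(plate_id = "P1", pos = c(100, 100), neg = c(200, 200),
                      compounds = numeric()) {
  wells <- list()
  k <- 0L
  add <- function(role, fp, cid = NA_character_) {
    k <<- k + 1L
    wells[[k]] <<- well_record(plate_id, well_coord(k), role, fp,
                               compound_id = cid)
  }
  for (v in pos) add("pos_control", v)
  for (v in neg) add("neg_control", v)
  for (i in seq_along(compounds)) {
    add("compound", compounds[[i]], cid = names(compounds)[i])
  }
  screen_plate(plate_id, wells)
}

well_coord <- function(i) paste0(LETTERS[(i - 1) %/% 24 + 1], (i - 1) %% 24 + 1)

# Independent brute-force oracle for the three-ranking hit rule:
# explicitly sort three copies of the table, slice the top, and count
# memberships.
oracle_select_hits <- function(tab, top_fraction, min_rankings) {
  n <- nrow(tab)
  cut <- ceiling(top_fraction * n)
  by_fp  <- tab[order(tab$mean_fp, tab$compound_id), "compound_id"][seq_len(cut)]
  by_npi <- tab[order(-tab$npi, tab$compound_id), "compound_id"][seq_len(cut)]
  by_z   <- tab[order(tab$z_score, tab$compound_id), "compound_id"][seq_len(cut)]
  counts <- vapply(tab$compound_id, function(id) {
    sum(id %in% by_fp, id %in% by_npi, id %in% by_z)
  }, numeric(1))
  sort(tab$compound_id[counts >= min_rankings])
}

random_score_table <- function(n, tie_prob = 0.3) {
  vals <- function() {
    v <- round(stats::rnorm(n, 100, 15), 1)
    if (stats::runif(1) < tie_prob) v[sample(n, 2)] <- v[1]  # force ties
    v
  }
  data.frame(compound_id = sprintf("K%03d", sample(999, n)),
             mean_fp = vals(), npi = vals(), z_score = vals(),
             stringsAsFactors = FALSE)
}

# Noiseless Boltzmann melt curve on the default DSF grid.
toy_melt <- function(f_min = 100, f_max = 1000, tm = 55, slope = 1.5,
                     t_min = 25, t_max = 99, dt = 0.5) {
  tt <- seq(t_min, t_max, by = dt)
  melt_curve(tt, boltzmann(tt, f_min, f_max, tm, slope))
}
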