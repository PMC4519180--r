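#!/usr/bin/env Rscript
# Stage 2: plate QC, compound scoring and hit triage.
#
# Reads the simulated plate table back from disk, scores every compound
# (mean FP, control-normalized percent inhibition, per-plate Z-score),
# applies the top-1% / >=2-of-3-rankings rule, confirms raw hits in a
# quadruplicate retest (two-tailed Welch t-test at alpha = 0.05 plus a
# -3 sigma effect requirement) and counter-screens confirmed hits for
# fluorescence quenching.

library(fpscreen)

cfg <- sim_config(seed = 42L)
plates <- read_plate_table("results/plates.csv")

res <- run_screen_pipeline(cfg, plates = plates, out_dir = "results")

cat(sprintf("pooled Z-factor: %.3f (per plate: %s)\n", res$qc$pooled_zfactor,
            paste(sprintf("%.2f", unlist(res$qc$per_plate_zfactor)),
                  collapse = ", ")))
cat(sprintf("raw hits (%d): %s\n", length(res$raw_hits),
            paste(res$raw_hits, collapse = ", ")))
conf <- res$confirmation
for (i in seq_len(nrow(conf))) {
  cat(sprintf("  %s: p = %.2g, effect = %+.1f sigma -> %s\n",
              conf$compound_id[i], conf$p_value[i], conf$sigma_delta[i],
              ifelse(conf$confirmed[i], "confirmed", "not confirmed")))
}
cat(sprintf("quencher-flagged: %s\n",
            paste(res$counter$compound_id[res$counter$quencher_flagged],
                  collapse = ", ")))
cat(sprintf("advanced to secondary assays (%d): %s\n", length(res$advanced),
            paste(res$advanced, collapse = ", ")))
cat("wrote results/scores.csv, results/hits.csv, results/qc.json, results/run.log\n")
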