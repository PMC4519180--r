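#!/usr/bin/env Rscript
# Stage 1: simulate the pilot screen.
#
# Generates the 4-plate, 1200-compound FP screen (28 positive + 28 negative
# control wells per plate, triplicate reads, five spiked inhibitors, one
# spiked quencher) and writes the raw long-format plate table that the
# scoring stage consumes.

library(fpscreen)

seed <- 42L
cfg <- sim_config(seed = seed)
dir.create("results", showWarnings = FALSE)

cat(sprintf("screen layout: %d plates x (%d compounds + %d pos + %d neg controls)\n",
            cfg$screen$n_plates, cfg$screen$compounds_per_plate,
            cfg$screen$n_pos, cfg$screen$n_neg))
cat(sprintf("control separation %g mP, within-plate well SD %.2f mP\n",
            cfg$screen$mu_pos - cfg$screen$mu_neg, cfg$screen$sigma_well))
cat(sprintf("analytic pooled Z-factor of the generating process: %.4f\n",
            analytic_zprime(cfg)))

plates <- generate_screen(cfg)
write_plate_table(plates, "results/plates.csv")
cat(sprintf("wrote results/plates.csv (%d wells, seed %d)\n",
            sum(vapply(plates, function(p) length(p$wells), integer(1))), seed))
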