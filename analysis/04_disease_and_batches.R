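#!/usr/bin/env Rscript
# Stage 4: disease separation and batch resilience of the noise curve.
#
# Compares healthy and disease cohorts sharing one young normalizer (the
# disease curve should sit above the healthy one across most age bins),
# then checks how far individual batches deviate from the across-batch
# median curve.

suppressMessages(library(methnoise))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- run_config("results/04_disease", seed = seed,
                  sim = simulation_config(n_probes = 600, n_samples = 400,
                                          seed = seed))
run_experiment(cfg, "barometer_disease")
diffs <- utils::read.csv("results/04_disease/cohort_difference.csv")
cat(sprintf("disease curve above healthy in %.0f%% of %d shared bins\n",
            100 * mean(diffs$delta > 0), nrow(diffs)))

cfgb <- run_config("results/04_batches", seed = seed,
                   sim = simulation_config(n_probes = 600, n_samples = 400,
                                           seed = seed),
                   n_datasets = 3)
run_experiment(cfgb, "batch_test")
dev <- utils::read.csv("results/04_batches/batch_deviations.csv")
cat(sprintf("batch test (3 batches): median |deviation| %.3f, max %.3f\n",
            median(dev$deviation), max(dev$deviation)))
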