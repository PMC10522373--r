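#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohorts.
#
# Emits a healthy and a disease cohort drawn from the same probe ground
# truth (drift, quiet-invariant, noisy-invariant and boundary probes), plus
# the truth table that later stages score recovery against.

suppressMessages(library(methnoise))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- run_config("results/01_cohorts", seed = seed,
                  sim = simulation_config(n_probes = 1000, n_samples = 400,
                                          seed = seed))
manifest <- run_experiment(cfg, "simulation_suite")

truth <- utils::read.csv("results/01_cohorts/probe_truth.csv")
cat("Simulated", nrow(truth), "probes x", cfg$sim$n_samples,
    "samples per cohort (healthy + disease), seed", seed, "\n")
print(table(truth$class))
cat("Artifacts:", paste(names(manifest$artifacts), collapse = ", "), "\n")
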