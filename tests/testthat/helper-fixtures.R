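# Shared fixtures, all built in code at test time.

# The 2-probe x 3-sample worked example used throughout the barometer math:
# beta = [[0.1, 0.2, 0.6], [0.9, 0.8, 0.4]], samples 1-2 young (ages 26, 27),
# sample 3 old (age 70).
worked_example <- function() {
  b <- beta_matrix(matrix(c(0.1, 0.9, 0.2, 0.8, 0.6, 0.4), nrow = 2),
                   c("p1", "p2"), c("s1", "s2", "s3"))
  s <- sample_table(c("s1", "s2", "s3"), c(26, 27, 70))
  list(beta = b, samples = s, data = align(b, s))
}

# Small aligned simulated cohort with default class mix.
small_cohort <- function(seed = 1, n_probes = 300, n_samples = 150, ...) {
  cfg <- simulation_config(n_probes = n_probes, n_samples = n_samples,
                           seed = seed, ...)
  sim <- simulate_cohort(cfg)
  list(config = cfg, sim = sim, data = align(sim$beta, sim$samples),
       truth = sim$truth)
}

# Clock model with hand-set raw-beta weights, built through the public
# coefficient loader.
manual_clock <- function(weights, intercept = 0) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  df <- data.frame(probe_id = c(names(weights), "(Intercept)"),
                   weight = c(unname(weights), intercept))
  utils::write.csv(df, path, row.names = FALSE)
  load_clock_coefficients(path)
}

# Minimal GEO-style series-matrix file for a beta matrix.
write_series_matrix <- function(beta, path) {
  con <- file(path, "w")
  writeLines(c("!Series_title\t\"synthetic fixture\"",
               "!series_matrix_table_begin"), con)
  writeLines(paste(c("\"ID_REF\"",
                     sprintf("\"%s\"", colnames(beta))), collapse = "\t"), con)
  for (i in seq_len(nrow(beta))) {
    v <- ifelse(is.na(beta[i, ]), "NA", sprintf("%.17g", beta[i, ]))
    writeLines(paste(c(rownames(beta)[i], v), collapse = "\t"), con)
  }
  writeLines("!series_matrix_table_end", con)
  close(con)
  path
}
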