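#' Configuration for the synthetic 450K-style cohort generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume in array data: bounded beta values, age-structured probe means,
#' and — for a planted probe subset — dispersion that grows with age.
#' Four probe classes are planted:
#' \describe{
#'   \item{drift}{mean methylation changes linearly with age (clock fodder).}
#'   \item{invariant_quiet}{flat mean, constant dispersion.}
#'   \item{invariant_noisy}{flat mean, dispersion rising with age — the
#'     noise-detector ground truth.}
#'   \item{boundary_methylated}{means pinned near 1 or near 0 with tiny
#'     young dispersion, emulating fully silenced / fully open loci.}
#' }
#'
#' @param n_probes,n_samples problem size.
#' @param age_range ages are drawn uniformly on this interval (years).
#' @param class_fractions named proportions over the four classes; must sum
#'   to 1.
#' @param young_sd baseline beta-value SD at the youngest age.
#' @param gamma noise amplification: fold-increase minus one of dispersion
#'   from the youngest to the oldest age for invariant_noisy probes
#'   (`gamma = 1` doubles the SD across the age range). Must be >= 0.
#' @param drift_slope_range absolute drift slope magnitudes, beta units per
#'   year; each drift probe draws a magnitude uniformly here with random sign.
#' @param n_drift_factors number of shared latent drift processes. Drift
#'   probes load on one factor each, so probes of a factor are mutually
#'   correlated beyond the common age trend — emulating the co-methylation
#'   blocks (epigenetic drift, cell-composition shift) that make array
#'   probes redundant. 0 gives conditionally independent drift probes.
#' @param factor_noise_sd SD of the shared per-sample factor noise, on the
#'   0-1 normalized age scale (a probe's shared noise SD is
#'   `|slope| * age_span * factor_noise_sd`).
#' @param disease_mean_shift,disease_mean_fraction additive mean shift applied
#'   to a random fraction of probes in disease cohorts.
#' @param disease_dispersion_mult dispersion multiplier applied to
#'   invariant_noisy probes in disease cohorts.
#' @param batch_sd SD of the per-dataset, per-probe additive mean offset.
#' @param missing_rate proportion of entries set missing (default 0).
#' @param dispersion_profile `"linear"` (default) or `"knot"`: with a knot,
#'   dispersion stays flat until `knot_age` and then rises linearly,
#'   emulating the young-adult low-noise plateau.
#' @param knot_age knot location in years (used when profile is `"knot"`).
#' @param seed integer; one global seed from which every draw flows.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_probes = 1000, n_samples = 300,
                              age_range = c(25, 85),
                              class_fractions = c(drift = 0.40,
                                                  invariant_quiet = 0.45,
                                                  invariant_noisy = 0.10,
                                                  boundary_methylated = 0.05),
                              young_sd = 0.02, gamma = 1,
                              drift_slope_range = c(0.001, 0.003),
                              n_drift_factors = 10, factor_noise_sd = 0.3,
                              disease_mean_shift = 0.01,
                              disease_mean_fraction = 0.05,
                              disease_dispersion_mult = 1.3,
                              batch_sd = 0.01, missing_rate = 0,
                              dispersion_profile = c("linear", "knot"),
                              knot_age = 45, seed = 1L) {
  dispersion_profile <- match.arg(dispersion_profile)
  need <- c("drift", "invariant_quiet", "invariant_noisy",
            "boundary_methylated")
  if (!setequal(names(class_fractions), need)) {
    stop("class_fractions must be named over: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class_fractions <- class_fractions[need]
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0)) {
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (young_sd <= 0 || batch_sd < 0 || missing_rate < 0 || missing_rate > 1) {
    stop("scales must be non-negative (young_sd strictly positive)",
         call. = FALSE)
  }
  if (diff(age_range) <= 0) stop("age_range must be increasing", call. = FALSE)
  structure(list(n_probes = as.integer(n_probes),
                 n_samples = as.integer(n_samples),
                 age_range = as.numeric(age_range),
                 class_fractions = class_fractions,
                 young_sd = young_sd, gamma = gamma,
                 drift_slope_range = as.numeric(drift_slope_range),
                 n_drift_factors = as.integer(n_drift_factors),
                 factor_noise_sd = factor_noise_sd,
                 disease_mean_shift = disease_mean_shift,
                 disease_mean_fraction = disease_mean_fraction,
                 disease_dispersion_mult = disease_dispersion_mult,
                 batch_sd = batch_sd, missing_rate = missing_rate,
                 dispersion_profile = dispersion_profile,
                 knot_age = knot_age, seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic substream seed: global seed offset by a key string so that
# distinct cohorts/datasets get distinct but reproducible streams.
substream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Draw the per-probe ground truth for a simulation
#'
#' Emits the oracle used by selection-recovery tests: each probe's class,
#' baseline mean, drift slope, and young/old dispersion. Shared across
#' datasets of a multi-batch simulation so planted probes are the same
#' probes in every batch.
#'
#' @param config a [simulation_config()].
#' @return data.frame (`probe_truth`) with columns probe_id, class, m0,
#'   slope, young_sd, old_sd.
#' @export
make_probe_truth <- function(config) {
  set.seed(substream_seed(config$seed, "probe_truth"))
  n <- config$n_probes
  counts <- round(config$class_fractions * n)
  counts[1] <- n - sum(counts[-1])  # absorb rounding in the first class
  if (any(counts < 0)) stop("class fractions infeasible for n_probes",
                            call. = FALSE)
  cls <- rep(names(counts), counts)
  cls <- sample(cls)
  m0 <- stats::runif(n, 0.2, 0.8)
  boundary <- cls == "boundary_methylated"
  m0[boundary] <- sample(c(0.985, 0.015), sum(boundary), replace = TRUE)
  slope <- numeric(n)
  drift <- cls == "drift"
  slope[drift] <- sample(c(-1, 1), sum(drift), replace = TRUE) *
    stats::runif(sum(drift), config$drift_slope_range[1],
                 config$drift_slope_range[2])
  factor_id <- rep(NA_integer_, n)
  if (config$n_drift_factors > 0 && any(drift)) {
    factor_id[drift] <- sample.int(config$n_drift_factors, sum(drift),
                                   replace = TRUE)
  }
  young_sd <- pmin(config$young_sd, 0.5 * sqrt(m0 * (1 - m0)))
  # fully silenced / fully open loci are tightly regulated when young
  young_sd[boundary] <- pmin(young_sd[boundary], config$young_sd / 2)
  if (any(!boundary & config$young_sd^2 >= m0 * (1 - m0))) {
    stop("config error: young_sd infeasible for a Beta law at some probe mean",
         call. = FALSE)
  }
  gam <- ifelse(cls == "invariant_noisy", config$gamma, 0)
  truth <- data.frame(probe_id = sprintf("cg%08d", seq_len(n)),
                      class = cls, m0 = m0, slope = slope,
                      factor = factor_id,
                      young_sd = young_sd,
                      old_sd = young_sd * (1 + gam),
                      stringsAsFactors = FALSE)
  class(truth) <- c("probe_truth", class(truth))
  truth
}

# Age-dependent dispersion multiplier in [1, 1 + gamma].
dispersion_scale <- function(age, gamma, age_range, profile, knot_age) {
  if (profile == "linear") {
    frac <- (age - age_range[1]) / diff(age_range)
  } else {
    frac <- pmax(0, age - knot_age) / (age_range[2] - knot_age)
  }
  1 + gamma * pmin(pmax(frac, 0), 1)
}

#' Simulate one cohort of array samples
#'
#' Ages are uniform on the configured range. Each beta value is drawn from a
#' Beta distribution parameterized by its probe's age-dependent mean
#' `m_j(age) = clamp(m0_j + slope_j * (age - age_min), 0.01, 0.99)` and SD
#' `s_j(age) = young_sd_j * dispersion_scale(age)`; Beta sampling (rather
#' than a clipped Gaussian) keeps values in \[0,1\] without distorting means
#' near the boundary, where the SD is capped at feasibility. Disease cohorts
#' apply the configured mean shift and dispersion multiplier. The same seed
#' yields bit-identical output.
#'
#' @param config a [simulation_config()].
#' @param cohort `"healthy"` or a disease label (anything else is treated as
#'   disease).
#' @param dataset_id batch label; with `batch_sd > 0` each dataset gets its
#'   own per-probe additive mean offset.
#' @param truth optional shared [make_probe_truth()] output; drawn from the
#'   config when omitted.
#' @return list with `beta` ([beta_matrix()]), `samples` (sample table) and
#'   `truth` (`probe_truth`).
#' @export
simulate_cohort <- function(config, cohort = "healthy",
                            dataset_id = "sim1", truth = NULL) {
  if (is.null(truth)) truth <- make_probe_truth(config)
  n_p <- nrow(truth)
  n_s <- config$n_samples
  set.seed(substream_seed(config$seed, paste0("cohort:", dataset_id, ":",
                                              cohort)))
  ages <- stats::runif(n_s, config$age_range[1], config$age_range[2])
  m0 <- truth$m0
  young_sd <- truth$young_sd
  gam <- ifelse(truth$class == "invariant_noisy", config$gamma, 0)

  diseased <- !identical(cohort, "healthy")
  if (diseased) {
    shifted <- stats::runif(n_p) < config$disease_mean_fraction
    m0 <- m0 + ifelse(shifted, config$disease_mean_shift, 0)
    disp_mult <- ifelse(truth$class == "invariant_noisy",
                        config$disease_dispersion_mult, 1)
  } else {
    disp_mult <- rep(1, n_p)
  }
  if (config$batch_sd > 0) {
    set.seed(substream_seed(config$seed, paste0("batch:", dataset_id)))
    m0 <- m0 + stats::rnorm(n_p, 0, config$batch_sd)
    set.seed(substream_seed(config$seed, paste0("cohort-draw:", dataset_id,
                                                ":", cohort)))
  }

  mean_mat <- outer(truth$slope, ages - config$age_range[1]) + m0
  if (config$n_drift_factors > 0 && any(!is.na(truth$factor))) {
    span <- diff(config$age_range)
    eta <- matrix(stats::rnorm(config$n_drift_factors * n_s, 0,
                               config$factor_noise_sd),
                  config$n_drift_factors, n_s)
    loaded <- which(!is.na(truth$factor))
    mean_mat[loaded, ] <- mean_mat[loaded, ] +
      (truth$slope[loaded] * span) * eta[truth$factor[loaded], , drop = FALSE]
  }
  mean_mat <- pmin(pmax(mean_mat, 0.01), 0.99)
  age_scale <- dispersion_scale(ages, 1, config$age_range,
                                config$dispersion_profile, config$knot_age) - 1
  sd_mat <- (young_sd * disp_mult) * (1 + outer(gam, age_scale))
  # cap at Beta feasibility
  sd_mat <- pmin(sd_mat, 0.95 * sqrt(mean_mat * (1 - mean_mat)))
  phi <- mean_mat * (1 - mean_mat) / sd_mat^2 - 1
  vals <- matrix(stats::rbeta(n_p * n_s, mean_mat * phi, (1 - mean_mat) * phi),
                 nrow = n_p)
  if (config$missing_rate > 0) {
    vals[stats::runif(length(vals)) < config$missing_rate] <- NA_real_
  }
  sample_ids <- sprintf("%s_s%04d", dataset_id, seq_len(n_s))
  beta <- beta_matrix(vals, truth$probe_id, sample_ids)
  samples <- sample_table(sample_ids, ages, cohort, dataset_id)
  list(beta = beta, samples = samples, truth = truth)
}

#' Simulate several batches sharing one probe truth
#'
#' Convenience wrapper for the multi-dataset designs (six healthy-control
#' batches, healthy-vs-disease pairs): the probe ground truth is drawn once
#' and reused so planted probes coincide across datasets, while each dataset
#' gets its own samples and batch offset.
#'
#' @param config a [simulation_config()] (per-dataset sample size).
#' @param n_datasets number of batches.
#' @param cohort cohort label applied to every batch.
#' @param dataset_prefix prefix for dataset ids.
#' @return list with `datasets` (list of [simulate_cohort()] outputs) and
#'   `truth`.
#' @export
simulate_batches <- function(config, n_datasets = 6, cohort = "healthy",
                             dataset_prefix = "batch") {
  truth <- make_probe_truth(config)
  datasets <- lapply(seq_len(n_datasets), function(k) {
    simulate_cohort(config, cohort = cohort,
                    dataset_id = sprintf("%s%02d", dataset_prefix, k),
                    truth = truth)
  })
  list(datasets = datasets, truth = truth)
}

#' Merge several datasets over their shared probes
#'
#' Column-concatenates beta matrices over the probe-id intersection and
#' stacks the sample tables, preserving each sample's dataset_id, then
#' aligns (dropping samples with missing values).
#'
#' @param datasets list of `list(beta=, samples=)` (or [simulate_cohort()] /
#'   `meth_dataset` objects).
#' @param suffix_duplicates if TRUE, duplicate sample ids across datasets are
#'   suffixed with their dataset id instead of raising an integrity error.
#' @return a `meth_dataset` over the probe intersection.
#' @export
merge_datasets <- function(datasets, suffix_duplicates = FALSE) {
  stopifnot(length(datasets) >= 1)
  betas <- lapply(datasets, function(d) d$beta)
  tables <- lapply(datasets, function(d) validate_sample_table(d$samples))
  shared <- Reduce(intersect, lapply(betas, rownames))
  if (length(shared) == 0) stop("no shared probe ids across datasets",
                                call. = FALSE)
  ids <- unlist(lapply(tables, function(s) s$sample_id))
  if (anyDuplicated(ids)) {
    if (!suffix_duplicates) {
      stop("integrity error: duplicate sample ids across datasets: ",
           paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
           call. = FALSE)
    }
    for (k in seq_along(tables)) {
      new_ids <- paste(tables[[k]]$sample_id, tables[[k]]$dataset_id,
                       sep = ".")
      colnames(betas[[k]])[match(tables[[k]]$sample_id,
                                 colnames(betas[[k]]))] <- new_ids
      tables[[k]]$sample_id <- new_ids
    }
  }
  big <- do.call(cbind, lapply(betas, function(b) {
    unclass(b)[shared, , drop = FALSE]
  }))
  all_samples <- do.call(rbind, tables)
  align(beta_matrix(big, shared, colnames(big)), all_samples)
}
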