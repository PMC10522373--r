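test_that("mu, ADM, zeta and sigma match the worked example exactly", {
  ex <- worked_example()
  mu <- probe_mean(ex$beta)
  expect_equal(mu, c(p1 = 0.3, p2 = 0.7))
  A <- adm(ex$beta, mu)
  expect_equal(unname(A["p1", ]), c(0.2, 0.1, 0.3))
  expect_equal(unname(colSums(A)), c(0.4, 0.2, 0.6))

  bar <- suppressWarnings(fit_barometer(ex$data, c("p1", "p2"),
                                        young = c(25, 28)))
  expect_equal(bar$zeta, 0.3)
  sigma <- noise_score(ex$data, bar)
  expect_equal(unname(sigma), c(4 / 3, 2 / 3, 2))

  # constant probe: mu equals the constant, ADM is zero
  bc <- beta_matrix(matrix(0.4, 1, 3), "pK", c("s1", "s2", "s3"))
  expect_equal(unname(probe_mean(bc)), 0.4)
  expect_true(all(adm(bc, c(pK = 0.4)) == 0))
  expect_error(adm(bc, c(other = 0.1)), "missing from mu")
})

test_that("sigma is non-negative, averages 1 over the young set, and scales", {
  for (s in c(2, 5)) {
    cc <- small_cohort(seed = s, n_probes = 120, n_samples = 200)
    probes <- head(cc$truth$probe_id[cc$truth$class == "invariant_noisy"], 10)
    bar <- suppressWarnings(fit_barometer(cc$data, probes))
    sigma <- noise_score(cc$data, bar)
    expect_true(all(sigma >= 0))
    ym <- methnoise:::young_mask(cc$data$samples$age, bar$young_definition)
    expect_equal(mean(sigma[ym]), 1, tolerance = 1e-12)

    # linearity: halving zeta doubles sigma
    bar2 <- bar; bar2$zeta <- bar$zeta / 2
    expect_equal(unname(noise_score(cc$data, bar2)), unname(2 * sigma))
  }
})

test_that("approach 1 misses when no probe is near-invariant and stages shrink", {
  set.seed(20)
  n <- 200
  age <- runif(n, 25, 85)
  # all probes strongly age-correlated: the invariance window excludes all
  B <- t(sapply(1:30, function(i) 0.3 + 0.005 * (age - 25) + rnorm(n, 0, 0.01)))
  B <- pmin(pmax(B, 0), 1)
  rownames(B) <- sprintf("cg%02d", 1:30); colnames(B) <- sprintf("s%03d", 1:n)
  d <- align(beta_matrix(B), sample_table(colnames(B), age))
  rep1 <- select_approach1(d)
  expect_length(rep1$probes, 0)
  expect_true(all(diff(rep1$stage_counts) <= 0))
})

test_that("approach-1 and approach-2 selections are enriched in invariant classes", {
  cc <- small_cohort(seed = 23, n_probes = 800, n_samples = 500, gamma = 2)
  rep1 <- select_approach1(cc$data)
  cls <- cc$truth$class[match(rep1$probes, cc$truth$probe_id)]
  stage1 <- rownames(cc$data$beta) %in% rep1$probes
  # no drift probes pass the invariance window, so enrichment is structural
  expect_false(any(cls == "drift"))
  prevalence <- mean(cc$truth$class %in%
                       c("invariant_quiet", "invariant_noisy",
                         "boundary_methylated"))
  if (length(rep1$probes) > 0) {
    expect_gt(mean(cls != "drift"), prevalence)
  }

  cfg <- simulation_config(n_probes = 500, n_samples = 250, seed = 24)
  sims <- simulate_batches(cfg, 3)
  datasets <- lapply(sims$datasets, function(s) align(s$beta, s$samples))
  rep2 <- select_approach2(datasets)
  cls2 <- sims$truth$class[match(rep2$probes, sims$truth$probe_id)]
  expect_false(any(cls2 == "drift"))
  expect_true(all(diff(rep2$stage_counts) <= 0))
})

test_that("young-SD stratification obeys its modes and identities", {
  cc <- small_cohort(seed = 25, n_probes = 300, n_samples = 400)
  probes <- cc$truth$probe_id
  most <- stratify_by_young_sd(cc$data, probes, 0.015, "absolute_mean",
                               "most_regulated")
  least <- stratify_by_young_sd(cc$data, probes, 0.015, "absolute_mean",
                                "least_regulated")
  expect_setequal(union(most, least), probes)  # threshold splits the set

  # relative-mode SD = absolute-mode SD / young mean
  abs_sd <- attr(stratify_by_young_sd(cc$data, probes, 1, "absolute_mean",
                                      "most_regulated"), "young_sd")
  rel_sd <- attr(stratify_by_young_sd(cc$data, probes, 1e9, "relative_mean",
                                      "most_regulated"), "young_sd")
  ym <- methnoise:::young_mask(cc$data$samples$age)
  ymean <- rowMeans(unclass(cc$data$beta)[probes, ym, drop = FALSE])
  expect_equal(rel_sd, abs_sd / ymean)

  # boundary probes (means near 1 or 0, tiny young SD) are most regulated
  boundary <- cc$truth$probe_id[cc$truth$class == "boundary_methylated"]
  most_b <- stratify_by_young_sd(cc$data, probes, 0.015, "absolute_mean",
                                 "most_regulated")
  expect_true(all(boundary %in% most_b))
})

test_that("White's test is calibrated, powered, and handles degeneracy", {
  set.seed(26)
  n <- 300; age <- runif(n, 25, 85)
  # null: homoscedastic
  p_null <- replicate(200, white_test(0.5 + rnorm(n, 0, 0.02), age))
  expect_gt(mean(p_null < 0.05), 0.005)
  expect_lt(mean(p_null < 0.05), 0.12)
  # alternative: SD doubling across the range
  p_alt <- replicate(50, white_test(0.5 + rnorm(n, 0,
                                                0.02 * (1 + (age - 25) / 60)),
                                    age))
  expect_gt(mean(p_alt < 0.05), 0.8)
  # degenerate zero-residual fit
  p_deg <- white_test(0.2 + 0.001 * age, age)
  expect_equal(as.numeric(p_deg), 1)
  expect_equal(attr(p_deg, "flag"), "degenerate")
  expect_error(white_test(c(0.1, 0.2, 0.3), c(1, 2, 3)), "n >= 5")
  expect_error(white_test(runif(10), rep(4, 10)), "constant")
})

test_that("White's statistic agrees with the studentized LM test", {
  skip_if_not_installed("lmtest")
  set.seed(27)
  n <- 150; age <- runif(n, 25, 85)
  b <- 0.4 + 0.001 * age + rnorm(n, 0, 0.02 * (1 + (age - 25) / 90))
  ours <- white_test(b, age)
  fit <- lm(b ~ age)
  ref <- lmtest::bptest(fit, ~ age + I(age^2), data = data.frame(age = age))
  expect_equal(attr(ours, "statistic"), unname(ref$statistic),
               tolerance = 1e-8)
  expect_equal(as.numeric(ours), unname(ref$p.value), tolerance = 1e-8)
})

test_that("approach 3 recovers planted heteroscedastic probes and controls nulls", {
  cc <- small_cohort(seed = 28, n_probes = 600, n_samples = 900, gamma = 1)
  rep3 <- select_approach3(cc$data)
  expect_true(all(diff(rep3$stage_counts) <= 0))
  noisy <- cc$truth$probe_id[cc$truth$class == "invariant_noisy"]
  expect_gt(mean(noisy %in% rep3$probes), 0.8)

  # null simulation (gamma = 0): survival rate bounded by alpha
  cc0 <- small_cohort(seed = 29, n_probes = 600, n_samples = 600, gamma = 0)
  rep0 <- select_approach3(cc0$data)
  n_probes <- nrow(cc0$data$beta)
  expect_lte(length(rep0$probes) / n_probes,
             0.05 + 2 * sqrt(0.05 * 0.95 / n_probes))

  # group-variance alternative runs and shrinks monotonically
  repf <- select_approach3(cc$data, variance_test = "group_f")
  expect_true(all(diff(repf$stage_counts) <= 0))
})

test_that("summed-SD curves match hand values and ignore silent probes", {
  b <- beta_matrix(matrix(c(0, 1, 0.3, 0.3, 1, 0, 0.3, 0.3), 2, 4,
                          byrow = FALSE),
                   c("pA", "pZ"), c("s1", "s2", "s3", "s4"))
  # bins: ages 26,27 -> young bin; 70,71 -> old bin; pA holds {0,1} per bin
  s <- sample_table(colnames(b), c(26, 27, 70, 71))
  d <- align(b, s)
  cur <- summed_sd_curve(d, c("pA", "pZ"), bin_width = 4,
                         normalize_by_young = FALSE)
  expect_equal(cur$summed_sd, rep(sd(c(0, 1)), 2), tolerance = 1e-12)
  expect_equal(cur$summed_sd[1], 0.7071, tolerance = 1e-4)

  # adding a zero-variance probe changes nothing
  b2 <- beta_matrix(rbind(unclass(b), pC = rep(0.5, 4)))
  d2 <- align(b2, s)
  cur2 <- summed_sd_curve(d2, c("pA", "pZ", "pC"), bin_width = 4,
                          normalize_by_young = FALSE)
  expect_equal(cur2$summed_sd, cur$summed_sd)

  # constant matrix: all sums zero; normalization flagged young bin = 1
  cc <- small_cohort(seed = 30, n_probes = 50, n_samples = 300)
  curn <- summed_sd_curve(cc$data, rownames(cc$data$beta)[1:10])
  expect_equal(curn$normalized[1], 1)
})

test_that("polynomial fits recover exact curves and invert monotonically", {
  x <- seq(25, 85, by = 5)
  expect_equal(methnoise:::fit_noise_curve_xy(x, 2 + 0.5 * x, 1),
               c(0.5, 2), tolerance = 1e-10)
  y3 <- 1 + 0.01 * (x - 25) + 2e-4 * (x - 25)^2 + 1e-6 * (x - 25)^3
  co <- methnoise:::fit_noise_curve_xy(x, y3, 3)
  expect_equal(methnoise:::polyval(co, x), y3, tolerance = 1e-8)

  # identity polynomial maps y -> y
  ident <- structure(list(poly_coefficients = c(1, 0),
                          age_domain = c(0, 100)),
                     class = "barometer_model")
  expect_equal(as.numeric(map_biological_age(ident, 42)), 42)

  # out-of-range values clamp to the nearer endpoint with a flag
  low <- map_biological_age(ident, -5)
  expect_equal(as.numeric(low), 0)
  expect_equal(attr(low, "flag"), "clamped")

  expect_error(fit_noise_curve(data.frame(midpoint = 1:3,
                                          normalized = 1:3), 3),
               "underdetermined")
})

test_that("cohort comparison shows planted disease noise above healthy", {
  cfg <- simulation_config(n_probes = 300, n_samples = 600, seed = 33)
  tr <- make_probe_truth(cfg)
  h <- simulate_cohort(cfg, "healthy", "hc", truth = tr)
  dz <- simulate_cohort(cfg, "arthritis", "dz", truth = tr)
  noisy <- tr$probe_id[tr$class == "invariant_noisy"]
  cmp <- compare_cohorts(align(h$beta, h$samples), align(dz$beta, dz$samples),
                         noisy)
  expect_gte(mean(cmp$difference$delta > 0), 0.8)

  # identical data: differences identically zero
  hd <- align(h$beta, h$samples)
  cmp0 <- compare_cohorts(hd, hd, noisy)
  expect_true(all(cmp0$difference$delta == 0))

  # a single probe runs end to end
  cmp1 <- compare_cohorts(hd, align(dz$beta, dz$samples), noisy[1])
  expect_true(nrow(cmp1$difference) >= 2)
})

test_that("batch resilience reports zero deviation for identical datasets", {
  cc <- small_cohort(seed = 34, n_probes = 200, n_samples = 300)
  probes <- cc$truth$probe_id[cc$truth$class == "invariant_noisy"]
  br0 <- batch_resilience(list(cc$data, cc$data), probes)
  expect_true(all(br0$deviations$deviation == 0))

  cfg <- simulation_config(n_probes = 200, n_samples = 300, seed = 35)
  sims <- simulate_batches(cfg, 3)
  datasets <- lapply(sims$datasets, function(s) align(s$beta, s$samples))
  br <- batch_resilience(datasets,
                         sims$truth$probe_id[sims$truth$class ==
                                               "invariant_noisy"])
  expect_true(all(br$deviations$deviation >= 0))
  expect_true(all(br$median_curve$n_datasets >= 1))
})

test_that("selected-probe curves track age better than all-probe curves", {
  cfg <- simulation_config(n_probes = 600, n_samples = 1200, gamma = 1.5,
                           class_fractions = c(drift = 0.60,
                                               invariant_quiet = 0.25,
                                               invariant_noisy = 0.10,
                                               boundary_methylated = 0.05),
                           seed = 36)
  sim <- simulate_cohort(cfg)
  d <- align(sim$beta, sim$samples)
  noisy <- sim$truth$probe_id[sim$truth$class == "invariant_noisy"]
  cur_sel <- summed_sd_curve(d, noisy)
  cur_all <- summed_sd_curve(d, rownames(d$beta))
  r_sel <- pearson_r(cur_sel$midpoint, cur_sel$normalized)
  r_all <- pearson_r(cur_all$midpoint, cur_all$normalized)
  expect_gt(r_sel, r_all)
  expect_gt(r_sel, 0.9)
})

test_that("noise curves trend upward only when noise is planted", {
  rho_pos <- rho_null <- numeric(0)
  for (s in 41:45) {
    cc <- small_cohort(seed = s, n_probes = 150, n_samples = 500, gamma = 1.5)
    noisy <- cc$truth$probe_id[cc$truth$class == "invariant_noisy"]
    cur <- summed_sd_curve(cc$data, noisy)
    rho_pos <- c(rho_pos, cor(cur$midpoint, cur$normalized,
                              method = "spearman"))
    cc0 <- small_cohort(seed = s, n_probes = 150, n_samples = 500, gamma = 0)
    noisy0 <- cc0$truth$probe_id[cc0$truth$class == "invariant_noisy"]
    cur0 <- summed_sd_curve(cc0$data, noisy0)
    rho_null <- c(rho_null, cor(cur0$midpoint, cur0$normalized,
                                method = "spearman"))
  }
  expect_true(all(rho_pos > 0))
  expect_lt(abs(mean(rho_null)), 0.5)
  expect_lt(mean(abs(rho_null)), mean(rho_pos))
})
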