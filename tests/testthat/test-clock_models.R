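test_that("elastic-net cost matches hand-evaluated cases", {
  # zero weights: (1/2n)||y||^2 with y = (2,2)
  expect_equal(elastic_net_cost(matrix(1, 2, 1), c(2, 2), 0, 1, 0.5), 2.0)
  # exact fit, no penalty
  expect_equal(elastic_net_cost(matrix(c(1, 2), 2, 1), c(1, 2), 1, 0, 0.5), 0)
  # X=[[1],[2]], y=(1,2), w=1, alpha=1, rho=0.5 -> 0 + 0.5 + 0.25
  expect_equal(elastic_net_cost(matrix(c(1, 2), 2, 1), c(1, 2), 1, 1, 0.5),
               0.75)
  expect_error(elastic_net_cost(matrix(1, 2, 1), c(1, 2, 3), 0, 1, 0.5),
               "dimension error")
})

test_that("pearson_r and median_abs_error match hand evaluation", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.982, tolerance = 5e-4)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "constant")
  # affine invariance
  set.seed(1); x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y))

  expect_equal(median_abs_error(1:4, 1:4), 0)
  expect_equal(median_abs_error(c(0, 0, 0), c(1, -3, 2)), 2)
  set.seed(2); a <- rnorm(9); p <- rnorm(9); perm <- sample(9)
  expect_equal(median_abs_error(a[perm], p[perm]), median_abs_error(a, p))
  expect_error(median_abs_error(1:3, 1:4), "dimension error")
})

test_that("a perfect single-probe signal is learned and predicted", {
  set.seed(5)
  n <- 120
  B <- matrix(runif(40 * n, 0.2, 0.8), 40, n,
              dimnames = list(sprintf("cg%02d", 1:40), sprintf("s%03d", 1:n)))
  y <- 10 * B["cg07", ]
  d <- align(beta_matrix(B), sample_table(colnames(B), age = y))
  fit <- train_clock(d, y, elastic_net_config(seed = 5))
  expect_true("cg07" %in% active_probes(fit$model))
  expect_lt(attr(fit$report, "summary")$medae, 0.1)

  # training-fit sanity and per-sample independence
  pred <- predict(fit$model, d$beta)
  expect_lt(median(abs(pred - y)), 0.1)
  dup <- beta_matrix(unclass(d$beta)[, c(1, 1, 2)],
                     rownames(d$beta), c("a", "a2", "b"))
  pd <- predict(fit$model, dup)
  expect_identical(unname(pd["a"]), unname(pd["a2"]))
})

test_that("training is reproducible and respects the cost contract", {
  cc <- small_cohort(seed = 8, n_probes = 250, n_samples = 160)
  cfg <- elastic_net_config(seed = 8)
  f1 <- train_clock(cc$data, "age", cfg)
  f2 <- train_clock(cc$data, "age", cfg)
  expect_identical(active_probes(f1$model), active_probes(f2$model))
  expect_identical(f1$model$alpha, f2$model$alpha)

  # reconstruct the standardized training design over the active set
  act <- active_probes(f1$model)
  X <- t(unclass(cc$data$beta)[act, f1$split$train, drop = FALSE])
  idx <- match(act, f1$model$scaler$probe_id)
  Xs <- sweep(sweep(X, 2, f1$model$scaler$mean[idx]), 2,
              f1$model$scaler$sd[idx], "/")
  y <- cc$data$samples$age[f1$split$train]
  yc <- y - mean(y)
  a <- f1$model$alpha; rho <- cfg$l1_ratio
  cost_hat <- elastic_net_cost(Xs, yc, f1$model$weights[act], a, rho)
  cost_zero <- elastic_net_cost(Xs, yc, rep(0, length(act)), a, rho)
  w_ols <- qr.coef(qr(Xs), yc)
  cost_ols <- elastic_net_cost(Xs, yc, w_ols, a, rho)
  expect_lte(cost_hat, cost_zero)
  expect_lte(cost_hat, cost_ols)
  expect_error(train_clock(cc$data, rep(3, ncol(cc$data$beta))),
               "constant response")
})

test_that("elastic net converges to OLS as the penalty vanishes", {
  set.seed(7)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  beta_true <- c(1, -2, 0.5, 0, 3)
  y <- as.numeric(X %*% beta_true + rnorm(n, 0, 0.05))
  Xs <- scale(X)
  en <- glmnet::glmnet(Xs, y, alpha = 0.5,
                       lambda = c(1, 0.1, 0.01, 0.001, 0),
                       standardize = FALSE, thresh = 1e-12)
  en_pred <- as.numeric(predict(en, Xs, s = 0))
  ols <- stats::lm.fit(cbind(1, Xs), y)
  ols_pred <- as.numeric(cbind(1, Xs) %*% ols$coefficients)
  expect_lt(max(abs(en_pred - ols_pred)), 1e-4)
})

test_that("OLS on a probe set recovers exact signals and matches EN closely", {
  # single probe, exact linear response
  set.seed(11)
  B <- matrix(runif(60, 0.2, 0.8), 1, 60,
              dimnames = list("cgA", sprintf("s%02d", 1:60)))
  y <- 5 + 20 * B["cgA", ]
  d <- align(beta_matrix(B), sample_table(colnames(B), y))
  fit <- ols_on_probes(d, "cgA", y)
  expect_equal(unname(fit$model$weights["cgA"]), 20, tolerance = 1e-8)
  expect_equal(fit$model$intercept, 5, tolerance = 1e-8)

  # rank deficiency is reported with the collinear probe
  B2 <- rbind(B, cgB = B["cgA", ])
  d2 <- align(beta_matrix(B2), sample_table(colnames(B2), y))
  expect_error(ols_on_probes(d2, c("cgA", "cgB"), y), "collinear")

  # on simulated data, OLS on the EN active set tracks the EN predictions
  cc <- small_cohort(seed = 12, n_probes = 300, n_samples = 250)
  en <- train_clock(cc$data, "age", elastic_net_config(seed = 12))
  act <- active_probes(en$model)
  ols2 <- ols_on_probes(cc$data, act, "age")
  expect_gt(pearson_r(predict(en$model, cc$data$beta),
                      predict(ols2$model, cc$data$beta)), 0.95)
  # OLS squared error cannot exceed the EN fit's squared-error term
  y_all <- cc$data$samples$age
  expect_lte(mean((predict(ols2$model, cc$data$beta) - y_all)^2),
             mean((predict(en$model, cc$data$beta) - y_all)^2) + 1e-12)
})

test_that("any regular numeric series is learnable from drift data", {
  # response = population count at birth year (monotone series), not age
  cc <- small_cohort(seed = 21, n_probes = 500, n_samples = 300,
                     class_fractions = c(drift = 1, invariant_quiet = 0,
                                         invariant_noisy = 0,
                                         boundary_methylated = 0))
  birth_year <- round(2012 - cc$data$samples$age)
  years <- sort(unique(birth_year))
  pop <- setNames(2e8 * 1.011^(years - min(years)), years)  # steady growth
  response <- as.numeric(pop[as.character(birth_year)])
  fit <- train_clock(cc$data, response, elastic_net_config(seed = 21),
                     response_name = "population")
  expect_gt(attr(fit$report, "summary")$pearson_r, 0.9)
})

test_that("residual summaries separate planted cohort offsets", {
  set.seed(31)
  resid_h <- rnorm(100, 0, 3)
  resid_d <- rnorm(100, 10, 3)
  rep_ <- prediction_report(sprintf("s%03d", 1:200),
                            actual = rep(50, 200),
                            predicted = 50 + c(resid_h, resid_d),
                            cohort = rep(c("healthy", "disease"), each = 100))
  tab <- residual_summary(rep_)
  expect_lt(tab$p_value[tab$cohort == "disease"], 1e-6)
  expect_equal(tab$mean_residual[tab$cohort == "disease"], 10, tolerance = 1)

  # identical groups: near-zero difference, p near 1
  rep2 <- prediction_report(sprintf("t%03d", 1:200), rep(50, 200),
                            50 + rep(resid_h, 2),
                            cohort = rep(c("healthy", "disease"), each = 100))
  tab2 <- residual_summary(rep2)
  expect_gt(tab2$p_value[tab2$cohort == "disease"], 0.99)

  # age-binned output has one row per (bin, cohort)
  rep3 <- prediction_report(sprintf("u%03d", 1:200),
                            actual = runif(200, 20, 80),
                            predicted = runif(200, 20, 80),
                            cohort = rep(c("healthy", "disease"), 100))
  tab3 <- residual_summary(rep3, age_bins = c(20, 50, 80))
  expect_equal(nrow(tab3), 4)
  expect_setequal(unique(tab3$cohort), c("healthy", "disease"))
})
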