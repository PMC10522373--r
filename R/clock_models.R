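#' Elastic-net training configuration
#'
#' Defaults follow common methylation-clock practice: mixing parameter 0.5,
#' a 10-value penalty grid chosen by 10-fold cross-validation, convergence
#' tolerance 0.001, at most 5000 coordinate-descent iterations, and a random
#' 80/20 train/test split.
#'
#' @param l1_ratio mixing parameter rho in \[0,1\]: 1 = pure lasso, 0 = pure
#'   ridge.
#' @param n_alphas size of the penalty grid searched by cross-validation.
#' @param cv_folds number of CV folds (>= 2).
#' @param tolerance solver convergence tolerance.
#' @param max_iterations solver iteration cap.
#' @param train_fraction fraction of samples used for training, in (0,1).
#' @param seed integer seed fixing the split, the folds, and hence the
#'   chosen penalty and active set.
#' @param stratify_by_age if TRUE the split is stratified by age quartile.
#' @return an `elastic_net_config` list.
#' @export
elastic_net_config <- function(l1_ratio = 0.5, n_alphas = 10, cv_folds = 10,
                               tolerance = 0.001, max_iterations = 5000,
                               train_fraction = 0.8, seed = 1L,
                               stratify_by_age = FALSE) {
  stopifnot(l1_ratio >= 0, l1_ratio <= 1, n_alphas >= 1, cv_folds >= 2,
            train_fraction > 0, train_fraction < 1, tolerance > 0,
            max_iterations >= 1)
  structure(list(l1_ratio = l1_ratio, n_alphas = as.integer(n_alphas),
                 cv_folds = as.integer(cv_folds), tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 stratify_by_age = isTRUE(stratify_by_age)),
            class = "elastic_net_config")
}

new_clock_model <- function(weights, intercept, scaler, alpha, config,
                            response_name, meta = NULL) {
  w <- as.numeric(weights)
  names(w) <- names(weights)
  structure(list(weights = w, intercept = as.numeric(intercept),
                 scaler = scaler, alpha = alpha, config = config,
                 response_name = response_name, meta = meta),
            class = "clock_model")
}

#' Probes carrying non-zero weight in a clock model
#' @param model a `clock_model`.
#' @return character vector of probe ids.
#' @export
active_probes <- function(model) {
  names(model$weights)[model$weights != 0]
}

#' @export
print.clock_model <- function(x, ...) {
  cat("clock_model:", length(active_probes(x)), "active probes;",
      "intercept", signif(x$intercept, 4), ";",
      "response:", x$response_name %||% "?", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Elastic-net cost function
#'
#' The penalized least-squares objective minimized during clock training:
#' \deqn{C(X,y,w,\alpha,\rho) = \frac{1}{2n}\|Xw - y\|_2^2
#'   + \alpha\rho\|w\|_1 + \frac{\alpha(1-\rho)}{2}\|w\|_2^2}
#' on a standardized design. Exposed so fitted weights can be audited
#' against the objective they are supposed to minimize.
#'
#' @param X standardized sample x probe design matrix.
#' @param y numeric responses.
#' @param w numeric weight vector, one per column of `X`.
#' @param alpha overall penalty strength, >= 0.
#' @param rho l1 mixing parameter in \[0,1\].
#' @return scalar cost.
#' @export
elastic_net_cost <- function(X, y, w, alpha, rho) {
  X <- as.matrix(X)
  stopifnot(alpha >= 0, rho >= 0, rho <= 1)
  if (length(y) != nrow(X) || length(w) != ncol(X)) {
    stop("dimension error: X is ", nrow(X), "x", ncol(X), " but |y| = ",
         length(y), ", |w| = ", length(w), call. = FALSE)
  }
  n <- nrow(X)
  resid <- as.numeric(X %*% w) - y
  sum(resid^2) / (2 * n) + alpha * rho * sum(abs(w)) +
    alpha * (1 - rho) / 2 * sum(w^2)
}

#' Pearson correlation between two vectors
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("dimension error: unequal lengths",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Median absolute prediction error
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return median of `|actual - predicted|`.
#' @export
median_abs_error <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("dimension error: unequal lengths", call. = FALSE)
  }
  stats::median(abs(actual - predicted))
}

#' Assemble a prediction report
#'
#' Per-sample actual/predicted/residual rows (residual = predicted - actual)
#' with the summary statistics used throughout the clock audits: Pearson r,
#' mean absolute error, median absolute error, and the mean and SD of the
#' signed residuals.
#'
#' @param sample_id,actual,predicted parallel vectors.
#' @param cohort optional cohort labels carried through for group summaries.
#' @return a `prediction_report` data.frame with a `summary` attribute.
#' @export
prediction_report <- function(sample_id, actual, predicted, cohort = NULL) {
  resid <- predicted - actual
  df <- data.frame(sample_id = as.character(sample_id), actual = actual,
                   predicted = predicted, residual = resid,
                   stringsAsFactors = FALSE)
  if (!is.null(cohort)) df$cohort <- as.character(cohort)
  summ <- list(
    pearson_r = if (stats::sd(actual) > 0 && stats::sd(predicted) > 0)
      pearson_r(actual, predicted) else NA_real_,
    mae = mean(abs(resid)),
    medae = median_abs_error(actual, predicted),
    mean_residual = mean(resid),
    sd_residual = stats::sd(resid))
  attr(df, "summary") <- summ
  class(df) <- c("prediction_report", class(df))
  df
}

#' @export
print.prediction_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "prediction_report: n=%d  r=%.3f  MAE=%.3f  MedAE=%.3f  mean resid=%.3f (SD %.3f)\n",
    nrow(x), s$pearson_r, s$mae, s$medae, s$mean_residual, s$sd_residual))
  invisible(x)
}

# Deterministic train/test split and CV folds from the config seed.
split_samples <- function(n, config, ages = NULL) {
  set.seed(config$seed)
  n_test <- max(1L, round((1 - config$train_fraction) * n))
  if (config$stratify_by_age && !is.null(ages)) {
    strata <- cut(rank(ages, ties.method = "first"), 4, labels = FALSE)
    test <- unlist(lapply(split(seq_len(n), strata), function(idx) {
      sample(idx, max(1L, round(length(idx) * (1 - config$train_fraction))))
    }), use.names = FALSE)
    test <- sort(test[seq_len(min(length(test), n_test))])
  } else {
    test <- sort(sample.int(n, n_test))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Train an elastic-net clock
#'
#' Splits the samples by the config seed, standardizes each probe on the
#' training samples only (the stored scaler is reused verbatim on held-out
#' and out-of-sample data), selects the penalty from an `n_alphas`-point
#' log-spaced grid anchored at the data's maximal penalty by
#' cross-validation, and fits by cyclic coordinate descent (glmnet). Probes
#' with zero training variance are dropped with a warning. The response is
#' treated as an opaque numeric series: age, population size, any regular
#' sequence — deliberately, since the audit's point is that the machinery is
#' indifferent to what the numbers mean.
#'
#' @param data a `meth_dataset` from [align()].
#' @param response numeric vector (one per sample, in `data$samples` order),
#'   or the string `"age"`.
#' @param config an [elastic_net_config()].
#' @param probes optional probe subset defining the training universe.
#' @param response_name label stored in the model.
#' @return list with `model` (a `clock_model`) and `report` (a
#'   [prediction_report()] on the held-out split).
#' @export
train_clock <- function(data, response = "age",
                        config = elastic_net_config(),
                        probes = NULL, response_name = NULL) {
  stopifnot(inherits(data, "meth_dataset"))
  if (identical(response, "age")) {
    response_name <- response_name %||% "age"
    response <- data$samples$age
  }
  response_name <- response_name %||% "response"
  y <- as.numeric(response)
  n <- ncol(data$beta)
  if (length(y) != n) stop("response length must match sample count",
                           call. = FALSE)
  if (any(!is.finite(y))) stop("response must be finite", call. = FALSE)
  if (stats::sd(y) == 0) stop("training error: constant response",
                              call. = FALSE)
  if (n < 2 * config$cv_folds) {
    stop("need at least 2 * cv_folds samples", call. = FALSE)
  }
  if (is.null(probes)) probes <- rownames(data$beta)
  X <- t(unclass(data$beta)[probes, , drop = FALSE])

  split <- split_samples(n, config, ages = data$samples$age)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]

  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant probe(s) excluded from training")
    Xtr <- Xtr[, keep, drop = FALSE]
    mu <- mu[keep]; sdv <- sdv[keep]
  }
  Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")

  rho <- max(config$l1_ratio, 1e-3)  # lambda_max undefined at pure ridge
  lambda_max <- max(abs(crossprod(Xs, ytr - mean(ytr)))) / (nrow(Xs) * rho)
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-3),
                  length.out = config$n_alphas))

  set.seed(config$seed + 1L)
  foldid <- sample(rep_len(seq_len(config$cv_folds), nrow(Xs)))
  cv <- glmnet::cv.glmnet(Xs, ytr, alpha = config$l1_ratio, lambda = grid,
                          foldid = foldid, standardize = FALSE,
                          thresh = 1e-7, maxit = config$max_iterations,
                          family = "gaussian")
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  w <- cf[-1, 1]
  intercept <- cf[1, 1]
  nz <- w != 0
  model <- new_clock_model(
    weights = w[nz], intercept = intercept,
    scaler = list(probe_id = names(w)[nz], mean = unname(mu[nz]),
                  sd = unname(sdv[nz])),
    alpha = cv$lambda.min, config = config, response_name = response_name,
    meta = list(n_train = length(split$train), n_test = length(split$test),
                probe_universe = length(probes),
                lambda_grid = grid))
  test_pred <- predict(model, data$beta[, split$test, drop = FALSE])
  report <- prediction_report(colnames(data$beta)[split$test],
                              y[split$test], test_pred,
                              cohort = data$samples$cohort[split$test])
  list(model = model, report = report, split = split)
}

#' Predict from a clock model
#'
#' Applies the stored scaler (if any) to the active probes and returns the
#' linear combination `w . x + intercept`, per sample. Probe-id
#' intersection handles 27K-in-450K style containment: prediction only
#' requires that every active probe be present.
#'
#' @param object a `clock_model`.
#' @param beta a [beta_matrix()] containing every active probe.
#' @param ... unused.
#' @return named numeric vector of per-sample predictions.
#' @export
predict.clock_model <- function(object, beta, ...) {
  act <- active_probes(object)
  if (length(act) == 0) {
    return(stats::setNames(rep(object$intercept, ncol(beta)), colnames(beta)))
  }
  missing_probes <- setdiff(act, rownames(beta))
  if (length(missing_probes) > 0) {
    stop("missing active probe(s): ",
         paste(utils::head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) ", ..." else "", call. = FALSE)
  }
  x <- t(unclass(beta)[act, , drop = FALSE])
  w <- object$weights[act]
  if (!is.null(object$scaler)) {
    idx <- match(act, object$scaler$probe_id)
    x <- sweep(sweep(x, 2, object$scaler$mean[idx]), 2,
               object$scaler$sd[idx], "/")
  }
  stats::setNames(as.numeric(x %*% w) + object$intercept, colnames(beta))
}

#' Ordinary least squares on a fixed probe set
#'
#' Unpenalized linear fit of the response on the named probes' raw beta
#' values (plus intercept). Used to show that once an elastic net has named
#' its probes, plain OLS on the same probes predicts comparably.
#'
#' @param data a `meth_dataset`.
#' @param probes probe ids to regress on; must number fewer than the samples.
#' @param response numeric responses or `"age"`.
#' @return list with `model` (dense-weight `clock_model`, no scaler) and
#'   `report` (in-sample [prediction_report()]).
#' @export
ols_on_probes <- function(data, probes, response = "age") {
  stopifnot(inherits(data, "meth_dataset"))
  if (identical(response, "age")) response <- data$samples$age
  y <- as.numeric(response)
  X <- t(unclass(data$beta)[probes, , drop = FALSE])
  if (nrow(X) <= ncol(X)) stop("need more samples than probes for OLS",
                               call. = FALSE)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1) {
    collinear <- colnames(X)[is.na(fit$coefficients[-1])]
    stop("rank deficiency; collinear probe(s): ",
         paste(utils::head(collinear, 5), collapse = ", "), call. = FALSE)
  }
  w <- fit$coefficients[-1]
  model <- new_clock_model(weights = w, intercept = fit$coefficients[1],
                           scaler = NULL, alpha = 0, config = NULL,
                           response_name = "ols")
  pred <- predict(model, data$beta)
  list(model = model,
       report = prediction_report(colnames(data$beta), y, pred,
                                  cohort = data$samples$cohort))
}

#' Group-wise residual summary with Welch tests
#'
#' The cohort-level error analysis: per cohort (optionally within age bins),
#' the sample count, mean and SD of the signed residuals
#' (predicted - actual) and of the absolute residuals, with two-sided
#' unequal-variance (Welch) p-values against the reference cohort.
#'
#' @param report a [prediction_report()] carrying a `cohort` column (or pass
#'   `groups`).
#' @param groups optional cohort labels overriding the report's column.
#' @param age_bins optional numeric bin edges (years); when given, summaries
#'   are computed per closed-open age bin and cohort.
#' @param reference reference cohort for the Welch tests (default
#'   `"healthy"`).
#' @return data.frame with one row per group (x bin), columns n,
#'   mean_residual, sd_residual, p_value, mean_abs_residual, sd_abs_residual,
#'   p_value_abs.
#' @export
residual_summary <- function(report, groups = NULL, age_bins = NULL,
                             reference = "healthy") {
  groups <- groups %||% report$cohort
  if (is.null(groups)) stop("no cohort labels available", call. = FALSE)
  groups <- as.character(groups)
  bins <- if (is.null(age_bins)) rep("all", nrow(report)) else {
    as.character(cut(report$actual, breaks = age_bins, right = FALSE,
                     include.lowest = FALSE))
  }
  out <- list()
  for (b in unique(bins[!is.na(bins)])) {
    in_bin <- !is.na(bins) & bins == b
    ref_resid <- report$residual[in_bin & groups == reference]
    for (g in unique(groups[in_bin])) {
      r <- report$residual[in_bin & groups == g]
      if (length(r) < 2) {
        warning("group '", g, "' in bin ", b, " has n < 2; excluded")
        next
      }
      welch <- function(a, b) {
        if (length(b) < 2 || g == reference) return(NA_real_)
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
          return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
        }
        stats::t.test(a, b, var.equal = FALSE)$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        age_bin = b, cohort = g, n = length(r),
        mean_residual = mean(r), sd_residual = stats::sd(r),
        p_value = welch(r, ref_resid),
        mean_abs_residual = mean(abs(r)),
        sd_abs_residual = stats::sd(abs(r)),
        p_value_abs = welch(abs(r), abs(ref_resid)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
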