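#' Assign ages to consecutive-integer-year bins
#'
#' Bins are closed intervals of `bin_width` consecutive integer years
#' starting at `start` (default: the floor of the youngest age), labelled
#' "25-28", "29-32", ... A 4-year width reproduces the canonical young
#' window 25-28.
#'
#' @param ages numeric ages in years.
#' @param bin_width bin width in integer years.
#' @param start first bin's lower edge; floor of the minimum age if NULL.
#' @return list with per-sample `index` and `label`, plus `index_levels`,
#'   `midpoint_levels`, `label_levels` describing the occupied bins.
#' @export
make_age_bins <- function(ages, bin_width = 4, start = NULL) {
  stopifnot(bin_width >= 1)
  if (is.null(start)) start <- floor(min(ages))
  idx <- (floor(ages) - start) %/% bin_width
  lo <- start + idx * bin_width
  label <- sprintf("%d-%d", lo, lo + bin_width - 1)
  lev <- sort(unique(idx))
  lev_lo <- start + lev * bin_width
  list(index = idx, label = label,
       index_levels = lev,
       midpoint_levels = lev_lo + (bin_width - 1) / 2,
       label_levels = sprintf("%d-%d", lev_lo, lev_lo + bin_width - 1))
}

# Samples whose (integer) age falls in the closed window [young[1], young[2]].
young_mask <- function(ages, young = c(25, 28)) {
  ages >= young[1] & ages < young[2] + 1
}

# Pick the young sample set; falls back to the youngest occupied
# window of the same width (with a warning) when the canonical one is empty.
resolve_young <- function(ages, young = c(25, 28)) {
  m <- young_mask(ages, young)
  if (any(m)) return(list(mask = m, window = young))
  width <- young[2] - young[1]
  lo <- floor(min(ages))
  repeat {
    m <- young_mask(ages, c(lo, lo + width))
    if (any(m)) break
    lo <- lo + 1
  }
  warning("no samples in young window [", young[1], ",", young[2],
          "]; using [", lo, ",", lo + width, "]")
  list(mask = m, window = c(lo, lo + width))
}

# Per-probe Pearson correlation of each row of B with y (NA for constant rows).
row_cor <- function(B, y) {
  yc <- y - mean(y)
  Bc <- B - rowMeans(B)
  denom <- sqrt(rowSums(Bc^2)) * sqrt(sum(yc^2))
  r <- as.numeric(Bc %*% yc) / denom
  r[denom == 0] <- NA_real_
  stats::setNames(r, rownames(B))
}

#' Per-probe reference mean methylation
#'
#' \eqn{\mu_j = \frac{1}{N}\sum_i \beta_{ij}}: the arithmetic mean beta of
#' each probe over the reference samples.
#'
#' @param beta a [beta_matrix()].
#' @param reference_samples sample ids to average over (default: all).
#' @return named numeric vector of per-probe means.
#' @export
probe_mean <- function(beta, reference_samples = NULL) {
  if (is.null(reference_samples)) reference_samples <- colnames(beta)
  if (length(reference_samples) == 0) stop("empty reference sample set",
                                           call. = FALSE)
  rowMeans(unclass(beta)[, reference_samples, drop = FALSE])
}

#' Absolute difference from the mean (ADM)
#'
#' \eqn{\bar{x}_{ij} = |\beta_{ij} - \mu_j|}: each sample's per-probe
#' deviation from the reference mean, the elementary noise contribution.
#'
#' @param beta a [beta_matrix()].
#' @param mu named per-probe means covering every probe of `beta`.
#' @return probes x samples matrix of absolute deviations.
#' @export
adm <- function(beta, mu) {
  missing_probes <- setdiff(rownames(beta), names(mu))
  if (length(missing_probes) > 0) {
    stop("probe(s) missing from mu: ",
         paste(utils::head(missing_probes, 5), collapse = ", "), call. = FALSE)
  }
  abs(unclass(beta) - mu[rownames(beta)])
}

new_selection_report <- function(approach, thresholds, stage_counts, probes,
                                 per_dataset = NULL) {
  structure(list(approach = approach, thresholds = thresholds,
                 stage_counts = stage_counts, probes = probes,
                 per_dataset = per_dataset),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report (approach ", x$approach, "): ",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Noise-detector selection, approach one
#'
#' Two stages on a single dataset: (1) keep probes whose beta-age Pearson
#' correlation is strictly inside the near-invariance window (small but
#' non-zero, excluding the exact zeroes typical of flat experimental
#' artifacts); (2) compute each surviving probe's ADM against the all-sample
#' mean and keep probes whose ADM correlates with age at or above
#' `adm_age_r_min` — on-average invariant, increasingly deviant.
#'
#' @param data a `meth_dataset`.
#' @param r_window `(lower, upper)` bounds on `|r(beta, age)|`, exclusive.
#' @param adm_age_r_min minimum signed Pearson r of ADM vs age.
#' @return a `selection_report` with stage counts and the final probe ids.
#' @export
select_approach1 <- function(data, r_window = c(0.02, 0.05),
                             adm_age_r_min = 0.2) {
  age <- data$samples$age
  if (length(unique(age)) < 2) stop("ages must span >= 2 distinct values",
                                    call. = FALSE)
  B <- unclass(data$beta)
  r <- row_cor(B, age)
  stage1 <- rownames(B)[!is.na(r) & abs(r) > r_window[1] &
                          abs(r) < r_window[2]]
  final <- character(0)
  if (length(stage1) > 0) {
    mu <- probe_mean(data$beta)[stage1]
    A <- abs(B[stage1, , drop = FALSE] - mu)
    r_adm <- row_cor(A, age)
    final <- stage1[!is.na(r_adm) & r_adm >= adm_age_r_min]
  }
  new_selection_report(1L,
                       list(r_window = r_window,
                            adm_age_r_min = adm_age_r_min),
                       c(total = nrow(B), r_window = length(stage1),
                         adm_vs_age = length(final)),
                       final)
}

#' Noise-detector selection, approach two
#'
#' Multi-dataset consensus on mean invariance: per dataset, keep probes
#' whose young-vs-old mean beta difference is below `mean_diff_max`
#' (absolute beta units) and whose beta-age correlation sits inside the
#' near-invariance window; the final set is the intersection across all
#' datasets.
#'
#' @param datasets list of healthy `meth_dataset`s (one per batch/study).
#' @param young young window in years, closed (default 25-28).
#' @param old_min minimum age of the old group (default 67, i.e. 67+).
#' @param mean_diff_max maximum |mean_young - mean_old| in beta units.
#' @param r_window near-invariance window on `|r(beta, age)|`, exclusive.
#' @return a `selection_report`; `per_dataset` holds each dataset's count.
#' @export
select_approach2 <- function(datasets, young = c(25, 28), old_min = 67,
                             mean_diff_max = 0.001,
                             r_window = c(0.02, 0.05)) {
  stopifnot(length(datasets) >= 1)
  per_dataset <- integer(0)
  sets <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    age <- d$samples$age
    y_mask <- young_mask(age, young)
    o_mask <- age >= old_min
    id <- d$samples$dataset_id[1]
    if (sum(y_mask) < 3 || sum(o_mask) < 3) {
      stop("dataset '", id, "' lacks young (n=", sum(y_mask),
           ") or old (n=", sum(o_mask), ") samples", call. = FALSE)
    }
    B <- unclass(d$beta)
    dmean <- abs(rowMeans(B[, y_mask, drop = FALSE]) -
                   rowMeans(B[, o_mask, drop = FALSE]))
    r <- row_cor(B, age)
    pass <- rownames(B)[dmean < mean_diff_max & !is.na(r) &
                          abs(r) > r_window[1] & abs(r) < r_window[2]]
    sets[[k]] <- pass
    per_dataset[id] <- length(pass)
  }
  final <- Reduce(intersect, sets)
  new_selection_report(2L,
                       list(young = young, old_min = old_min,
                            mean_diff_max = mean_diff_max,
                            r_window = r_window),
                       c(total = nrow(datasets[[1]]$beta),
                         max_per_dataset = max(per_dataset),
                         intersection = length(final)),
                       final, per_dataset = per_dataset)
}

#' Stratify selected probes by their dispersion in the young cohort
#'
#' Splits a probe set by how tightly regulated each probe is in the young
#' samples: the young-cohort SD of beta (`mode = "absolute_mean"`) or of
#' beta scaled so the young mean is 1 (`mode = "relative_mean"`, i.e. SD
#' divided by the young mean) is compared against `sd_threshold`.
#' `side = "most_regulated"` keeps SD <= threshold; `"least_regulated"`
#' keeps SD >= threshold. Both `sd_threshold` and `side` must be stated
#' explicitly — the direction is part of the scientific claim, so there is
#' no default.
#'
#' @param data a `meth_dataset`.
#' @param probes candidate probe ids (subset of the data's probes).
#' @param sd_threshold SD cut point (canonical values: 0.015 and 0.3).
#' @param mode `"absolute_mean"` or `"relative_mean"`.
#' @param side `"most_regulated"` or `"least_regulated"`.
#' @param young young window in years.
#' @return character vector of surviving probe ids (possibly empty), with
#'   the per-probe young SDs attached as attribute `young_sd`.
#' @export
stratify_by_young_sd <- function(data, probes, sd_threshold,
                                 mode = c("absolute_mean", "relative_mean"),
                                 side = c("most_regulated",
                                          "least_regulated"),
                                 young = c(25, 28)) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  missing_probes <- setdiff(probes, rownames(data$beta))
  if (length(missing_probes) > 0) stop("unknown probe(s): ",
                                       paste(utils::head(missing_probes, 5),
                                             collapse = ", "), call. = FALSE)
  y_mask <- resolve_young(data$samples$age, young)$mask
  B <- unclass(data$beta)[probes, y_mask, drop = FALSE]
  s <- apply(B, 1, stats::sd)
  if (mode == "relative_mean") {
    m <- rowMeans(B)
    if (any(m <= 0)) stop("relative mode undefined for zero-mean probe",
                          call. = FALSE)
    s <- s / m
  }
  keep <- if (side == "most_regulated") s <= sd_threshold else s >= sd_threshold
  structure(probes[keep], young_sd = s)
}

#' White's test for age-dependent heteroscedasticity of one probe
#'
#' Fits `beta ~ age` by least squares, regresses the squared residuals on
#' `(age, age^2)`, and refers `n * R^2` of that auxiliary regression to a
#' chi-squared distribution with 2 degrees of freedom. A degenerate
#' auxiliary fit (zero or constant squared residuals) returns p = 1 with a
#' `"degenerate"` flag attribute.
#'
#' @param beta_j numeric beta values for one probe.
#' @param age numeric ages, non-constant; n >= 5 required (>= 20
#'   recommended).
#' @return upper-tail p-value with attributes `statistic` and `flag`.
#' @export
white_test <- function(beta_j, age) {
  n <- length(beta_j)
  if (n < 5) stop("need n >= 5", call. = FALSE)
  if (length(age) != n) stop("dimension error: unequal lengths", call. = FALSE)
  if (stats::sd(age) == 0) stop("age is constant", call. = FALSE)
  p <- white_test_matrix(matrix(beta_j, nrow = 1), age)
  out <- p$p[1]
  attr(out, "statistic") <- p$statistic[1]
  attr(out, "flag") <- p$flag[1]
  out
}

# Vectorized White machinery over the rows of B (probes x samples).
white_test_matrix <- function(B, age) {
  n <- ncol(B)
  D <- cbind(1, age)
  C1 <- t(solve(crossprod(D), crossprod(D, t(B))))   # probes x 2
  E2 <- (B - C1 %*% t(D))^2
  Z <- cbind(1, age, age^2)
  C2 <- t(solve(crossprod(Z), crossprod(Z, t(E2))))
  rss <- rowSums((E2 - C2 %*% t(Z))^2)
  tss <- rowSums((E2 - rowMeans(E2))^2)
  degenerate <- tss <= .Machine$double.eps * n
  r2 <- ifelse(degenerate, 0, pmax(0, 1 - rss / tss))
  statistic <- n * r2
  p <- stats::pchisq(statistic, df = 2, lower.tail = FALSE)
  p[degenerate] <- 1
  list(p = p, statistic = statistic,
       flag = ifelse(degenerate, "degenerate", ""))
}

#' Noise-detector selection, approach three
#'
#' Genome-scale heteroscedasticity screen on one (possibly merged) dataset:
#' filter 1 keeps probes significantly heteroscedastic in age by White's
#' test (p < `alpha`); filter 2 keeps probes whose old-group SD exceeds the
#' young-group SD by at least `sd_increase_min` (a 20% rise by default).
#' A two-group variance F-test can replace White's test via
#' `variance_test = "group_f"`.
#'
#' @param data a `meth_dataset`.
#' @param alpha significance level for filter 1.
#' @param sd_increase_min minimum fractional old-over-young SD increase.
#' @param young,old_min group windows (years).
#' @param variance_test `"white"` (default) or `"group_f"`.
#' @return a `selection_report` with counts after each filter.
#' @export
select_approach3 <- function(data, alpha = 0.05, sd_increase_min = 0.20,
                             young = c(25, 28), old_min = 67,
                             variance_test = c("white", "group_f")) {
  variance_test <- match.arg(variance_test)
  age <- data$samples$age
  y_mask <- young_mask(age, young)
  o_mask <- age >= old_min
  if (!any(y_mask) || !any(o_mask)) {
    stop("young or old group is empty", call. = FALSE)
  }
  B <- unclass(data$beta)
  if (variance_test == "white") {
    wt <- white_test_matrix(B, age)
    pass1 <- wt$p < alpha
  } else {
    sd_y2 <- apply(B[, y_mask, drop = FALSE], 1, stats::var)
    sd_o2 <- apply(B[, o_mask, drop = FALSE], 1, stats::var)
    f <- sd_o2 / sd_y2
    p <- stats::pf(f, sum(o_mask) - 1, sum(y_mask) - 1, lower.tail = FALSE)
    pass1 <- p < alpha
  }
  sd_y <- apply(B[, y_mask, drop = FALSE], 1, stats::sd)
  sd_o <- apply(B[, o_mask, drop = FALSE], 1, stats::sd)
  pass2 <- pass1 & sd_o >= (1 + sd_increase_min) * sd_y
  new_selection_report(3L,
                       list(alpha = alpha,
                            sd_increase_min = sd_increase_min,
                            young = young, old_min = old_min,
                            variance_test = variance_test),
                       c(total = nrow(B),
                         heteroscedastic = sum(pass1),
                         sd_increase = sum(pass2)),
                       rownames(B)[pass2])
}

#' Fit a barometer model on a healthy dataset
#'
#' Computes the per-probe reference means, the young-cohort normalizer
#' \eqn{\zeta} (the mean over young samples of each sample's summed ADM),
#' the per-bin noise curve, and a polynomial fit of noise against bin
#' midpoint used for biological-age mapping.
#'
#' @param data a healthy `meth_dataset`.
#' @param probes selected noise-detector probe ids.
#' @param young young window for \eqn{\zeta} (closed, years).
#' @param bin_width age-bin width for the noise curve.
#' @param degree polynomial degree of the noise-age fit (1-5; default 3).
#' @param curve_stat `"median_sigma"` (per-bin median of per-sample noise
#'   scores; default) or `"summed_sd"` (per-bin young-normalized summed SD).
#' @param reference_samples samples defining \eqn{\mu_j} (default: all).
#' @return a `barometer_model`: probes, mu, zeta, young window, polynomial
#'   coefficients (highest degree first), degree, age_domain, bin_width.
#' @export
fit_barometer <- function(data, probes, young = c(25, 28), bin_width = 4,
                          degree = 3, curve_stat = c("median_sigma",
                                                     "summed_sd"),
                          reference_samples = NULL) {
  curve_stat <- match.arg(curve_stat)
  stopifnot(length(probes) >= 1, degree >= 1)
  mu <- probe_mean(data$beta, reference_samples)[probes]
  A <- adm(data$beta[probes, , drop = FALSE], mu)
  sums <- colSums(A)
  yw <- resolve_young(data$samples$age, young)
  zeta <- mean(sums[yw$mask])
  if (!(zeta > 0)) stop("zeta must be positive; young samples have zero ADM",
                        call. = FALSE)
  model <- structure(list(probes = probes, mu = as.list(mu), zeta = zeta,
                          young_definition = yw$window,
                          poly_coefficients = NULL, degree = degree,
                          age_domain = NULL, bin_width = bin_width,
                          curve_stat = curve_stat),
                     class = "barometer_model")
  if (curve_stat == "median_sigma") {
    curve <- median_sigma_curve(data, model, bin_width)
    x <- curve$midpoint; y <- curve$median_sigma
  } else {
    curve <- summed_sd_curve(data, probes, bin_width)
    x <- curve$midpoint; y <- curve$normalized
  }
  model$age_domain <- range(x)
  if (length(x) >= degree + 1) {
    model$poly_coefficients <- fit_noise_curve_xy(x, y, degree)
  } else {
    warning("too few age bins (", length(x), ") for a degree-", degree,
            " fit; no polynomial stored")
  }
  model$curve <- curve
  model
}

#' @export
print.barometer_model <- function(x, ...) {
  cat("barometer_model:", length(x$probes), "probes; zeta =",
      signif(x$zeta, 4), "; young window",
      paste(x$young_definition, collapse = "-"), "y; degree",
      x$degree, "fit on", paste(x$age_domain, collapse = "-"), "y\n")
  invisible(x)
}

#' Per-sample epigenetic noise score
#'
#' \eqn{\sigma_i = \frac{1}{\zeta}\sum_j \bar{x}_{ij}} over the model's
#' probes: each sample's summed absolute deviation from the reference
#' means, normalized so the young cohort used to fit \eqn{\zeta} averages
#' exactly 1.
#'
#' @param data a `meth_dataset` containing every model probe.
#' @param model a `barometer_model` (from [fit_barometer()]).
#' @return named numeric vector of per-sample noise scores.
#' @export
noise_score <- function(data, model) {
  probes <- model$probes
  missing_probes <- setdiff(probes, rownames(data$beta))
  if (length(missing_probes) > 0) {
    stop("probe(s) missing from data: ",
         paste(utils::head(missing_probes, 5), collapse = ", "), call. = FALSE)
  }
  mu <- unlist(model$mu)[probes]
  A <- adm(data$beta[probes, , drop = FALSE], mu)
  colSums(A) / model$zeta
}

#' Binned summed-SD noise curve
#'
#' Per age bin, the sample SD of each selected probe's beta values across
#' the bin's samples, summed over probes; optionally normalized by the
#' youngest valid bin. Bins with fewer than `min_bin_n` samples are
#' excluded and listed in the `excluded_bins` attribute.
#'
#' @param data a `meth_dataset`.
#' @param probes probe ids to sum over.
#' @param bin_width age-bin width (consecutive integer years).
#' @param normalize_by_young divide by the youngest valid bin's value.
#' @param min_bin_n minimum samples per bin (default 2).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return a `noise_curve` data.frame: bin, midpoint, n, summed_sd,
#'   normalized.
#' @export
summed_sd_curve <- function(data, probes, bin_width = 4,
                            normalize_by_young = TRUE, min_bin_n = 2,
                            sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  B <- unclass(data$beta)[probes, , drop = FALSE]
  bins <- make_age_bins(data$samples$age, bin_width)
  counts <- table(bins$index)
  ok <- as.integer(names(counts))[counts >= min_bin_n]
  if (length(ok) < 2) stop("need >= 2 bins with >= ", min_bin_n, " samples",
                           call. = FALSE)
  rows <- lapply(ok, function(b) {
    sub <- B[, bins$index == b, drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (sd_denominator == "n") {
      sds <- sds * sqrt((ncol(sub) - 1) / ncol(sub))
    }
    pos <- match(b, bins$index_levels)
    data.frame(bin = bins$label_levels[pos],
               midpoint = bins$midpoint_levels[pos],
               n = ncol(sub), summed_sd = sum(sds),
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$midpoint), ]
  rownames(curve) <- NULL
  curve$normalized <- if (normalize_by_young) {
    curve$summed_sd / curve$summed_sd[1]
  } else curve$summed_sd
  attr(curve, "excluded_bins") <-
    setdiff(bins$label_levels, curve$bin)
  class(curve) <- c("noise_curve", class(curve))
  curve
}

#' Per-bin median noise score
#'
#' The per-sample noise scores aggregated as a median within each age bin:
#' the curve the biological-age polynomial is fitted to.
#'
#' @inheritParams summed_sd_curve
#' @param model a `barometer_model`.
#' @return data.frame with bin, midpoint, n, median_sigma.
#' @export
median_sigma_curve <- function(data, model, bin_width = 4, min_bin_n = 2) {
  sigma <- noise_score(data, model)
  bins <- make_age_bins(data$samples$age, bin_width)
  counts <- table(bins$index)
  ok <- as.integer(names(counts))[counts >= min_bin_n]
  rows <- lapply(ok, function(b) {
    pos <- match(b, bins$index_levels)
    data.frame(bin = bins$label_levels[pos],
               midpoint = bins$midpoint_levels[pos],
               n = sum(bins$index == b),
               median_sigma = stats::median(sigma[bins$index == b]),
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  curve[order(curve$midpoint), , drop = FALSE]
}

# Least-squares polynomial fit, coefficients returned highest degree first.
fit_noise_curve_xy <- function(x, y, degree) {
  if (length(x) < degree + 1) {
    stop("underdetermined: ", length(x), " points for degree ", degree,
         call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  rev(unname(stats::coef(fit)))
}

#' Fit a polynomial to a noise curve
#'
#' @param curve a [summed_sd_curve()] / [median_sigma_curve()] data.frame
#'   (columns midpoint and normalized / median_sigma / summed_sd).
#' @param degree polynomial degree (needs at least degree+1 bins).
#' @param value which column to fit; defaults to `normalized` when present,
#'   else `median_sigma`.
#' @return numeric coefficients, highest degree first.
#' @export
fit_noise_curve <- function(curve, degree = 3, value = NULL) {
  if (is.null(value)) {
    value <- if ("normalized" %in% names(curve)) "normalized" else
      "median_sigma"
  }
  fit_noise_curve_xy(curve$midpoint, curve[[value]], degree)
}

# Horner evaluation; coefficients highest degree first.
polyval <- function(coef, x) {
  out <- rep(0, length(x))
  for (c_k in coef) out <- out * x + c_k
  out
}

#' Map a noise value onto biological age
#'
#' Inverts the model's noise-vs-age polynomial: finds the real roots of
#' `poly(x) = noise_value` and returns the root inside the age domain.
#' The barometer's construct is that noise rises with age, so with several
#' in-domain roots the one on the longest monotone-increasing branch is
#' returned and a `"multiple_roots"` flag is raised; with none, the nearer
#' domain endpoint is returned with a `"clamped"` flag.
#'
#' @param model a `barometer_model` with a fitted polynomial.
#' @param noise_value noise score / normalized summed SD to invert.
#' @return biological age in years, with attribute `flag` (`""`,
#'   `"multiple_roots"` or `"clamped"`).
#' @export
map_biological_age <- function(model, noise_value) {
  coef <- model$poly_coefficients
  if (is.null(coef) || length(coef) < 2) {
    stop("model has no fitted polynomial of degree >= 1", call. = FALSE)
  }
  dom <- model$age_domain
  shifted <- coef
  shifted[length(shifted)] <- shifted[length(shifted)] - noise_value
  roots <- polyroot(rev(shifted))
  scale <- max(1, abs(noise_value), abs(coef))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * scale])
  tol <- 1e-8 * max(1, abs(dom))
  in_dom <- real[real >= dom[1] - tol & real <= dom[2] + tol]
  in_dom <- pmin(pmax(in_dom, dom[1]), dom[2])
  if (length(in_dom) == 0) {
    lo_gap <- abs(polyval(coef, dom[1]) - noise_value)
    hi_gap <- abs(polyval(coef, dom[2]) - noise_value)
    out <- if (lo_gap <= hi_gap) dom[1] else dom[2]
    attr(out, "flag") <- "clamped"
    return(out)
  }
  if (length(in_dom) == 1) {
    out <- in_dom
    attr(out, "flag") <- ""
    return(out)
  }
  # several candidates: prefer the root on the longest increasing branch
  dcoef <- coef[-length(coef)] * rev(seq_len(length(coef) - 1))
  grid <- seq(dom[1], dom[2], length.out = 257)
  rising <- polyval(dcoef, grid) > 0
  runs <- rle(rising)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  inc <- which(runs$values)
  if (length(inc) > 0) {
    best <- inc[which.max(runs$lengths[inc])]
    branch <- c(grid[starts[best]], grid[ends[best]])
    dist <- pmax(0, pmax(branch[1] - in_dom, in_dom - branch[2]))
    out <- in_dom[which.min(dist)]
  } else {
    out <- in_dom[1]
  }
  attr(out, "flag") <- "multiple_roots"
  out
}

#' Compare healthy and disease noise curves
#'
#' Computes summed-SD curves for both cohorts over the same probes with a
#' *shared* normalizer (the healthy cohort's young bin), so a
#' disease-imposed elevation in noise is directly visible, and reports the
#' per-bin difference on the bins the cohorts share.
#'
#' @param healthy,disease `meth_dataset`s with the same probes.
#' @param probes noise-detector probe ids (a single probe is allowed).
#' @param bin_width age-bin width.
#' @return list with `healthy`, `disease` (noise curves, shared
#'   normalization), `difference` (bin, midpoint, healthy, disease, delta,
#'   sign), and `normalizer`.
#' @export
compare_cohorts <- function(healthy, disease, probes, bin_width = 4) {
  h <- summed_sd_curve(healthy, probes, bin_width, normalize_by_young = FALSE)
  d <- summed_sd_curve(disease, probes, bin_width, normalize_by_young = FALSE)
  normalizer <- h$summed_sd[1]
  h$normalized <- h$summed_sd / normalizer
  d$normalized <- d$summed_sd / normalizer
  shared <- intersect(h$bin, d$bin)
  if (length(shared) == 0) stop("no overlapping age bins", call. = FALSE)
  hi <- h[match(shared, h$bin), ]
  di <- d[match(shared, d$bin), ]
  diff <- data.frame(bin = shared, midpoint = hi$midpoint,
                     healthy = hi$normalized, disease = di$normalized,
                     delta = di$normalized - hi$normalized,
                     stringsAsFactors = FALSE)
  diff$sign <- sign(diff$delta)
  list(healthy = h, disease = d, difference = diff, normalizer = normalizer)
}

#' Batch-resilience check of a noise curve
#'
#' Each dataset's young-normalized summed-SD curve is computed separately;
#' per bin, the across-dataset median is reported together with each
#' dataset's absolute deviation from that median. Bins occupied by a single
#' dataset are flagged.
#'
#' @param datasets list of >= 2 healthy `meth_dataset`s.
#' @param probes noise-detector probe ids.
#' @param bin_width age-bin width.
#' @return list with `median_curve` (bin, midpoint, n_datasets,
#'   median_normalized, flag) and `deviations` (dataset, bin, midpoint,
#'   normalized, deviation).
#' @export
batch_resilience <- function(datasets, probes, bin_width = 4) {
  stopifnot(length(datasets) >= 2)
  curves <- lapply(datasets, function(d) {
    cbind(dataset = d$samples$dataset_id[1],
          summed_sd_curve(d, probes, bin_width),
          stringsAsFactors = FALSE)
  })
  all_curves <- do.call(rbind, curves)
  bins <- unique(all_curves[, c("bin", "midpoint")])
  bins <- bins[order(bins$midpoint), ]
  med <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    vals <- all_curves$normalized[all_curves$bin == bins$bin[i]]
    data.frame(bin = bins$bin[i], midpoint = bins$midpoint[i],
               n_datasets = length(vals),
               median_normalized = stats::median(vals),
               flag = if (length(vals) < 2) "single_dataset" else "",
               stringsAsFactors = FALSE)
  }))
  dev <- merge(all_curves, med[, c("bin", "median_normalized")], by = "bin")
  dev$deviation <- abs(dev$normalized - dev$median_normalized)
  dev <- dev[order(dev$midpoint, dev$dataset),
             c("dataset", "bin", "midpoint", "normalized", "deviation")]
  rownames(dev) <- NULL
  list(median_curve = med, deviations = dev)
}
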