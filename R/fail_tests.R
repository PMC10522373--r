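#' Per-age-bin correlation audit of a clock
#'
#' Whole-range Pearson r between predicted and actual age can be high while
#' within-bin correlations are weak (range restriction): this computes r of
#' predicted vs actual age independently inside each closed-open age bin.
#' Bins with fewer than 3 samples, fewer than 2 distinct ages, or a constant
#' prediction are flagged and report `NA`.
#'
#' @param model a `clock_model`.
#' @param data a `meth_dataset` with ages.
#' @param bin_edges numeric bin edges in years; bin b is `[e_b, e_{b+1})`.
#' @return data.frame with bin_start, bin_end, n, r, flag.
#' @export
binned_correlations <- function(model, data, bin_edges) {
  stopifnot(length(bin_edges) >= 2)
  pred <- predict(model, data$beta)
  age <- data$samples$age
  out <- lapply(seq_len(length(bin_edges) - 1), function(b) {
    in_bin <- age >= bin_edges[b] & age < bin_edges[b + 1]
    n <- sum(in_bin)
    r <- NA_real_; flag <- ""
    if (n < 3) {
      flag <- "too_few_samples"
    } else if (length(unique(age[in_bin])) < 2) {
      flag <- "single_age"
    } else if (stats::sd(pred[in_bin]) == 0) {
      flag <- "constant_prediction"
    } else {
      r <- pearson_r(pred[in_bin], age[in_bin])
    }
    data.frame(bin_start = bin_edges[b], bin_end = bin_edges[b + 1],
               n = n, r = r, flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Remove the clock's probes and retrain
#'
#' The Model-0 / Model-1 experiment: train a clock, delete every probe it
#' selected from the training universe, and retrain with the identical
#' config, seed and split. If the selected probes were uniquely informative
#' biomarkers, the retrained model should collapse; on redundant array data
#' it instead performs nearly as well on a disjoint probe set.
#'
#' @param data a `meth_dataset`.
#' @param config an [elastic_net_config()].
#' @param response responses or `"age"`.
#' @return list with `model0`, `model1`, `report0`, `report1`, and
#'   `overlap` (intersection of the two active sets; empty by construction).
#' @export
remove_and_retrain <- function(data, config = elastic_net_config(),
                               response = "age") {
  fit0 <- train_clock(data, response, config)
  act0 <- active_probes(fit0$model)
  universe <- rownames(data$beta)
  if (length(act0) >= length(universe)) {
    stop("model0 selected every probe; cannot retrain on the remainder",
         call. = FALSE)
  }
  fit1 <- train_clock(data, response, config,
                      probes = setdiff(universe, act0))
  list(model0 = fit0$model, model1 = fit1$model,
       report0 = fit0$report, report1 = fit1$report,
       overlap = intersect(act0, active_probes(fit1$model)))
}

#' Random removal of non-clock probes, retraining at each step
#'
#' Trains a base clock, then for each removal fraction independently draws a
#' uniform-random subset of the *original* non-clock probe list (draws are
#' not nested unless `nested = TRUE`), deletes it, and retrains with the
#' identical config and split. Reports the share of the original clock's
#' active set that the retrained model no longer uses
#' (`unused_fraction`). Stable biomarkers would give a flat zero line;
#' an optimizer re-solving on a perturbed feature space does not.
#'
#' @param data a `meth_dataset`.
#' @param config an [elastic_net_config()].
#' @param fractions sorted removal fractions in \[0,1\].
#' @param seed seed for the removal draws (distinct from the training seed).
#' @param nested if TRUE each draw extends the previous one.
#' @param response responses or `"age"`.
#' @return list with `base` (the original fit) and `scan`, a data.frame of
#'   removal_fraction, n_removed, active_size, unused_fraction.
#' @export
nonclock_removal_scan <- function(data, config = elastic_net_config(),
                                  fractions = seq(0, 0.10, by = 0.01),
                                  seed = config$seed, nested = FALSE,
                                  response = "age") {
  stopifnot(!is.unsorted(fractions), all(fractions >= 0 & fractions <= 1))
  base <- train_clock(data, response, config)
  act0 <- active_probes(base$model)
  universe <- rownames(data$beta)
  nonclock <- setdiff(universe, act0)
  removed_prev <- character(0)
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    n_rm <- round(f * length(nonclock))
    set.seed(substream_seed(seed, sprintf("removal:%d", i)))
    removed <- if (nested) {
      extra <- sample(setdiff(nonclock, removed_prev),
                      max(0, n_rm - length(removed_prev)))
      removed_prev <<- c(removed_prev, extra)
      removed_prev
    } else if (n_rm > 0) sample(nonclock, n_rm) else character(0)
    keep <- setdiff(universe, removed)
    fit <- train_clock(data, response, config, probes = keep)
    act <- active_probes(fit$model)
    data.frame(removal_fraction = f, n_removed = length(removed),
               active_size = length(act),
               unused_fraction = mean(!(act0 %in% act)),
               heldout_r = attr(fit$report, "summary")$pearson_r,
               stringsAsFactors = FALSE)
  })
  list(base = base, scan = do.call(rbind, rows), seed = seed)
}

# Shared rank/fit-quality table machinery for the two rank audits.
rank_signal_table <- function(model, probe_r2, flags) {
  act <- active_probes(model)
  w <- model$weights[act]
  rank <- rank(-abs(w), ties.method = "first")
  tab <- data.frame(probe_id = act, weight = unname(w), rank = rank,
                    r2 = probe_r2[act], flag = flags[act],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  spearman <- if (stats::sd(tab$r2) > 0) {
    stats::cor(tab$rank, tab$r2, method = "spearman")
  } else NA_real_
  structure(list(table = tab, mean_r2 = mean(tab$r2), spearman = spearman),
            class = "rank_signal")
}

#' @export
print.rank_signal <- function(x, ...) {
  cat(sprintf("rank_signal: %d probes; mean R^2 = %.4f; rank~R^2 Spearman = %s\n",
              nrow(x$table), x$mean_r2,
              if (is.na(x$spearman)) "NA" else sprintf("%.3f", x$spearman)))
  invisible(x)
}

#' Weight rank versus age-signal audit
#'
#' For each active probe, regresses its beta values on age and records the
#' fit R-squared against the probe's rank by absolute weight (rank 1 =
#' largest). If clocks selected probes *because* their methylation tracks
#' age, rank and R-squared would be strongly associated; the summary reports
#' the mean R-squared (the flat reference line) and the Spearman correlation
#' of rank vs R-squared. Constant probes get R-squared 0 with a flag.
#'
#' @param model a `clock_model` with >= 2 active probes.
#' @param data a `meth_dataset`.
#' @return a `rank_signal` object: `table` (probe_id, weight, rank, r2,
#'   flag), `mean_r2`, `spearman`.
#' @export
rank_vs_age_signal <- function(model, data) {
  act <- active_probes(model)
  if (length(act) < 2) stop("need >= 2 active probes", call. = FALSE)
  missing_probes <- setdiff(act, rownames(data$beta))
  if (length(missing_probes) > 0) {
    stop("active probe(s) absent from data: ",
         paste(utils::head(missing_probes, 5), collapse = ", "), call. = FALSE)
  }
  age <- data$samples$age
  B <- unclass(data$beta)[act, , drop = FALSE]
  r2 <- numeric(length(act)); names(r2) <- act
  flags <- character(length(act)); names(flags) <- act
  for (p in act) {
    v <- B[p, ]
    if (stats::sd(v) == 0) {
      r2[p] <- 0; flags[p] <- "constant_probe"
    } else {
      r2[p] <- pearson_r(v, age)^2; flags[p] <- ""
    }
  }
  rank_signal_table(model, r2, flags)
}

#' Weight rank versus dispersion-change audit
#'
#' For each active probe, computes the within-age-bin SD of its beta values,
#' regresses those SDs on bin midpoints, and records the R-squared against
#' the probe's weight rank. This asks whether clocks select probes whose
#' *noise* grows with age — the quantity the barometer is built on.
#'
#' @param model a `clock_model`.
#' @param data a `meth_dataset`.
#' @param bin_width_years bin width (consecutive integer years; default 4).
#' @return a `rank_signal` object where `r2` is the SD-vs-age fit quality.
#' @export
rank_vs_sd_change <- function(model, data, bin_width_years = 4) {
  act <- active_probes(model)
  if (length(act) < 2) stop("need >= 2 active probes", call. = FALSE)
  bins <- make_age_bins(data$samples$age, bin_width_years)
  ok_bins <- names(which(table(bins$index) >= 3))
  if (length(ok_bins) < 3) {
    stop("need >= 3 age bins with >= 3 samples each", call. = FALSE)
  }
  mids <- bins$midpoint_levels[match(as.integer(ok_bins), bins$index_levels)]
  B <- unclass(data$beta)[act, , drop = FALSE]
  r2 <- numeric(length(act)); names(r2) <- act
  flags <- character(length(act)); names(flags) <- act
  for (p in act) {
    sds <- vapply(ok_bins, function(b) {
      stats::sd(B[p, bins$index == as.integer(b)])
    }, numeric(1))
    if (stats::sd(sds) == 0) {
      r2[p] <- 0; flags[p] <- "constant_sd"
    } else {
      r2[p] <- pearson_r(sds, mids)^2; flags[p] <- ""
    }
  }
  rank_signal_table(model, r2, flags)
}
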