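#' Construct a validated beta-value matrix
#'
#' A beta matrix holds Illumina-array methylation estimates as probes x
#' samples, each value a beta in \[0,1\] (0 = unmethylated, 1 = methylated).
#' Probes are rows and samples are columns, following the GEO series-matrix
#' convention; all internal computation uses this orientation.
#'
#' @param values numeric matrix (probes x samples); missing values allowed.
#' @param probe_ids,sample_ids row/column identifiers; default to the
#'   dimnames of `values`. Must be unique and non-empty.
#' @return a numeric matrix of class `beta_matrix` with probe/sample dimnames.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("beta_matrix requires probe and sample identifiers", call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids)) {
    stop("dimension mismatch between values and identifiers", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("integrity error: duplicate probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("integrity error: duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta value out of [0,1] at probe '", probe_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "' (value ",
         values[bad[1, , drop = FALSE]], ")", call. = FALSE)
  }
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x), "probes x", ncol(x), "samples;",
      sum(is.na(x)), "missing\n")
  invisible(x)
}

#' Construct a per-sample metadata table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param age numeric ages in years, non-negative.
#' @param cohort cohort labels; `"healthy"` is the distinguished reference
#'   level used by residual summaries and cohort comparisons.
#' @param dataset_id batch / study-of-origin label.
#' @return a `data.frame` with columns sample_id, age, cohort, dataset_id.
#' @export
sample_table <- function(sample_id, age, cohort = "healthy",
                         dataset_id = "dataset1") {
  sample_id <- as.character(sample_id)
  age <- as.numeric(age)
  if (anyDuplicated(sample_id)) {
    stop("integrity error: duplicate sample id(s) in sample table", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("ages must be finite and non-negative", call. = FALSE)
  }
  cohort <- as.character(rep_len(cohort, length(sample_id)))
  if (any(!nzchar(cohort))) stop("cohort labels must be non-empty", call. = FALSE)
  data.frame(sample_id = sample_id, age = age, cohort = cohort,
             dataset_id = as.character(rep_len(dataset_id, length(sample_id))),
             stringsAsFactors = FALSE)
}

validate_sample_table <- function(samples) {
  need <- c("sample_id", "age", "cohort")
  if (!all(need %in% names(samples))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(samples$dataset_id)) samples$dataset_id <- "dataset1"
  sample_table(samples$sample_id, samples$age, samples$cohort,
               samples$dataset_id)
}

#' Read a beta matrix from disk
#'
#' Supports plain CSV (first column = probe id, header = sample ids) and the
#' GEO series-matrix dialect: only the table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` is read, with
#' quoted sample headers unquoted. The markers `"NA"`, `"null"` and the empty
#' string become missing values; any value outside \[0,1\] is rejected with
#' its probe/sample coordinates.
#'
#' @param path file path.
#' @param format `"csv"` or `"series_matrix_tsv"`.
#' @param na_strings tokens treated as missing.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, format = c("csv", "series_matrix_tsv"),
                             na_strings = c("NA", "null", "")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, na.strings = na_strings,
                          stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
      stop("parse error: series-matrix table markers missing or empty in ",
           path, call. = FALSE)
    }
    block <- lines[(begin + 1):(end - 1)]
    df <- utils::read.delim(text = block, check.names = FALSE,
                            na.strings = na_strings, quote = "\"",
                            stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2) {
    stop("parse error: header line defines fewer than two columns in ",
         path, call. = FALSE)
  }
  probe_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  non_numeric <- is.na(vals) & !is.na(as.matrix(df[, -1, drop = FALSE]))
  if (any(non_numeric)) {
    bad <- which(non_numeric, arr.ind = TRUE)[1, ]
    stop("parse error: non-numeric beta at probe '", probe_ids[bad[1]],
         "', column ", bad[2] + 1L, call. = FALSE)
  }
  beta_matrix(vals, probe_ids, colnames(vals))
}

#' Write a beta matrix as canonical CSV
#'
#' Values are serialized with 17 significant digits so that
#' `read_beta_matrix(write_beta_matrix(x))` reproduces `x` bit-exactly.
#'
#' @param beta a [beta_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  txt <- vapply(seq_len(ncol(beta)), function(j) {
    v <- beta[, j]
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }, character(nrow(beta)))
  txt <- matrix(txt, nrow = nrow(beta))
  header <- paste(c("probe_id", colnames(beta)), collapse = ",")
  rows <- paste(rownames(beta), apply(txt, 1, paste, collapse = ","), sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' @param path CSV with columns sample_id, age, cohort and optionally
#'   dataset_id.
#' @return a validated sample table data.frame.
#' @export
read_sample_table <- function(path) {
  validate_sample_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_table
#' @param samples a sample table.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(validate_sample_table(samples), path, row.names = FALSE)
  invisible(path)
}

#' Extract numeric ages from GEO characteristic strings
#'
#' GEO sample characteristics encode age as free text (e.g. `"age: 43"`).
#' The extraction regex is declared per dataset, never guessed; its first
#' capture group must be the numeric age.
#'
#' @param x character vector of characteristic strings.
#' @param regex regular expression whose first capture group is the age.
#' @return numeric ages; NA where the regex does not match.
#' @export
parse_age <- function(x, regex = "age[^0-9]*([0-9]+\\.?[0-9]*)") {
  m <- regmatches(x, regexec(regex, x))
  vapply(m, function(g) if (length(g) >= 2) as.numeric(g[2]) else NA_real_,
         numeric(1))
}

#' Align a beta matrix with a sample table
#'
#' Restricts both objects to their shared samples (in the beta matrix's
#' column order) and enforces completeness: any sample with at least one
#' missing beta among the retained probes is dropped entirely, so downstream
#' statistics see a complete matrix. Probe-wise dropping is available for
#' exploratory use via `missing = "drop_probes"`.
#'
#' @param beta a [beta_matrix()].
#' @param samples a sample table.
#' @param missing `"drop_samples"` (default) or `"drop_probes"`.
#' @return a `meth_dataset`: list with elements `beta` (complete
#'   beta_matrix), `samples` (matching rows, same order) and `dropped`
#'   (number of samples removed for missingness).
#' @export
align <- function(beta, samples, missing = c("drop_samples", "drop_probes")) {
  missing <- match.arg(missing)
  samples <- validate_sample_table(samples)
  shared <- intersect(colnames(beta), samples$sample_id)
  if (length(shared) == 0) {
    stop("alignment error: no shared sample ids", call. = FALSE)
  }
  keep <- colnames(beta)[colnames(beta) %in% shared]
  b <- beta[, keep, drop = FALSE]
  dropped <- 0L
  if (anyNA(b)) {
    if (missing == "drop_samples") {
      complete <- colSums(is.na(b)) == 0
      dropped <- sum(!complete)
      if (!any(complete)) {
        stop("alignment error: every shared sample has missing values",
             call. = FALSE)
      }
      b <- b[, complete, drop = FALSE]
    } else {
      b <- b[rowSums(is.na(b)) == 0, , drop = FALSE]
      if (nrow(b) == 0) {
        stop("alignment error: every probe has missing values", call. = FALSE)
      }
    }
  }
  s <- samples[match(colnames(b), samples$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  out <- list(beta = beta_matrix(unclass(b)), samples = s,
              dropped = as.integer(dropped))
  class(out) <- "meth_dataset"
  out
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat("meth_dataset:", nrow(x$beta), "probes x", ncol(x$beta), "samples (",
      x$dropped, "dropped );",
      "age", min(x$samples$age), "-", max(x$samples$age), "y;",
      "cohorts:", paste(unique(x$samples$cohort), collapse = ", "), "\n")
  invisible(x)
}

#' Load externally published clock coefficients
#'
#' Reads a CSV of `(probe_id, weight)` rows, with an optional intercept row
#' whose probe id is `"(Intercept)"` or `"intercept"`. The result carries no
#' standardization parameters: predictions apply the weights to raw beta
#' values, which is how published coefficient sets are distributed.
#'
#' @param path coefficient CSV.
#' @param response_name label for what the clock predicts.
#' @return a `clock_model`.
#' @export
load_clock_coefficients <- function(path, response_name = "age") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("parse error: expected (probe_id, weight) columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  w <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(w)) {
    stop("parse error: non-numeric weight for probe '",
         ids[which(is.na(w))[1]], "'", call. = FALSE)
  }
  is_int <- tolower(ids) %in% c("(intercept)", "intercept")
  intercept <- if (any(is_int)) sum(w[is_int]) else 0
  new_clock_model(weights = stats::setNames(w[!is_int], ids[!is_int]),
                  intercept = intercept, scaler = NULL, alpha = NA_real_,
                  config = NULL, response_name = response_name)
}

#' Serialize a fitted model to JSON
#'
#' Both clock models and barometer models are stored as versioned JSON so a
#' fit can be archived next to the report it produced and reloaded
#' bit-identically.
#'
#' @param model a `clock_model` or `barometer_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, c("clock_model", "barometer_model")))
  payload <- c(list(schema_version = 1L, model_class = class(model)[1]),
               unclass(model))
  if (!is.null(payload$weights)) payload$weights <- as.list(payload$weights)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

#' @rdname serialize_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$model_class
  p$schema_version <- NULL
  p$model_class <- NULL
  if (identical(cls, "clock_model")) {
    new_clock_model(weights = unlist(p$weights), intercept = p$intercept,
                    scaler = p$scaler, alpha = p$alpha, config = p$config,
                    response_name = p$response_name, meta = p$meta)
  } else if (identical(cls, "barometer_model")) {
    structure(p, class = "barometer_model")
  } else {
    stop("unknown model class in ", path, call. = FALSE)
  }
}

#' Read an Illumina-style probe manifest
#'
#' Minimal manifest join support: a CSV whose first three columns are probe
#' id, gene symbol and genomic coordinate. Used to annotate selected probe
#' sets; gene-function curation is out of scope.
#'
#' @param path manifest CSV.
#' @return data.frame with columns probe_id, gene, coordinates.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("manifest must have >= 3 columns", call. = FALSE)
  stats::setNames(df[, 1:3], c("probe_id", "gene", "coordinates"))
}
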