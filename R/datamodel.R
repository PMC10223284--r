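#' @keywords internal
"_PACKAGE"

# Valid enum levels shared by validation and the generator
.assay_levels <- c("uc_ppb", "hep_clearance", "calibration")
.sample_type_levels <- c("standard", "blank", "T1hr", "T5hr", "AF",
                         "hep_cells", "cellfree_ctrl", "inactivated_ctrl")
.ionization_levels <- c("ionized", "neutral")

.measurement_cols <- c("chem_id", "assay", "sample_type", "batch_id",
                       "replicate", "time_min", "nominal_conc",
                       "response_ratio", "censored")

#' Construct a validated measurement table
#'
#' One row per mass-spectrometry observation: an analyte:internal-standard
#' response ratio together with its assay context (chemical, assay type,
#' sample type, measurement day/batch, replicate, depletion timepoint and,
#' for calibration standards, the nominal at-instrument concentration in nM).
#'
#' @param df data.frame with columns `chem_id`, `assay`, `sample_type`,
#'   `batch_id`, `replicate`, `time_min`, `nominal_conc`, `response_ratio`
#'   and optionally `censored` (logical; responses below the detection
#'   threshold are carried left-censored rather than dropped).
#' @return the validated data.frame with class `tk_measurements`.
#' @export
as_measurements <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"censored" %in% names(df)) df$censored <- FALSE
  missing_cols <- setdiff(.measurement_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, c(.measurement_cols, setdiff(names(df), .measurement_cols))]
  probs <- validate_measurements(df)
  if (length(probs) > 0L) {
    stop("invalid measurement rows:\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  }
  class(df) <- c("tk_measurements", "data.frame")
  df
}

# Row-indexed diagnostics; returns character(0) when clean.
validate_measurements <- function(df) {
  n <- nrow(df)
  probs <- character(0)
  bad <- function(i, msg) sprintf("row %d: %s", i, msg)
  rr <- suppressWarnings(as.numeric(df$response_ratio))
  nonnum <- which(!is.na(df$response_ratio) & is.na(rr))
  for (i in nonnum) probs <- c(probs, bad(i, "non-numeric response_ratio"))
  ok <- setdiff(seq_len(n), nonnum)
  for (i in ok) {
    if (!df$assay[i] %in% .assay_levels) {
      probs <- c(probs, bad(i, paste0("unknown assay '", df$assay[i], "'")))
      next
    }
    if (!df$sample_type[i] %in% .sample_type_levels) {
      probs <- c(probs, bad(i, paste0("unknown sample_type '",
                                      df$sample_type[i], "'")))
      next
    }
    if (df$sample_type[i] == "standard") {
      if (is.na(df$nominal_conc[i]) || df$nominal_conc[i] <= 0)
        probs <- c(probs, bad(i, "standard lacks positive nominal_conc"))
    } else if (!is.na(df$nominal_conc[i])) {
      probs <- c(probs, bad(i, "nominal_conc on a non-standard sample"))
    }
    if (df$assay[i] == "hep_clearance") {
      if (is.na(df$time_min[i]) || df$time_min[i] < 0)
        probs <- c(probs, bad(i, "hep_clearance sample lacks time_min >= 0"))
    } else if (!is.na(df$time_min[i])) {
      probs <- c(probs, bad(i, "time_min outside the depletion assay"))
    }
    if (!is.na(rr[i]) && rr[i] < 0 && !isTRUE(df$censored[i]))
      probs <- c(probs, bad(i, "negative response_ratio"))
    if (is.na(df$replicate[i]) || df$replicate[i] < 1)
      probs <- c(probs, bad(i, "replicate must be >= 1"))
  }
  probs
}

#' Construct a validated chemical table
#'
#' @param df data.frame with columns `chem_id`, `name`, `mol_weight`
#'   (g/mol, > 0), `category`, `ionization_class` ("ionized" or "neutral"),
#'   and optionally `loec` (lowest-observed-effect concentration, uM, > 0)
#'   and `rb` (chemical-specific blood:plasma ratio override, required for
#'   neutral-class chemicals before IVIVE).
#' @return validated data.frame with class `tk_chemicals`.
#' @export
as_chemicals <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("chem_id", "name", "mol_weight", "category", "ionization_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("chemical table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"loec" %in% names(df)) df$loec <- rep(NA_real_, nrow(df))
  if (!"rb" %in% names(df)) df$rb <- rep(NA_real_, nrow(df))
  if (any(!is.na(df$mol_weight) & df$mol_weight <= 0))
    stop("mol_weight must be > 0", call. = FALSE)
  if (any(!is.na(df$loec) & df$loec <= 0))
    stop("loec, when present, must be > 0", call. = FALSE)
  if (any(!df$ionization_class %in% .ionization_levels))
    stop("ionization_class must be 'ionized' or 'neutral'", call. = FALSE)
  if (anyDuplicated(df$chem_id))
    stop("duplicated chem_id in chemical table", call. = FALSE)
  class(df) <- c("tk_chemicals", "data.frame")
  df
}

#' Read a measurement table from CSV
#'
#' Comma-separated, UTF-8, "." decimal. Rows violating the record invariants
#' (standards without a nominal concentration, negative response ratios,
#' depletion samples without a timepoint, ...) are rejected with row-indexed
#' diagnostics.
#'
#' @param path CSV file path.
#' @param schema either "measurements" or "chemicals".
#' @return a `tk_measurements` or `tk_chemicals` data.frame.
#' @export
read_measurements <- function(path, schema = c("measurements", "chemicals")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (schema == "chemicals") return(as_chemicals(df))
  if ("response_ratio" %in% names(df) && is.character(df$response_ratio)) {
    conv <- suppressWarnings(as.numeric(df$response_ratio))
    bad <- which(!is.na(df$response_ratio) & is.na(conv))
    if (length(bad) > 0L)
      stop("non-numeric response_ratio in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    df$response_ratio <- conv
  }
  if ("censored" %in% names(df)) df$censored <- as.logical(df$censored)
  as_measurements(df)
}

#' Write a measurement or chemical table to CSV
#'
#' @param df a validated table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the point-estimate pipeline, the
#' physiological scalars used by IVIVE and the MCMC settings. All cutoffs are
#' fractions in (0, 1).
#'
#' @param alpha_ftest significance level for the depletion-slope F-test.
#' @param plasma_loss_cutoff plasma-stability exclusion: chemicals losing
#'   strictly more than this fraction between T1hr and T5hr are removed.
#' @param abiotic_loss_cutoff cell-free (abiotic) exclusion: loss of this
#'   fraction or more at `abiotic_check_time` excludes the chemical.
#' @param abiotic_check_time minutes; timepoint of the abiotic check.
#' @param ivive an [ivive_params()] list.
#' @param bayes a [bayes_config()] list.
#' @param seed integer seed used by stochastic stages.
#' @return a list with class `tk_config`.
#' @export
pipeline_config <- function(alpha_ftest = 0.05,
                            plasma_loss_cutoff = 0.60,
                            abiotic_loss_cutoff = 0.50,
                            abiotic_check_time = 120,
                            ivive = ivive_params(),
                            bayes = bayes_config(),
                            seed = 1L) {
  stopifnot(alpha_ftest > 0, alpha_ftest < 1,
            plasma_loss_cutoff > 0, plasma_loss_cutoff < 1,
            abiotic_loss_cutoff > 0, abiotic_loss_cutoff < 1,
            abiotic_check_time > 0)
  structure(list(alpha_ftest = alpha_ftest,
                 plasma_loss_cutoff = plasma_loss_cutoff,
                 abiotic_loss_cutoff = abiotic_loss_cutoff,
                 abiotic_check_time = abiotic_check_time,
                 ivive = ivive, bayes = bayes, seed = as.integer(seed)),
            class = "tk_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys matching [pipeline_config()]
#'   arguments override the defaults (nested `ivive:` and `bayes:` blocks
#'   override [ivive_params()] / [bayes_config()] fields).
#' @return a `tk_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  y <- yaml::read_yaml(path)
  iv <- do.call(ivive_params, y$ivive %||% list())
  bc <- do.call(bayes_config, y$bayes %||% list())
  y$ivive <- NULL; y$bayes <- NULL
  do.call(pipeline_config, c(y, list(ivive = iv, bayes = bc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
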