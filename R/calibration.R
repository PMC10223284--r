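#' Fit a response-ratio calibration curve
#'
#' Fits analyte:internal-standard response ratio against nominal
#' at-instrument concentration (nM) by weighted least squares, using either a
#' linear or quadratic model, and evaluates the fit by back-calculating every
#' standard through the inverse curve. A model is `accepted` when each
#' calibration level's back-calculated concentration lies within +/-30% of
#' its nominal value, the usual bioanalytical accuracy rule.
#'
#' @param standards a `tk_measurements` table (or plain data.frame) of
#'   calibration standards for one chemical and batch: columns
#'   `nominal_conc` and `response_ratio`.
#' @param model_form "linear" or "quadratic".
#' @param weighting "none", "1/x" or "1/x2" (weights 1, 1/C, 1/C^2).
#' @return an object of class `calibration_fit`: coefficients (intercept,
#'   slope, curvature), the per-level accuracy table (%), `accepted`, the
#'   calibrated concentration and response ranges, and slots for `emdl` and
#'   `eloq` filled by [estimate_emdl()] / [estimate_eloq()].
#' @seealso [back_calculate()], [select_calibration()]
#' @export
fit_calibration <- function(standards,
                            model_form = c("linear", "quadratic"),
                            weighting = c("none", "1/x", "1/x2")) {
  model_form <- match.arg(model_form)
  weighting <- match.arg(weighting)
  std <- standards[standards$sample_type %||col% "standard" == "standard", ,
                   drop = FALSE]
  std <- std[!is.na(std$nominal_conc) & !is.na(std$response_ratio), ,
             drop = FALSE]
  conc <- std$nominal_conc
  resp <- std$response_ratio
  nlev <- length(unique(conc))
  if (nlev < 3L)
    stop("calibration needs >= 3 distinct nominal levels", call. = FALSE)
  if (nlev < 5L)
    warning("fewer than 5 calibration levels: degenerate curve", call. = FALSE)
  if (model_form == "quadratic" && nlev < 4L)
    stop("quadratic calibration needs >= 4 distinct levels", call. = FALSE)
  if (stats::var(resp) == 0)
    stop("all responses identical: singular calibration fit", call. = FALSE)

  w <- switch(weighting, none = rep(1, length(conc)),
              "1/x" = 1 / conc, "1/x2" = 1 / conc^2)
  fml <- if (model_form == "linear") resp ~ conc else resp ~ conc + I(conc^2)
  fit <- stats::lm(fml, weights = w)
  cf <- stats::coef(fit)
  coefficients <- c(intercept = unname(cf[1]), slope = unname(cf[2]),
                    curvature = if (model_form == "quadratic")
                      unname(cf[3]) else 0)

  obj <- structure(list(
    chem_id = if ("chem_id" %in% names(std)) std$chem_id[1] else NA_character_,
    batch_id = if ("batch_id" %in% names(std)) std$batch_id[1] else NA_character_,
    model_form = model_form, weighting = weighting,
    coefficients = coefficients,
    conc_range = range(conc), resp_range = range(resp),
    emdl = NA_real_, eloq = NA_real_), class = "calibration_fit")

  back <- vapply(resp, function(r) back_calculate(obj, r, check_range = FALSE),
                 numeric(1))
  acc <- 100 * back / conc
  acc_tab <- stats::aggregate(list(accuracy = acc), list(nominal = conc),
                              function(a) a[which.max(abs(a - 100))])
  acc_tab <- acc_tab[order(acc_tab$nominal), ]
  rownames(acc_tab) <- NULL
  obj$accuracy_table <- acc_tab
  obj$accepted <- all(is.finite(acc_tab$accuracy)) &&
    all(abs(acc_tab$accuracy - 100) <= 30)
  if (coefficients["slope"] < 0) {
    warning("negative fitted calibration slope", call. = FALSE)
    obj$accepted <- FALSE
  }
  obj
}

# standards tables may arrive without a sample_type column
`%||col%` <- function(df_col, default) {
  if (is.null(df_col)) default else df_col
}

#' Pick model form and weighting for a calibration batch
#'
#' Tries linear then quadratic; within each form tries unweighted, then 1/x,
#' then 1/x^2 weighting, and returns the first fit whose back-calculation
#' accuracy table passes the +/-30% rule. Falls back to the best-scoring
#' (smallest worst-level deviation) non-accepted fit when none passes.
#'
#' @inheritParams fit_calibration
#' @return a `calibration_fit`.
#' @export
select_calibration <- function(standards) {
  best <- NULL
  best_dev <- Inf
  for (form in c("linear", "quadratic")) {
    for (wt in c("none", "1/x", "1/x2")) {
      fit <- tryCatch(
        suppressWarnings(fit_calibration(standards, form, wt)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (isTRUE(fit$accepted)) return(fit)
      dev <- suppressWarnings(
        max(abs(fit$accuracy_table$accuracy - 100), na.rm = TRUE))
      if (dev < best_dev) { best <- fit; best_dev <- dev }
    }
  }
  if (is.null(best)) stop("no calibration model could be fit", call. = FALSE)
  best
}

#' Back-calculate concentration from a response ratio
#'
#' Inverts the fitted calibration curve. For a quadratic curve the root lying
#' inside [0, 1.2 x top calibration level] is chosen; if both or neither root
#' lies in that domain the result is invalid (NA) rather than an error, since
#' calibration curves are monotone over their validated range.
#'
#' @param model a `calibration_fit`.
#' @param response_ratio observed analyte:IS peak ratio.
#' @param check_range flag responses outside the calibrated response range.
#' @return concentration in nM; NA for invalid inversions. Attributes
#'   `below_range`/`above_range` mark extrapolation when `check_range`.
#' @export
back_calculate <- function(model, response_ratio, check_range = TRUE) {
  stopifnot(inherits(model, "calibration_fit"))
  b0 <- model$coefficients["intercept"]
  b1 <- model$coefficients["slope"]
  b2 <- model$coefficients["curvature"]
  if (is.na(response_ratio)) return(NA_real_)
  if (model$model_form == "linear" || b2 == 0) {
    conc <- (response_ratio - b0) / b1
  } else {
    disc <- b1^2 - 4 * b2 * (b0 - response_ratio)
    if (disc < 0) return(NA_real_)
    roots <- (-b1 + c(1, -1) * sqrt(disc)) / (2 * b2)
    dom <- c(0, 1.2 * model$conc_range[2])
    inside <- roots >= dom[1] & roots <= dom[2]
    if (sum(inside) != 1L) return(NA_real_)
    conc <- roots[inside]
  }
  conc <- unname(conc)
  if (check_range) {
    attr(conc, "below_range") <- response_ratio < model$resp_range[1]
    attr(conc, "above_range") <- response_ratio > model$resp_range[2]
  }
  conc
}

#' Estimated method detection limit (eMDL)
#'
#' The minimum concentration distinguishable from a method blank with 99%
#' confidence, computed from seven replicate injections of a low-end
#' calibration standard: eMDL = sd(back-calculated concentrations) x
#' t(0.99, 6 df), the one-tailed 99% Student-t critical value at 6 degrees
#' of freedom (about 3.14). The t multiplier is evaluated from the
#' t-distribution at run time, so the 7-replicate design is load-bearing:
#' any other replicate count is an error.
#'
#' @param low_level_replicates exactly 7 back-calculated concentrations (nM)
#'   of the same low-end standard.
#' @return eMDL in nM.
#' @export
estimate_emdl <- function(low_level_replicates) {
  x <- low_level_replicates[!is.na(low_level_replicates)]
  if (length(x) != 7L)
    stop("eMDL requires exactly 7 replicate measures (6 df)", call. = FALSE)
  stats::sd(x) * stats::qt(0.99, df = 6)
}

#' Estimated limit of quantitation (eLOQ)
#'
#' The lowest calibration level at which all seven replicate back-calculated
#' concentrations fall within +/-30% of the nominal value.
#'
#' @param levels named list: one element per calibration level (names are the
#'   nominal concentrations, nM), each a vector of 7 back-calculated
#'   concentrations.
#' @param tolerance accuracy half-width as a fraction (default 0.30).
#' @return eLOQ in nM, or NA (flagged via attribute `qualified = FALSE`) when
#'   no level qualifies.
#' @export
estimate_eloq <- function(levels, tolerance = 0.30) {
  noms <- as.numeric(names(levels))
  stopifnot(!anyNA(noms), !is.unsorted(noms))
  for (i in seq_along(levels)) {
    x <- levels[[i]]
    if (length(x) != 7L)
      stop("each eLOQ level needs exactly 7 replicates", call. = FALSE)
    if (all(!is.na(x)) && all(abs(x / noms[i] - 1) <= tolerance)) {
      return(structure(noms[i], qualified = TRUE))
    }
  }
  structure(NA_real_, qualified = FALSE)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s, weighting %s)%s\n", x$model_form,
              x$weighting, if (isTRUE(x$accepted)) "" else " [NOT accepted]"))
  if (!is.na(x$chem_id))
    cat(sprintf("  chemical %s, batch %s\n", x$chem_id, x$batch_id))
  cat(sprintf("  intercept %.4g  slope %.4g ratio/nM",
              x$coefficients["intercept"], x$coefficients["slope"]))
  if (x$coefficients["curvature"] != 0)
    cat(sprintf("  curvature %.4g", x$coefficients["curvature"]))
  cat(sprintf("\n  calibrated range %.4g-%.4g nM\n",
              x$conc_range[1], x$conc_range[2]))
  if (!is.na(x$emdl)) cat(sprintf("  eMDL %.4g nM", x$emdl))
  if (!is.na(x$eloq)) cat(sprintf("  eLOQ %.4g nM", x$eloq))
  if (!is.na(x$emdl) || !is.na(x$eloq)) cat("\n")
  worst <- max(abs(x$accuracy_table$accuracy - 100))
  cat(sprintf("  worst back-calculated accuracy deviation %.2f%%\n", worst))
  invisible(x)
}
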