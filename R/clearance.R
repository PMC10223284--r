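# Scalar converting a first-order depletion rate constant (1/min) measured at
# 50,000 cells/100 uL into intrinsic clearance per million cells:
# 10^6 cells occupy 2000 uL at that density, so Clint [uL/min/10^6 cells]
# = 2000 * k. Equivalently Clint = 2000 * 0.693 / T_half.
.cells_scalar <- 2000

#' Fit a substrate-depletion series
#'
#' Ordinary least squares of ln(concentration) on time (semi-log depletion
#' plot) across all replicate points, with the standard F-test for a nonzero
#' slope. Depletion is declared significant when p < alpha AND the slope is
#' negative; the rate constant is k = -slope, half-life T1/2 = 0.693/k and
#' intrinsic clearance Clint = 2000 x k uL/(min x 10^6 cells) at the assay
#' density of 50,000 cells/100 uL. A non-significant (or positive) slope
#' reports Clint = 0, "no detectable clearance".
#'
#' Censored (below-detection) points are excluded and the series is truncated
#' at the last timepoint retaining at least `min_quantifiable` quantifiable
#' replicates; the truncation time is reported so background subtraction can
#' be matched to the same window.
#'
#' @param time_min timepoints in minutes (one per observation).
#' @param conc concentrations (nM); values <= 0 or NA are treated as censored.
#' @param alpha F-test significance level (default 0.05).
#' @param censored optional logical marking below-detection observations.
#' @param min_quantifiable replicates needed to keep a timepoint (default 2).
#' @return object of class `depletion_fit`: slope (1/min), k, t_half (min),
#'   clint, f_pvalue, significant, truncation_time, n_points, and bookkeeping
#'   slots (`background_k`, `adjusted`, `excluded_abiotic`) filled later.
#' @export
fit_depletion <- function(time_min, conc, alpha = 0.05, censored = NULL,
                          min_quantifiable = 2L) {
  stopifnot(length(time_min) == length(conc), alpha > 0, alpha < 1)
  if (is.null(censored)) censored <- rep(FALSE, length(conc))
  usable <- !censored & !is.na(conc) & conc > 0
  # truncate at the last timepoint with enough quantifiable replicates
  tp <- sort(unique(time_min))
  counts <- vapply(tp, function(t) sum(usable & time_min == t), integer(1))
  keep_tp <- tp[counts >= min_quantifiable]
  if (length(keep_tp) < 2L) {
    return(structure(list(slope = NA_real_, k = NA_real_, t_half = NA_real_,
                          clint = NA_real_, f_pvalue = NA_real_,
                          significant = FALSE, truncation_time = NA_real_,
                          n_points = sum(usable), fitted = NULL,
                          background_k = NA_real_, adjusted = FALSE,
                          excluded_abiotic = FALSE,
                          flag = "insufficient quantifiable timepoints"),
                     class = "depletion_fit"))
  }
  trunc_t <- max(keep_tp)
  sel <- usable & time_min <= trunc_t
  t_ <- time_min[sel]
  y <- log(conc[sel])
  fit <- stats::lm(y ~ t_)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  # F-test of slope = 0; identical to the square of the slope t-statistic
  pval <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
  significant <- is.finite(pval) && pval < alpha && slope < 0
  flag <- NA_character_
  if (is.finite(pval) && pval < alpha && slope > 0)
    flag <- "significant positive slope (anomaly)"
  k <- if (significant) -slope else 0
  t_half <- if (significant) 0.693 / k else Inf
  clint <- .cells_scalar * k
  structure(list(slope = slope, k = k, t_half = t_half, clint = clint,
                 f_pvalue = unname(pval), significant = significant,
                 truncation_time = trunc_t, n_points = length(t_),
                 fitted = fit, background_k = NA_real_, adjusted = FALSE,
                 excluded_abiotic = FALSE, flag = flag),
            class = "depletion_fit")
}

#' Background-adjust a hepatocyte depletion fit
#'
#' Subtracts the cell-free (abiotic) first-order loss rate from the
#' hepatocyte rate: k_met = max(0, k_cells - k_cellfree), Clint = 2000 x
#' k_met. Subtraction is on rate constants since both compartments follow
#' first-order loss. The cell-free fit should be truncated to the hepatocyte
#' fit's truncation time so both rates cover the same window; this function
#' warns when they differ.
#'
#' @param cells_fit `depletion_fit` for the hepatocyte condition.
#' @param cellfree_fit `depletion_fit` for the cell-free control (NULL when
#'   unavailable: the unadjusted rate is returned with a warning).
#' @return the cells fit with `k`, `t_half`, `clint`, `background_k` and
#'   `adjusted` updated.
#' @export
background_adjust <- function(cells_fit, cellfree_fit = NULL) {
  stopifnot(inherits(cells_fit, "depletion_fit"))
  if (is.null(cellfree_fit)) {
    if (isTRUE(cells_fit$significant))
      warning("no cell-free control: clearance reported unadjusted",
              call. = FALSE)
    return(cells_fit)
  }
  stopifnot(inherits(cellfree_fit, "depletion_fit"))
  if (!is.na(cells_fit$truncation_time) &&
      !is.na(cellfree_fit$truncation_time) &&
      cells_fit$truncation_time != cellfree_fit$truncation_time)
    warning("cells and cell-free fits truncated at different timepoints",
            call. = FALSE)
  k_bg <- if (isTRUE(cellfree_fit$significant)) cellfree_fit$k else 0
  k_met <- max(0, cells_fit$k - k_bg)
  cells_fit$background_k <- k_bg
  cells_fit$k <- k_met
  cells_fit$t_half <- if (k_met > 0) 0.693 / k_met else Inf
  cells_fit$clint <- .cells_scalar * k_met
  cells_fit$adjusted <- isTRUE(cellfree_fit$significant)
  cells_fit
}

#' Abiotic-instability exclusion
#'
#' Chemicals losing 50% or more of their cell-free (media only) concentration
#' by the 120-minute check are deemed unstable in the assay matrix and
#' excluded; the comparison is inclusive at exactly 50% loss.
#'
#' @param time_min,conc cell-free series (minutes, nM).
#' @param cutoff loss fraction (default 0.50).
#' @param check_time minutes (default 120).
#' @return list: `excluded`, `loss` (fraction at check_time), `flag` set when
#'   the t = 0 or check-time samples are missing.
#' @export
abiotic_exclusion <- function(time_min, conc, cutoff = 0.50,
                              check_time = 120) {
  stopifnot(cutoff > 0, cutoff < 1, check_time > 0)
  c0 <- conc[time_min == 0 & !is.na(conc)]
  ct <- conc[time_min == check_time & !is.na(conc)]
  if (length(c0) == 0L || mean(c0) <= 0)
    return(list(excluded = FALSE, loss = NA_real_,
                flag = "no t=0 cell-free sample"))
  if (length(ct) == 0L)
    return(list(excluded = FALSE, loss = NA_real_,
                flag = sprintf("no t=%g cell-free sample", check_time)))
  loss <- 1 - mean(ct) / mean(c0)
  list(excluded = loss >= cutoff, loss = loss, flag = NA_character_)
}

#' Hepatocyte clearance analysis for one chemical
#'
#' Back-calculates depletion responses through the batch calibration, fits the
#' hepatocyte and control series (controls truncated to the hepatocyte
#' window), applies the abiotic exclusion rule and background adjustment.
#'
#' @param measurements `tk_measurements` rows of assay "hep_clearance" for
#'   one chemical (sample types hep_cells / cellfree_ctrl /
#'   inactivated_ctrl).
#' @param calibrations named list of `calibration_fit` keyed by batch_id.
#' @param config a `tk_config` (alpha, abiotic cutoff and check time).
#' @param subtract which control drives background subtraction.
#' @return object of class `clearance_result`: per-condition fits, the
#'   adjusted fit, `excluded_abiotic`, and the abiotic loss fraction.
#' @export
hepatic_clearance_analysis <- function(measurements, calibrations,
                                       config = pipeline_config(),
                                       subtract = c("cellfree", "inactivated")) {
  subtract <- match.arg(subtract)
  chem <- unique(measurements$chem_id)
  stopifnot(length(chem) == 1L)
  series <- function(stype) {
    rows <- measurements[measurements$sample_type == stype, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    conc <- vapply(seq_len(nrow(rows)), function(i) {
      cal <- calibrations[[rows$batch_id[i]]]
      if (is.null(cal)) return(NA_real_)
      as.numeric(back_calculate(cal, rows$response_ratio[i],
                                check_range = FALSE))
    }, numeric(1))
    list(time = rows$time_min, conc = conc, censored = rows$censored)
  }
  cells <- series("hep_cells")
  cellfree <- series("cellfree_ctrl")
  inact <- series("inactivated_ctrl")
  if (is.null(cells))
    stop("no hepatocyte samples for ", chem, call. = FALSE)

  cells_fit <- fit_depletion(cells$time, cells$conc,
                             alpha = config$alpha_ftest,
                             censored = cells$censored)
  trunc <- cells_fit$truncation_time
  ctrl_fit <- function(s) {
    if (is.null(s)) return(NULL)
    keep <- if (is.na(trunc)) rep(TRUE, length(s$time)) else s$time <= trunc
    fit_depletion(s$time[keep], s$conc[keep], alpha = config$alpha_ftest,
                  censored = s$censored[keep])
  }
  cellfree_fit <- ctrl_fit(cellfree)
  inact_fit <- ctrl_fit(inact)

  abiotic <- if (!is.null(cellfree)) {
    abiotic_exclusion(cellfree$time, cellfree$conc,
                      cutoff = config$abiotic_loss_cutoff,
                      check_time = config$abiotic_check_time)
  } else list(excluded = FALSE, loss = NA_real_, flag = "no cell-free series")

  bg <- switch(subtract, cellfree = cellfree_fit, inactivated = inact_fit)
  adjusted <- background_adjust(cells_fit, bg)
  adjusted$excluded_abiotic <- isTRUE(abiotic$excluded)

  structure(list(chem_id = chem, fit = adjusted, cells_fit = cells_fit,
                 cellfree_fit = cellfree_fit, inactivated_fit = inact_fit,
                 excluded_abiotic = isTRUE(abiotic$excluded),
                 abiotic_loss = abiotic$loss, abiotic_flag = abiotic$flag),
            class = "clearance_result")
}

#' @export
print.depletion_fit <- function(x, ...) {
  if (is.na(x$slope)) {
    cat("Depletion fit: unfit (", x$flag, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Depletion fit over %d points (truncated at %g min)\n",
              x$n_points, x$truncation_time))
  cat(sprintf("  slope %.5g /min, F-test p = %.3g -> %s\n", x$slope,
              x$f_pvalue,
              if (x$significant) "significant depletion" else "no detectable clearance"))
  if (x$significant || x$adjusted)
    cat(sprintf("  k = %.4g /min, T1/2 = %.4g min, Clint = %.4g uL/(min x 10^6 cells)%s\n",
                x$k, x$t_half, x$clint,
                if (x$adjusted) " [background-adjusted]" else ""))
  invisible(x)
}

#' @export
print.clearance_result <- function(x, ...) {
  cat(sprintf("Hepatocyte clearance result for %s\n", x$chem_id))
  if (x$excluded_abiotic)
    cat(sprintf("  EXCLUDED: abiotic loss %.0f%% at the stability check\n",
                100 * x$abiotic_loss))
  cat(sprintf("  Clint = %.4g uL/(min x 10^6 cells)%s\n", x$fit$clint,
              if (x$fit$adjusted) " (background-adjusted)" else ""))
  invisible(x)
}
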