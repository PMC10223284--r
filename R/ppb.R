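#' Fraction unbound in plasma from ultracentrifugation samples
#'
#' The UC assay spikes plasma to 10 uM, incubates 1 h (T1hr aliquot), spins
#' at 850,000 x g for 4 h and samples the protein-free aqueous fraction (AF)
#' alongside a non-spun aliquot kept at 37 C (T5hr). Fraction unbound in
#' plasma is the AF concentration divided by the T5hr concentration.
#' Replicate aliquots are unpaired, so means are taken before the ratio.
#' Measurement noise can push the raw ratio above 1; the returned `fup` is
#' capped at 1 (the physical maximum) and the raw ratio is kept alongside.
#'
#' @param af_concs back-calculated aqueous-fraction concentrations (nM).
#' @param t5_concs back-calculated T5hr concentrations (nM).
#' @return list: `fup` (capped at 1), `raw_ratio`, `n_af`, `n_t5`,
#'   `valid` (FALSE with `reason` when the estimate is undefined).
#' @export
estimate_fup <- function(af_concs, t5_concs) {
  af <- af_concs[!is.na(af_concs)]
  t5 <- t5_concs[!is.na(t5_concs)]
  if (length(af) < 1L || length(t5) < 1L)
    return(list(fup = NA_real_, raw_ratio = NA_real_,
                n_af = length(af), n_t5 = length(t5),
                valid = FALSE, reason = "no valid replicate pair"))
  m5 <- mean(t5)
  if (m5 <= 0)
    return(list(fup = NA_real_, raw_ratio = NA_real_,
                n_af = length(af), n_t5 = length(t5),
                valid = FALSE, reason = "mean T5hr concentration <= 0"))
  raw <- mean(af) / m5
  list(fup = min(1, raw), raw_ratio = raw,
       n_af = length(af), n_t5 = length(t5), valid = TRUE, reason = NA_character_)
}

#' Plasma-stability screen for the UC assay
#'
#' Percent chemical remaining over the assay (T5hr/T1hr) flags chemicals too
#' unstable in plasma to yield a trustworthy binding estimate. A chemical is
#' excluded when its loss, 1 - mean(T5hr)/mean(T1hr), strictly exceeds the
#' cutoff; exactly 60% loss is retained. With no T1hr measurements the screen
#' cannot run and the chemical is conservatively retained but flagged
#' "stability unknown".
#'
#' @param t1_concs,t5_concs back-calculated concentrations (nM).
#' @param cutoff loss fraction above which the chemical is excluded
#'   (default 0.60).
#' @return list: `stability_ratio` (T5hr/T1hr), `loss`, `excluded`, `flag`.
#' @export
plasma_stability_screen <- function(t1_concs, t5_concs, cutoff = 0.60) {
  stopifnot(cutoff > 0, cutoff < 1)
  t1 <- t1_concs[!is.na(t1_concs)]
  t5 <- t5_concs[!is.na(t5_concs)]
  if (length(t1) < 1L || length(t5) < 1L || mean(t1) <= 0)
    return(list(stability_ratio = NA_real_, loss = NA_real_,
                excluded = FALSE, flag = "stability unknown"))
  ratio <- mean(t5) / mean(t1)
  loss <- 1 - ratio
  list(stability_ratio = ratio, loss = loss,
       excluded = loss > cutoff, flag = NA_character_)
}

#' UC assay analysis for one chemical
#'
#' Back-calculates all UC sample responses through the batch calibration,
#' estimates fraction unbound, and applies the plasma-stability screen.
#' Censored (below-detection) responses are treated as missing by this point
#' estimator; the Bayesian model handles them as left-censored.
#'
#' @param measurements `tk_measurements` rows of assay "uc_ppb" for one
#'   chemical.
#' @param calibrations named list of `calibration_fit` objects keyed by
#'   batch_id.
#' @param cutoff plasma-loss exclusion cutoff.
#' @return object of class `uc_result`: `chem_id`, `fup_point`, `raw_ratio`,
#'   `stability_ratio`, `excluded`, `exclusion_reason`, `replicate_values`.
#' @export
uc_assay_analysis <- function(measurements, calibrations, cutoff = 0.60) {
  chem <- unique(measurements$chem_id)
  stopifnot(length(chem) == 1L)
  conc_of <- function(rows) {
    if (nrow(rows) == 0L) return(numeric(0))
    vapply(seq_len(nrow(rows)), function(i) {
      if (isTRUE(rows$censored[i])) return(NA_real_)
      cal <- calibrations[[rows$batch_id[i]]]
      if (is.null(cal)) return(NA_real_)
      as.numeric(back_calculate(cal, rows$response_ratio[i],
                                check_range = FALSE))
    }, numeric(1))
  }
  af <- conc_of(measurements[measurements$sample_type == "AF", , drop = FALSE])
  t1 <- conc_of(measurements[measurements$sample_type == "T1hr", , drop = FALSE])
  t5 <- conc_of(measurements[measurements$sample_type == "T5hr", , drop = FALSE])

  screen <- plasma_stability_screen(t1, t5, cutoff)
  est <- estimate_fup(af, t5)

  excluded <- isTRUE(screen$excluded) || !est$valid
  reason <- if (isTRUE(screen$excluded)) {
    sprintf("plasma loss %.0f%% > %.0f%%", 100 * screen$loss, 100 * cutoff)
  } else if (!est$valid) est$reason else NA_character_

  structure(list(chem_id = chem,
                 fup_point = est$fup, raw_ratio = est$raw_ratio,
                 stability_ratio = screen$stability_ratio,
                 stability_flag = screen$flag,
                 excluded = excluded, exclusion_reason = reason,
                 replicate_values = list(AF = af, T1hr = t1, T5hr = t5)),
            class = "uc_result")
}

#' Summarize fraction unbound across a cohort
#'
#' @param results list of `uc_result` objects (excluded chemicals are
#'   dropped), or a numeric vector of capped fup values.
#' @return named vector: min, p25, median, mean, p75, max, n. Percentiles use
#'   linear interpolation (`stats::quantile` type 7).
#' @export
summarize_fup <- function(results) {
  vals <- if (is.numeric(results)) results else
    vapply(Filter(function(r) !r$excluded, results),
           function(r) r$fup_point, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    return(c(min = NA, p25 = NA, median = NA, mean = NA, p75 = NA,
             max = NA, n = 0))
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(min = min(vals), p25 = q[1], median = q[2], mean = mean(vals),
    p75 = q[3], max = max(vals), n = length(vals))
}

#' Reference-compound (4NT) batch check
#'
#' 4-nitrotoluene is carried in every UC batch as a performance reference.
#' Each batch's 4NT fraction unbound is compared against a configured
#' historical band; out-of-band batches get a warning flag.
#'
#' @param results list of `uc_result` objects for the reference compound,
#'   one per batch (names = batch ids).
#' @param band length-2 numeric, the acceptable fup interval.
#' @return data.frame: batch, fup, in_band.
#' @export
check_reference_compound <- function(results, band = c(0.05, 0.5)) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  out <- data.frame(
    batch = names(results) %||% as.character(seq_along(results)),
    fup = vapply(results, function(r)
      if (is.list(r)) r$fup_point else as.numeric(r), numeric(1)))
  out$in_band <- !is.na(out$fup) & out$fup >= band[1] & out$fup <= band[2]
  for (i in which(!out$in_band))
    warning(sprintf("reference compound out of band in batch %s (fup=%.3g)",
                    out$batch[i], out$fup[i]), call. = FALSE)
  out
}

#' @export
print.uc_result <- function(x, ...) {
  cat(sprintf("UC assay result for %s\n", x$chem_id))
  if (x$excluded) {
    cat(sprintf("  EXCLUDED: %s\n", x$exclusion_reason))
  } else {
    cat(sprintf("  fup = %.4g (raw ratio %.4g)\n", x$fup_point, x$raw_ratio))
  }
  if (!is.na(x$stability_ratio))
    cat(sprintf("  plasma stability T5hr/T1hr = %.3f\n", x$stability_ratio))
  invisible(x)
}
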