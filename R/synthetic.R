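#' Specification for the synthetic assay-data generator
#'
#' Bundles the ground truth and design of one simulated chemical. Defaults
#' mirror the laboratory designs: 15-point calibration curves spanning
#' 1.75-1250 nM (plasma assay) and 7-5000 nM (hepatocyte assay) at the
#' instrument, a 10 uM ultracentrifugation assay with 3 replicates (250 nM at
#' the instrument after the 1:3 acetonitrile crash and 1:10 analytical
#' dilution), and a 1 uM depletion assay at 50,000 cells/100 uL with
#' triplicate timepoints at {0, 15, 30, 60, 120, 240} min plus cell-free and
#' inactivated-hepatocyte controls (50 nM at the instrument after the 1:1
#' crash and 1:9 dilution).
#'
#' Responses are generated from the true calibration line with
#' heteroscedastic Normal noise, sd = sqrt(sigma0^2 + (cv * mu)^2) - the same
#' family the Bayesian measurement model assumes, so coverage tests are
#' well-posed. `lognormal_noise = TRUE` switches to multiplicative lognormal
#' response noise to probe misspecification.
#'
#' @param chem_id,name identifiers of the simulated chemical.
#' @param true_fup true fraction unbound in plasma, in [0, 1].
#' @param true_D true T1hr->T5hr plasma stability fraction, in (0, 1].
#' @param true_k_met,true_k_bg true metabolic and abiotic first-order rate
#'   constants, 1/min (Clint truth = 2000 * true_k_met).
#' @param mol_weight,loec,ionization_class,rb chemical attributes passed
#'   through to the chemical table.
#' @param beta0,beta1,beta2 true calibration coefficients (ratio, ratio/nM,
#'   ratio/nM^2).
#' @param sigma0 additive response noise sd.
#' @param cv proportional response noise (fraction of the mean response).
#' @param pipetting_sdlog lognormal sd of the latent incubation
#'   concentrations around nominal.
#' @param cal_levels number of calibration levels.
#' @param cal_range_uc,cal_range_hep calibration ranges, nM at instrument.
#' @param cal_replicates replicate injections per calibration level (the
#'   routine replicate count is not pinned by the assay design; 1 by
#'   default, with the 7-injection low-level set generated separately for
#'   detection limits).
#' @param uc_replicates UC assay replicates (3).
#' @param depletion_times depletion timepoint grid, min.
#' @param depletion_replicates replicates per depletion timepoint (3).
#' @param uc_nominal,hep_nominal nominal at-instrument concentrations, nM.
#' @param censor_at_emdl censor generated responses below the batch eMDL
#'   (computed from 7 synthetic low-level replicates), the default; negative
#'   response draws are censored regardless.
#' @param lognormal_noise use multiplicative lognormal response noise
#'   instead of the heteroscedastic Normal family.
#' @param seed integer seed; identical spec + seed give identical tables.
#' @return a list with class `generator_spec`.
#' @export
generator_spec <- function(chem_id = "SYN0001", name = "synthetic chemical",
                           true_fup = 0.1, true_D = 1,
                           true_k_met = 0.01, true_k_bg = 0,
                           mol_weight = 300, loec = NA_real_,
                           ionization_class = "ionized", rb = NA_real_,
                           beta0 = 0, beta1 = 0.002, beta2 = 0,
                           sigma0 = 0.001, cv = 0.10,
                           pipetting_sdlog = 0.05,
                           cal_levels = 15,
                           cal_range_uc = c(1.75, 1250),
                           cal_range_hep = c(7, 5000),
                           cal_replicates = 1,
                           uc_replicates = 3,
                           depletion_times = c(0, 15, 30, 60, 120, 240),
                           depletion_replicates = 3,
                           uc_nominal = 250, hep_nominal = 50,
                           censor_at_emdl = TRUE,
                           lognormal_noise = FALSE,
                           seed = 1L) {
  stopifnot(true_fup >= 0, true_fup <= 1, true_D > 0, true_D <= 1,
            true_k_met >= 0, true_k_bg >= 0, cv >= 0, sigma0 >= 0,
            cal_levels >= 2, uc_replicates >= 1, depletion_replicates >= 1,
            length(depletion_times) >= 2, !is.unsorted(depletion_times),
            all(depletion_times >= 0))
  spec <- as.list(environment())
  spec$seed <- as.integer(seed)
  structure(spec, class = "generator_spec")
}

# True mean response at concentration conc, and one noisy draw from it.
.true_response <- function(spec, conc) {
  spec$beta0 + spec$beta1 * conc + spec$beta2 * conc^2
}

.noisy_response <- function(spec, conc) {
  mu <- .true_response(spec, conc)
  if (spec$lognormal_noise) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog) +
      stats::rnorm(length(mu), 0, spec$sigma0)
  } else {
    stats::rnorm(length(mu), mu, sqrt(spec$sigma0^2 + (spec$cv * mu)^2))
  }
}

.blank_row <- function(spec, assay, batch_id, replicate) {
  data.frame(chem_id = spec$chem_id, assay = assay, sample_type = "blank",
             batch_id = batch_id, replicate = replicate, time_min = NA_real_,
             nominal_conc = NA_real_,
             response_ratio = pmax(0, stats::rnorm(1, spec$beta0, spec$sigma0)),
             censored = FALSE)
}

#' Generate calibration standards
#'
#' Geometric level spacing across the assay's stated range; responses follow
#' the true calibration curve with the spec's noise model. Includes one blank
#' per batch.
#'
#' @param spec a [generator_spec()].
#' @param assay "uc_ppb" or "hep_clearance" (selects the calibration range).
#' @param batch_id measurement-day identifier for the standards.
#' @return `tk_measurements` of standards + blank.
#' @export
generate_calibration <- function(spec, assay = c("uc_ppb", "hep_clearance"),
                                 batch_id = "batch1") {
  assay <- match.arg(assay)
  set.seed(spec$seed + 101L)
  rng <- if (assay == "uc_ppb") spec$cal_range_uc else spec$cal_range_hep
  levels <- exp(seq(log(rng[1]), log(rng[2]), length.out = spec$cal_levels))
  conc <- rep(levels, each = spec$cal_replicates)
  df <- data.frame(chem_id = spec$chem_id, assay = "calibration",
                   sample_type = "standard", batch_id = batch_id,
                   replicate = rep(seq_len(spec$cal_replicates),
                                   times = spec$cal_levels),
                   time_min = NA_real_, nominal_conc = conc,
                   response_ratio = pmax(0, .noisy_response(spec, conc)),
                   censored = FALSE)
  as_measurements(rbind(df, .blank_row(spec, "calibration", batch_id, 1L)))
}

# Response-scale censoring threshold from 7 synthetic low-level replicates:
# back-calculate through the true line, take sd x t(.99, 6), convert back to
# a response. Returns 0 (censor nothing) unless spec$censor_at_emdl.
.censor_threshold <- function(spec, assay) {
  if (!isTRUE(spec$censor_at_emdl)) return(0)
  rng <- if (assay == "uc_ppb") spec$cal_range_uc else spec$cal_range_hep
  low <- rng[1]
  y7 <- .noisy_response(spec, rep(low, 7))
  conc7 <- (y7 - spec$beta0) / spec$beta1  # true line is linear in practice
  emdl <- estimate_emdl(conc7)
  .true_response(spec, emdl)
}

# Mark assay responses below the threshold as left-censored. Negative draws
# (possible near zero concentration under additive noise) are always
# censored: a peak ratio cannot be negative, such samples are below
# detection.
.apply_censoring <- function(df, threshold) {
  cens <- df$sample_type != "standard" & !is.na(df$response_ratio) &
    df$response_ratio < max(0, threshold)
  df$censored <- df$censored | cens
  df$response_ratio[cens] <- NA_real_
  df$response_ratio[df$sample_type == "standard"] <-
    pmax(0, df$response_ratio[df$sample_type == "standard"])
  df
}

#' Generate an ultracentrifugation (plasma binding) assay
#'
#' Latent incubation concentration lognormal around the nominal
#' at-instrument level; T5hr = D x T1hr, AF = fup x T5hr; responses through
#' the true calibration curve plus noise; optional censoring below the
#' synthetic eMDL.
#'
#' @inheritParams generate_calibration
#' @return `tk_measurements` with T1hr, T5hr and AF rows.
#' @export
generate_uc_assay <- function(spec, batch_id = "batch1") {
  set.seed(spec$seed + 202L)
  n <- spec$uc_replicates
  c1 <- spec$uc_nominal *
    stats::rlnorm(n, -spec$pipetting_sdlog^2 / 2, spec$pipetting_sdlog)
  c5 <- spec$true_D * spec$uc_nominal *
    stats::rlnorm(n, -spec$pipetting_sdlog^2 / 2, spec$pipetting_sdlog)
  caf <- spec$true_fup * spec$true_D * spec$uc_nominal *
    stats::rlnorm(n, -spec$pipetting_sdlog^2 / 2, spec$pipetting_sdlog)
  row <- function(stype, conc) {
    data.frame(chem_id = spec$chem_id, assay = "uc_ppb", sample_type = stype,
               batch_id = batch_id, replicate = seq_len(n),
               time_min = NA_real_, nominal_conc = NA_real_,
               response_ratio = .noisy_response(spec, conc), censored = FALSE)
  }
  df <- rbind(row("T1hr", c1), row("T5hr", c5), row("AF", caf))
  df <- .apply_censoring(df, .censor_threshold(spec, "uc_ppb"))
  as_measurements(df)
}

#' Generate a substrate-depletion assay
#'
#' Hepatocyte series decays at k_met + k_bg, cell-free and inactivated
#' controls at k_bg, from lognormal latent starting concentrations;
#' triplicates per timepoint; optional censoring below the synthetic eMDL.
#'
#' @inheritParams generate_calibration
#' @return `tk_measurements` with hep_cells, cellfree_ctrl and
#'   inactivated_ctrl rows.
#' @export
generate_depletion <- function(spec, batch_id = "batch1") {
  set.seed(spec$seed + 303L)
  times <- spec$depletion_times
  n <- spec$depletion_replicates
  series <- function(stype, k) {
    c0 <- spec$hep_nominal *
      stats::rlnorm(1, -spec$pipetting_sdlog^2 / 2, spec$pipetting_sdlog)
    tt <- rep(times, each = n)
    conc <- c0 * exp(-k * tt)
    data.frame(chem_id = spec$chem_id, assay = "hep_clearance",
               sample_type = stype, batch_id = batch_id,
               replicate = rep(seq_len(n), times = length(times)),
               time_min = tt, nominal_conc = NA_real_,
               response_ratio = .noisy_response(spec, conc), censored = FALSE)
  }
  df <- rbind(series("hep_cells", spec$true_k_met + spec$true_k_bg),
              series("cellfree_ctrl", spec$true_k_bg),
              series("inactivated_ctrl", spec$true_k_bg))
  df <- .apply_censoring(df, .censor_threshold(spec, "hep_clearance"))
  as_measurements(df)
}

#' Generate the full measurement bundle for one chemical
#'
#' Calibration standards for both assays (distinct batch ids), the UC assay
#' and the depletion assay.
#'
#' @param spec a [generator_spec()].
#' @return list: `measurements` (one `tk_measurements` table), `chemical`
#'   (one-row `tk_chemicals`), `truth` (named list of the generating values).
#' @export
generate_chemical <- function(spec) {
  b_uc <- paste0(spec$chem_id, "_uc_d1")
  b_hep <- paste0(spec$chem_id, "_hep_d1")
  cal_uc <- generate_calibration(spec, "uc_ppb", b_uc)
  cal_hep <- generate_calibration(spec, "hep_clearance", b_hep)
  uc <- generate_uc_assay(spec, b_uc)
  dep <- generate_depletion(spec, b_hep)
  meas <- as_measurements(rbind(as.data.frame(cal_uc), as.data.frame(cal_hep),
                                as.data.frame(uc), as.data.frame(dep)))
  chem <- as_chemicals(data.frame(
    chem_id = spec$chem_id, name = spec$name, mol_weight = spec$mol_weight,
    category = "synthetic", ionization_class = spec$ionization_class,
    loec = spec$loec, rb = spec$rb))
  truth <- list(fup = spec$true_fup, D = spec$true_D,
                k_met = spec$true_k_met, k_bg = spec$true_k_bg,
                clint = 2000 * spec$true_k_met)
  list(measurements = meas, chemical = chem, truth = truth)
}

#' Generate a synthetic cohort with known truth
#'
#' Samples true fractions unbound from a right-skewed lognormal body capped
#' at 1 (reproducing the skew of measured PFAS binding: a low median with a
#' long tail toward weak binding) and intrinsic clearance from a mixture with
#' a point mass at zero (metabolically stable chemicals). Emits the combined
#' measurement and chemical tables plus a truth table for recovery scoring.
#'
#' @param n_chemicals cohort size (the measured PFAS cohort was 43).
#' @param seed integer seed.
#' @param fup_meanlog,fup_sdlog lognormal body of true fup (defaults give a
#'   median near 0.09 with mean > median after capping at 1).
#' @param p_zero_clint probability a chemical has no metabolic clearance.
#' @param kmet_meanlog,kmet_sdlog lognormal of true k_met for cleared
#'   chemicals (1/min).
#' @param cv response noise passed to each chemical's [generator_spec()].
#' @param ... further arguments forwarded to [generator_spec()].
#' @return list: `truth` (data.frame), `measurements`, `chemicals`.
#' @export
generate_cohort <- function(n_chemicals = 43, seed = 1L,
                            fup_meanlog = log(0.09), fup_sdlog = 1.2,
                            p_zero_clint = 0.3,
                            kmet_meanlog = log(0.008), kmet_sdlog = 0.6,
                            cv = 0.10, ...) {
  stopifnot(n_chemicals >= 1)
  set.seed(seed)
  fup <- pmin(1, stats::rlnorm(n_chemicals, fup_meanlog, fup_sdlog))
  zero <- stats::runif(n_chemicals) < p_zero_clint
  kmet <- ifelse(zero, 0, stats::rlnorm(n_chemicals, kmet_meanlog, kmet_sdlog))
  seeds <- sample.int(1e6, n_chemicals)
  bundles <- lapply(seq_len(n_chemicals), function(i) {
    spec <- generator_spec(chem_id = sprintf("SYN%04d", i),
                           name = sprintf("synthetic chemical %d", i),
                           true_fup = fup[i], true_k_met = kmet[i],
                           cv = cv, seed = seeds[i], ...)
    generate_chemical(spec)
  })
  truth <- data.frame(
    chem_id = vapply(bundles, function(b) b$chemical$chem_id, character(1)),
    true_fup = fup, true_k_met = kmet, true_clint = 2000 * kmet)
  meas <- as_measurements(
    do.call(rbind, lapply(bundles, function(b) as.data.frame(b$measurements))))
  chems <- as_chemicals(
    do.call(rbind, lapply(bundles, function(b) as.data.frame(b$chemical))))
  list(truth = truth, measurements = meas, chemicals = chems)
}
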