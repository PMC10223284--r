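# Shared fixture builders: everything is generated in code at test time.

# Quick standards table on an exact curve (optionally perturbed).
make_standards <- function(conc, response, chem_id = "CHEM1",
                           batch_id = "b1") {
  data.frame(chem_id = chem_id, assay = "calibration",
             sample_type = "standard", batch_id = batch_id,
             replicate = 1L, time_min = NA_real_, nominal_conc = conc,
             response_ratio = response, censored = FALSE)
}

# The laboratory plasma calibration grid: 15 geometric levels 1.75-1250 nM.
plasma_levels <- function(n = 15)
  exp(seq(log(1.75), log(1250), length.out = n))

# Minimal UC measurement rows from explicit response ratios.
make_uc_rows <- function(responses, sample_type, chem_id = "CHEM1",
                         batch_id = "b1") {
  data.frame(chem_id = chem_id, assay = "uc_ppb", sample_type = sample_type,
             batch_id = batch_id, replicate = seq_along(responses),
             time_min = NA_real_, nominal_conc = NA_real_,
             response_ratio = responses, censored = FALSE)
}

# Reduced-size MCMC settings used across the Bayesian tests.
test_bayes_config <- function(seed = 1L, ...) {
  bayes_config(n_chains = 4, burn_in = 2000, iterations = 5000,
               samples_per_chain = 1000, max_extensions = 3, seed = seed, ...)
}

# One chemical's combined standards + UC table from the generator.
uc_dataset <- function(spec) {
  as_measurements(rbind(
    as.data.frame(generate_calibration(spec, "uc_ppb", "b1")),
    as.data.frame(generate_uc_assay(spec, "b1"))))
}

# One chemical's combined standards + depletion table from the generator.
depletion_dataset <- function(spec) {
  as_measurements(rbind(
    as.data.frame(generate_calibration(spec, "hep_clearance", "b1")),
    as.data.frame(generate_depletion(spec, "b1"))))
}

# Point-estimate fup from a combined table (calibration + back-calculation).
point_fup <- function(m) {
  cal <- select_calibration(m[m$sample_type == "standard", ])
  cc <- function(st) {
    rows <- m[m$sample_type == st & !m$censored, ]
    vapply(rows$response_ratio, function(r)
      as.numeric(back_calculate(cal, r, check_range = FALSE)), numeric(1))
  }
  estimate_fup(cc("AF"), cc("T5hr"))$fup
}

# Point-estimate clearance result from a combined table.
point_clearance <- function(m, config = pipeline_config()) {
  cal <- select_calibration(m[m$sample_type == "standard", ])
  hepatic_clearance_analysis(
    m[m$assay == "hep_clearance" & m$sample_type != "standard", ],
    stats::setNames(list(cal), unique(m$batch_id)), config)
}
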