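#' Run the full in vitro toxicokinetics pipeline
#'
#' For each chemical with measurements: fit one calibration per batch
#' (measurement day), back-calculate assay samples, estimate fraction unbound
#' (with the plasma-stability screen) and intrinsic clearance (with abiotic
#' exclusion and background adjustment), and, where both an f_up and a Cl_int
#' (possibly an explicit zero, "no detectable clearance") survive, extrapolate
#' to steady-state concentration and administered equivalent dose. Chemicals
#' failing a screen, or lacking calibration standards, land in the exclusion
#' log and the pipeline continues; every chemical with data appears exactly
#' once, in the results or in the exclusion log.
#'
#' @param measurements a `tk_measurements` table (all chemicals, all assays).
#' @param chemicals a `tk_chemicals` table.
#' @param config a [pipeline_config()].
#' @param bayes also run the Bayesian uncertainty models per chemical
#'   (slower; uses `config$bayes`).
#' @return object of class `tk_pipeline_result`: `results` (one row per
#'   retained chemical: fup, stability_ratio, clint, f_pvalue, fub, cl_renal,
#'   cl_hep, css, aed, and credible intervals when `bayes`), `exclusions`
#'   (chem_id, reason), `details` (per-chemical fit objects).
#' @export
run_pipeline <- function(measurements, chemicals, config = pipeline_config(),
                         bayes = FALSE) {
  stopifnot(is.data.frame(measurements), is.data.frame(chemicals))
  chems <- unique(measurements$chem_id)
  if (length(chems) == 0L) {
    warning("empty measurement table: nothing to analyse", call. = FALSE)
    return(structure(list(results = data.frame(), exclusions = data.frame(),
                          details = list()), class = "tk_pipeline_result"))
  }
  rows <- list()
  excl <- list()
  details <- list()
  for (chem in chems) {
    m <- measurements[measurements$chem_id == chem, , drop = FALSE]
    std <- m[m$sample_type == "standard", , drop = FALSE]
    if (nrow(std) == 0L) {
      excl[[chem]] <- "no calibration"
      next
    }
    cals <- lapply(split(std, std$batch_id), function(s)
      tryCatch(select_calibration(s), error = function(e) NULL))
    cals <- Filter(Negate(is.null), cals)
    if (length(cals) == 0L) {
      excl[[chem]] <- "no calibration"
      next
    }

    uc_m <- m[m$assay == "uc_ppb" & m$sample_type != "standard", ,
              drop = FALSE]
    uc <- if (nrow(uc_m) > 0L)
      uc_assay_analysis(uc_m, cals, cutoff = config$plasma_loss_cutoff)
    else NULL

    hep_m <- m[m$assay == "hep_clearance" & m$sample_type != "standard", ,
               drop = FALSE]
    hep <- if (nrow(hep_m) > 0L && any(hep_m$sample_type == "hep_cells"))
      hepatic_clearance_analysis(hep_m, cals, config)
    else NULL

    detail <- list(calibrations = cals, uc = uc, clearance = hep)

    if (!is.null(uc) && uc$excluded) {
      excl[[chem]] <- uc$exclusion_reason
      details[[chem]] <- detail
      next
    }
    if (!is.null(hep) && hep$excluded_abiotic) {
      excl[[chem]] <- sprintf("abiotic loss %.0f%% at stability check",
                              100 * hep$abiotic_loss)
      details[[chem]] <- detail
      next
    }

    row <- data.frame(
      chem_id = chem,
      fup = if (!is.null(uc)) uc$fup_point else NA_real_,
      fup_raw = if (!is.null(uc)) uc$raw_ratio else NA_real_,
      stability_ratio = if (!is.null(uc)) uc$stability_ratio else NA_real_,
      clint = if (!is.null(hep)) hep$fit$clint else NA_real_,
      clint_significant = if (!is.null(hep)) hep$fit$significant else NA,
      f_pvalue = if (!is.null(hep)) hep$fit$f_pvalue else NA_real_)

    if (isTRUE(bayes)) {
      cl <- .pipeline_censor_limits(cals)
      if (!is.null(uc)) {
        post <- run_mcmc(build_uc_model(rbind(
          m[m$sample_type == "standard" &
              m$batch_id %in% unique(uc_m$batch_id), ], uc_m),
          censor_limits = cl), config$bayes)
        s <- post$summary[post$summary$parameter == "fup", ]
        row$fup_median <- s$median
        row$fup_ci_lower <- s$ci_lower
        row$fup_ci_upper <- s$ci_upper
        row$fup_uncertain <- s$uncertain
        detail$uc_posterior <- post
      }
      if (!is.null(hep)) {
        post <- run_mcmc(build_clearance_model(rbind(
          m[m$sample_type == "standard" &
              m$batch_id %in% unique(hep_m$batch_id), ], hep_m),
          censor_limits = cl), config$bayes)
        s <- post$summary[post$summary$parameter == "clint", ]
        row$clint_median <- s$median
        row$clint_ci_lower <- s$ci_lower
        row$clint_ci_upper <- s$ci_upper
        row$clint_uncertain <- s$uncertain
        detail$clearance_posterior <- post
      }
    }

    ch <- chemicals[chemicals$chem_id == chem, , drop = FALSE]
    have_fup <- !is.na(row$fup) && row$fup > 0
    have_clint <- !is.na(row$clint)
    if (nrow(ch) == 1L && have_fup && have_clint) {
      iv <- tryCatch(
        ivive(row$fup, row$clint, ch$mol_weight,
              ionization_class = ch$ionization_class, rb = ch$rb,
              loec = ch$loec, params = config$ivive),
        error = function(e) NULL)
      if (!is.null(iv)) {
        row$fub <- iv$fub
        row$cl_renal <- iv$cl_renal
        row$cl_hep <- iv$cl_hep
        row$css <- iv$css
        row$aed <- iv$aed
      }
    }
    rows[[chem]] <- row
    details[[chem]] <- detail
  }

  results <- if (length(rows) > 0L) {
    all_cols <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    }))
  } else data.frame()
  rownames(results) <- NULL
  exclusions <- if (length(excl) > 0L)
    data.frame(chem_id = names(excl), reason = unlist(excl),
               row.names = NULL)
  else data.frame(chem_id = character(0), reason = character(0))
  structure(list(results = results, exclusions = exclusions,
                 details = details), class = "tk_pipeline_result")
}

# Response-scale censoring threshold per batch for the Bayesian models:
# the calibration response at the batch eMDL when known, else 0.
.pipeline_censor_limits <- function(cals) {
  vapply(cals, function(cal) {
    if (is.na(cal$emdl)) return(0)
    cal$coefficients["intercept"] + cal$coefficients["slope"] * cal$emdl
  }, numeric(1))
}

#' @export
print.tk_pipeline_result <- function(x, ...) {
  cat(sprintf("Toxicokinetics pipeline: %d chemical(s) analysed, %d excluded\n",
              nrow(x$results), nrow(x$exclusions)))
  if (nrow(x$results) > 0L) {
    shown <- x$results[, intersect(c("chem_id", "fup", "clint", "css", "aed"),
                                   names(x$results)), drop = FALSE]
    num <- vapply(shown, is.numeric, logical(1))
    shown[num] <- lapply(shown[num], signif, digits = 4)
    print(utils::head(shown, 10), row.names = FALSE)
    if (nrow(shown) > 10) cat("  ...\n")
  }
  if (nrow(x$exclusions) > 0L) {
    cat("Exclusions:\n")
    print(x$exclusions, row.names = FALSE)
  }
  invisible(x)
}
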