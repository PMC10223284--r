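#' Physiological scalars for IVIVE
#'
#' Defaults describe a reference adult human: body weight 70 kg, glomerular
#' filtration rate 6.7 L/h, liver blood flow 90 L/h, hepatocellularity
#' 110 x 10^6 cells per gram of liver, liver mass 1596 g, and a default
#' blood:plasma concentration ratio of 0.55 for ionized chemicals (neutral
#' chemicals need a chemical-specific `rb` supplied with the chemical table).
#' Dosing is a continuous-equivalent 1 mg/kg/day unless overridden.
#'
#' @param body_weight kg.
#' @param gfr glomerular filtration rate, L/h.
#' @param rb_default blood:plasma ratio applied to ionized chemicals.
#' @param liver_blood_flow hepatic blood flow Q_h, L/h.
#' @param hepatocellularity 10^6 cells per g liver.
#' @param liver_mass g.
#' @param dose mg/kg/day.
#' @return a list with class `ivive_params`.
#' @export
ivive_params <- function(body_weight = 70, gfr = 6.7, rb_default = 0.55,
                         liver_blood_flow = 90, hepatocellularity = 110,
                         liver_mass = 1596, dose = 1) {
  p <- list(body_weight = body_weight, gfr = gfr, rb_default = rb_default,
            liver_blood_flow = liver_blood_flow,
            hepatocellularity = hepatocellularity, liver_mass = liver_mass,
            dose = dose)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(p, class = "ivive_params")
}

#' Fraction unbound in blood
#'
#' Adjusts the plasma fraction unbound by the blood:plasma concentration
#' ratio, f_ub = f_up / Rb, capped at the physical maximum of 1.
#'
#' @param fup fraction unbound in plasma, (0, 1].
#' @param rb blood:plasma concentration ratio, > 0.
#' @return f_ub in (0, 1].
#' @export
fraction_unbound_blood <- function(fup, rb) {
  stopifnot(fup > 0, fup <= 1, rb > 0)
  min(1, fup / rb)
}

#' Renal clearance by glomerular filtration
#'
#' Nonmetabolic renal clearance = GFR x fraction unbound in blood.
#'
#' @param fub fraction unbound in blood, (0, 1].
#' @param gfr glomerular filtration rate, L/h.
#' @return L/h.
#' @export
renal_clearance <- function(fub, gfr = 6.7) {
  stopifnot(fub > 0, fub <= 1, gfr > 0)
  gfr * fub
}

#' Whole-liver hepatic clearance (well-stirred model)
#'
#' Scales intrinsic clearance measured per million hepatocytes up to the
#' whole liver, CL_u = Clint x hepatocellularity x liver mass x 60 x 1e-6
#' (L/h), then applies the well-stirred liver model
#' Cl_hep = Q_h f_ub CL_u / (Q_h + f_ub CL_u), which is bounded above by
#' hepatic blood flow Q_h.
#'
#' @param clint intrinsic clearance, uL/(min x 10^6 cells), >= 0.
#' @param fub fraction unbound in blood, (0, 1].
#' @param params an [ivive_params()] list.
#' @return hepatic blood clearance, L/h (0 when clint = 0).
#' @export
hepatic_clearance_whole_liver <- function(clint, fub,
                                          params = ivive_params()) {
  stopifnot(clint >= 0, fub > 0, fub <= 1)
  if (clint == 0) return(0)
  # uL/min -> L/h: x 60 min/h x 1e-6 L/uL
  cl_u <- clint * params$hepatocellularity * params$liver_mass * 60 * 1e-6
  qh <- params$liver_blood_flow
  qh * fub * cl_u / (qh + fub * cl_u)
}

#' Steady-state plasma concentration under continuous dosing
#'
#' Css = molar dose rate / total clearance, where the daily oral dose is
#' treated as a continuous equivalent infusion: dose rate =
#' dose x BW / MW x 1000 / 24 umol/h, giving Css in umol/L = uM.
#'
#' @param mol_weight g/mol.
#' @param cl_renal,cl_hep clearances, L/h.
#' @param params an [ivive_params()] list (dose, body weight).
#' @return Css in uM; `Inf` (with a warning) when total clearance is zero.
#' @export
steady_state_css <- function(mol_weight, cl_renal, cl_hep,
                             params = ivive_params()) {
  stopifnot(mol_weight > 0, cl_renal >= 0, cl_hep >= 0)
  dose_rate <- params$dose * params$body_weight / mol_weight * 1000 / 24
  total <- cl_renal + cl_hep
  if (total <= 0) {
    warning("zero total clearance: infinite steady-state concentration",
            call. = FALSE)
    return(Inf)
  }
  dose_rate / total
}

#' Administered equivalent dose
#'
#' The external daily dose whose steady-state plasma concentration equals an
#' in vitro bioactive concentration: AED = LOEC / Css x dose, with Css
#' computed at `dose` (default 1 mg/kg/day).
#'
#' @param loec lowest-observed-effect concentration, uM.
#' @param css steady-state concentration at `dose`, uM.
#' @param dose mg/kg/day at which `css` was computed.
#' @return mg/kg/day.
#' @export
administered_equivalent_dose <- function(loec, css, dose = 1) {
  stopifnot(loec > 0, css > 0, dose > 0)
  loec / css * dose
}

#' In vitro-in vivo extrapolation for one chemical
#'
#' Chains the IVIVE steps: blood binding adjustment, renal (GFR x f_ub) and
#' hepatic (well-stirred) clearance, steady-state plasma concentration at the
#' configured dose, and, when a bioactivity LOEC is available, the
#' administered equivalent dose.
#'
#' @param fup fraction unbound in plasma (capped value).
#' @param clint intrinsic clearance, uL/(min x 10^6 cells); use 0 for
#'   chemicals with no detectable clearance.
#' @param mol_weight g/mol.
#' @param ionization_class "ionized" (uses `params$rb_default`) or "neutral"
#'   (requires `rb`).
#' @param rb chemical-specific blood:plasma ratio override.
#' @param loec optional bioactivity concentration, uM.
#' @param params an [ivive_params()] list.
#' @return object of class `ivive_result`: fub, cl_renal, cl_hep, css, aed.
#' @export
ivive <- function(fup, clint, mol_weight,
                  ionization_class = "ionized", rb = NA_real_,
                  loec = NA_real_, params = ivive_params()) {
  if (is.na(rb)) {
    if (identical(ionization_class, "neutral"))
      stop("neutral-class chemicals need a chemical-specific rb", call. = FALSE)
    rb <- params$rb_default
  }
  fub <- fraction_unbound_blood(fup, rb)
  cl_renal <- renal_clearance(fub, params$gfr)
  cl_hep <- hepatic_clearance_whole_liver(clint, fub, params)
  css <- steady_state_css(mol_weight, cl_renal, cl_hep, params)
  aed <- if (is.na(loec)) NA_real_ else
    administered_equivalent_dose(loec, css, params$dose)
  structure(list(fub = fub, cl_renal = cl_renal, cl_hep = cl_hep,
                 css = css, aed = aed, loec = loec,
                 dose = params$dose), class = "ivive_result")
}

#' Worked IVIVE example inputs
#'
#' Measured inputs (molecular weight, plasma fraction unbound, intrinsic
#' clearance, bioactivity LOEC, ionization class and, for the one neutral
#' compound, its back-solved blood:plasma ratio) for the 16 PFAS with
#' complete in vitro toxicokinetic data, as packaged plain-text data. Running
#' [ivive()] over these rows reproduces the published clearance, Css and AED
#' values.
#'
#' @return a `tk_chemicals` data.frame with columns `chem_id`, `name`,
#'   `mol_weight`, `category`, `ionization_class`, `loec`, `rb`, `fup`,
#'   `clint`.
#' @export
pfas_ivive_examples <- function() {
  path <- system.file("extdata", "pfas_ivive_inputs.csv", package = "pfastk",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chem <- as_chemicals(df[, c("chem_id", "name", "mol_weight", "category",
                              "ionization_class", "loec", "rb")])
  chem$fup <- df$fup
  chem$clint <- df$clint
  chem
}

#' @export
print.ivive_result <- function(x, ...) {
  cat(sprintf("IVIVE at %g mg/kg/day:\n", x$dose))
  cat(sprintf("  f_ub = %.4g, Cl_renal = %.4g L/h, Cl_hep = %.4g L/h\n",
              x$fub, x$cl_renal, x$cl_hep))
  cat(sprintf("  Css = %.4g uM", x$css))
  if (!is.na(x$aed))
    cat(sprintf(", AED = %.4g mg/kg/day (LOEC %g uM)", x$aed, x$loec))
  cat("\n")
  invisible(x)
}
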