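---
title: "In vitro toxicokinetics of data-poor PFAS: models and methods"
author: "pfastk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vitro toxicokinetics of data-poor PFAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfastk)
```

## The problem

Most per- and polyfluoroalkyl substances (PFAS) lack the toxicokinetic data
needed to turn an in vitro bioactive concentration into an external dose.
`pfastk` implements the laboratory-to-dose chain for GC-MS/MS assay data:

1. **Calibration** — analyte:internal-standard response ratios are mapped to
   concentration through per-batch calibration curves, with estimated method
   detection (eMDL) and quantitation (eLOQ) limits.
2. **Plasma protein binding** — the ultracentrifugation (UC) assay yields
   the fraction unbound in plasma, `fup = mean(AF) / mean(T5hr)`, with a
   plasma-stability exclusion screen.
3. **Hepatocyte clearance** — substrate-depletion time courses give a
   first-order rate constant `k = -slope` of the `ln(C)` vs time regression,
   half-life `T1/2 = 0.693 / k`, and intrinsic clearance
   `Clint = 2000 k` in uL/(min x 10^6 cells), background-adjusted by the
   cell-free control rate.
4. **Bayesian uncertainty** — a joint measurement-error model propagates
   calibration and assay noise into credible intervals for `fup` and
   `Clint`.
5. **IVIVE** — fraction unbound in blood `fub = min(1, fup / Rb)`, renal
   clearance `GFR x fub`, well-stirred hepatic clearance
   `Qh fub CLu / (Qh + fub CLu)`, steady-state plasma concentration
   `Css = dose rate / (Cl_renal + Cl_hep)` and administered equivalent dose
   `AED = LOEC / Css x dose`.

`run_pipeline()` chains these stages for a whole measurement table and keeps
an exclusion log, so every chemical with data lands either in the results or
in the log with a reason.

## Assay designs and units

Concentrations are carried **at the instrument** (nM in the injected
solution). The UC assay incubates plasma at 10 uM; after the 1:3
acetonitrile crash and 1:10 analytical dilution the nominal at-instrument
level is 250 nM. The depletion assay runs at 1 uM and 50,000 cells/100 uL;
after the 1:1 crash and 1:9 dilution the nominal level is 50 nM. Because
`fup` and depletion slopes are ratios of samples diluted identically,
dilution factors never enter the estimates — this removes a silent
unit-error class. The `2000` in the clearance equation is the volume (uL)
holding one million cells at the assay density.

Calibration curves use 15 geometric levels over 1.75–1250 nM (plasma) or
7–5000 nM (hepatocyte). A fit is accepted when every level back-calculates
within ±30% of nominal; model form (linear/quadratic) and weighting
(none, 1/x, 1/x²) are tried in that order and the first passing combination
wins — the laboratory practice is "weighting if necessary" without a stated
rule, so the package makes the choice deterministic. The eMDL is
`sd x t(0.99, 6 df)` over exactly seven replicate injections (the multiplier,
about 3.14, is computed from the t distribution at run time); the eLOQ is the
lowest level whose seven replicates all fall within ±30%.

## Exclusion rules

* **Plasma stability:** loss `1 - mean(T5hr)/mean(T1hr)` strictly greater
  than 60% excludes the chemical; exactly 60% is retained. Missing T1hr
  data give "stability unknown" rather than an assumed nominal anchor.
* **Abiotic instability:** cell-free loss of 50% **or more** at 120 min
  excludes (inclusive boundary).
* **Censoring:** responses below the batch eMDL are carried as
  left-censored records. Point estimators treat them as missing and truncate
  depletion series at the last timepoint with at least two quantifiable
  replicates; the matched cell-free fit is truncated to the same window
  before rates are subtracted. The Bayesian model uses the censoring bound
  directly.

Background subtraction acts on rate constants, `k_met = max(0,
k_cells - k_cellfree)`, because both compartments are first-order. When both
cell-free and inactivated-hepatocyte controls exist, the cell-free rate is
subtracted by default (it isolates abiotic loss without cellular protein);
this is switchable. The slope F-test uses alpha = 0.05 — conventional, the
source protocol states no level — and depletion is declared only for
negative slopes, which makes the realized false-positive rate roughly half
the nominal level (the suite checks it stays below 6%).

## The Bayesian measurement model

Per chemical, the model couples (a) per-batch calibration lines with
heteroscedastic response noise `sd(mu) = sqrt(sigma0^2 + (nu mu)^2)` and (b)
the assay structure: latent incubation concentrations lognormal around
nominal, a degradation factor `D` in (0, 1] with `C_T5 = D C_T1`, and
`C_AF = fup C_T5` with `fup ~ Uniform(0, 1)`; or two exponential-decay
compartments with half-Normal priors on `k_met` and `k_bg` and the derived
`clint = 2000 k_met`. One `fup` is shared across measurement days; each day
gets its own calibration. Priors (uniform on fractions, half-Cauchy noise
scales, half-Normal(0.05 /min) rates, lognormal sd 0.3 on latent
concentrations) are weakly informative and configurable; the suite includes
a prior-sensitivity check.

Sampling runs in JAGS. Each extension is a burn-in followed by a thinned
sampling window; after every extension the Brooks–Gelman multivariate shrink
factor over the headline parameters is compared with the 1.05 threshold, and
chains are extended until it passes or a cap is reached (then
`converged = FALSE` is reported with the summaries). The production defaults
are five chains, 50,000-iteration burn-in and 50,000 iterations thinned to
2,000 per chain (10,000 pooled draws at convergence); the test suite runs 4
chains x 5,000 iterations to keep wall time down. The shrink factor is
floored at 1 — the variance decomposition can dip below 1 by sampling noise —
so identical chains report exactly 1. An estimate is flagged *uncertain*
when its 95% credible interval spans more than three orders of magnitude.

## IVIVE scalars

The physiological scalars default to a reference adult: body weight 70 kg,
GFR 6.7 L/h, liver blood flow 90 L/h, hepatocellularity 110 x 10^6 cells/g,
liver mass 1596 g, blood:plasma ratio 0.55 for ionized chemicals, and a
continuous-equivalent dose of 1 mg/kg/day. The ratio `GFR/Rb = 12.18` and
the well-stirred pair `(Qh, hepatocellularity x liver mass)` reproduce all
thirteen worked example rows shipped in
`inst/extdata/pfas_ivive_inputs.csv`; the one neutral-class compound (a
tosylate) requires its own `Rb` (about 12.3, back-solved from its published
clearances) — the package deliberately refuses to predict partitioning for
neutral chemicals. Reproduced steady-state concentrations sit within ~1% of
published values (a consistent ~0.8% residual suggests the original scalar
set differed slightly in a late decimal; the package documents rather than
chases it).

```{r ivive-example}
r <- subset(pfas_ivive_examples(), chem_id == "DTXSID2060965")
ivive(r$fup, r$clint, r$mol_weight, loec = r$loec)
```

## The synthetic-data generator

`generator_spec()` fixes a ground truth (`true_fup`, stability `D`,
`k_met`, `k_bg`, calibration coefficients) and emits measurement tables with
the laboratory designs: 15-point calibrations, triplicate UC samples,
triplicate depletion timepoints at {0, 15, 30, 60, 120, 240} min with
cell-free and inactivated controls. Response noise is heteroscedastic Normal
with proportional scale `cv` (default 10%, a mid-range assay CV) and a small
additive floor `sigma0` (0.001 response units, i.e. about 0.5 nM at the
default response factor — an eMDL comfortably under the lowest calibration
level); latent concentrations carry 5% lognormal pipetting noise. The noise
family matches the Bayesian likelihood by construction so that coverage
tests are well-posed; a `lognormal_noise` switch probes misspecification.
Responses below the synthetic batch eMDL are emitted as left-censored, which
closes the loop with the truncation rule above.

What the generator does **not** emulate: matrix effects, chromatographic
drift or carryover, correlated between-day calibration shifts, and chemical
loss mechanisms that are not first-order. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated error model, not
robustness to every failure mode of real GC-MS/MS data.

`generate_cohort()` samples a right-skewed binding distribution (lognormal
body with median near 0.09, capped at 1) and a clearance mixture with a
point mass at zero, mimicking a realistic screening cohort in which the
median `fup` sits well below the mean and a fraction of chemicals shows no
detectable metabolism.

## Numerical choices and problem sizes

* Quadratic curves are inverted by choosing the root inside
  [0, 1.2 x top level]; zero or two admissible roots yield an invalid (NA)
  value, never an exception.
* `fup` is capped at 1 with the raw ratio retained; replicate means are
  ratioed (aliquots are unpaired).
* Monte-Carlo checks in the suite use 100 generator seeds for point-estimate
  recovery, 100 simulated datasets for credible-interval coverage (4 chains
  x 5,000 iterations each), 1,000 noise-only series for the F-test level,
  and a 43-chemical cohort for end-to-end rank recovery — sizes chosen to
  keep Monte-Carlo error a few percent while the whole suite runs in
  minutes.

## Known limitations

Single-concentration substrate depletion cannot see saturable metabolism;
the UC assay yields one equilibrium fraction, not a binding isotherm; the
well-stirred model bounds hepatic clearance by liver blood flow and ignores
extrahepatic metabolism; `Css` assumes continuous equivalent dosing at
steady state with no population variability. Below-range extrapolation in
back-calculation is flagged but permitted, since strongly bound chemicals
produce aqueous-fraction concentrations beneath the lowest standard.
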