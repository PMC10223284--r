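#' MCMC settings for the uncertainty analysis
#'
#' Defaults follow the study protocol: five Markov chains, each extension a
#' 50,000-iteration burn-in followed by 50,000 iterations thinned to 2,000
#' retained samples per chain, extended until the multivariate shrink factor
#' across chains drops below 1.05, giving 10,000 pooled samples at
#' convergence. Reduced settings (fewer/shorter chains) are appropriate for
#' quick exploration and are used throughout the test suite.
#'
#' @param n_chains number of chains (>= 2).
#' @param burn_in iterations discarded at the start of every extension.
#' @param iterations iterations retained (pre-thinning) per extension.
#' @param samples_per_chain retained draws per chain after thinning.
#' @param shrink_threshold convergence declared below this multivariate
#'   potential-scale-reduction factor (> 1).
#' @param max_extensions give up (converged = FALSE) after this many
#'   extensions.
#' @param seed integer; chain c uses seed + c.
#' @return a list with class `bayes_config`.
#' @export
bayes_config <- function(n_chains = 5, burn_in = 50000, iterations = 50000,
                         samples_per_chain = 2000, shrink_threshold = 1.05,
                         max_extensions = 10, seed = 1L) {
  stopifnot(n_chains >= 2, shrink_threshold > 1, burn_in >= 0,
            iterations >= samples_per_chain, max_extensions >= 1)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 samples_per_chain = as.integer(samples_per_chain),
                 shrink_threshold = shrink_threshold,
                 max_extensions = as.integer(max_extensions),
                 seed = as.integer(seed)), class = "bayes_config")
}

# ---- shrink factors ---------------------------------------------------------

#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman multivariate shrink factor across chains:
#' sqrt((n-1)/n + (m+1)/m * lambda1), lambda1 the largest eigenvalue of
#' W^-1 B/n, with W the pooled within-chain covariance and B/n the
#' between-chain covariance of the chain means. The estimate is floored at 1
#' (the variance decomposition can dip below 1 by sampling noise), so
#' identical chains give exactly 1.
#'
#' @param chains list of matrices (iterations x parameters), one per chain,
#'   or a `coda::mcmc.list`.
#' @return scalar shrink factor >= 1.
#' @export
multivariate_psrf <- function(chains) {
  chains <- lapply(chains, as.matrix)
  m <- length(chains)
  stopifnot(m >= 2)
  n <- nrow(chains[[1]])
  stopifnot(all(vapply(chains, nrow, integer(1)) == n), n >= 2)
  means <- t(vapply(chains, colMeans, numeric(ncol(chains[[1]]))))
  if (ncol(chains[[1]]) == 1L) means <- matrix(means, ncol = 1)
  # drop constant (zero-variance) parameters; they carry no convergence info
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  keep <- diag(as.matrix(W)) > 0
  if (!any(keep)) return(1)
  W <- as.matrix(W)[keep, keep, drop = FALSE]
  Bn <- stats::cov(means[, keep, drop = FALSE])  # = B/n
  if (all(Bn == 0)) return(1)
  lambda1 <- tryCatch(
    max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
    error = function(e) max(diag(Bn) / diag(W)))
  rhat <- sqrt((n - 1) / n + (m + 1) / m * lambda1)
  max(1, rhat)
}

# Univariate PSRF per parameter, same flooring convention.
univariate_psrf <- function(chains) {
  chains <- lapply(chains, as.matrix)
  p <- ncol(chains[[1]])
  vapply(seq_len(p), function(j) {
    multivariate_psrf(lapply(chains, function(ch) ch[, j, drop = FALSE]))
  }, numeric(1))
}

# ---- model builders ---------------------------------------------------------

# Shared JAGS fragment: per-batch calibration lines with heteroscedastic
# response noise sd(mu) = sqrt(sigma0^2 + (nu*mu)^2); responses below the
# detection threshold enter as left-censored via dinterval (ind = 0,
# lim = threshold; observed points use ind = 1, lim = -1e6).
.jags_calibration_block <- "
  for (b in 1:B) {
    beta0[b] ~ dnorm(0, 1 / (0.1 * 0.1))
    beta1[b] ~ dnorm(0, 1 / (10 * 10)) T(0,)
  }
  sigma0 ~ dt(0, 1 / (sigma0_scale * sigma0_scale), 1) T(0,)
  nu ~ dt(0, 1 / (0.2 * 0.2), 1) T(0,)
  for (i in 1:Nstd) {
    mu_std[i] <- beta0[batch_std[i]] + beta1[batch_std[i]] * conc_std[i]
    y_std[i] ~ dnorm(mu_std[i], 1 / (sigma0^2 + pow(nu * mu_std[i], 2)))
  }
"

# Package measurement rows of one sample type into observation vectors for
# JAGS, mapping censored rows to (y = NA, ind = 0, lim = threshold).
.obs_block <- function(rows, batch_index, censor_limits) {
  n <- nrow(rows)
  if (n == 0L) return(list(n = 0L, y = numeric(0), batch = integer(0),
                           ind = integer(0), lim = numeric(0),
                           time = numeric(0)))
  cens <- !is.na(rows$censored) & rows$censored
  lim <- ifelse(cens, censor_limits[rows$batch_id], -1e6)
  list(n = n,
       y = ifelse(cens, NA_real_, rows$response_ratio),
       batch = batch_index[rows$batch_id],
       ind = as.integer(!cens),
       lim = unname(lim),
       time = rows$time_min)
}

#' Build the Bayesian measurement model for one chemical's UC assay
#'
#' Joint model of (a) the per-batch MS response factor: standard responses
#' are Normal around the calibration line with heteroscedastic noise, and
#' (b) the UC assay: a latent incubation concentration centered lognormally
#' on the nominal at-instrument level, per-replicate lognormal aliquot
#' variation, a degradation factor D in (0,1] linking T5hr to T1hr, and
#' fraction unbound fup ~ Uniform(0,1) linking the aqueous fraction to T5hr.
#' Responses below the detection threshold are left-censored. One fup is
#' shared across batches; each batch gets its own calibration line.
#'
#' @param measurements `tk_measurements` for one chemical: calibration
#'   standards plus UC samples (T1hr, T5hr, AF) sharing batch ids.
#' @param nominal_conc nominal at-instrument T1hr concentration, nM
#'   (10 uM assay concentration after the crash and analytical dilutions;
#'   250 nM under the packaged defaults).
#' @param censor_limits named numeric, response-scale censoring threshold per
#'   batch (defaults to 0: nothing censorable below zero response).
#' @param priors list overriding prior scales: `sigma0_scale` (half-Cauchy
#'   scale of the additive response noise), `conc_sdlog` (latent
#'   concentration lognormal sd), `rep_sdlog_scale` (half-Cauchy scale of the
#'   replicate aliquot variation).
#' @return a `tk_bayes_model`: JAGS code, data, monitored parameters, and
#'   the headline parameters entering the multivariate shrink factor
#'   (fup, D, nu).
#' @export
build_uc_model <- function(measurements, nominal_conc = 250,
                           censor_limits = NULL, priors = list()) {
  pr <- utils::modifyList(list(sigma0_scale = 0.01, conc_sdlog = 0.3,
                               rep_sdlog_scale = 0.2), priors)
  std <- measurements[measurements$sample_type == "standard", , drop = FALSE]
  if (nrow(std) == 0L)
    stop("no calibration standards for the UC model", call. = FALSE)
  batches <- sort(unique(measurements$batch_id))
  assay_batches <- unique(measurements$batch_id[
    measurements$sample_type %in% c("T1hr", "T5hr", "AF")])
  if (!all(assay_batches %in% std$batch_id))
    stop("assay batch without calibration standards: ",
         paste(setdiff(assay_batches, std$batch_id), collapse = ", "),
         call. = FALSE)
  bidx <- stats::setNames(seq_along(batches), batches)
  if (is.null(censor_limits))
    censor_limits <- stats::setNames(rep(0, length(batches)), batches)

  t1 <- .obs_block(measurements[measurements$sample_type == "T1hr", ],
                   bidx, censor_limits)
  t5 <- .obs_block(measurements[measurements$sample_type == "T5hr", ],
                   bidx, censor_limits)
  af <- .obs_block(measurements[measurements$sample_type == "AF", ],
                   bidx, censor_limits)
  if (t5$n == 0L || af$n == 0L)
    stop("UC model needs T5hr and AF samples", call. = FALSE)

  code <- paste0("model {\n", .jags_calibration_block, "
  fup ~ dunif(0, 1)
  D ~ dunif(0, 1)
  C1 ~ dlnorm(log(c_nom), 1 / (conc_sdlog * conc_sdlog))
  sd_rep ~ dt(0, 1 / (rep_scale * rep_scale), 1) T(0,)
  prec_rep <- 1 / (sd_rep * sd_rep)
  for (r in 1:N1) {
    CT1[r] ~ dlnorm(log(C1), prec_rep)
    mu1[r] <- beta0[batch1[r]] + beta1[batch1[r]] * CT1[r]
    ind1[r] ~ dinterval(y1[r], lim1[r])
    y1[r] ~ dnorm(mu1[r], 1 / (sigma0^2 + pow(nu * mu1[r], 2)))
  }
  for (r in 1:N5) {
    CT5[r] ~ dlnorm(log(D * C1), prec_rep)
    mu5[r] <- beta0[batch5[r]] + beta1[batch5[r]] * CT5[r]
    ind5[r] ~ dinterval(y5[r], lim5[r])
    y5[r] ~ dnorm(mu5[r], 1 / (sigma0^2 + pow(nu * mu5[r], 2)))
  }
  for (r in 1:Naf) {
    CAF[r] ~ dlnorm(log(fup * D * C1), prec_rep)
    muA[r] <- beta0[batchA[r]] + beta1[batchA[r]] * CAF[r]
    indA[r] ~ dinterval(yA[r], limA[r])
    yA[r] ~ dnorm(muA[r], 1 / (sigma0^2 + pow(nu * muA[r], 2)))
  }
}\n")
  data <- list(B = length(batches), Nstd = nrow(std),
               conc_std = std$nominal_conc, y_std = std$response_ratio,
               batch_std = unname(bidx[std$batch_id]),
               c_nom = nominal_conc,
               conc_sdlog = pr$conc_sdlog, rep_scale = pr$rep_sdlog_scale,
               sigma0_scale = pr$sigma0_scale,
               N1 = t1$n, y1 = t1$y, batch1 = t1$batch, ind1 = t1$ind,
               lim1 = t1$lim,
               N5 = t5$n, y5 = t5$y, batch5 = t5$batch, ind5 = t5$ind,
               lim5 = t5$lim,
               Naf = af$n, yA = af$y, batchA = af$batch, indA = af$ind,
               limA = af$lim)
  if (t1$n == 0L) {
    data$N1 <- NULL; data$y1 <- NULL; data$batch1 <- NULL
    data$ind1 <- NULL; data$lim1 <- NULL
    code <- sub("(?s)  for \\(r in 1:N1\\) \\{.*?\\n  \\}\\n", "", code,
                perl = TRUE)
  }
  structure(list(code = code, data = data,
                 monitor = c("fup", "D", "nu", "sigma0", "C1"),
                 headline = c("fup", "D", "nu"),
                 kind = "uc"), class = "tk_bayes_model")
}

#' Build the Bayesian measurement model for one chemical's depletion assay
#'
#' Joint model of the per-batch calibration (as in [build_uc_model()]) and
#' two first-order decay compartments: hepatocyte concentrations decay at
#' k_met + k_bg, cell-free controls at k_bg, both from lognormal latent
#' starting concentrations centered on the nominal at-instrument level.
#' Rate constants carry half-Normal priors so metabolism is attributed only
#' beyond what the abiotic background explains. The derived intrinsic
#' clearance clint = 2000 k_met is monitored directly.
#'
#' @inheritParams build_uc_model
#' @param nominal_conc nominal at-instrument t = 0 concentration, nM
#'   (1 uM assay concentration after crash and dilution; 50 nM by default).
#' @param priors list; additionally `k_scale`, the half-Normal sd of the
#'   rate-constant priors (1/min).
#' @return a `tk_bayes_model` with headline parameters clint, k_bg, nu.
#' @export
build_clearance_model <- function(measurements, nominal_conc = 50,
                                  censor_limits = NULL, priors = list()) {
  pr <- utils::modifyList(list(sigma0_scale = 0.01, conc_sdlog = 0.3,
                               k_scale = 0.05), priors)
  std <- measurements[measurements$sample_type == "standard", , drop = FALSE]
  if (nrow(std) == 0L)
    stop("no calibration standards for the clearance model", call. = FALSE)
  batches <- sort(unique(measurements$batch_id))
  bidx <- stats::setNames(seq_along(batches), batches)
  if (is.null(censor_limits))
    censor_limits <- stats::setNames(rep(0, length(batches)), batches)

  cells <- .obs_block(measurements[measurements$sample_type == "hep_cells", ],
                      bidx, censor_limits)
  cfree <- .obs_block(
    measurements[measurements$sample_type == "cellfree_ctrl", ],
    bidx, censor_limits)
  if (cells$n == 0L || cfree$n == 0L)
    stop("clearance model needs hepatocyte and cell-free series", call. = FALSE)

  code <- paste0("model {\n", .jags_calibration_block, "
  k_met ~ dnorm(0, 1 / (k_scale * k_scale)) T(0,)
  k_bg ~ dnorm(0, 1 / (k_scale * k_scale)) T(0,)
  C0 ~ dlnorm(log(c_nom), 1 / (conc_sdlog * conc_sdlog))
  C0f ~ dlnorm(log(c_nom), 1 / (conc_sdlog * conc_sdlog))
  clint <- 2000 * k_met
  for (i in 1:Nc) {
    muc[i] <- beta0[batchc[i]] +
      beta1[batchc[i]] * C0 * exp(-(k_met + k_bg) * tc[i])
    indc[i] ~ dinterval(yc[i], limc[i])
    yc[i] ~ dnorm(muc[i], 1 / (sigma0^2 + pow(nu * muc[i], 2)))
  }
  for (i in 1:Nf) {
    muf[i] <- beta0[batchf[i]] + beta1[batchf[i]] * C0f * exp(-k_bg * tf[i])
    indf[i] ~ dinterval(yf[i], limf[i])
    yf[i] ~ dnorm(muf[i], 1 / (sigma0^2 + pow(nu * muf[i], 2)))
  }
}\n")
  data <- list(B = length(batches), Nstd = nrow(std),
               conc_std = std$nominal_conc, y_std = std$response_ratio,
               batch_std = unname(bidx[std$batch_id]),
               c_nom = nominal_conc, conc_sdlog = pr$conc_sdlog,
               sigma0_scale = pr$sigma0_scale, k_scale = pr$k_scale,
               Nc = cells$n, yc = cells$y, batchc = cells$batch,
               indc = cells$ind, limc = cells$lim, tc = cells$time,
               Nf = cfree$n, yf = cfree$y, batchf = cfree$batch,
               indf = cfree$ind, limf = cfree$lim, tf = cfree$time)
  structure(list(code = code, data = data,
                 monitor = c("clint", "k_met", "k_bg", "nu", "sigma0"),
                 headline = c("clint", "k_bg", "nu"),
                 kind = "clearance"), class = "tk_bayes_model")
}

#' Assemble an arbitrary JAGS model for the MCMC protocol
#'
#' Mostly useful for tests and diagnostics (e.g. toy targets with known
#' posteriors).
#'
#' @param code JAGS model string.
#' @param data named list of data nodes.
#' @param monitor parameters to record.
#' @param headline subset of `monitor` entering the multivariate shrink
#'   factor (defaults to all monitored parameters).
#' @return a `tk_bayes_model`.
#' @export
tk_bayes_model <- function(code, data = list(), monitor,
                           headline = monitor) {
  structure(list(code = code, data = data, monitor = monitor,
                 headline = headline, kind = "custom"),
            class = "tk_bayes_model")
}

# ---- sampling protocol ------------------------------------------------------

#' Run the extend-until-converged MCMC protocol
#'
#' Runs `n_chains` JAGS chains. Each extension discards `burn_in` iterations
#' then retains `iterations` thinned down to `samples_per_chain` draws per
#' chain. After every extension the multivariate shrink factor over the
#' model's headline parameters is computed from that extension's draws;
#' sampling stops once it falls below `shrink_threshold` or after
#' `max_extensions` extensions (then `converged = FALSE`, with summaries
#' still emitted under a warning). Posterior summaries (median and central
#' 95% credible interval) come from the final extension pooled over chains.
#'
#' @param model a `tk_bayes_model`.
#' @param config a [bayes_config()].
#' @param quiet suppress JAGS progress output.
#' @return object of class `tk_posterior`: `summary` data.frame (parameter,
#'   median, ci_lower, ci_upper, n_samples, psrf, converged, uncertain),
#'   `draws` (coda::mcmc.list of the final extension), `mpsrf`,
#'   `n_extensions`, `converged`.
#' @export
run_mcmc <- function(model, config = bayes_config(), quiet = TRUE) {
  stopifnot(inherits(model, "tk_bayes_model"), inherits(config, "bayes_config"))
  inits <- lapply(seq_len(config$n_chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + c))
  jm <- NULL
  for (attempt in 1:5) {
    jm <- tryCatch(
      rjags::jags.model(textConnection(model$code), data = model$data,
                        inits = inits, n.chains = config$n_chains,
                        n.adapt = 1000, quiet = quiet),
      error = function(e) e)
    if (!inherits(jm, "error")) break
    # perturb chain seeds and retry initialization
    inits <- lapply(inits, function(i) {
      i$.RNG.seed <- i$.RNG.seed + 1000L; i })
  }
  if (inherits(jm, "error"))
    stop("JAGS initialization failed after 5 attempts: ",
         conditionMessage(jm), call. = FALSE)

  thin <- max(1L, config$iterations %/% config$samples_per_chain)
  draws <- NULL
  mpsrf <- Inf
  converged <- FALSE
  ext <- 0L
  while (ext < config$max_extensions) {
    ext <- ext + 1L
    if (config$burn_in > 0)
      stats::update(jm, n.iter = config$burn_in, progress.bar = "none")
    draws <- rjags::coda.samples(jm, variable.names = model$monitor,
                                 n.iter = config$iterations, thin = thin,
                                 progress.bar = "none")
    head_cols <- intersect(model$headline, coda::varnames(draws))
    head_draws <- lapply(draws, function(ch)
      as.matrix(ch)[, head_cols, drop = FALSE])
    mpsrf <- multivariate_psrf(head_draws)
    if (mpsrf < config$shrink_threshold) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "chains not converged after %d extension(s): shrink factor %.3f",
      ext, mpsrf), call. = FALSE)

  mats <- lapply(draws, as.matrix)
  pooled <- do.call(rbind, mats)
  psrf_uni <- univariate_psrf(mats)
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  summ <- data.frame(parameter = colnames(pooled),
                     median = qs[2, ], ci_lower = qs[1, ], ci_upper = qs[3, ],
                     n_samples = nrow(pooled), psrf = psrf_uni,
                     converged = converged, row.names = NULL)
  summ$uncertain <- vapply(seq_len(nrow(summ)), function(i)
    flag_uncertain(summ$ci_lower[i], summ$ci_upper[i]), logical(1))
  structure(list(summary = summ, draws = draws, mpsrf = mpsrf,
                 n_extensions = ext, converged = converged,
                 config = config), class = "tk_posterior")
}

#' Flag an uncertain posterior estimate
#'
#' An estimate is flagged uncertain when its 95% credible interval spans more
#' than three orders of magnitude (upper/lower > 1000). For strictly positive
#' parameters whose lower bound underflows to <= 0, the ratio is computed on
#' a configured floor and the result is marked via the `floored` attribute.
#'
#' @param ci_lower,ci_upper credible interval bounds.
#' @param floor positive lower bound substituted when ci_lower <= 0.
#' @return logical; attribute `floored` records whether the floor was used.
#' @export
flag_uncertain <- function(ci_lower, ci_upper, floor = 1e-6) {
  if (is.na(ci_lower) || is.na(ci_upper)) return(NA)
  floored <- ci_lower <= 0
  lo <- if (floored) floor else ci_lower
  structure(ci_upper / lo > 1000, floored = floored)
}

#' @export
print.tk_posterior <- function(x, ...) {
  cat(sprintf(
    "Posterior summary (%d chains, %d extension(s), shrink factor %.4f%s)\n",
    length(x$draws), x$n_extensions, x$mpsrf,
    if (x$converged) "" else ", NOT converged"))
  df <- x$summary
  df$median <- signif(df$median, 4)
  df$ci_lower <- signif(df$ci_lower, 4)
  df$ci_upper <- signif(df$ci_upper, 4)
  df$psrf <- round(df$psrf, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
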