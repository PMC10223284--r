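test_that("identical chains give a shrink factor of exactly one", {
  set.seed(1)
  ch <- matrix(rnorm(600), ncol = 3)
  expect_identical(multivariate_psrf(list(ch, ch, ch, ch)), 1)
  # constant (zero-variance) columns carry no convergence information
  ch2 <- cbind(ch, 5)
  expect_identical(multivariate_psrf(list(ch2, ch2)), 1)
})

test_that("the shrink factor agrees with the coda reference on dispersed chains", {
  # coda scales the between-chain term by (1 + 1/Nvar); Brooks-Gelman use
  # (m+1)/m over chains, so match the two by using 2 chains x 2 parameters
  set.seed(2)
  chains <- lapply(c(-1, 1), function(mu)
    matrix(rnorm(2000, mean = mu), ncol = 2))
  ours <- multivariate_psrf(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$mpsrf
  expect_gt(ours, 1.5)  # genuinely dispersed
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("a standard-normal toy target is recovered by the protocol", {
  model <- tk_bayes_model("model { theta ~ dnorm(0, 1) }", list(),
                          monitor = "theta")
  post <- run_mcmc(model, test_bayes_config(seed = 5))
  expect_true(post$converged)
  draws <- do.call(rbind, lapply(post$draws, as.matrix))
  expect_lt(abs(mean(draws[, "theta"])), 0.05)
  expect_lt(abs(sd(draws[, "theta"]) - 1), 0.05)
  expect_equal(nrow(draws), 4 * 1000)
  s <- post$summary[post$summary$parameter == "theta", ]
  expect_lte(s$ci_lower, s$median)
  expect_lte(s$median, s$ci_upper)
})

test_that("a capped extension budget reports non-convergence but still summarizes", {
  # two flat parameters identified only through their sum: Gibbs updates
  # random-walk along the unidentified direction, so short chains started
  # from dispersed prior draws cannot converge on either parameter
  code <- "model {
    theta1 ~ dnorm(0, 1e-4)
    theta2 ~ dnorm(0, 1e-4)
    y ~ dnorm(theta1 + theta2, 1)
  }"
  model <- tk_bayes_model(code, list(y = 0), monitor = c("theta1", "theta2"))
  cfg <- bayes_config(n_chains = 4, burn_in = 10, iterations = 40,
                      samples_per_chain = 40, max_extensions = 2,
                      shrink_threshold = 1.05, seed = 2)
  expect_warning(post <- run_mcmc(model, cfg), "not converged")
  expect_false(post$converged)
  expect_equal(post$n_extensions, 2L)
  expect_true(is.finite(post$summary$median[1]))
})

test_that("the UC model recovers binding in the low-noise limit", {
  spec <- generator_spec(true_fup = 0.1, true_D = 1, sigma0 = 1e-5,
                         cv = 0.005, pipetting_sdlog = 0.002, seed = 8)
  post <- run_mcmc(build_uc_model(uc_dataset(spec)),
                   test_bayes_config(seed = 8))
  s <- post$summary
  fup <- s[s$parameter == "fup", ]
  expect_equal(fup$median, 0.1, tolerance = 0.01)
  expect_lt(fup$ci_upper - fup$ci_lower, 0.01)
  # no degradation generated: D concentrates near its upper bound
  expect_gt(s[s$parameter == "D", "median"], 0.95)
  # the posterior respects the [0, 1] support in every draw
  draws <- do.call(rbind, lapply(post$draws, as.matrix))
  expect_true(all(draws[, "fup"] >= 0 & draws[, "fup"] <= 1))
})

test_that("posterior medians track the point estimators on quiet data", {
  spec <- generator_spec(true_fup = 0.25, cv = 0.05, seed = 15)
  m <- uc_dataset(spec)
  post <- run_mcmc(build_uc_model(m), test_bayes_config(seed = 15))
  bayes_fup <- post$summary[post$summary$parameter == "fup", "median"]
  expect_equal(bayes_fup, point_fup(m), tolerance = 0.10)

  spec2 <- generator_spec(true_k_met = 0.01, true_k_bg = 0, cv = 0.05,
                          seed = 16)
  m2 <- depletion_dataset(spec2)
  post2 <- run_mcmc(build_clearance_model(m2), test_bayes_config(seed = 16))
  bayes_clint <- post2$summary[post2$summary$parameter == "clint", "median"]
  point <- suppressWarnings(point_clearance(m2))$fit$clint
  expect_equal(bayes_clint, point, tolerance = 0.10)
})

test_that("the clearance model recovers truth and attributes background", {
  spec <- generator_spec(true_k_met = 0.01, true_k_bg = 0, cv = 0.10,
                         seed = 20)
  post <- run_mcmc(build_clearance_model(depletion_dataset(spec)),
                   test_bayes_config(seed = 20))
  clint <- post$summary[post$summary$parameter == "clint", ]
  expect_equal(clint$median, 20, tolerance = 0.15)

  # no metabolism: clint mass near zero even with nonzero background loss
  spec0 <- generator_spec(true_k_met = 0, true_k_bg = 0.006, cv = 0.10,
                          seed = 21)
  post0 <- run_mcmc(build_clearance_model(depletion_dataset(spec0)),
                    test_bayes_config(seed = 21))
  draws0 <- do.call(rbind, lapply(post0$draws, as.matrix))
  expect_lt(mean(draws0[, "clint"] > 5), 0.1)
  # the background rate itself is identified
  expect_equal(post0$summary[post0$summary$parameter == "k_bg", "median"],
               0.006, tolerance = 0.25)
})

test_that("posterior conclusions are insensitive to reasonable prior rescaling", {
  spec <- generator_spec(true_fup = 0.15, cv = 0.10, seed = 33)
  m <- uc_dataset(spec)
  p1 <- run_mcmc(build_uc_model(m), test_bayes_config(seed = 33))
  p2 <- run_mcmc(build_uc_model(m, priors = list(conc_sdlog = 0.6,
                                                 rep_sdlog_scale = 0.4)),
                 test_bayes_config(seed = 34))
  f1 <- p1$summary[p1$summary$parameter == "fup", "median"]
  f2 <- p2$summary[p2$summary$parameter == "fup", "median"]
  expect_equal(f1, f2, tolerance = 0.10)
})

test_that("credible intervals tighten (or hold) with more replicates", {
  width_at <- function(reps, s) {
    spec <- generator_spec(true_fup = 0.12, cv = 0.10, uc_replicates = reps,
                           seed = 4000 + s)
    post <- run_mcmc(build_uc_model(uc_dataset(spec)),
                     test_bayes_config(seed = s))
    q <- post$summary[post$summary$parameter == "fup", ]
    q$ci_upper - q$ci_lower
  }
  w3 <- vapply(1:12, function(s) width_at(3, s), numeric(1))
  w6 <- vapply(1:12, function(s) width_at(6, s), numeric(1))
  expect_lte(median(w6), median(w3) * 1.05)
})

test_that("uncertainty flagging follows the three-orders-of-magnitude rule", {
  expect_false(as.logical(flag_uncertain(0.001, 0.9)))    # 900x
  expect_true(as.logical(flag_uncertain(0.0001, 0.9)))    # 9000x
  for (x in c(1e-4, 0.3, 50)) {
    expect_true(as.logical(flag_uncertain(x, 1000.01 * x)))
    expect_false(as.logical(flag_uncertain(x, 999.9 * x)))
  }
  fl <- flag_uncertain(0, 0.01)
  expect_true(attr(fl, "floored"))
  expect_true(as.logical(fl))  # 0.01 / 1e-6 >> 1000
})

test_that("model builders validate their measurement prerequisites", {
  spec <- generator_spec(seed = 2)
  uc_only <- generate_uc_assay(spec, "b1")
  expect_error(build_uc_model(uc_only), "no calibration standards")
  cal <- generate_calibration(spec, "uc_ppb", "b_other")
  mismatch <- as_measurements(rbind(as.data.frame(cal),
                                    as.data.frame(uc_only)))
  expect_error(build_uc_model(mismatch), "without calibration standards")
  dep <- depletion_dataset(spec)
  no_cells <- dep[dep$sample_type != "hep_cells", ]
  expect_error(build_clearance_model(no_cells), "hepatocyte")
})
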