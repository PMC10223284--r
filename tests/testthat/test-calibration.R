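test_that("noiseless linear standards are recovered exactly", {
  lv <- plasma_levels()
  fit <- fit_calibration(make_standards(lv, 0.002 * lv), "linear", "none")
  expect_equal(unname(fit$coefficients["slope"]), 0.002, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["intercept"]), 0, tolerance = 1e-12)
  expect_true(all(abs(fit$accuracy_table$accuracy - 100) < 1e-6))
  expect_true(fit$accepted)
  expect_equal(fit$conc_range, c(1.75, 1250))
})

test_that("curvature breaks a forced linear fit but a quadratic absorbs it", {
  lv <- plasma_levels()
  resp <- 0.002 * lv + 1e-7 * lv^2
  lin <- suppressWarnings(fit_calibration(make_standards(lv, resp),
                                          "linear", "none"))
  expect_false(lin$accepted)
  expect_gt(max(abs(lin$accuracy_table$accuracy - 100)), 30)
  quad <- fit_calibration(make_standards(lv, resp), "quadratic", "none")
  expect_true(quad$accepted)
  expect_equal(unname(quad$coefficients["curvature"]), 1e-7,
               tolerance = 1e-6)
  # the weighting/form cascade lands on the accepted quadratic
  sel <- select_calibration(make_standards(lv, resp))
  expect_true(sel$accepted)
})

test_that("back-calculation inverts the curve and flags range violations", {
  lv <- plasma_levels()
  fit <- fit_calibration(make_standards(lv, 0.002 * lv), "linear", "none")
  expect_equal(as.numeric(back_calculate(fit, 0.5)), 250, tolerance = 1e-9)
  below <- back_calculate(fit, 0.0001)
  expect_true(attr(below, "below_range"))
  above <- back_calculate(fit, 10)
  expect_true(attr(above, "above_range"))

  # internal consistency: re-deriving the accuracy table reproduces it
  resp <- 0.002 * lv * (1 + 0.02 * sin(seq_along(lv)))
  f2 <- fit_calibration(make_standards(lv, resp), "linear", "none")
  acc <- 100 * vapply(resp, function(r)
    as.numeric(back_calculate(f2, r, check_range = FALSE)), numeric(1)) / lv
  expect_equal(unname(f2$accuracy_table$accuracy), unname(acc),
               tolerance = 1e-9)
})

test_that("quadratic inversion picks the in-domain root and censors ambiguity", {
  lv <- plasma_levels()
  resp <- 0.002 * lv + 1e-7 * lv^2
  quad <- fit_calibration(make_standards(lv, resp), "quadratic", "none")
  for (target in c(5, 100, 1000)) {
    y <- 0.002 * target + 1e-7 * target^2
    expect_equal(as.numeric(back_calculate(quad, y, check_range = FALSE)),
                 target, tolerance = 1e-6)
  }
  # no real root in the calibrated domain -> NA, not an error
  downward <- fit_calibration(
    make_standards(lv[1:8], 0.01 * lv[1:8] - 1e-5 * lv[1:8]^2), "quadratic",
    "none")
  expect_true(is.na(back_calculate(downward, 1e3, check_range = FALSE)))
})

test_that("degenerate standards raise the documented errors", {
  lv <- plasma_levels(4)
  expect_warning(fit_calibration(make_standards(lv, 0.002 * lv), "linear"),
                 "fewer than 5")
  expect_error(fit_calibration(make_standards(lv[1:2], c(0.1, 0.2))),
               ">= 3 distinct")
  expect_error(
    suppressWarnings(
      fit_calibration(make_standards(plasma_levels(5), rep(0.1, 5)))),
    "singular")
  expect_warning(
    f <- fit_calibration(make_standards(plasma_levels(5),
                                        0.5 - 0.0003 * plasma_levels(5))),
    "negative")
  expect_false(f$accepted)
})

test_that("eMDL is sd times the one-tailed 99% t critical value at 6 df", {
  # independent oracle: recover the critical value by bisection on the t CDF
  f <- function(x) stats::pt(x, df = 6) - 0.99
  lo <- 0; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  t_crit <- (lo + hi) / 2
  expect_equal(round(t_crit, 2), 3.14)

  reps <- c(9.2, 10.1, 10.9, 9.7, 10.3, 9.9, 10.6)
  expect_equal(estimate_emdl(reps), stats::sd(reps) * t_crit,
               tolerance = 1e-10)
  # linear scaling in the replicate sd
  expect_equal(estimate_emdl(3 * reps), 3 * estimate_emdl(reps),
               tolerance = 1e-10)
  expect_equal(estimate_emdl(rep(5, 7)), 0)
  expect_error(estimate_emdl(1:6), "exactly 7")
})

test_that("eLOQ is the lowest level with all seven replicates within 30%", {
  lvl_a <- c(0.5, 0.8, 1.4, 1.31, 0.69, 1.0, 1.0) * 2    # 2 nM, wild
  lvl_b <- c(0.95, 1.05, 0.9, 1.1, 1.0, 0.98, 1.02) * 10 # 10 nM, tight
  out <- estimate_eloq(list(`2` = lvl_a, `10` = lvl_b))
  expect_equal(as.numeric(out), 10)
  expect_true(attr(out, "qualified"))

  all_in <- estimate_eloq(list(`2` = rep(2, 7), `10` = rep(10, 7)))
  expect_equal(as.numeric(all_in), 2)

  none <- estimate_eloq(list(`2` = lvl_a))
  expect_true(is.na(none))
  expect_false(attr(none, "qualified"))
  expect_error(estimate_eloq(list(`2` = rep(2, 5))), "exactly 7")
})

test_that("eLOQ falls as low-end noise shrinks", {
  lv <- c(2, 5, 10, 25, 60)
  eloq_at <- function(noise_scale, seed) {
    set.seed(seed)
    levels <- lapply(lv, function(c0)
      c0 * (1 + stats::rnorm(7, 0, noise_scale / c0)))
    names(levels) <- lv
    as.numeric(estimate_eloq(levels))
  }
  # sigma proportional to 1/C: smaller scale can only qualify lower levels
  hi <- vapply(1:20, function(s) eloq_at(4, s), numeric(1))
  lo <- vapply(1:20, function(s) eloq_at(0.4, s), numeric(1))
  expect_true(mean(lo, na.rm = TRUE) < mean(hi, na.rm = TRUE))
})

test_that("weighted fits pass the accuracy rule where unweighted fails", {
  # a 25%-inflated top standard tilts an unweighted line so the low end
  # misses by hundreds of percent; 1/x^2 weighting restores the low end at
  # the cost of an acceptable (< 30%) error at the top
  lv <- plasma_levels()
  resp <- 0.002 * lv
  resp[15] <- resp[15] * 1.25
  fits <- lapply(c("none", "1/x", "1/x2"), function(w)
    suppressWarnings(fit_calibration(make_standards(lv, resp), "linear", w)))
  worst <- vapply(fits, function(f)
    max(abs(f$accuracy_table$accuracy - 100)), numeric(1))
  expect_true(all(diff(worst) < 0))
  expect_false(fits[[1]]$accepted)
  expect_false(fits[[2]]$accepted)
  expect_true(fits[[3]]$accepted)
  # the cascade lands on the first passing weighting
  sel <- select_calibration(make_standards(lv, resp))
  expect_equal(sel$weighting, "1/x2")
  expect_true(sel$accepted)
})
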