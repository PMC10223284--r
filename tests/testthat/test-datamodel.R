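test_that("well-formed measurement CSVs round-trip losslessly", {
  spec <- generator_spec(seed = 11)
  m <- generate_uc_assay(spec, "b1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path, "measurements")
  expect_s3_class(back, "tk_measurements")
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$response_ratio, m$response_ratio, tolerance = 1e-12)
  expect_identical(back$sample_type, m$sample_type)
  expect_identical(back$censored, m$censored)

  # a second write of the re-read table is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("a small hand-written CSV parses into the expected records", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "chem_id,assay,sample_type,batch_id,replicate,time_min,nominal_conc,response_ratio,censored",
    "C1,calibration,standard,b1,1,NA,10,0.02,FALSE",
    "C1,uc_ppb,T5hr,b1,1,NA,NA,0.5,FALSE",
    "C1,uc_ppb,AF,b1,1,NA,NA,0.05,FALSE"), path)
  m <- read_measurements(path, "measurements")
  expect_equal(nrow(m), 3L)
  expect_equal(m$nominal_conc[1], 10)
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  base <- data.frame(chem_id = "C1", assay = "calibration",
                     sample_type = "standard", batch_id = "b1",
                     replicate = 1L, time_min = NA_real_,
                     nominal_conc = NA_real_, response_ratio = 0.1,
                     censored = FALSE)
  expect_error(as_measurements(base), "row 1.*nominal_conc")

  neg <- base
  neg$nominal_conc <- 5
  neg$response_ratio <- -0.2
  expect_error(as_measurements(neg), "negative response_ratio")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "chem_id,assay,sample_type,batch_id,replicate,time_min,nominal_conc,response_ratio,censored",
    "C1,calibration,standard,b1,1,NA,10,abc,FALSE"), path)
  expect_error(read_measurements(path), "non-numeric response_ratio in row\\(s\\) 1")
})

test_that("chemical table validation enforces positivity and enums", {
  ok <- data.frame(chem_id = "C1", name = "x", mol_weight = 100,
                   category = "cat", ionization_class = "ionized")
  expect_s3_class(as_chemicals(ok), "tk_chemicals")
  bad_mw <- transform(ok, mol_weight = -1)
  expect_error(as_chemicals(bad_mw), "mol_weight")
  bad_ion <- transform(ok, ionization_class = "mystery")
  expect_error(as_chemicals(bad_ion), "ionization_class")
  bad_loec <- ok
  bad_loec$loec <- 0
  expect_error(as_chemicals(bad_loec), "loec")
})

test_that("pipeline analyses a small synthetic cohort with an empty exclusion log", {
  cohort <- generate_cohort(n_chemicals = 5, seed = 42, p_zero_clint = 0.2)
  out <- run_pipeline(cohort$measurements, cohort$chemicals)
  expect_equal(nrow(out$results), 5L)
  expect_equal(nrow(out$exclusions), 0L)
  # every chemical with data shows up exactly once across results + exclusions
  expect_setequal(c(out$results$chem_id, out$exclusions$chem_id),
                  unique(cohort$measurements$chem_id))
})

test_that("pipeline routes failures into the exclusion log and keeps going", {
  stable <- generate_chemical(generator_spec(chem_id = "OK1", seed = 5))
  unstable <- generate_chemical(
    generator_spec(chem_id = "BAD1", true_D = 0.3, seed = 6))
  meas <- as_measurements(rbind(as.data.frame(stable$measurements),
                                as.data.frame(unstable$measurements)))
  chems <- as_chemicals(rbind(as.data.frame(stable$chemical),
                              as.data.frame(unstable$chemical)))
  out <- run_pipeline(meas, chems)
  expect_equal(out$results$chem_id, "OK1")
  expect_equal(out$exclusions$chem_id, "BAD1")
  expect_match(out$exclusions$reason, "plasma loss")
  expect_equal(nrow(out$results) + nrow(out$exclusions),
               length(unique(meas$chem_id)))

  # a chemical with no standards is flagged "no calibration", not fatal
  nostd <- as.data.frame(generate_uc_assay(
    generator_spec(chem_id = "NOCAL", seed = 7), "orphan_batch"))
  out2 <- run_pipeline(
    as_measurements(rbind(as.data.frame(stable$measurements), nostd)),
    chems)
  expect_true("NOCAL" %in% out2$exclusions$chem_id)
  expect_match(out2$exclusions$reason[out2$exclusions$chem_id == "NOCAL"],
               "no calibration")
})

test_that("empty input yields empty results with a warning", {
  empty <- as_measurements(data.frame(
    chem_id = character(0), assay = character(0),
    sample_type = character(0), batch_id = character(0),
    replicate = integer(0), time_min = numeric(0),
    nominal_conc = numeric(0), response_ratio = numeric(0),
    censored = logical(0)))
  chems <- as_chemicals(data.frame(chem_id = character(0),
                                   name = character(0),
                                   mol_weight = numeric(0),
                                   category = character(0),
                                   ionization_class = character(0)))
  expect_warning(out <- run_pipeline(empty, chems), "empty")
  expect_equal(nrow(out$results), 0L)
})

test_that("config invariants are enforced and YAML configs load", {
  expect_error(pipeline_config(plasma_loss_cutoff = 1.5))
  expect_error(bayes_config(shrink_threshold = 1))
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha_ftest: 0.01",
               "ivive:", "  gfr: 7.0",
               "bayes:", "  n_chains: 3"), path)
  cfg <- read_config(path)
  expect_equal(cfg$alpha_ftest, 0.01)
  expect_equal(cfg$ivive$gfr, 7.0)
  expect_equal(cfg$bayes$n_chains, 3L)
  expect_equal(cfg$plasma_loss_cutoff, 0.60)
})
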