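test_that("generator config validates effects and CBPI target", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(cbpi_target = 0.9), "cbpi_target")
  expect_error(synthetic_config(effects = list(RA = list(during = 0.5))),
               "unknown timing")
  expect_error(synthetic_config(effects = list(RA = list(pre = 1.5))),
               "protection fraction")
})

test_that("same seed yields an identical dataset (calibration and screening)", {
  cfg <- synthetic_config(seed = 77,
                          effects = list(RA = list(pre = 0.58, post = 0.08)))
  a <- simulate_calibration_dataset(cfg)
  b <- simulate_calibration_dataset(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  s1 <- simulate_screening_experiment(cfg)
  s2 <- simulate_screening_experiment(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # and the CSV round trip is byte-identical
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_scoring_table(s1, p1); write_scoring_table(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("calibration draws follow the configured mean structure", {
  # degenerate schedule: slope 0 gives Poisson(baseline) everywhere
  cfg0 <- synthetic_config(slope = 0, donor_sd = 0, seed = 5,
                           calibration_doses = c(0, 1000, 2000))
  recs <- simulate_calibration_dataset(cfg0)
  f <- mn_frequency_per_500(recs$mn_count, recs$n_bc_scored)
  se <- sqrt(cfg0$baseline_freq / length(f))
  expect_lt(abs(mean(f) - cfg0$baseline_freq), 3 * se)

  # default design: records span the dose schedule with all arms labelled
  cfg <- synthetic_config(seed = 6)
  cal <- simulate_calibration_dataset(cfg)
  expect_equal(nrow(cal), 20 * 6 * 5)
  expect_setequal(unique(cal$dose_mGy), cfg$calibration_doses)
  expect_true(all(cal$substance == "control" & cal$timing == "none"))
})

test_that("dispersion 0 gives Poisson-like variance-to-mean ratios", {
  cfg <- synthetic_config(slope = 0, donor_sd = 0, seed = 8,
                          calibration_doses = 0, n_donors = 1,
                          n_experiments = 200)
  ratios <- replicate(50, {
    r <- simulate_calibration_dataset(synthetic_config(
      slope = 0, donor_sd = 0, calibration_doses = 0, n_donors = 1,
      n_experiments = 200, seed = NULL))
    stats::var(r$mn_count) / mean(r$mn_count)
  })
  # var/mean ~ 1 with SD ~ sqrt(2/n) per replicate
  mc_se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * mc_se + 0.02)

  # overdispersed draws inflate the ratio towards 1 + dispersion
  set.seed(9)
  r2 <- simulate_calibration_dataset(synthetic_config(
    slope = 0, donor_sd = 0, dispersion = 2, calibration_doses = 0,
    n_donors = 1, n_experiments = 2000, seed = 10))
  expect_gt(stats::var(r2$mn_count) / mean(r2$mn_count), 1.5)
})

test_that("screening arms follow the effects map and solvent rule", {
  cfg <- synthetic_config(
    seed = 12, donor_sd = 0, n_experiments = 50,
    effects = list(RA = list(pre = 0.58, post = 0.08),
                   vitE = list(pre = 0.5, solvent = "dmso"))
  )
  recs <- simulate_screening_experiment(cfg)
  truth <- attr(recs, "truth")$arms
  # configured truth: multiplicative protection on the irradiated control,
  # DMSO offset added in the pre arm only
  expect_equal(truth$mean_freq[truth$substance == "RA" & truth$timing == "pre"],
               (1 - 0.58) * 26)
  expect_equal(truth$mean_freq[truth$substance == "vitE"],
               (1 - 0.5 - cfg$dmso_offset) * 26)
  expect_equal(truth$mean_freq[truth$substance == "dmso" & truth$timing == "post"],
               26)
  # empirical arm means track the configured truth (treated arms)
  f <- mn_frequency_per_500(recs$mn_count, recs$n_bc_scored)
  arm <- paste(recs$substance, recs$timing)
  treated <- truth[truth$substance != "control", ]
  for (i in seq_len(nrow(treated))) {
    obs <- f[arm == paste(treated$substance[i], treated$timing[i])]
    se <- sqrt(treated$mean_freq[i] / length(obs))
    expect_lt(abs(mean(obs) - treated$mean_freq[i]), 4 * se)
  }
  # empty effects map: only control arms
  only_ctrl <- simulate_screening_experiment(synthetic_config(seed = 13))
  expect_true(all(only_ctrl$substance == "control"))
})

test_that("zero protection fraction reproduces the irradiated control arm", {
  cfg <- synthetic_config(seed = 14, donor_sd = 0, n_experiments = 100,
                          effects = list(inert = list(pre = 0)))
  recs <- simulate_screening_experiment(cfg)
  f <- mn_frequency_per_500(recs$mn_count, recs$n_bc_scored)
  ctrl <- f[recs$substance == "control" & recs$dose_mGy > 0]
  trt <- f[recs$substance == "inert"]
  expect_gt(stats::t.test(ctrl, trt)$p.value, 0.001)
  expect_lt(abs(mean(trt) - 26), 4 * sqrt(26 / length(trt)))
})

test_that("CBPI tallies hit the configured proliferation target", {
  cfg <- synthetic_config(cbpi_target = 1.65, seed = 15)
  tal <- simulate_cbpi_tallies(cfg, n_cells = 20000)
  v <- cbpi(tal["n_mono"], tal["n_bi"], tal["n_multi"])
  expect_lt(abs(unname(v) - 1.65), 0.05)
  expect_equal(unname(cbpi_quality_flag(v)), "pass")

  all_mono <- simulate_cbpi_tallies(synthetic_config(cbpi_target = 1,
                                                     seed = 16), 500)
  expect_equal(unname(all_mono["n_mono"]), 500)
})

test_that("synthetic dataset writer emits matching CSV and truth JSON", {
  cfg <- synthetic_config(seed = 17, effects = list(RA = list(pre = 0.58)))
  recs <- simulate_screening_experiment(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  truth <- withr::local_tempfile(fileext = ".json")
  write_synthetic_dataset(recs, csv, truth)
  back <- read_scoring_table(csv)
  expect_equal(nrow(back), nrow(recs))
  tj <- jsonlite::read_json(truth, simplifyVector = TRUE)
  expect_true("arms" %in% names(tj))
  expect_equal(tj$arms$mean_freq[tj$arms$substance == "RA"],
               (1 - 0.58) * 26)
})
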