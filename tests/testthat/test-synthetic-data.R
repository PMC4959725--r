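test_that("generated populations follow the preset class Gaussians", {
  rec <- generate_population("maize_zd958", n = 1260, seed = 2)
  expect_equal(nrow(rec), 1260)
  for (cl in c("haploid", "diploid")) {
    v <- rec$ocr_pct[rec$true_class == cl]
    mu <- if (cl == "haploid") 3.6 else 5.5
    sdv <- if (cl == "haploid") 0.47 else 0.52
    expect_lt(abs(mean(v) - mu), 3 * sdv / sqrt(length(v)))
  }
  # oil mass is consistent with OCR and mass by construction
  expect_equal(rec$oil_mass_mg, rec$ocr_pct * rec$mass_g * 10)
  expect_true(all(rec$mass_g > 0.05))
  expect_true(all(rec$ocr_pct > 0))
})

test_that("population generation is deterministic and honors the class fraction", {
  r1 <- generate_population("maize_zd958", n = 200, seed = 9)
  r2 <- generate_population("maize_zd958", n = 200, seed = 9)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_kernel_records(r1, f1); write_kernel_records(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # all-haploid limit
  p <- population_preset("maize_zd958")
  p$haploid_fraction <- 1
  all_h <- generate_population(p, n = 50, seed = 1)
  expect_true(all(all_h$true_class == "haploid"))

  # realistic induction preset is haploid-sparse
  ind <- generate_population("maize_zd958_induction", n = 2000, seed = 3)
  frac <- mean(ind$true_class == "haploid")
  expect_lt(abs(frac - 0.086), 3 * sqrt(0.086 * 0.914 / 2000))
})

test_that("truncated sampling leaves well-separated class means unchanged", {
  set.seed(13)
  x <- kernelscreen:::rnorm_trunc(2e5, 3.6, 0.47, lower = 0)
  expect_lt(abs(mean(x) - 3.6) / 3.6, 0.001)
  # truncation actually binds when the bound is near the mean
  y <- kernelscreen:::rnorm_trunc(1e4, 0.1, 1, lower = 0)
  expect_true(all(y > 0))
  expect_gt(mean(y), 0.1)
})

test_that("soybean presets generate single-class populations with preset OCR", {
  rec <- generate_population("soybean_feng2", n = 400, seed = 5)
  expect_true(all(rec$true_class == "unknown"))
  expect_lt(abs(mean(rec$ocr_pct) - 20.4), 3 * 1.0 / sqrt(400))
  expect_lt(abs(sd(rec$ocr_pct) - 1.0), 0.15)
})

test_that("noiseless forward simulation inverts exactly through the pipeline", {
  rec <- generate_population("maize_zd958", n = 100, seed = 7)
  calib <- calibration_model(361.7, 0)
  relax <- relaxation_params()
  acq <- acquisition_config(echo_times = c(7.5), noise_sd = 0)
  sig <- population_to_signals(rec, calib, relax, acq)

  dec <- decompose_echo_trains(sig, method = "single_echo", te = 7.5,
                               relax = relax, correct = TRUE)
  oil_mg <- apply_calibration(calib, dec$s_oil_v)
  ocr_out <- compute_ocr(oil_mg, rec$mass_g[match(dec$kernel_id, rec$kernel_id)])
  expect_lt(max(abs(ocr_out - rec$ocr_pct)), 0.005)

  # zero-oil kernel comes out at OCR 0
  zk <- data.frame(kernel_id = "Z1", mass_g = 0.4, oil_mass_mg = 0,
                   water_mass_mg = 40)
  zsig <- population_to_signals(zk, calib, relax, acq)
  zdec <- decompose_echo_trains(zsig, method = "single_echo", te = 7.5,
                                relax = relax, correct = TRUE)
  # a zero-oil kernel reads back at the water-leak floor, well below 0.005 pp
  expect_lt(compute_ocr(apply_calibration(calib, pmax(zdec$s_oil_v, 0)), 0.4),
            0.005)
})

test_that("changing the instrument response is absorbed by matched standards", {
  rec <- generate_population("maize_zd958", n = 60, seed = 15)
  relax <- relaxation_params()
  acq <- acquisition_config(echo_times = c(7.5), noise_sd = 0)
  pipeline_ocr <- function(k_true) {
    calib_true <- calibration_model(k_true, 0)
    std <- simulate_calibration_standards(seq(5, 50, length.out = 8),
                                          calib = calib_true, relax = relax)
    calib_fit <- fit_calibration(std$signal_v, std$mass_mg)
    sig <- population_to_signals(rec, calib_true, relax, acq)
    dec <- decompose_echo_trains(sig, method = "single_echo", te = 7.5,
                                 relax = relax, correct = FALSE)
    compute_ocr(apply_calibration(calib_fit, dec$s_oil_v), rec$mass_g)
  }
  ocr1 <- pipeline_ocr(361.7)
  ocr2 <- pipeline_ocr(2 * 361.7)  # doubled k halves all signals
  expect_equal(ocr1, ocr2, tolerance = 1e-10)
  # inversion is exact up to the bound-water leak (< 1e-3 relative)
  expect_equal(ocr1, rec$ocr_pct, tolerance = 1e-3)
})

test_that("feeder simulation reproduces its Bernoulli success model", {
  perfect <- feeder_model(c(ideal = 1.0))
  ev <- simulate_feeder(500, perfect, "ideal", seed = 1)
  expect_equal(ev$n_failures, 0)
  expect_true(all(ev$retries_before_success == 0))

  # bench-scale run: failures within 3 binomial sd of n(1-p)
  ev2 <- simulate_feeder(9490, category = "round_corn", seed = 2)
  expected_fail <- 9490 * 0.08
  expect_lt(abs(ev2$n_failures - expected_fail), 3 * sqrt(9490 * 0.92 * 0.08))
  expect_equal(ev2$n_attempts, 9490)

  # law of large numbers
  ev3 <- simulate_feeder(1e6, category = "soybean", seed = 3)
  expect_equal(ev3$success_rate, 0.974, tolerance = 0.002)

  # determinism and input validation
  expect_identical(simulate_feeder(100, category = "flat_corn", seed = 4),
                   simulate_feeder(100, category = "flat_corn", seed = 4))
  expect_error(simulate_feeder(10, category = "pebbles"), "unknown")
})

test_that("repeat measurements of one kernel are unbiased with sd tracking noise", {
  kernel <- data.frame(kernel_id = "K1", mass_g = 0.42,
                       oil_mass_mg = 6.7 * 0.42 * 10, water_mass_mg = 42)

  r0 <- repeat_measurement(kernel, n_repeats = 10, noise_sd = 0, seed = 1)
  expect_equal(unname(r0$summary["sd"]), 0)
  expect_equal(unname(r0$summary["mean"]), 6.7, tolerance = 1e-3)

  # noise chosen to put the OCR sd near 0.2 percentage points
  rn <- repeat_measurement(kernel, n_repeats = 50, noise_sd = 0.00215, seed = 2)
  expect_lt(abs(rn$summary[["mean"]] - 6.7), 0.1)
  expect_gt(rn$summary[["sd"]], 0.1)
  expect_lt(rn$summary[["sd"]], 0.35)

  # OCR sd scales linearly with the receiver noise level
  s1 <- repeat_measurement(kernel, n_repeats = 200, noise_sd = 0.001, seed = 3)
  s2 <- repeat_measurement(kernel, n_repeats = 200, noise_sd = 0.002, seed = 3)
  expect_equal(s2$summary[["sd"]] / s1$summary[["sd"]], 2, tolerance = 0.2)
})
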