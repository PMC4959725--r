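test_that("compute_ocr is the oil/mass ratio in common units", {
  # the stability-test kernel: 0.42 g at 6.7% OCR carries 28.14 mg of oil
  expect_equal(compute_ocr(28.14, 0.42), 6.7, tolerance = 1e-12)
  expect_equal(round(compute_ocr(28.0, 0.42), 1), 6.7)
  expect_equal(compute_ocr(0, 0.5), 0)
  # scale invariance
  expect_equal(compute_ocr(28, 0.42), compute_ocr(56, 0.84))
  expect_error(compute_ocr(28, 0), "positive")
})

test_that("labelled Gaussian fits recover the generating class parameters", {
  rec <- draw_records(630, 630, seed = 11)
  cm <- fit_class_gaussians(rec)
  expect_equal(cm$ocr_mean[["haploid"]], 3.6, tolerance = 0.05 / 3.6)
  expect_equal(cm$ocr_mean[["diploid"]], 5.5, tolerance = 0.05 / 5.5)
  expect_equal(cm$proportion[["haploid"]], 0.5)

  # permutation invariance
  cm2 <- fit_class_gaussians(rec[sample(nrow(rec)), ])
  expect_equal(cm2$ocr_mean, cm$ocr_mean)

  # degenerate and missing classes are rejected
  degen <- data.frame(true_class = rep(c("haploid", "diploid"), each = 2),
                      ocr_pct = c(3, 3, 5, 5), mass_g = c(0.4, 0.4, 0.4, 0.4))
  expect_error(fit_class_gaussians(degen), "degenerate|zero variance")
  expect_error(fit_class_gaussians(rec[rec$true_class == "haploid", ]),
               "haploid and diploid")
})

test_that("the unlabelled mixture fit agrees with the labelled fit", {
  rec <- draw_records(630, 630, seed = 21)
  cm_lab <- fit_class_gaussians(rec)
  cm_mix <- fit_mixture(rec$ocr_pct)
  se_h <- cm_lab$ocr_sd[["haploid"]] / sqrt(630)
  se_d <- cm_lab$ocr_sd[["diploid"]] / sqrt(630)
  expect_lt(abs(cm_mix$ocr_mean[["haploid"]] - cm_lab$ocr_mean[["haploid"]]), 3 * se_h)
  expect_lt(abs(cm_mix$ocr_mean[["diploid"]] - cm_lab$ocr_mean[["diploid"]]), 3 * se_d)
  expect_true(attr(cm_mix, "converged"))
})

test_that("the mixture fit resolves near-degenerate well-separated components", {
  set.seed(4)
  x <- c(rnorm(200, 3.6, 0.01), rnorm(200, 5.5, 0.01))
  cm <- fit_mixture(x)
  expect_equal(cm$ocr_mean[["haploid"]], 3.6, tolerance = 1e-3)
  expect_equal(cm$ocr_mean[["diploid"]], 5.5, tolerance = 1e-3)

  expect_error(fit_mixture(rep(4, 100)), "identical")
  expect_error(fit_mixture(rnorm(10)), "at least 20")
})

test_that("classification thresholds at the class boundary go to diploid", {
  expect_equal(classify_ocr(3.6, 4.25), "haploid")
  expect_equal(classify_ocr(5.5, 4.25), "diploid")
  expect_equal(classify_ocr(4.25, 4.25), "diploid")  # tie convention
})

test_that("the haploid-called set grows monotonically with the threshold", {
  set.seed(6)
  ocr <- runif(500, 2, 7)
  prev <- rep(FALSE, 500)
  for (thr in seq(2, 7.5, by = 0.25)) {
    cur <- classify_ocr(ocr, thr) == "haploid"
    expect_true(all(cur[prev]))  # once haploid, stays haploid as thr rises
    prev <- cur
  }
})

test_that("analytic error rates match a Monte-Carlo oracle and their limits", {
  m <- field_class_model()
  r <- model_error_rates(m, 4.25)

  # Monte-Carlo oracle: fraction of diploid draws below threshold
  set.seed(17)
  mc_fn <- 100 * mean(rnorm(1e6, 5.5, 0.52) < 4.25)
  expect_lt(abs(r$false_negative - mc_fn), 0.02)
  mc_fp <- 100 * mean(rnorm(1e6, 3.6, 0.47) >= 4.25)
  expect_lt(abs(r$false_positive - mc_fp), 0.05)

  expect_equal(r$total_error, r$false_negative + r$false_positive)
  expect_equal(r$weighted_total_error,
               0.5 * r$false_negative + 0.5 * r$false_positive)

  # limits: an extreme threshold trades one error for the other
  lo <- model_error_rates(m, 1e-6)
  expect_equal(lo$false_negative, 0, tolerance = 1e-6)
  expect_equal(lo$false_positive, 100, tolerance = 1e-6)
})

test_that("empirical error rates count the confusion table correctly", {
  clean <- data.frame(true_class = rep(c("haploid", "diploid"), each = 50),
                      ocr_pct = rep(c(3.0, 6.0), each = 50))
  r <- empirical_error_rates(clean, 4.25)
  expect_equal(r$total_error, 0)
  expect_equal(r$accuracy, 100)
  expect_equal(sum(r$counts), 100)

  # one stray diploid among 99 correct kernels: 1/50 of the diploids
  one_off <- clean
  one_off$ocr_pct[51] <- 3.0
  r1 <- empirical_error_rates(one_off, 4.25)
  expect_equal(r1$false_negative, 100 * 1 / 50)
  expect_equal(r1$counts[["diploid", "haploid"]], 1)
  expect_equal(sum(r1$counts), 100)
})

test_that("empirical rates converge to the analytic rates at large n", {
  n <- 5000
  rec <- draw_records(n, n, seed = 33)
  emp <- empirical_error_rates(rec, 4.25)
  mod <- model_error_rates(field_class_model(), 4.25)
  se_fn <- 100 * sqrt(mod$false_negative / 100 * (1 - mod$false_negative / 100) / n)
  se_fp <- 100 * sqrt(mod$false_positive / 100 * (1 - mod$false_positive / 100) / n)
  expect_lt(abs(emp$false_negative - mod$false_negative), 3 * se_fn)
  expect_lt(abs(emp$false_positive - mod$false_positive), 3 * se_fp)
})

test_that("selection accuracy is the true-haploid share of the selected pool", {
  t2 <- table2_counts()
  acc <- accuracy_from_counts(t2$identified, t2$true_haploids)
  ok <- t2$cross != "XY335"
  expect_equal(acc[ok], t2$printed_accuracy[ok])
  # the XY335 row as printed is internally inconsistent: 299/315 is 94.92,
  # 0.02 below the tabulated accuracy
  expect_equal(acc[!ok], 94.92)
  expect_equal(accuracy_from_counts(100, 100), 100)
  expect_error(accuracy_from_counts(0, 0), "positive")
  expect_error(accuracy_from_counts(10, 11), "identified")
})

test_that("separability compares the mean gap to the average width", {
  m <- field_class_model()
  s_ocr <- separability(m, "ocr")
  expect_equal(s_ocr$mean_difference, 1.9)
  expect_equal(s_ocr$half_width_sum, 0.495)
  expect_true(s_ocr$separable)

  s_w <- separability(m, "weight")
  expect_equal(s_w$mean_difference, 0.03)
  expect_equal(s_w$half_width_sum, 0.042)
  expect_false(s_w$separable)

  # identical class distributions are never separable
  same_w <- class_model(ocr_mean = c(haploid = 3.6, diploid = 5.5),
                        ocr_sd = c(haploid = 0.47, diploid = 0.52),
                        weight_mean = c(haploid = 0.4, diploid = 0.4),
                        weight_sd = c(haploid = 0.04, diploid = 0.04))
  s0 <- separability(same_w, "weight")
  expect_equal(s0$mean_difference, 0)
  expect_false(s0$separable)
})

test_that("OCR screening beats any oil-mass-only threshold when weight varies", {
  rec <- draw_records(630, 630, seed = 44)
  rec$oil_mass_mg <- rec$ocr_pct * rec$mass_g * 10

  # oracle: grid search over thresholds on both variables; the best OCR
  # threshold strictly beats the best oil-mass threshold
  best_oil <- optimize_threshold(rec$oil_mass_mg, rec$true_class, step = 0.01)
  best_ocr <- optimize_threshold(rec$ocr_pct, rec$true_class, step = 0.01)
  expect_lt(best_ocr$total_error, best_oil$total_error)

  # even against the sample-optimal oil threshold, the haploid pool selected
  # by OCR is cleaner
  cmp <- ocr_vs_oil_only(rec, oil_threshold = best_oil$threshold,
                         ocr_threshold = 4.25)
  expect_gt(cmp$contamination_ratio, 1)

  # constant weight: oil mass carries the same information as OCR
  rec2 <- rec
  rec2$mass_g <- 0.42
  rec2$oil_mass_mg <- rec2$ocr_pct * 0.42 * 10
  cmp2 <- ocr_vs_oil_only(rec2, oil_threshold = 4.25 * 0.42 * 10,
                          ocr_threshold = 4.25)
  expect_equal(cmp2$ocr, cmp2$oil_only)

  expect_error(ocr_vs_oil_only(rec[rec$true_class == "diploid", ],
                               oil_threshold = 18), "haploid")
})

test_that("replicate comparison reproduces the paired-t arithmetic", {
  # constructed differences with exact mean -0.02 and sd 0.122
  d <- as.numeric(scale(1:10)) * 0.122 - 0.02
  y1 <- seq(5, 7, length.out = 10)
  y2 <- y1 + d
  r <- compare_replicates(y1, y2)
  expect_equal(r$mean_diff, -0.02)
  expect_equal(r$sd_diff, 0.122)
  expect_equal(r$se, 0.122 / sqrt(10))
  expect_equal(r$t_statistic, -0.02 / (0.122 / sqrt(10)))
  expect_equal(r$df, 9)

  # cross-check against the stock paired t-test
  tt <- t.test(y2, y1, paired = TRUE)
  expect_equal(r$t_statistic, unname(tt$statistic))
  expect_equal(r$p_value, tt$p.value)

  # identical and shifted series
  r0 <- compare_replicates(y1, y1)
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$correlation, 1)
  rs <- compare_replicates(y1, y1 + 0.3)
  expect_equal(rs$mean_diff, 0.3)
  expect_equal(rs$correlation, 1)

  expect_error(compare_replicates(1:3, 1:4), "equal length")
})
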