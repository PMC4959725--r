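#' Population presets
#'
#' Named seed-population presets shipped with the package as JSON under
#' `extdata/presets/`. Each preset holds per-class Gaussian parameters for
#' OCR (percent) and kernel weight (g), the haploid fraction, and a Gaussian
#' water-content-ratio (WCR) model.
#'
#' Available presets:
#' \describe{
#'   \item{`maize_zd958`}{ZD958 x CHOI3 induction-cross field population:
#'     haploid OCR N(3.6, 0.47), diploid N(5.5, 0.52); weights N(0.40,
#'     0.049) / N(0.43, 0.035) g; balanced classes for testing.}
#'   \item{`maize_zd958_induction`}{Same Gaussians with a realistic
#'     induction-rate haploid fraction of 0.086 (321 haploids among 3742
#'     screened kernels).}
#'   \item{`zheng58_cauhoi`}{Zheng58 x CAUHOI cross; diploid OCR centred on
#'     6.7% (the stability-test kernel: 0.42 g, mean OCR 6.7%), haploid
#'     below half of that.}
#'   \item{`soybean_feng1`, `soybean_feng2`}{Single-class high-oil soybean
#'     populations: OCR N(17.5, 2.0) and N(20.4, 1.0), seed weights in the
#'     0.35-0.6 g and 0.12-0.3 g ranges.}
#' }
#'
#' @param name Preset name, or a path to a preset JSON file.
#' @return A `population_preset` object.
#' @examples
#' population_preset("maize_zd958")
#' @export
population_preset <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "presets", paste0(name, ".json"),
                package = "kernelscreen")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_input("unknown preset '", name, "' (no such file or shipped preset)")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_preset(x)
  structure(x, class = "population_preset")
}

#' @rdname population_preset
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "kernelscreen")
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}

validate_preset <- function(x) {
  if (is.null(x$name) || is.null(x$classes) || length(x$classes) < 1L) {
    stop_input("invalid preset: needs 'name' and at least one class")
  }
  for (cl in names(x$classes)) {
    p <- x$classes[[cl]]
    need <- c("ocr_mean", "ocr_sd", "weight_mean", "weight_sd")
    if (!all(need %in% names(p))) {
      stop_input("invalid preset class '", cl, "': needs ",
                 paste(need, collapse = ", "))
    }
    if (p$ocr_sd <= 0 || p$weight_sd <= 0) {
      stop_input("invalid preset: class sds must be positive")
    }
  }
  if (length(x$classes) > 1L) {
    hf <- x$haploid_fraction
    if (is.null(hf) || hf <= 0 || hf > 1) {
      stop_input("invalid preset: haploid_fraction must lie in (0,1]")
    }
  }
  if (is.null(x$wcr_mean) || is.null(x$wcr_sd) || x$wcr_sd <= 0) {
    stop_input("invalid preset: needs wcr_mean and positive wcr_sd")
  }
  invisible(x)
}

#' @export
print.population_preset <- function(x, ...) {
  cat(sprintf("Population preset '%s':\n", x$name))
  for (cl in names(x$classes)) {
    p <- x$classes[[cl]]
    cat(sprintf("  %-8s OCR N(%g, %g)%%, weight N(%g, %g) g\n",
                cl, p$ocr_mean, p$ocr_sd, p$weight_mean, p$weight_sd))
  }
  if (!is.null(x$haploid_fraction)) {
    cat(sprintf("  haploid fraction %g\n", x$haploid_fraction))
  }
  cat(sprintf("  WCR N(%g, %g)%%\n", x$wcr_mean, x$wcr_sd))
  invisible(x)
}

# Gaussian draws truncated below at `lower`, by resampling.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a labelled kernel population
#'
#' Samples kernel records from a preset's class Gaussians: the class is
#' Bernoulli(haploid fraction), weight comes from the class weight Gaussian
#' truncated at 0.05 g, OCR from the class OCR Gaussian truncated at 0, and
#' WCR from the preset's water model. Oil and water masses follow from the
#' ratios (`oil_mass_mg = ocr_pct * mass_g * 10`). OCR and weight are
#' sampled independently within a class.
#'
#' @param preset A [population_preset()] or preset name.
#' @param n Number of kernels (>= 1).
#' @param seed Integer seed; identical seeds give identical populations.
#' @return A kernel-record data.frame: `kernel_id`, `true_class`, `mass_g`,
#'   `oil_mass_mg`, `water_mass_mg`, `ocr_pct`, `wcr_pct`, `assigned_class`
#'   (NA until classified).
#' @examples
#' head(generate_population("maize_zd958", n = 5, seed = 1))
#' @export
generate_population <- function(preset, n, seed = NULL) {
  if (is.character(preset)) preset <- population_preset(preset)
  stopifnot(inherits(preset, "population_preset"))
  if (!is.numeric(n) || n < 1 || n != round(n)) stop_input("n must be a positive integer")
  n <- as.integer(n)
  cls_names <- names(preset$classes)
  with_seed(seed, {
    true_class <- if (length(cls_names) == 1L) {
      rep(cls_names, n)
    } else {
      ifelse(rbinom(n, 1L, preset$haploid_fraction) == 1L, "haploid", "diploid")
    }
    mass <- numeric(n); ocr <- numeric(n)
    for (cl in cls_names) {
      i <- which(true_class == cl)
      p <- preset$classes[[cl]]
      mass[i] <- rnorm_trunc(length(i), p$weight_mean, p$weight_sd, lower = 0.05)
      ocr[i] <- rnorm_trunc(length(i), p$ocr_mean, p$ocr_sd, lower = 0)
    }
    wcr <- rnorm_trunc(n, preset$wcr_mean, preset$wcr_sd, lower = 0)
    data.frame(
      kernel_id = sprintf("K%05d", seq_len(n)),
      true_class = true_class,
      mass_g = mass,
      oil_mass_mg = ocr * mass * 10,   # pct of g expressed in mg
      water_mass_mg = wcr * mass * 10,
      ocr_pct = ocr,
      wcr_pct = wcr,
      assigned_class = NA_character_,
      stringsAsFactors = FALSE)
  })
}

#' Forward-simulate echo trains for a kernel population
#'
#' Inverts the calibration to convert each kernel's oil and water masses
#' into signal amplitudes (`S = (A - b) / k`), then simulates one echo train
#' per kernel under the relaxation model and acquisition settings. Running
#' the measurement pipeline (decompose, calibrate, OCR) on the noiseless
#' output reproduces each record's OCR.
#'
#' @param records Kernel-record data.frame from [generate_population()].
#' @param calib A [calibration_model()] (the "true" instrument response).
#' @param relax A [relaxation_params()].
#' @param acq An [acquisition_config()]; its `seed` drives all noise.
#' @return Long-form echo-train table (`kernel_id`, `time_ms`,
#'   `amplitude_v`).
#' @export
population_to_signals <- function(records, calib = calibration_model(361.7, 0),
                                  relax = relaxation_params(),
                                  acq = acquisition_config(echo_times = c(7.5))) {
  stopifnot(inherits(calib, "calibration_model"),
            inherits(relax, "relaxation_params"),
            inherits(acq, "acquisition_config"))
  s_oil <- pmax((records$oil_mass_mg - calib$b) / calib$k, 0)
  s_wat <- pmax((records$water_mass_mg - calib$b) / calib$k, 0)
  t <- c(0, acq$echo_times)
  # clean signal matrix: kernels x time points
  clean <- outer(s_oil, exp(-t / relax$t2_oil)) +
    outer(s_wat, exp(-t / relax$t2_water))
  eff_sd <- acq$noise_sd / sqrt(acq$n_averages)
  noisy <- with_seed(acq$seed, clean + rnorm(length(clean), 0, eff_sd))
  data.frame(
    kernel_id = rep(records$kernel_id, each = length(t)),
    time_ms = rep(t, times = nrow(records)),
    amplitude_v = as.numeric(t(noisy)),
    stringsAsFactors = FALSE)
}

#' Feeder model and presets
#'
#' Single-kernel feeder success probabilities per kernel-shape category, as
#' observed in long-duration bench tests: 0.92 for round maize kernels (672
#' failed pick-ups in 9490 attempts), 0.90 for flat maize kernels, 0.974 for
#' soybean, and up to 0.98 for other round seeds such as peanut.
#'
#' @param probabilities Named numeric vector of success probabilities in
#'   (0, 1].
#' @return A `feeder_model` object.
#' @examples
#' feeder_model()
#' @export
feeder_model <- function(probabilities = c(round_corn = 0.92, flat_corn = 0.90,
                                           soybean = 0.974, other_round = 0.98)) {
  if (!is.numeric(probabilities) || is.null(names(probabilities)) ||
      any(probabilities <= 0) || any(probabilities > 1)) {
    stop_input("probabilities must be named values in (0, 1]")
  }
  structure(list(probabilities = probabilities), class = "feeder_model")
}

#' Simulate single-kernel feeder events
#'
#' Bernoulli event stream of pick-up attempts for one kernel-shape
#' category, with the per-attempt success probability of the feeder model.
#'
#' @param n_attempts Number of pick-up attempts (>= 1).
#' @param model A [feeder_model()].
#' @param category Kernel-shape category; must be one of the model's names.
#' @param seed Integer seed.
#' @return A list: `events` (data.frame `attempt`, `success`), `n_attempts`,
#'   `n_failures`, `success_rate`, and `retries_before_success` (failure-run
#'   lengths preceding each success).
#' @examples
#' simulate_feeder(100, category = "round_corn", seed = 1)$success_rate
#' @export
simulate_feeder <- function(n_attempts, model = feeder_model(),
                            category = "round_corn", seed = NULL) {
  stopifnot(inherits(model, "feeder_model"))
  if (!is.numeric(n_attempts) || n_attempts < 1) {
    stop_input("n_attempts must be >= 1")
  }
  if (!category %in% names(model$probabilities)) {
    stop_input("unknown feeder category '", category, "'")
  }
  p <- model$probabilities[[category]]
  success <- with_seed(seed, rbinom(as.integer(n_attempts), 1L, p) == 1L)
  runs <- rle(success)
  retries <- integer(0)
  fails_pending <- 0L
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i]) {
      retries <- c(retries, fails_pending, rep(0L, runs$lengths[i] - 1L))
      fails_pending <- 0L
    } else {
      fails_pending <- runs$lengths[i]
    }
  }
  list(events = data.frame(attempt = seq_along(success), success = success),
       n_attempts = length(success),
       n_failures = sum(!success),
       success_rate = mean(success),
       retries_before_success = retries)
}

#' Repeated measurement of one kernel
#'
#' Runs the full measurement pipeline (forward-simulate with fresh noise,
#' single-echo decomposition, calibration, OCR) `n_repeats` times on one
#' fixed kernel, emulating a bench stability test.
#'
#' @param kernel A single kernel record (one-row data.frame with `mass_g`,
#'   `oil_mass_mg`, `water_mass_mg`).
#' @param n_repeats Number of repeat measurements (>= 2).
#' @param calib A [calibration_model()] used both to synthesise the signal
#'   and to read it back.
#' @param relax A [relaxation_params()].
#' @param noise_sd Single-shot receiver noise sd, volts.
#' @param n_averages Accumulated scans per measurement.
#' @param te Echo time of the production measurement, ms.
#' @param seed Integer seed.
#' @return A list: `ocr` (vector of length `n_repeats`) and `summary`
#'   (min/max/mean/sd).
#' @export
repeat_measurement <- function(kernel, n_repeats = 50,
                               calib = calibration_model(361.7, 0),
                               relax = relaxation_params(),
                               noise_sd = 0, n_averages = 1, te = 7.5,
                               seed = NULL) {
  if (nrow(kernel) != 1L) stop_input("kernel must be a single record")
  if (n_repeats < 2L) stop_input("n_repeats must be >= 2")
  reps <- kernel[rep(1L, n_repeats), , drop = FALSE]
  reps$kernel_id <- sprintf("R%05d", seq_len(n_repeats))
  acq <- acquisition_config(echo_times = c(te), noise_sd = noise_sd,
                            n_averages = n_averages, seed = seed)
  sig <- population_to_signals(reps, calib, relax, acq)
  dec <- decompose_echo_trains(sig, method = "single_echo", te = te,
                               relax = relax, correct = TRUE)
  oil_mg <- apply_calibration(calib, pmax(dec$s_oil_v, 0))
  ocr <- compute_ocr(oil_mg, kernel$mass_g)
  list(ocr = ocr,
       summary = c(min = min(ocr), max = max(ocr),
                   mean = mean(ocr), sd = sd(ocr)))
}
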