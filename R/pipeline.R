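#' Forward-simulate calibration standards through the instrument model
#'
#' Converts known oil masses into true signal amplitudes via the inverse of
#' the instrument's calibration line, simulates their echo trains, and
#' records the raw echo amplitude at the production echo time as each
#' standard's signal. Because the standards are measured exactly like the
#' kernels, refitting the calibration on them absorbs the oil-decay factor
#' exp(-te/T2o) of the uncorrected single-echo readout.
#'
#' @param masses Known oil masses of the standards, mg.
#' @param calib True instrument response, a [calibration_model()].
#' @param relax A [relaxation_params()].
#' @param te Production echo time, ms.
#' @param noise_sd,n_averages Acquisition noise settings.
#' @param seed Integer seed.
#' @return Standards data.frame: `standard_id`, `signal_v`, `mass_mg`.
#' @export
simulate_calibration_standards <- function(masses,
                                           calib = calibration_model(361.7, 0),
                                           relax = relaxation_params(),
                                           te = 7.5, noise_sd = 0,
                                           n_averages = 1, seed = NULL) {
  if (length(masses) < 2L) stop_input("at least 2 standards are required")
  records <- data.frame(
    kernel_id = sprintf("S%03d", seq_along(masses)),
    mass_g = 1, oil_mass_mg = masses, water_mass_mg = 0,
    stringsAsFactors = FALSE)
  acq <- acquisition_config(echo_times = c(te), noise_sd = noise_sd,
                            n_averages = n_averages, seed = seed)
  sig <- population_to_signals(records, calib, relax, acq)
  dec <- decompose_echo_trains(sig, method = "single_echo", te = te,
                               relax = relax, correct = FALSE)
  data.frame(standard_id = dec$kernel_id, signal_v = dec$s_oil_v,
             mass_mg = masses, stringsAsFactors = FALSE)
}

#' Fit a calibration from a standards file
#'
#' Reads a standards CSV (`standard_id, signal_v, mass_mg`), fits the linear
#' signal-to-mass calibration, and optionally writes the model JSON.
#'
#' @param standards_csv Path to the standards CSV.
#' @param output_path Optional path for the model JSON.
#' @return The fitted [calibration_model()].
#' @export
run_calibration <- function(standards_csv, output_path = NULL) {
  std <- read_calibration_standards(standards_csv)
  model <- fit_calibration(std$signal_v, std$mass_mg)
  if (!is.null(output_path)) write_calibration_model(model, output_path)
  model
}

#' Read and write kernel-record CSVs
#'
#' Columns: `kernel_id, true_class, mass_g, oil_mass_mg, water_mass_mg,
#' ocr_pct, assigned_class`, plus any extra columns present.
#'
#' @param records Kernel-record data.frame.
#' @param path File path.
#' @return `read_kernel_records()`: a data.frame. `write_kernel_records()`
#'   returns `path` invisibly.
#' @export
write_kernel_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kernel_records
#' @export
read_kernel_records <- function(path) {
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("kernel_id", "true_class", "mass_g", "oil_mass_mg", "ocr_pct")
  if (!all(need %in% names(tbl))) {
    stop_input("malformed kernel-record CSV: expected columns ",
               paste(need, collapse = ", "))
  }
  tbl
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("kernelscreen_config_error", "error", "condition"),
    list(message = sprintf("config field '%s': %s", field, msg), call = NULL)))
}

# Fill and validate a run configuration.
normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) config_error("(root)", "must be a list or JSON path")
  defaults <- list(
    preset = "maize_zd958", n_kernels = 1260L, seed = 1L,
    method = "single_echo", te = 7.5, threshold = 4.25,
    relaxation = list(t2_oil_ms = 100, t2_water_ms = 0.75),
    acquisition = list(echo_times_ms = NULL, noise_sd_v = 0, n_averages = 1),
    output_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- defaults[[nm]][[sub]]
      }
    }
  }
  # calibration defaults: when absent, simulate standards from the nominal
  # instrument response; when present, respect the user's source choice
  if (is.null(config$calibration)) {
    config$calibration <- list(k = 361.7, b = 0, simulate_standards = TRUE)
  }
  if (isTRUE(config$calibration$simulate_standards)) {
    if (is.null(config$calibration$k)) config$calibration$k <- 361.7
    if (is.null(config$calibration$b)) config$calibration$b <- 0
    if (is.null(config$calibration$n_standards)) config$calibration$n_standards <- 10
  }
  if (!is.numeric(config$n_kernels) || config$n_kernels < 1) {
    config_error("n_kernels", "must be a positive integer")
  }
  if (!config$method %in% c("single_echo", "biexp")) {
    config_error("method", "must be 'single_echo' or 'biexp'")
  }
  if (!is.numeric(config$threshold) || config$threshold <= 0) {
    config_error("threshold", "must be positive")
  }
  cal <- config$calibration
  has_fixed <- !is.null(cal$k) && !isTRUE(cal$simulate_standards) &&
    is.null(cal$standards_csv)
  has_sim <- isTRUE(cal$simulate_standards)
  has_csv <- !is.null(cal$standards_csv)
  if (has_sim + has_csv + has_fixed != 1L) {
    config_error("calibration",
                 "exactly one source required: fixed {k,b}, simulate_standards, or standards_csv")
  }
  if (has_csv && !file.exists(cal$standards_csv)) {
    config_error("calibration.standards_csv", paste0("file not found: ", cal$standards_csv))
  }
  if (is.null(config$acquisition$echo_times_ms)) {
    config$acquisition$echo_times_ms <- if (config$method == "single_echo") {
      config$te
    } else {
      sort(unique(c(default_echo_times(), config$te)))
    }
  }
  tryCatch(population_preset(config$preset),
           error = function(e) config_error("preset", conditionMessage(e)))
  config$calibration_source <- if (has_sim) "simulated_standards"
    else if (has_csv) "standards_csv" else "fixed"
  config
}

#' Run the end-to-end screening pipeline
#'
#' Orchestrates a full virtual screening run: generate a labelled kernel
#' population from a preset, forward-simulate its echo trains, establish the
#' signal-to-mass calibration, decompose each train into an oil signal,
#' convert to oil mass and OCR, classify against the threshold, and report
#' empirical and model-based error rates.
#'
#' Calibration sources (exactly one):
#' \describe{
#'   \item{simulated standards (default)}{standards with known masses are
#'     forward-simulated through the same measurement as the kernels and the
#'     calibration refitted, so the uncorrected single-echo readout bias is
#'     absorbed (`calibration = list(k, b, simulate_standards = TRUE)`; k, b
#'     give the true instrument response).}
#'   \item{standards file}{`calibration = list(standards_csv = path)`.}
#'   \item{fixed}{`calibration = list(k, b, simulate_standards = FALSE)`;
#'     the decomposition then applies the exp(te/T2o) correction since no
#'     refit absorbs it.}
#' }
#'
#' A single top-level `seed` is expanded deterministically into per-stage
#' sub-seeds (population, standards, acquisition); identical configs give
#' byte-identical outputs.
#'
#' @param config A configuration list or path to a config JSON. Recognised
#'   fields: `preset`, `n_kernels`, `seed`, `method`, `te`, `threshold`,
#'   `relaxation` (`t2_oil_ms`, `t2_water_ms`), `acquisition`
#'   (`echo_times_ms`, `noise_sd_v`, `n_averages`), `calibration` (above),
#'   `output_dir`.
#' @return An object of class `screening_run`: the classified `records`,
#'   fitted `calibration`, fitted `class_model`, `empirical` report,
#'   `model_rates`, `separability` (OCR and weight), the normalized
#'   `config`, and output `paths` (if `output_dir` was set: `kernels.csv`,
#'   `report.json`, `run.log`).
#' @examples
#' run <- run_screening(list(n_kernels = 200, seed = 7))
#' run$empirical$accuracy
#' @export
run_screening <- function(config = list()) {
  t0 <- proc.time()[["elapsed"]]
  config <- normalize_config(config)
  preset <- population_preset(config$preset)
  relax <- relaxation_params(config$relaxation$t2_oil_ms,
                             config$relaxation$t2_water_ms)
  seed_pop <- substream_seed(config$seed, 1L)
  seed_std <- substream_seed(config$seed, 2L)
  seed_acq <- substream_seed(config$seed, 3L)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  records <- generate_population(preset, config$n_kernels, seed = seed_pop)
  say("generate: %d kernels from preset '%s' (seed %d)",
      nrow(records), preset$name, seed_pop)

  # calibration
  cal_cfg <- config$calibration
  if (config$calibration_source == "fixed") {
    true_calib <- calibration_model(cal_cfg$k,
                                    if (is.null(cal_cfg$b)) 0 else cal_cfg$b)
    calib <- true_calib
    correct <- TRUE
    say("calibrate: fixed k = %g mg/V, b = %g mg (decay correction applied)",
        calib$k, calib$b)
  } else if (config$calibration_source == "standards_csv") {
    calib <- run_calibration(cal_cfg$standards_csv)
    true_calib <- calib
    correct <- FALSE
    say("calibrate: fitted from %s (k = %.4g mg/V, R^2 = %.5f)",
        cal_cfg$standards_csv, calib$k, calib$r_squared)
  } else {
    true_calib <- calibration_model(cal_cfg$k, cal_cfg$b)
    masses <- cal_cfg$standard_masses_mg
    if (is.null(masses)) {
      masses <- seq(5, 50, length.out = cal_cfg$n_standards)
    }
    std <- simulate_calibration_standards(
      masses, calib = true_calib, relax = relax, te = config$te,
      noise_sd = config$acquisition$noise_sd_v,
      n_averages = config$acquisition$n_averages, seed = seed_std)
    calib <- fit_calibration(std$signal_v, std$mass_mg)
    correct <- FALSE
    say("calibrate: %d simulated standards, fitted k = %.6g mg/V (true response %g)",
        length(masses), calib$k, true_calib$k)
  }

  # instrument forward simulation
  acq <- acquisition_config(echo_times = config$acquisition$echo_times_ms,
                            noise_sd = config$acquisition$noise_sd_v,
                            n_averages = config$acquisition$n_averages,
                            seed = seed_acq)
  signals <- population_to_signals(records, calib = true_calib,
                                   relax = relax, acq = acq)
  say("simulate: %d echo-train points (%d per kernel, noise sd %g V)",
      nrow(signals), length(acq$echo_times) + 1L, acq$noise_sd)

  # decomposition and quantification
  dec <- decompose_echo_trains(signals, method = config$method, te = config$te,
                               relax = relax, correct = correct)
  oil_mg <- suppressWarnings(apply_calibration(calib, pmax(dec$s_oil_v, 0)))
  water_mg <- suppressWarnings(apply_calibration(calib, pmax(dec$s_water_v, 0)))
  measured <- records
  measured$true_ocr_pct <- records$ocr_pct
  measured$oil_mass_mg <- oil_mg[match(records$kernel_id, dec$kernel_id)]
  measured$water_mass_mg <- water_mg[match(records$kernel_id, dec$kernel_id)]
  measured$ocr_pct <- compute_ocr(measured$oil_mass_mg, measured$mass_g)
  measured$wcr_pct <- compute_ocr(measured$water_mass_mg, measured$mass_g)
  measured$assigned_class <- classify_ocr(measured$ocr_pct, config$threshold)
  say("decompose: method '%s' at te = %g ms; quantify and classify at %.4g%%",
      config$method, config$te, config$threshold)

  rep <- report_from_records(measured, config$threshold)
  if (!is.null(rep$empirical)) {
    say("report: accuracy %.4g%%, FN %.4g%%, FP %.4g%%",
        rep$empirical$accuracy, rep$empirical$false_negative,
        rep$empirical$false_positive)
  } else {
    say("report: single-class population, no confusion statistics")
  }

  paths <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      kernels = file.path(config$output_dir, "kernels.csv"),
      report = file.path(config$output_dir, "report.json"),
      log = file.path(config$output_dir, "run.log"))
    write_kernel_records(measured, paths$kernels)
    write_screening_report_json(rep, config, calib, paths$report)
    say("done in %.2f s", proc.time()[["elapsed"]] - t0)
    writeLines(log_lines, paths$log)
  }

  structure(list(records = measured, calibration = calib,
                 class_model = rep$class_model, empirical = rep$empirical,
                 model_rates = rep$model_rates, separability = rep$separability,
                 config = config, log = log_lines, paths = paths),
            class = "screening_run")
}

#' @export
print.screening_run <- function(x, ...) {
  cat("Screening run:\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Build the screening report from classified kernel records
#'
#' Computes everything downstream of the kernel-record table: per-class
#' Gaussian fits of the measured OCR and weight, analytic error rates under
#' the fitted model, empirical confusion rates, and the OCR/weight
#' separability lines. Works directly on a kernel-record CSV read back with
#' [read_kernel_records()], so a run can be reproduced from its record file
#' alone.
#'
#' @param records Kernel records with `true_class`, `mass_g`, `ocr_pct`.
#' @param threshold Decision threshold, percent.
#' @return A list: `empirical` ([empirical_error_rates()] output),
#'   `class_model`, `model_rates`, `separability` (with `ocr` and `weight`
#'   elements). For single-class populations only summary statistics of the
#'   OCR are returned (`ocr_summary`).
#' @export
report_from_records <- function(records, threshold = 4.25) {
  two_class <- all(c("haploid", "diploid") %in% records$true_class)
  if (!two_class) {
    return(list(empirical = NULL, class_model = NULL, model_rates = NULL,
                separability = NULL,
                ocr_summary = c(mean = mean(records$ocr_pct),
                                sd = sd(records$ocr_pct))))
  }
  cm <- fit_class_gaussians(records)
  list(empirical = empirical_error_rates(records, threshold),
       class_model = cm,
       model_rates = model_error_rates(cm, threshold),
       separability = list(ocr = separability(cm, "ocr"),
                           weight = separability(cm, "weight")),
       ocr_summary = c(mean = mean(records$ocr_pct), sd = sd(records$ocr_pct)))
}

# Serialize a screening report (no timestamps: reruns are byte-identical).
write_screening_report_json <- function(rep, config, calib, path) {
  out <- list(
    threshold_pct = config$threshold,
    n_kernels = config$n_kernels,
    seed = config$seed,
    preset = config$preset,
    method = config$method,
    calibration = list(k_mg_per_v = calib$k, b_mg = calib$b,
                       r_squared = calib$r_squared,
                       source = config$calibration_source))
  if (!is.null(rep$empirical)) {
    e <- rep$empirical
    cm <- rep$class_model
    m <- rep$model_rates
    out$empirical <- list(
      false_negative_pct = e$false_negative,
      false_positive_pct = e$false_positive,
      total_error_pct = e$total_error,
      weighted_total_error_pct = e$weighted_total_error,
      accuracy_pct = e$accuracy,
      confusion = list(
        haploid_as_haploid = e$counts["haploid", "haploid"],
        haploid_as_diploid = e$counts["haploid", "diploid"],
        diploid_as_haploid = e$counts["diploid", "haploid"],
        diploid_as_diploid = e$counts["diploid", "diploid"]))
    out$model <- list(
      false_negative_pct = m$false_negative,
      false_positive_pct = m$false_positive,
      total_error_pct = m$total_error,
      weighted_total_error_pct = m$weighted_total_error)
    out$class_gaussians <- list(
      haploid = list(ocr_mean = cm$ocr_mean[["haploid"]],
                     ocr_sd = cm$ocr_sd[["haploid"]],
                     weight_mean = cm$weight_mean[["haploid"]],
                     weight_sd = cm$weight_sd[["haploid"]],
                     proportion = cm$proportion[["haploid"]]),
      diploid = list(ocr_mean = cm$ocr_mean[["diploid"]],
                     ocr_sd = cm$ocr_sd[["diploid"]],
                     weight_mean = cm$weight_mean[["diploid"]],
                     weight_sd = cm$weight_sd[["diploid"]],
                     proportion = cm$proportion[["diploid"]]))
    out$separability <- list(
      ocr = rep$separability$ocr,
      weight = rep$separability$weight)
  } else {
    out$ocr_summary <- as.list(rep$ocr_summary)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
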