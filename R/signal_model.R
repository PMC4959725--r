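#' Transverse relaxation parameters of a seed
#'
#' In dried seeds (moisture below about 15%) the two proton pools visible to
#' a low-field spin-echo measurement are oil (slow transverse relaxation,
#' typically longer than 80 ms) and bound water (fast, typically below 1 ms).
#' The defaults, 100 ms for oil and 0.75 ms for bound water, are the line
#' constants used throughout the package.
#'
#' @param t2_oil Transverse relaxation time of the oil pool, ms.
#' @param t2_water Transverse relaxation time of the bound-water pool, ms.
#' @return An object of class `relaxation_params`.
#' @examples
#' relaxation_params()
#' relaxation_params(t2_oil = 90, t2_water = 0.8)
#' @export
relaxation_params <- function(t2_oil = 100, t2_water = 0.75) {
  assert_scalar_number(t2_oil, "t2_oil")
  assert_scalar_number(t2_water, "t2_water")
  if (t2_oil <= 0 || t2_water <= 0) stop_input("relaxation times must be positive")
  if (t2_oil <= t2_water) {
    stop_input("t2_oil must exceed t2_water (oil is the slow component)")
  }
  structure(list(t2_oil = t2_oil, t2_water = t2_water),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("Relaxation parameters: T2(oil) = %g ms, T2(water) = %g ms\n",
              x$t2_oil, x$t2_water))
  invisible(x)
}

#' Oil/water signal composition of a kernel
#'
#' Holds the noise-free signal amplitudes (volts) contributed by the oil and
#' bound-water proton pools. Their sum is the zero-time amplitude measured by
#' the FID.
#'
#' @param oil_amplitude Oil signal amplitude S_o, volts (>= 0).
#' @param water_amplitude Water signal amplitude S_w, volts (>= 0).
#' @return An object of class `kernel_composition` with fields
#'   `oil_amplitude`, `water_amplitude` and `total_amplitude`.
#' @examples
#' kernel_composition(2, 1)$total_amplitude  # 3
#' @export
kernel_composition <- function(oil_amplitude, water_amplitude) {
  assert_scalar_number(oil_amplitude, "oil_amplitude")
  assert_scalar_number(water_amplitude, "water_amplitude")
  if (oil_amplitude < 0 || water_amplitude < 0) {
    stop_input("signal amplitudes must be non-negative")
  }
  structure(list(oil_amplitude = oil_amplitude,
                 water_amplitude = water_amplitude,
                 total_amplitude = oil_amplitude + water_amplitude),
            class = "kernel_composition")
}

#' Default echo-time grid
#'
#' Twelve echo times log-spaced between 0.3 ms and 120 ms, spanning both the
#' bound-water decay (sub-millisecond) and the oil decay (~100 ms). The FID
#' point at t = 0 is always recorded separately by [simulate_echo_train()],
#' so it is not part of the grid.
#'
#' @param n Number of echoes.
#' @param t_min,t_max Grid end points, ms.
#' @return Numeric vector of echo times in ms, strictly increasing.
#' @examples
#' default_echo_times()
#' @export
default_echo_times <- function(n = 12, t_min = 0.3, t_max = 120) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Acquisition settings for a simulated measurement
#'
#' @param echo_times Echo times, ms; strictly positive and strictly
#'   increasing. These are full echo times t as used in the decay model
#'   S(t), not half echo times.
#' @param noise_sd Standard deviation of single-shot additive Gaussian
#'   receiver noise, volts.
#' @param n_averages Number of accumulated scans; recorded amplitudes carry
#'   noise of sd `noise_sd / sqrt(n_averages)`. Production-style settings
#'   use 2 or 4 scans depending on oil content.
#' @param seed Integer seed controlling the noise realization, or NULL to
#'   use the current RNG stream.
#' @param metadata Optional named list of instrument provenance strings
#'   (Larmor frequency, pulse widths, bandwidth, recycle time); never used
#'   numerically.
#' @return An object of class `acquisition_config`.
#' @examples
#' acquisition_config(noise_sd = 0.01, n_averages = 4, seed = 1)
#' @export
acquisition_config <- function(echo_times = default_echo_times(),
                               noise_sd = 0, n_averages = 1,
                               seed = NULL, metadata = NULL) {
  if (!is.numeric(echo_times) || length(echo_times) < 1L) {
    stop_input("echo_times must be a non-empty numeric vector")
  }
  if (any(echo_times <= 0)) stop_input("echo times must be strictly positive")
  if (any(diff(echo_times) <= 0)) stop_input("echo times must be strictly increasing")
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  if (!is.numeric(n_averages) || n_averages < 1 || n_averages != round(n_averages)) {
    stop_input("n_averages must be a positive integer")
  }
  structure(list(echo_times = as.numeric(echo_times), noise_sd = noise_sd,
                 n_averages = as.integer(n_averages), seed = seed,
                 metadata = metadata),
            class = "acquisition_config")
}

#' Bi-exponential spin-echo signal
#'
#' Evaluates the two-pool transverse decay
#' `S(t) = S_o exp(-t / T2o) + S_w exp(-t / T2w)`.
#' At t = 0 this is the total proton amplitude S(0) = S_o + S_w, the
#' quantity measured by the FID.
#'
#' @param composition A [kernel_composition()].
#' @param relax A [relaxation_params()].
#' @param t Time(s) since excitation, ms; non-negative, vectorized.
#' @return Signal amplitude(s) in volts, same length as `t`.
#' @examples
#' comp <- kernel_composition(2, 3)
#' biexp_signal(comp, relaxation_params(), t = 0)    # 5
#' biexp_signal(comp, relaxation_params(), t = 7.5)  # oil term only, nearly
#' @export
biexp_signal <- function(composition, relax, t) {
  stopifnot(inherits(composition, "kernel_composition"),
            inherits(relax, "relaxation_params"))
  if (!is.numeric(t) || any(!is.finite(t))) stop_input("t must be finite numeric")
  if (any(t < 0)) stop_input("t must be non-negative")
  composition$oil_amplitude * exp(-t / relax$t2_oil) +
    composition$water_amplitude * exp(-t / relax$t2_water)
}

#' Residual water signal fraction at a given echo time
#'
#' The fraction of the bound-water amplitude surviving at echo time `te`,
#' `exp(-te / t2_water)`. With the line constants te = 7.5 ms and
#' T2w = 0.75 ms this is exp(-10) ~ 5e-5, which is why a single echo at
#' 7.5 ms isolates the oil signal.
#'
#' @param te Echo time, ms (> 0); vectorized.
#' @param t2_water Bound-water relaxation time, ms (> 0).
#' @return Attenuation fraction in (0, 1).
#' @examples
#' water_attenuation_factor(7.5, 0.75)  # ~5e-5
#' @export
water_attenuation_factor <- function(te, t2_water) {
  if (!is.numeric(te) || any(!is.finite(te)) || any(te <= 0)) {
    stop_input("te must be positive")
  }
  assert_scalar_number(t2_water, "t2_water")
  if (t2_water <= 0) stop_input("t2_water must be positive")
  exp(-te / t2_water)
}

#' Simulate one kernel's echo train
#'
#' Forward-simulates the observables of a single measurement: the FID
#' amplitude (a noisy realization of S(0)) and the echo amplitudes (noisy
#' realizations of S(t) at the acquisition echo times). Noise is additive
#' i.i.d. Gaussian with standard deviation `noise_sd / sqrt(n_averages)` on
#' every recorded amplitude, the usual receiver-noise model for averaged
#' scans.
#'
#' @param composition A [kernel_composition()].
#' @param relax A [relaxation_params()].
#' @param acq An [acquisition_config()].
#' @return An object of class `echo_train` with fields `fid_amplitude`,
#'   `echo_times`, `echo_amplitudes` and `noise_sd` (the effective per-point
#'   noise sd after averaging).
#' @examples
#' tr <- simulate_echo_train(kernel_composition(2, 1), relaxation_params(),
#'                           acquisition_config(noise_sd = 0.01, seed = 7))
#' tr$fid_amplitude
#' @export
simulate_echo_train <- function(composition, relax, acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  clean <- biexp_signal(composition, relax, c(0, acq$echo_times))
  eff_sd <- acq$noise_sd / sqrt(acq$n_averages)
  noisy <- with_seed(acq$seed, clean + rnorm(length(clean), 0, eff_sd))
  echo_train(fid_amplitude = noisy[1L],
             echo_times = acq$echo_times,
             echo_amplitudes = noisy[-1L],
             noise_sd = eff_sd)
}

#' Construct an echo train
#'
#' Container for one kernel's recorded NMR observables: the FID amplitude
#' (t = 0) and the echo amplitudes on their echo-time grid.
#'
#' @param fid_amplitude FID amplitude, volts.
#' @param echo_times Echo times, ms, strictly increasing and positive.
#' @param echo_amplitudes Echo amplitudes, volts, same length as
#'   `echo_times`.
#' @param noise_sd Effective per-point noise sd, volts (metadata).
#' @return An object of class `echo_train`.
#' @export
echo_train <- function(fid_amplitude, echo_times, echo_amplitudes,
                       noise_sd = NA_real_) {
  if (length(echo_times) != length(echo_amplitudes)) {
    stop_input("echo_times and echo_amplitudes must have equal length")
  }
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop_input("echo times must be positive and strictly increasing")
  }
  structure(list(fid_amplitude = fid_amplitude,
                 echo_times = as.numeric(echo_times),
                 echo_amplitudes = as.numeric(echo_amplitudes),
                 noise_sd = noise_sd),
            class = "echo_train")
}

#' @export
print.echo_train <- function(x, ...) {
  cat(sprintf("Echo train: FID %.4g V, %d echoes over %.3g-%.3g ms (noise sd %.3g V)\n",
              x$fid_amplitude, length(x$echo_times),
              min(x$echo_times), max(x$echo_times), x$noise_sd))
  invisible(x)
}

#' Convert echo trains to/from the long table form
#'
#' The on-disk form of a set of echo trains is a long table with columns
#' `kernel_id`, `time_ms`, `amplitude_v`, where the FID amplitude appears as
#' the `time_ms = 0` row of each kernel.
#'
#' @param trains Named list of `echo_train` objects (names are kernel ids).
#' @return A data.frame with columns `kernel_id`, `time_ms`, `amplitude_v`.
#' @seealso [read_echo_trains()], [write_echo_trains()]
#' @export
echo_trains_to_table <- function(trains) {
  stopifnot(is.list(trains), length(trains) > 0, !is.null(names(trains)))
  do.call(rbind, lapply(names(trains), function(id) {
    tr <- trains[[id]]
    data.frame(kernel_id = id,
               time_ms = c(0, tr$echo_times),
               amplitude_v = c(tr$fid_amplitude, tr$echo_amplitudes),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname echo_trains_to_table
#' @param tbl A data.frame in the long echo-train form.
#' @export
table_to_echo_trains <- function(tbl) {
  need <- c("kernel_id", "time_ms", "amplitude_v")
  if (!all(need %in% names(tbl))) {
    stop_input("echo-train table needs columns ", paste(need, collapse = ", "))
  }
  ids <- unique(tbl$kernel_id)
  trains <- lapply(ids, function(id) {
    d <- tbl[tbl$kernel_id == id, , drop = FALSE]
    d <- d[order(d$time_ms), , drop = FALSE]
    if (d$time_ms[1L] != 0) stop_input("kernel ", id, " has no FID (time_ms = 0) row")
    echo_train(fid_amplitude = d$amplitude_v[1L],
               echo_times = d$time_ms[-1L],
               echo_amplitudes = d$amplitude_v[-1L])
  })
  names(trains) <- ids
  trains
}

#' Read or write an echo-train CSV
#'
#' @param path File path of a CSV with header
#'   `kernel_id,time_ms,amplitude_v` (UTF-8, '.' decimal separator).
#' @return `read_echo_trains()` returns the long-form data.frame;
#'   `write_echo_trains()` returns `path` invisibly.
#' @export
read_echo_trains <- function(path) {
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("kernel_id", "time_ms", "amplitude_v")
  if (!all(need %in% names(tbl))) {
    stop_input("malformed echo-train CSV: expected columns ",
               paste(need, collapse = ", "))
  }
  tbl
}

#' @rdname read_echo_trains
#' @param tbl Long-form echo-train table (see [echo_trains_to_table()]).
#' @export
write_echo_trains <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
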