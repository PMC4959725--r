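#' Fit the linear signal-to-mass calibration
#'
#' Ordinary least-squares fit of the calibration line `A = k S + b` that
#' converts an NMR signal amplitude S (volts) into a fluid mass A (mg). The
#' regression is of mass on signal, matching the direction in which the
#' model is applied. A small background signal makes the intercept b
#' generally non-zero.
#'
#' @param signals Signal amplitudes of the calibration standards, volts.
#' @param masses Known oil (or water) masses of the standards, mg.
#' @return An object of class `calibration_model` with fields `k` (mg/V),
#'   `b` (mg), `r_squared` and `n_points`.
#' @examples
#' fit_calibration(c(1, 2), c(461.7, 823.4))  # k = 361.7, b = 100
#' @export
fit_calibration <- function(signals, masses) {
  if (!is.numeric(signals) || !is.numeric(masses)) {
    stop_input("signals and masses must be numeric")
  }
  if (length(signals) != length(masses)) {
    stop_input("signals and masses must have equal length")
  }
  if (length(signals) < 2L) stop_input("at least 2 calibration points are required")
  if (var(signals) == 0) stop_input("calibration signals have zero variance")
  fit <- lm(masses ~ signals)
  ss_tot <- sum((masses - mean(masses))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(resid(fit)^2) / ss_tot
  r2 <- min(max(r2, 0), 1)  # guard float round-off at the boundaries
  calibration_model(k = coef(fit)[[2L]], b = coef(fit)[[1L]],
                    r_squared = r2, n_points = length(signals))
}

#' Construct a calibration model
#'
#' @param k Calibration constant, mg per volt (> 0 for a physical
#'   calibration).
#' @param b Background/intercept, mg.
#' @param r_squared Coefficient of determination of the fit, if known.
#' @param n_points Number of standards used, if known.
#' @param fitted_at Optional provenance timestamp string (calibrations are
#'   refreshed on a schedule in production; the schedule itself is out of
#'   scope here).
#' @return An object of class `calibration_model`.
#' @examples
#' calibration_model(k = 361.7, b = 0)
#' @export
calibration_model <- function(k, b = 0, r_squared = NA_real_,
                              n_points = NA_integer_, fitted_at = NULL) {
  assert_scalar_number(k, "k")
  assert_scalar_number(b, "b")
  if (k <= 0) stop_input("calibration constant k must be positive")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop_input("r_squared must lie in [0, 1]")
  }
  structure(list(k = k, b = b, r_squared = r_squared,
                 n_points = n_points, fitted_at = fitted_at),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: A = %.4g mg/V * S + %.4g mg (R^2 = %s, n = %s)\n",
              x$k, x$b,
              if (is.na(x$r_squared)) "NA" else sprintf("%.5f", x$r_squared),
              x$n_points))
  invisible(x)
}

#' Convert a signal amplitude to a mass
#'
#' Applies `A = k S + b`. A small negative result (possible near S = 0 with
#' a negative intercept) is clipped to zero with a warning, since a fluid
#' mass cannot be negative.
#'
#' @param model A [calibration_model()].
#' @param signal Signal amplitude(s), volts (>= 0).
#' @return Mass(es) in mg.
#' @examples
#' apply_calibration(calibration_model(361.7, 0), 0.1)  # 36.17 mg
#' @export
apply_calibration <- function(model, signal) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(signal < 0)) stop_input("signal must be non-negative")
  a <- model$k * signal + model$b
  neg <- a < 0
  if (any(neg)) {
    warning("negative calibrated mass clipped to 0")
    a[neg] <- 0
  }
  a
}

#' Read calibration standards / write a calibration model
#'
#' Standards CSV columns: `standard_id, signal_v, mass_mg`. The model JSON
#' stores `k_mg_per_v`, `b_mg`, `r_squared`, `n_points`.
#'
#' @param path File path.
#' @return `read_calibration_standards()`: a data.frame.
#'   `write_calibration_model()` returns `path` invisibly;
#'   `read_calibration_model()` returns a [calibration_model()].
#' @export
read_calibration_standards <- function(path) {
  tbl <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop_input("cannot parse standards CSV: ",
                                                 conditionMessage(e)))
  need <- c("standard_id", "signal_v", "mass_mg")
  if (!all(need %in% names(tbl)) || nrow(tbl) == 0) {
    stop_input("malformed standards CSV: expected non-empty columns ",
               paste(need, collapse = ", "))
  }
  tbl
}

#' @rdname read_calibration_standards
#' @param model A [calibration_model()].
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    list(k_mg_per_v = model$k, b_mg = model$b,
         r_squared = model$r_squared, n_points = model$n_points),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname read_calibration_standards
#' @export
read_calibration_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(k = x$k_mg_per_v, b = x$b_mg,
                    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
                    n_points = if (is.null(x$n_points)) NA_integer_ else x$n_points)
}
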