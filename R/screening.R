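#' Oil content ratio (OCR)
#'
#' OCR is the oil mass divided by the total kernel mass, in percent, with
#' both masses expressed in the same unit before taking the ratio. Oil mass
#' comes from the calibrated NMR signal (mg); kernel mass from the weighing
#' sensor (g). WCR, the water content ratio, is computed the same way from
#' the water mass.
#'
#' @param oil_mass Oil mass, mg (vectorized).
#' @param mass Kernel mass, g (> 0, vectorized).
#' @return OCR in percent.
#' @examples
#' compute_ocr(28, 0.42)  # 6.67%
#' @export
compute_ocr <- function(oil_mass, mass) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop_input("mass must be positive")
  if (any(oil_mass < 0)) stop_input("oil_mass must be non-negative")
  100 * (oil_mass / 1000) / mass
}

#' Two-class Gaussian population model
#'
#' Per-class Gaussian parameters for OCR (percent) and kernel weight (g),
#' plus class proportions. The same object drives population simulation and
#' threshold-classification error analysis. By convention the haploid class
#' has the lower OCR mean: in high-oil induction crosses the inducer raises
#' the oil content of diploid kernels.
#'
#' @param ocr_mean,ocr_sd Named numeric vectors with elements `haploid` and
#'   `diploid`: class OCR means and sds, percent.
#' @param weight_mean,weight_sd Named numeric vectors as above: class kernel
#'   weight means and sds, g (optional, NA if unknown).
#' @param proportion Named class proportions in (0, 1), summing to 1.
#' @return An object of class `class_model`.
#' @examples
#' maize <- class_model(
#'   ocr_mean = c(haploid = 3.6, diploid = 5.5),
#'   ocr_sd = c(haploid = 0.47, diploid = 0.52),
#'   weight_mean = c(haploid = 0.40, diploid = 0.43),
#'   weight_sd = c(haploid = 0.049, diploid = 0.035))
#' @export
class_model <- function(ocr_mean, ocr_sd,
                        weight_mean = c(haploid = NA_real_, diploid = NA_real_),
                        weight_sd = c(haploid = NA_real_, diploid = NA_real_),
                        proportion = c(haploid = 0.5, diploid = 0.5)) {
  cls <- c("haploid", "diploid")
  for (nm in c("ocr_mean", "ocr_sd", "weight_mean", "weight_sd", "proportion")) {
    v <- get(nm)
    if (!all(cls %in% names(v))) stop_input(nm, " needs elements 'haploid' and 'diploid'")
  }
  ocr_mean <- ocr_mean[cls]; ocr_sd <- ocr_sd[cls]
  weight_mean <- weight_mean[cls]; weight_sd <- weight_sd[cls]
  proportion <- proportion[cls]
  if (any(ocr_sd <= 0, na.rm = TRUE) || any(weight_sd <= 0, na.rm = TRUE)) {
    stop_input("class standard deviations must be positive")
  }
  if (any(proportion <= 0) || any(proportion >= 1) ||
      abs(sum(proportion) - 1) > 1e-8) {
    stop_input("proportions must lie in (0,1) and sum to 1")
  }
  if (ocr_mean[["haploid"]] >= ocr_mean[["diploid"]]) {
    stop_input("labeling convention violated: haploid OCR mean must be below diploid")
  }
  structure(list(ocr_mean = ocr_mean, ocr_sd = ocr_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 proportion = proportion),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat("Two-class Gaussian model:\n")
  for (cl in c("haploid", "diploid")) {
    cat(sprintf("  %-8s OCR %.3g%% (sd %.3g), weight %.3g g (sd %.3g), proportion %.3g\n",
                cl, x$ocr_mean[[cl]], x$ocr_sd[[cl]],
                x$weight_mean[[cl]], x$weight_sd[[cl]], x$proportion[[cl]]))
  }
  invisible(x)
}

#' Fit per-class Gaussians to labelled kernel records
#'
#' Sample mean and standard deviation of OCR and weight per class, with
#' class proportions taken from the label counts.
#'
#' @param records Kernel-record data.frame with columns `true_class`
#'   (values `haploid`/`diploid`), `ocr_pct` and `mass_g`.
#' @return A [class_model()].
#' @export
fit_class_gaussians <- function(records) {
  need <- c("true_class", "ocr_pct", "mass_g")
  if (!all(need %in% names(records))) {
    stop_input("records need columns ", paste(need, collapse = ", "))
  }
  cls <- c("haploid", "diploid")
  if (!all(cls %in% records$true_class)) {
    stop_input("both haploid and diploid records are required")
  }
  stat <- function(cl, col) {
    v <- records[[col]][records$true_class == cl]
    if (length(v) < 2L) stop_input("at least 2 records per class are required")
    s <- sd(v)
    if (s == 0) stop_input("degenerate class '", cl, "': zero variance in ", col)
    c(mean(v), s)
  }
  ocr <- vapply(cls, stat, numeric(2), col = "ocr_pct")
  wgt <- vapply(cls, stat, numeric(2), col = "mass_g")
  n <- vapply(cls, function(cl) sum(records$true_class == cl), numeric(1))
  class_model(ocr_mean = ocr[1L, ], ocr_sd = ocr[2L, ],
              weight_mean = wgt[1L, ], weight_sd = wgt[2L, ],
              proportion = n / sum(n))
}

#' Fit a two-component Gaussian mixture to unlabelled OCR values
#'
#' Expectation-maximisation fit of a two-component univariate Gaussian
#' mixture with unequal variances, for populations where class labels are
#' not available. The lower-mean component is reported as haploid. The fit
#' is deterministic: initialisation uses model-based hierarchical
#' clustering, not random starts.
#'
#' @param ocrs Unlabelled OCR values, percent (n >= 20).
#' @return A [class_model()] with the OCR fields and proportions filled
#'   (weight fields NA) and an attribute `converged`.
#' @export
fit_mixture <- function(ocrs) {
  if (!is.numeric(ocrs) || length(ocrs) < 20L) {
    stop_input("at least 20 OCR values are required for a mixture fit")
  }
  if (var(ocrs) == 0) stop_input("degenerate input: all OCR values identical")
  fit <- tryCatch(
    mclust::Mclust(ocrs, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop_input("mixture EM failed to produce a fit")
  }
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, 2L)  # equal-variance fallback
  pro <- fit$parameters$pro
  o <- order(mu)
  cls <- c("haploid", "diploid")
  out <- class_model(
    ocr_mean = setNames(mu[o], cls),
    ocr_sd = setNames(sig[o], cls),
    proportion = setNames(pro[o], cls))
  attr(out, "converged") <- TRUE
  attr(out, "loglik") <- fit$loglik
  out
}

#' Threshold classification of kernels by OCR
#'
#' A kernel with OCR below the threshold is called haploid, otherwise
#' diploid. The boundary value itself is called diploid: for haploid
#' selection this is the conservative convention (it never adds false
#' haploid calls).
#'
#' @param ocr OCR value(s), percent.
#' @param threshold Decision threshold, percent.
#' @return Character vector of `"haploid"`/`"diploid"`.
#' @examples
#' classify_ocr(c(3.6, 5.5, 4.25), threshold = 4.25)
#' @export
classify_ocr <- function(ocr, threshold = 4.25) {
  assert_scalar_number(threshold, "threshold")
  ifelse(ocr < threshold, "haploid", "diploid")
}

#' Analytic error rates of threshold screening under a Gaussian class model
#'
#' Given per-class Gaussian OCR distributions and a threshold T, the false
#' negative probability (a diploid mis-called haploid) is
#' `Phi((T - mu_d)/sigma_d)` and the false positive probability (a haploid
#' mis-called diploid) is `1 - Phi((T - mu_h)/sigma_h)`. The total error is
#' reported both as the plain sum FN + FP of the class-conditional rates and
#' as the proportion-weighted mixture error.
#'
#' @param model A [class_model()].
#' @param threshold Decision threshold, percent.
#' @return An object of class `error_rates`: `threshold`, `false_negative`,
#'   `false_positive`, `total_error` (FN + FP), `weighted_total_error`
#'   (proportion-weighted), all in percent.
#' @examples
#' m <- class_model(ocr_mean = c(haploid = 3.6, diploid = 5.5),
#'                  ocr_sd = c(haploid = 0.47, diploid = 0.52))
#' model_error_rates(m, 4.25)
#' @export
model_error_rates <- function(model, threshold = 4.25) {
  stopifnot(inherits(model, "class_model"))
  assert_scalar_number(threshold, "threshold")
  fn <- 100 * pnorm((threshold - model$ocr_mean[["diploid"]]) /
                      model$ocr_sd[["diploid"]])
  fp <- 100 * (1 - pnorm((threshold - model$ocr_mean[["haploid"]]) /
                           model$ocr_sd[["haploid"]]))
  structure(list(threshold = threshold,
                 false_negative = fn, false_positive = fp,
                 total_error = fn + fp,
                 weighted_total_error = model$proportion[["diploid"]] * fn +
                   model$proportion[["haploid"]] * fp),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf(
    "Threshold %.4g%%: FN %.3g%%, FP %.3g%%, total %.3g%% (weighted %.3g%%)\n",
    x$threshold, x$false_negative, x$false_positive,
    x$total_error, x$weighted_total_error))
  invisible(x)
}

#' Empirical error rates from labelled records
#'
#' Classifies every record by its OCR and tabulates the confusion counts
#' against the true labels. Rates are class-conditional percentages to match
#' the analytic convention of [model_error_rates()].
#'
#' @param records Kernel-record data.frame with `true_class` and `ocr_pct`.
#' @param threshold Decision threshold, percent.
#' @return An object of class `screening_report`: threshold, rates (percent),
#'   2x2 confusion `counts` (true class x assigned class), and overall
#'   `accuracy` (percent of kernels correctly classified).
#' @export
empirical_error_rates <- function(records, threshold = 4.25) {
  need <- c("true_class", "ocr_pct")
  if (!all(need %in% names(records))) {
    stop_input("records need columns ", paste(need, collapse = ", "))
  }
  cls <- c("haploid", "diploid")
  if (!all(records$true_class %in% cls)) {
    stop_input("true_class must be 'haploid' or 'diploid'")
  }
  assigned <- classify_ocr(records$ocr_pct, threshold)
  counts <- table(factor(records$true_class, levels = cls),
                  factor(assigned, levels = cls))
  dimnames(counts) <- list(true = cls, assigned = cls)
  n_h <- sum(counts["haploid", ])
  n_d <- sum(counts["diploid", ])
  if (n_h == 0 || n_d == 0) stop_input("both classes must be present")
  fn <- 100 * counts["diploid", "haploid"] / n_d
  fp <- 100 * counts["haploid", "diploid"] / n_h
  structure(list(threshold = threshold,
                 false_negative = fn, false_positive = fp,
                 total_error = fn + fp,
                 weighted_total_error = 100 *
                   (counts["diploid", "haploid"] + counts["haploid", "diploid"]) /
                   sum(counts),
                 counts = counts,
                 accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = c("screening_report", "error_rates"))
}

#' @export
print.screening_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("Accuracy %.4g%% over %d kernels\n", x$accuracy, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Screening accuracy from selection counts
#'
#' The accuracy of a haploid-selection run: the percentage of kernels
#' selected as haploid that are truly haploid, reported to 2 decimals.
#'
#' @param identified Number of kernels the screen called haploid (> 0).
#' @param true_positive Number of those that are truly haploid.
#' @return Accuracy in percent, rounded to 2 decimals.
#' @examples
#' accuracy_from_counts(321, 308)  # 95.95
#' @export
accuracy_from_counts <- function(identified, true_positive) {
  if (any(identified <= 0)) stop_input("identified count must be positive")
  if (any(true_positive < 0) || any(true_positive > identified)) {
    stop_input("true_positive must lie in [0, identified]")
  }
  round(100 * true_positive / identified, 2)
}

#' Class separability of a variable
#'
#' Compares the between-class mean difference |E2 - E1| to the average
#' distribution width (sigma1 + sigma2)/2. A variable separates the classes
#' when the mean difference exceeds the average width; kernel weight fails
#' this test while OCR passes it, which is why the weight sensor alone
#' cannot sort kernels but the weight-normalised oil signal can.
#'
#' @param model A [class_model()].
#' @param variable `"ocr"` or `"weight"`.
#' @return A list: `mean_difference`, `half_width_sum`, `separable`.
#' @export
separability <- function(model, variable = c("ocr", "weight")) {
  stopifnot(inherits(model, "class_model"))
  variable <- match.arg(variable)
  mu <- if (variable == "ocr") model$ocr_mean else model$weight_mean
  sig <- if (variable == "ocr") model$ocr_sd else model$weight_sd
  if (any(is.na(mu)) || any(is.na(sig))) {
    stop_input("model has no ", variable, " parameters")
  }
  d <- abs(mu[["diploid"]] - mu[["haploid"]])
  hw <- (sig[["haploid"]] + sig[["diploid"]]) / 2
  list(mean_difference = d, half_width_sum = hw, separable = d > hw)
}

#' Grid-search threshold minimising the summed error rate
#'
#' Scans thresholds on a fixed-step grid between the two class means of the
#' chosen variable and returns the one minimising FN + FP (class-conditional
#' empirical rates). Provided for analysis; the screening threshold itself
#' is an input parameter, not derived.
#'
#' @param values Per-kernel values of the screening variable.
#' @param true_class Labels, `"haploid"`/`"diploid"`.
#' @param step Grid step in the variable's unit.
#' @return A list: `threshold`, `false_negative`, `false_positive`,
#'   `total_error` (percent).
#' @export
optimize_threshold <- function(values, true_class, step = 0.01) {
  h <- values[true_class == "haploid"]
  d <- values[true_class == "diploid"]
  if (length(h) == 0 || length(d) == 0) stop_input("both classes must be present")
  grid <- seq(min(values), max(values) + step, by = step)
  fn <- vapply(grid, function(thr) 100 * mean(d < thr), numeric(1))
  fp <- vapply(grid, function(thr) 100 * mean(h >= thr), numeric(1))
  i <- which.min(fn + fp)
  list(threshold = grid[i], false_negative = fn[i], false_positive = fp[i],
       total_error = fn[i] + fp[i])
}

#' Compare OCR-based screening with oil-mass-only screening
#'
#' Weight varies between kernels, so an absolute oil-mass threshold mixes
#' weight variation into the decision. This compares the confusion rates of
#' an oil-mass-only threshold against the OCR threshold, including the
#' contamination of the selected haploid pool (the fraction of kernels
#' called haploid that are truly diploid) and its ratio between the two
#' classifiers.
#'
#' @param records Labelled kernel records with `true_class`, `oil_mass_mg`
#'   and `ocr_pct`.
#' @param oil_threshold Oil-mass decision threshold, mg (oil mass below the
#'   threshold is called haploid).
#' @param ocr_threshold OCR decision threshold, percent.
#' @return A list with per-classifier sub-lists (`ocr`, `oil_only`), each
#'   holding `false_negative`, `false_positive`, `total_error`,
#'   `pool_contamination` (percent), plus `contamination_ratio`
#'   (oil-only / OCR; Inf when the OCR pool is clean).
#' @export
ocr_vs_oil_only <- function(records, oil_threshold, ocr_threshold = 4.25) {
  need <- c("true_class", "oil_mass_mg", "ocr_pct")
  if (!all(need %in% names(records))) {
    stop_input("records need columns ", paste(need, collapse = ", "))
  }
  if (!any(records$true_class == "haploid")) stop_input("no haploid records")
  if (!any(records$true_class == "diploid")) stop_input("no diploid records")
  rates <- function(called_haploid) {
    h <- records$true_class == "haploid"
    fn <- 100 * mean(called_haploid[!h])
    fp <- 100 * mean(!called_haploid[h])
    pool <- sum(called_haploid)
    cont <- if (pool == 0) NA_real_ else 100 * sum(called_haploid & !h) / pool
    list(false_negative = fn, false_positive = fp, total_error = fn + fp,
         pool_contamination = cont)
  }
  ocr_r <- rates(records$ocr_pct < ocr_threshold)
  oil_r <- rates(records$oil_mass_mg < oil_threshold)
  ratio <- if (is.na(ocr_r$pool_contamination) || is.na(oil_r$pool_contamination)) {
    NA_real_
  } else if (ocr_r$pool_contamination == 0) {
    if (oil_r$pool_contamination == 0) 1 else Inf
  } else {
    oil_r$pool_contamination / ocr_r$pool_contamination
  }
  list(ocr = ocr_r, oil_only = oil_r, contamination_ratio = ratio)
}

#' Paired comparison of replicate measurements
#'
#' Summary of the paired differences y2 - y1 between two replicate
#' measurement series (e.g. the same kernels measured at two acquisition
#' times): mean, sd, standard error, paired t statistic with its degrees of
#' freedom and two-tailed p-value, plus the Pearson correlation of the two
#' series.
#'
#' @param y1,y2 Equal-length paired measurement vectors (n >= 2).
#' @return A list: `mean_diff`, `sd_diff`, `se`, `t_statistic`, `df`,
#'   `p_value`, `correlation`.
#' @examples
#' compare_replicates(c(6.5, 6.7, 6.9), c(6.6, 6.6, 7.0))
#' @export
compare_replicates <- function(y1, y2) {
  if (length(y1) != length(y2)) stop_input("y1 and y2 must have equal length")
  if (length(y1) < 2L) stop_input("at least 2 pairs are required")
  d <- y2 - y1
  m <- mean(d)
  s <- sd(d)
  se <- s / sqrt(length(d))
  tval <- if (se == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else m / se
  df <- length(d) - 1L
  list(mean_diff = m, sd_diff = s, se = se, t_statistic = tval, df = df,
       p_value = 2 * pt(-abs(tval), df),
       correlation = if (sd(y1) == 0 || sd(y2) == 0) {
         if (all(d == d[1L])) 1 else NA_real_
       } else cor(y1, y2))
}
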