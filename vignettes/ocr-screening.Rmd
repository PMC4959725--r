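---
title: "Oil-content-ratio screening of seeds: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oil-content-ratio screening of seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelscreen)
```

## The measurement model

`kernelscreen` is a software twin of a single-kernel NMR screening
instrument. A dried seed (moisture below roughly 15%) contains two proton
pools a low-field spin-echo measurement can see: oil, with a long
transverse relaxation time, and bound water, with a very short one. The
echo amplitude therefore decays bi-exponentially,

$$S(t) = S_o\, e^{-t/T_{2o}} + S_w\, e^{-t/T_{2w}},$$

with $S(0) = S_o + S_w$ measured directly by the FID. The package fixes the
line constants at $T_{2o} = 100$ ms and $T_{2w} = 0.75$ ms; they are
treated as properties of the instrument and seed type, identical across
kernels, and are exposed through `relaxation_params()`.

All times are **full echo times** $t$, the variable the decay law is
written in. Amplitudes are in volts and masses in mg (kernel mass in g);
instrument settings that do not enter the computation (Larmor frequency,
pulse widths, bandwidth, recycle time) can be carried as provenance strings
in `acquisition_config()` but are never used numerically.

### Why a single echo at 7.5 ms suffices

At $t = 7.5$ ms the bound-water term has decayed by
$e^{-10} \approx 4.5\times10^{-5}$ (`water_attenuation_factor(7.5, 0.75)`),
so the echo contains only oil signal up to that leak:
$S(TE) = S_o e^{-TE/T_{2o}} \approx 0.928\, S_o$. The production
decomposition (`oil_amplitude_single_echo()`, `correct = FALSE`) returns
this raw amplitude. The multiplicative bias 0.928 is identical for every
kernel sharing $T_{2o}$, so it cancels when the signal-to-mass calibration
is fitted on standards measured at the same echo time — the default
configuration of `run_screening()` does exactly that, and the fitted slope
comes out as $k/0.928$. With `correct = TRUE` the decay factor is divided
out instead, which is the right choice when a fixed externally-supplied
calibration is used. Both routes agree to better than $10^{-3}$ relative on
noiseless data; the residual difference is the water leak, which also sets
the accuracy floor (~$5\times10^{-4}$ OCR percentage points) of the
otherwise exact noiseless pipeline inversion.

### Full bi-exponential fitting

`fit_biexponential()` estimates all four parameters $(S_o, T_{2o}, S_w,
T_{2w})$ by bound-constrained Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), including the FID as the $t=0$ point. Starting
values come from a deterministic two-stage log-linear fit: the slow
component is fitted on the tail ($t$ beyond ten times the earliest echo
time), subtracted, and the fast component fitted on the early points.
There are no random restarts; the fit is reproducible by construction.
Convergence tolerance is $10^{-10}$ on the cost with at most 500
iterations. If the two fitted relaxation times differ by less than 5% the
components are declared non-separable and the fit is flagged
`converged = FALSE`. The default acquisition grid (`default_echo_times()`)
is 12 echoes log-spaced from 0.3 ms to 120 ms — chosen to sample both decay
regimes, roughly three points per decade — plus the FID; the grid is fully
configurable and any grid spanning at least a decade with five or more
echoes is accepted.

## Noise model

The only stochastic element of the instrument model is additive i.i.d.
Gaussian receiver noise on every recorded amplitude, with standard
deviation `noise_sd / sqrt(n_averages)`; accumulating 2 or 4 scans is the
instrument's own trade between speed and precision. This is the standard
relaxometry assumption; it deliberately omits multiplicative gain drift,
temperature effects and $B_1$ inhomogeneity. Receiver noise of a few mV on
signals of order 0.1–0.3 V reproduces repeat-measurement OCR scatter of
roughly 0.2 percentage points at an OCR of 6.7%, which is the plausible
reading of the bench stability test (a printed sd of 0.7 percentage points
is inconsistent with the printed 6.5–7.2 range over 50 repeats and is not
used).

## Calibration

`fit_calibration()` is an ordinary least-squares fit of mass on signal,
$A = kS + b$; the reference response used throughout the examples is
$k = 361.7$ mg/V with a small background $b$. The regression direction
matches how the model is applied (signal in, mass out), and no weighting is
used since no error model for the standards is assumed. Re-calibration
scheduling is an operations concern and out of scope; `calibration_model()`
carries an optional provenance timestamp only.

## Screening statistics

OCR is `compute_ocr(oil_mass_mg, mass_g)` = oil mass over kernel mass in
percent, with the unit conversion explicit in the function. Classification
is a fixed threshold (default 4.25%): OCR below it is called haploid, at or
above it diploid. The boundary goes to diploid — the conservative choice
for haploid selection, since it never adds false haploid calls. The
threshold is an *input*: for the reference class parameters neither the
equal-density crossing (≈ 4.5%) nor the minimum of FN + FP reproduces
4.25 exactly, so the package never derives it; `optimize_threshold()` is
provided for analysis but is not used to set defaults.

Error rates come in two flavours, both exposed:

* `model_error_rates()` — analytic, from per-class Gaussians:
  $FN = \Phi((T-\mu_d)/\sigma_d)$, $FP = 1-\Phi((T-\mu_h)/\sigma_h)$.
  With the reference field parameters (diploid $N(5.5, 0.52)$, threshold
  4.25) the false-negative rate is 0.81%, matching the reported 0.83%
  within rounding of two-decimal class parameters. The analytic false
  positive from $N(3.6, 0.47)$ is 8.33%; a reported value of 7.27% cannot
  be recovered from those printed parameters, so both computations are
  available for comparison.
* `empirical_error_rates()` — class-conditional confusion rates from
  labelled records.

The total error is reported both as the plain sum FN + FP (the convention
used in the original field analysis, where 0.83 + 7.27 ≈ 8.2) and as the
proportion-weighted mixture error, which is the probability a random kernel
is mis-sorted; the additive convention is unusual, hence both.

Class models are fitted either from labels (`fit_class_gaussians()`,
sample moments per class) or without labels (`fit_mixture()`, a
two-component unequal-variance Gaussian mixture fitted by EM via *mclust*
with deterministic hierarchical initialisation). The lower-mean component
is always reported as haploid, following the biology: a high-oil inducer
raises the oil content of diploid kernels. `separability()` compares the
class mean gap to the average distribution width, the diagnostic that shows
weight alone (gap 0.03 g vs width 0.04 g) cannot sort kernels while OCR
(gap 1.9 vs width 0.5 percentage points) can.

## The synthetic-data generator

`generate_population()` inverts the observation that field OCR and weight
histograms are Gaussian per class: class by Bernoulli(haploid fraction),
OCR and weight by per-class truncated Gaussians (weight > 0.05 g, OCR > 0 —
bounds many standard deviations from the means, so class moments shift by
far less than 0.1%), WCR by a common Gaussian. OCR and weight are sampled
independently within a class; no correlation structure is asserted because
none is known. The water model defaults to WCR $N(10, 1)$% — dried-seed
moisture is only known to be below about 15%, so a mid-range mean with
modest spread was chosen once as a realistic default and is configurable in
every preset.

Bundled presets: `maize_zd958` (haploid OCR $N(3.6, 0.47)$, diploid
$N(5.5, 0.52)$; weights $N(0.40, 0.049)$ / $N(0.43, 0.035)$ g; balanced
classes for testing), `maize_zd958_induction` (same Gaussians at a
realistic haploid fraction 0.086 = 321/3742), `zheng58_cauhoi` (diploid
OCR centred on the 6.7%/0.42 g stability-test kernel; the haploid class
and all sds are synthetic stand-ins, marked as such), and the single-class
soybean presets `soybean_feng1` / `soybean_feng2`. Feeder pick-up success
rates (0.92 round maize, 0.90 flat maize, 0.974 soybean, 0.98 other round
seeds) are available through `feeder_model()` / `simulate_feeder()` as
plain Bernoulli streams.

What the generator does *not* emulate: kernel-to-kernel variation in
relaxation times, correlated OCR/weight, non-Gaussian tails, feeder
vibration coupling, temperature drift. Tests passing on synthetic
populations therefore validate the statistical pipeline — decomposition,
calibration algebra, threshold arithmetic, error-rate estimation — not the
biology or the hardware.

## The pipeline

`run_screening()` chains generate → simulate → calibrate → decompose →
quantify → classify → report. One top-level seed is expanded into
deterministic per-stage sub-seeds (a Lehmer step keeps them valid 32-bit
seeds), so identical configurations give byte-identical record CSVs and
report JSONs; timings go to the log file only. The report can be rebuilt
from the kernel-record CSV alone (`report_from_records()`), so intermediate
files are disposable. Exactly one calibration source must be configured:
simulated standards (default; absorbs the single-echo bias), a standards
CSV, or a fixed $(k, b)$ pair (which switches the decomposition to the
corrected readout). Configuration errors and data errors raise distinct
condition classes, mapped to exit codes 2 and 3 by the CLI.

## Numerical choices and edge cases

* Negative water amplitudes (noise exceeding signal) clip to zero with a
  warning; likewise negative calibrated masses near zero signal.
* Echo-time lookup matches the nearest acquired echo within 1% of the
  request; the single-echo readout refuses echo times whose residual water
  fraction is ≥ $10^{-3}$.
* `accuracy_from_counts()` reports to 2 decimals; probabilities print at 2
  significant figures.
* Mixture fits require ≥ 20 points and positive variance; degenerate
  inputs raise input errors rather than returning silently wrong numbers.

## Problem sizes used in the test suite

The suite simulates at the study's own field-test scale where that is
informative (1260-kernel populations for parameter recovery; 100 seeded
replicates for noisy relaxometry recovery; $10^4$ kernels for
empirical-vs-analytic rate agreement, where the binomial Monte-Carlo error
of a 0.8% rate is ±0.13 percentage points) and at smaller sizes for pure
algebraic properties. These sizes are the package's own choices balancing
statistical power of each assertion against quick iteration.

## Known limitations

* Relaxation times are line constants; no per-kernel $T_2$ variation or
  multi-exponential ($>2$) spectra (no inverse-Laplace fitting).
* No Bloch-level simulation: off-resonance, $B_1$, $T_1$ saturation and
  steady-state sequences are out of scope.
* The Gaussian class model is assumed, not tested against real kernels;
  real accuracies on breeding material can only come from an instrument.
* The additive FN + FP "total error" mixes class-conditional rates; use
  the weighted total for a per-kernel mis-sort probability.
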