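---
title: "Dynamic force spectroscopy with afmdfs: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic force spectroscopy with afmdfs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmdfs)
library(dplyr)
```

## Scope

`afmdfs` turns AFM force–distance curves into single-bond energy-landscape
parameters.  The pipeline has five analysis stages — curve I/O and
pre-processing, rupture-event detection, adhesion statistics and maps,
contact-time kinetics, and the Friddle–Noy–de Yoreo (FNdY) fit — plus a
synthetic-data module that generates every input with known ground truth.
All mechanical quantities use pN, nm, s; energies use pN·nm internally and
kcal/mol in reports (1 kcal/mol = 6.9477 pN·nm).

## The FNdY two-regime model

Force spectra of single intermolecular bonds are rarely linear in
log-loading rate.  The FNdY description splits bond rupture into a
near-equilibrium regime — below an equilibrium force $f_{eq}$ the bond
re-forms faster than it is pulled apart, so no ruptures are recorded there —
and a kinetic regime in which the rupture force grows with the logarithm of
the loading rate $r$.  The interpolating mean-force expression is

$$F(r) = f_{eq} + f_\beta \ln\!\left(1 + e^{-\gamma}\,\frac{r}{k_{off} f_\beta}\right),$$

with $\gamma = 0.577$, the thermal force $f_\beta = k_B T / x_t$ set by the
energy-barrier width $x_t$, and $k_{off}$ the dissociation rate at $f_{eq}$.
$F(r)$ is increasing and concave in $r$; in $\ln r$ it is convex, with slope
rising from 0 toward $f_\beta$ (the classic force-vs-log-rate line appears
asymptotically).  Derived quantities follow exactly from the fit:
$x_t = k_B T / f_\beta$, $\tau_0 = 1/k_{off}$, and
$|\Delta G| = f_{eq}^2 / (2 k_c)$, which requires the cantilever spring
constant $k_c$ — when $k_c$ is unknown the package omits $\Delta G$ with a
warning instead of guessing, because typical functionalised levers span
10–20 pN/nm and $\Delta G$ scales inversely with $k_c$.

### Fitting

`fit_fndy()` performs three-parameter Levenberg–Marquardt least squares
(`minpack.lm`), capped at 500 iterations with a chi-square change tolerance
of $10^{-15}$.  Design choices:

* **Log-parameterisation.** $(f_{eq}, f_\beta, k_{off})$ are physically
  positive, so iterates run on the log scale; confidence intervals are
  computed there from the linearised covariance with $t$ quantiles
  ($df = n - 3$) and transformed back, giving asymmetric, always-positive
  99% intervals.  Prediction bands add the residual variance.
* **Initialisation** is deterministic and data-driven: $f_{eq}^0$ = smallest
  binned force, $f_\beta^0$ = slope of $F$ vs $\ln r$ over the top decade,
  $k_{off}^0$ solved from the model at the median point.
* **Per-event vs binned.** By default every rupture contributes one point.
  `bin_dfs()` reduces the spectrum to log-spaced loading-rate bins
  (geometric-mean rate; Gaussian-mode force for bins with ≥ 30 events, mean
  otherwise).  On noiseless model data, binned and per-event fits coincide
  when each bin summarises replicates of a single rate; bins that mix
  distinct rates inherit a small curvature bias (the mean force over a
  log-rate window is not the model value at the geometric-mean rate), of
  order a few percent on $f_\beta$ at 8 bins over two decades.  This is a
  property of binning, not of the optimiser.

## The rupture simulator and what "agreement" means

`sample_rupture_forces()` draws ruptures from the first-passage law of a
Bell-type escape rate referenced to $f_{eq}$, with rebinding below $f_{eq}$
treated as instantaneous (a hard floor):

$$S(F) = \exp\!\left(-\frac{f_\beta k_{off}}{r}\left(e^{(F-f_{eq})/f_\beta} - 1\right)\right),
\qquad F \ge f_{eq},$$

sampled exactly by inversion.  This law has a closed-form mean,
$f_{eq} + f_\beta\, e^{b} E_1(b)$ with $b = f_\beta k_{off} / r$, which the
unit tests verify against numeric quadrature to Monte-Carlo precision.

The FNdY expression above is an *interpolation* between the two regimes: it
is exact as $r \to 0$ and asymptotically exact (including the $e^{-\gamma}$
factor) deep in the kinetic regime, but in the crossover window
$r \sim k_{off} f_\beta$ it undershoots the exact first-passage mean — by up
to roughly 10–25% of the mean force for parameter sets with barrier widths
of 0.1–0.6 Å and dissociation rates of 100–1000 s⁻¹ over loading rates of
100–20,000 pN/s (the acceptance script computes this deviation at run time).
Two practical consequences, both quantified by `scripts/acceptance.R`:

* the simulator's empirical mean only matches `fndy_mean_force()` to within
  a few percent away from the crossover, not uniformly across the spectrum;
* fitting the interpolation to exact first-passage data recovers $f_{eq}$
  accurately (median error well under 1%) but systematically inflates
  $f_\beta$ (median error of order 50%) and deflates $k_{off}$ (ratio
  ≈ 0.55), because the optimiser bends the curve upward to chase the
  crossover.  Reported $x_t$ inherits the $f_\beta$ bias.  Fitted parameters
  from crossover-dominated spectra should therefore be read as
  FNdY-effective parameters, not as the generative constants.

## Event detection

`detect_events()` works on baseline-corrected retraction segments
(`correct_baseline()` removes offset and tilt fitted to the far-field tail;
default `tail_fraction = 0.3`; noise estimated as MAD × 1.4826, robust to
residual events; windows containing excursions beyond 5σ are auto-shrunk).
Candidate events are local minima of a centred running median (default
window 7 samples, used for localisation only) deeper than
`threshold_sigma = 3` noise SD, followed by a jump back toward baseline
within `min_separation = 10` nm; overlapping candidates keep the deeper
minimum.  Rupture forces are read from the *unsmoothed* channel so
magnitudes are not attenuated.  The loading rate is measured per event as
the force-vs-time slope over the 20 samples preceding the rupture, matching
the notion of a critical loading rate at the instant of rupture rather than
the nominal $k_c v$ product.  Events at rupture distances within the default
(20, 500) nm window are flagged specific; the window is configurable per
experiment since antibody and lectin tethers differ.

With events ≥ 5 noise SD, recall and precision on synthetic curves exceed
0.95 (acceptance-checked on 200 curves).  The detector assumes essentially
single events per curve separated by `min_separation`; deconvolution of
overlapping multi-bond ruptures is out of scope.

## Adhesion statistics, maps, and kinetics

Adhesion-force histograms use 10 pN bins over at least 0–300 pN;
`fit_gaussian_histogram()` least-squares fits a Gaussian to bin counts (the
convention behind "μ ± σ pN" summaries), with a moments-based MLE
alternative.  Fits require ≥ 30 events; degenerate inputs return the
histogram only.  Adhesion frequency is the fraction of curves with ≥ 1
specific event; `blocking_comparison()` reports the drop and ratio after a
competitor-sugar control (default blocked cutoff: ratio < 0.5).
`render_adhesion_map()` summarises events per force-volume pixel (default:
maximum specific rupture force; binary white/black view via `autoplot()`,
plain-text CSV/PGM writers).

Contact-time kinetics follow the saturating hyperbola
$f(t) = f_{max} t / (k_{0.5} + t)$.  The double-reciprocal (Lineweaver–Burk)
estimator is provided for parity with common practice, but the reciprocal
transform amplifies noise at small frequencies, so the nonlinear fit is
always computed alongside and a > 25% disagreement in $k_{0.5}$ triggers a
warning.  A caution on study design: with binomial sampling at n = 64 curves
per contact time over a 7-point ladder, the sampling error of $\hat k_{0.5}$
is itself ≈ 20–25% (median), so single-experiment estimates at that depth
cannot be expected inside 20% of truth; `scripts/acceptance.R` computes the
realised median error over 20 seeded replicates, and the unit tests verify
20% recovery at n = 1024 where the data support it.

## Synthetic data: what it does and does not emulate

Generators cover stochastic rupture forces (above), full force–distance
curves (linear contact ramp to a 500 pN setpoint; linear tether loading at
constant effective stiffness, default 2 pN/nm, with instantaneous release;
seeded Gaussian force noise, default 5 pN; retract speeds 1–6 µm/s), spatial
force-volume maps (per-pixel Bernoulli adhesion with circular high-density
patches emulating chitin-rich bud-scar regions; Gaussian event forces), and
binomial contact-time frequency tables.  Every generator requires an
explicit seed, never touches global RNG state, and attaches/writes a
ground-truth sidecar.

Not emulated: worm-like-chain tether elasticity, instrument drift,
hydrodynamic drag, multiple parallel bonds, surface roughness, or the
heterogeneity of living-cell walls.  Passing closed-loop tests therefore
demonstrates correctness of the algorithms under idealised single-bond
conditions, not performance on real cell-surface data.

## Problem sizes and numerical choices

Test and acceptance runs use 12 log-spaced loading rates in
[100, 20,000] pN/s with ~167 ruptures per rate (≈ 2000 per spectrum), 20
replicates per parameter set for recovery statistics, 1000 forces per
Gaussian regime, 200 curves for detection scoring, and one 32 × 32 map
(1024 curves) for frequency checks — sizes chosen so the full validation
executes in minutes on one CPU while keeping Monte-Carlo error well below
the tolerances being checked.  Curves are sampled at 2048 Hz over a 600 nm
retract.  Ties and degenerate inputs: identical forces yield `fit_ok =
FALSE` rather than a zero-width Gaussian; zero frequencies are excluded
(with a warning) from reciprocal fits; spectra with fewer than 5 distinct
rates or under one decade of span are flagged poorly conditioned; LM trial
steps that overflow the model on the log scale are penalised rather than
allowed to error.

## Known limitations

* The FNdY interpolation-vs-first-passage mismatch in the crossover regime
  (quantified above) is intrinsic to the model pairing, not a defect of the
  optimiser; comparisons of fitted $f_\beta$, $x_t$, $k_{off}$ across
  instruments should use a common fitting convention.
* $\Delta G$ depends on the per-probe $k_c$; reported values scale as
  $1/k_c$ within the 10–20 pN/nm calibration range.
* Rupture distances are reported against piezo height (not tip–sample
  separation); for the 20–500 nm distances involved the difference is
  second-order, and the `distance_mode` metadata flag records the
  convention.
* Multi-peak (multi-bond) curves contribute all their specific events to
  histograms; alternative conventions (first event only) are available in
  the per-pixel map summary but not in the histogram builder.
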