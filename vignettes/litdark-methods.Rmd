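---
title: "Models and methods behind litdark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind litdark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litdark)
```

`litdark` analyzes lit/dark measurements of a photoswitchable enzyme — an
optogenetic fusion in which a LOV2 light-sensing domain allosterically
modulates catalysis. This vignette documents the models, the tunable
parameters, the synthetic-data generator, and the design decisions that
were genuinely open, in enough detail that a user can judge what a passing
test suite does and does not demonstrate.

## 1. From absorbance traces to turnover numbers

Catalysis is assayed by NADPH depletion at 340 nm under saturating
substrate and cofactor, so the reaction is zero order and the progress
curve is linear until a reactant is exhausted. `initial_velocity()` fits a
straight line to the first 15 s of the trace (the window is a parameter,
`window_s`, in seconds) and converts the slope through Beer's law,
`v0 = -slope / (eps * l)` with `eps = 13.2` mM^-1 cm^-1 for NADPH and a
1 cm path. `kcat_from_velocity()` divides by the enzyme concentration. A
negative velocity is reported and flagged rather than clamped: silently
truncating a pathological trace would hide instrument problems from the
downstream fits.

## 2. Eyring analysis with bootstrap errors

Transition-state theory decomposes the turnover number into an activation
enthalpy and entropy,

$$k_{cat}(T) = \frac{k_B T}{h}
  e^{-\Delta H^\ddagger/RT} e^{\Delta S^\ddagger/R},$$

with `R = 1.987` cal/(mol K). `fit_eyring()` uses ordinary least squares
on the linearized form; the estimates are closed-form, there is no
convergence question, and the fit reproduces a "line of best fit" on the
conventional Eyring plot exactly. A direct nonlinear fit of `ln(kcat)` is
algebraically equivalent here (the `ln T` offset cancels in the
residuals), which the tests verify.

Measurements above `t_max = 35` degrees C are excluded before anything else
happens: above the melting temperature of these marginally stable fusions
the rate-temperature relationship is no longer linear, so the
high-temperature points do not report on the transition state. The
exclusion count is kept on the fit object.

Errors come from a nonparametric bootstrap (`bootstrap_eyring()`,
`n_boot = 5000` by default): each iteration resamples the pooled filtered
(T, kcat) pairs with replacement and refits. Two open choices were decided
as follows.

* **Pooled, not stratified, resampling.** The per-condition dataset is
  described as a pool of 21 measurements, so the default bootstrap
  resamples all pairs jointly; stratified resampling (replicates within
  each temperature) is available via `stratified = TRUE` for users who
  prefer to condition on the temperature design.
* **Degenerate draws are redrawn.** A resample containing fewer than two
  distinct temperatures cannot identify a slope; such draws are redrawn
  and counted (`n_redrawn`). With seven temperatures the event is
  vanishingly rare (probability about 7^-20 per draw).

Standard errors are bootstrap standard deviations and intervals are
2.5/97.5 percentiles. Point estimates always come from the full dataset,
never from the bootstrap mean. Percentile intervals on 21 observations
undercover slightly (their true coverage in our calibration runs is close
to 90-93% rather than a nominal 95%); this is a known property of the
percentile bootstrap at small n, not a defect of the implementation.

## 3. Lit-minus-dark energetics

`allostery_energetics()` differences a lit and a dark fit:
`ddH`, `ddS`, `ddG(T_ref) = ddH - T_ref*ddS`, and the fold change
`exp(-ddG/(R*T_ref))`. Three details matter.

* **Pairing.** The lit and dark experiments are independent, so their
  bootstrap streams are independent; iteration *i* of one stream is paired
  with iteration *i* of the other to form the difference distribution.
  This is the standard independent-condition bootstrap and assumes nothing
  about correlation between conditions.
* **Units of the entropic term.** Quantities like "an entropic penalty at
  30 °C" are conventionally quoted as an energy. The object therefore
  exposes both `ddS` in cal/(mol K) and `TddS_at_ref = T_ref * ddS` in
  cal/mol (default `T_ref = 303.15` K), so neither reading is guessed
  silently.
* **Exact identities.** `ddG = ddH - T_ref*ddS` and
  `fold = exp(-ddG/(R*T_ref))` hold to machine precision for every output,
  including every bootstrap iteration; the tests assert this.

`predicted_fold_change()` evaluates the implied activation at any
temperature. When `ddH < 0` (an enthalpic benefit of light) the profile is
strictly decreasing in temperature — allostery is strongest in the cold —
because `d ln(fold)/dT = ddH/(R T^2)`.

Temperatures are converted as `T(K) = T(°C) + 273.15` throughout. Melt
equations in the literature sometimes use `+273`; the difference is below
0.05% and far below reporting precision, so a single convention is used
everywhere.

## 4. CD melts: cleaning, windowing, two-state fitting

### Light-pulse removal

During a melt the LOV2 chromophore is kept in its lit (or probed in its
dark) state by periodic LED pulses; a CD sample acquired while a pulse
fires shows a sharp transient drop in the photomultiplier (HT) voltage and
a corrupted ellipticity reading. `detect_light_pulses()` flags samples
whose drop from the preceding level exceeds `k_mad = 5` times the MAD of
successive HT differences *and* whose signal recovers by the same margin
within `max_run = 3` samples. The recovery requirement is what
distinguishes a transient artifact from a genuine monotone decline such as
the HT decay that accompanies aggregation: a plain first-difference
threshold alone would either miss consecutive pulse hits or cascade into
false positives on a steep aggregation decay at low noise. The numeric
threshold is a default, not a claim about any particular instrument.

`clean_melt()` removes flagged rows per wavelength channel and then
averages the dual 222/222.1 nm channels onto a single grid
(nearest-temperature clustering within half a ramp step), so a pulse that
corrupted one channel leaves the other channel's reading in place.
`aggregate_melt_scans()` applies the same logic across replicate scans of
the same ramp — melts are recorded as repeated scans precisely so that
pulse-induced gaps average out.

### The two-state model

`two_state_model()` implements a monomer in equilibrium between folded and
unfolded states with temperature-linear baselines:

$$\theta(T) = \frac{K}{1+K}\left[(F + C_f T) - (U + C_U T)\right] + (U + C_U T),
\qquad K = \exp\!\left[\frac{\Delta H}{R\,T_K}
\left(\frac{T_K}{T_{M,K}} - 1\right)\right].$$

`ΔH` (cal/mol) is the folding enthalpy and is negative; `K` is the
folded/unfolded equilibrium constant, equal to 1 at `T_M`. The exponent is
clipped at ±700 to avoid floating-point overflow at extreme arguments; the
clip is unreachable for physically sensible inputs.

Because these melts are not reversible at high temperature, no free energy
of unfolding is computed from the fit: only `Tm` is interpreted
quantitatively, and the fitted `ΔH` is treated as a fit-internal shape
parameter (it absorbs, e.g., residual baseline misspecification).

### The aggregation-aware fit window

Dark-state melts of aggregation-prone constructs show a second transition
just above 50 °C: a rapid rise in the CD signal accompanied by a decline
in HT voltage, with visible precipitate afterwards. This is an artifact of
aggregation, not a third thermodynamic state, so the fit treats unfolding
as two-state below the artifact and excludes the artifact by windowing
(`fit_window()`):

* the window starts at the lowest measured temperature;
* when the HT channel shows an aggregation signature (a decline after its
  maximum exceeding 25% of its range), the window ends at the midpoint
  between the temperature of the CD maximum and the temperature of the HT
  maximum;
* otherwise — or when the midpoint would leave under 10 °C of data — the
  full range is used and the fallback is recorded.

The endpoint rule is stated in the literature in terms of "the maximum CD
value and the maximum HT value"; reading the midpoint on the temperature
axis (between the two argmax positions) is the only version that yields a
usable fit bound, and is the main interpretive decision in this module.
One figure caption in the source literature calls the fitted model "three
state" while the text and methods specify two-state; the two-state text is
treated as authoritative and the caption as a typo.

### Fitting and flagging

`fit_two_state()` runs Levenberg-Marquardt least squares (via
`minpack.lm::nlsLM`) over the six parameters, initialized from the data:
`Tm` from the extremum of the derivative of a 5-point moving-average
smoothed trace, baselines from linear fits to the outer 20% temperature
segments, `ΔH` from `dH_init = -50000` cal/mol, and `ΔH` constrained
negative. A fit that fails, puts `Tm` on the window boundary, or has a
transition amplitude indistinguishable from the residual noise is returned
with `accepted = FALSE` and a reason — never as a silent number.
`fraction_folded()` refuses flagged fits.

## 5. Variant aggregation

`build_variant_record()` joins the lit/dark Eyring and melt results of one
construct; all derived quantities (`dTm = Tm_lit - Tm_dark`, tradeoff
coordinates, profiles) are exact functions of their inputs — nothing is
refit at this stage, and aggregation is idempotent.

* **Tradeoff plot.** Variants are placed at `(T_ref*ddS, ddH)`; the
  diagonal `x = y` is exact enthalpy-entropy compensation (zero net
  allosteric free energy), and the signed off-diagonal offset
  `gain = T_ref*ddS - ddH = -ddG` is reported in cal/mol with bootstrap
  intervals. The offset is invariant to translation along the diagonal.
* **Classification.** A variant is called enhancing/disrupting/neutral by
  comparing its 95% fold-change CI with the reference construct's CI
  (strictly above, strictly below, or overlapping). The source analyses
  give no explicit rule; CI overlap is the conservative choice, and it
  guarantees that a record compared against itself is always neutral.
* **Stability-activity correlation.** The line of best fit of `dTm` on
  `ddG` is computed on an explicitly passed record set; the exclusion set
  is an argument (`exclude =`), never hard-coded, so the with/without
  contrast of excluding the stability-only outliers is reproducible. The
  regression direction for the printed line is not uniquely determined by
  the axes, so both directions are reported
  (`slope`/`reverse_slope`).

## 6. The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth without any deposited raw data. What it emulates:

* **Rate panels** — the study design of 7 temperatures (5–35 °C) in
  triplicate, 21 measurements per condition, with an 8th temperature
  (40 °C) available to exercise the exclusion rule. Replicate noise is
  multiplicative lognormal with `sigma = log(1 + kcat_cv)` and a default
  CV of 5%: rates are positive and kinetic replicate scatter scales with
  the rate. The noise model itself is a modeling choice (no noise model is
  stated in the source literature).
* **Absorbance traces** — zero-order depletion with a hard floor when the
  limiting reactant (25 µM substrate vs 90 µM cofactor) is exhausted.
  Saturating assays justify the hard floor over a Michaelis-Menten
  rollover.
* **Melt curves** — the two-state model plus Gaussian CD noise
  (0.2 mdeg default), dual 222/222.1 nm rows, an HT channel that rises
  smoothly with unfolding (arbitrary "volt" units; only relative changes
  matter), pulse artifacts mapped onto the ramp through the measurement
  times (10.25 s pulse cycle against a 0.5 °C/min ramp with 1 s
  integration, giving irregular hits on roughly 12% of samples, each a
  single-sample HT dip plus a CD offset), and an optional aggregation
  signature.
* **Aggregation artifact** — above the onset (default 50 °C) the HT
  channel decays exponentially toward a floor, and the CD channel shows a
  sharp, bounded surge: a second transition that rises steeply to a peak a
  few degrees above the onset and then settles as precipitate leaves the
  beam. An unbounded linear-in-temperature surge was considered and
  rejected: it would place the CD maximum at the end of the grid, which
  makes the literature's window-endpoint rule include tens of degrees of
  artifact and contradicts the procedure the artifact is supposed to be
  cleaned by. The peaked shape reproduces the qualitative signature
  (rapid CD increase with concomitant HT decrease just above the onset)
  while keeping the windowing rule self-consistent. The exact HT response
  to a 250 ms pulse is not documented; the single-sample square dip is a
  modeling choice.
* **Relaxation traces** — one-phase association
  `A(t) = plateau + (A0 - plateau) e^{-kt}`.

Every generator is a pure function of its parameters and seed; identical
calls are bitwise identical. What the generator does **not** emulate:
instrument drift, temperature-lag between the probe and the cuvette,
photobleaching, Michaelis-Menten rollover near sub-saturating substrate,
aggregation kinetics beyond the qualitative signature, or photocycle
photophysics. Passing recovery tests therefore demonstrate that the
pipeline is correct and well-calibrated *under the stated noise model*,
not that it is robust to every failure mode of real instruments.

## 7. Problem sizes and calibration properties

The suite and the acceptance script use the study-sized designs
throughout: 21-point rate panels, 5000 bootstrap iterations, 0.5 °C melt
grids from 5 to 90 °C in dual wavelength, triplicate melt scans, 100
seeded recovery runs for the energetics and 200 for the single-condition
CI calibration. These sizes run in seconds because the bootstrap is
vectorized (closed-form OLS on index matrices rather than repeated model
objects).

Calibration: across seeded recovery runs at the study design, the 95%
bootstrap CIs for `ddH` and `T*ddS` cover the generating values in at
least 90% of runs, and the clean → window → fit melt chain recovers
generating melting temperatures of 33.9 °C (dark, with aggregation
artifact) and 31.3 °C (lit) to within 0.3 °C from triplicate scans.

## 8. Known limitations

* The percentile bootstrap slightly undercovers at n = 21 (see §2);
  users needing calibrated coverage at small n may prefer stratified
  resampling plus BCa-style corrections, which are out of scope here.
* The fit-window rule depends on argmax positions of noisy channels; on
  very noisy HT data the endpoint can jitter by a few grid steps. The
  windowed fit is robust to this in our calibration runs, but pathological
  HT traces should be inspected with `autoplot()` before trusting `Tm`.
* `ΔH` from the melt fit is not a calorimetric enthalpy (irreversibility,
  baseline absorption); only `Tm` is meant for quantitative comparison.
* Pulse detection cannot flag a pulse coinciding with the very first or
  last sample of a scan (no observable drop-and-recovery); with the
  default phase this does not occur.
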