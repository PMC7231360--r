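---
title: "cardiosens: models and methods for dual-readout cardiomyocyte sensing"
author: "cardiosens maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiosens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosens)
```

# The measurement problem

A cardiomyocyte monolayer cultured on a polymer cantilever with an
interdigitated electrode (IDE) array offers two complementary, simultaneous
readouts. The impedance between the electrode combs and the culture medium
tracks how many cells are present and how tightly they adhere — drugs that
damage the monolayer or loosen focal adhesions lower it. The cantilever's
out-of-plane deflection, measured by a laser vibrometer, tracks the
synchronized contraction of the monolayer — negative inotropes reduce it,
and repolarization-prolonging compounds widen and destabilize the beat.
`cardiosens` implements the full analysis chain for both channels plus a
seeded synthetic-data generator that stands in for the physical device.

# Device model

**IDE cell constant.** For simple comb geometries the cell constant is
approximated by $K = 2S / (3\,W\,L\,(N-1))$, with finger spacing $S$, width
$W$, length $L$ and finger count $N$. $K$ is a reciprocal length (reported
in cm$^{-1}$, the ECIS convention; all lengths are SI meters internally); a
low $K$ means the measured resistance responds strongly to changes at the
cell–electrode interface. Dense arrays ($S \le W$, $L \ge 1$ mm, $N \ge 10$)
stay below 1 cm$^{-1}$. The formula is linear in $S$ and monotone in every
factor, which the test suite verifies by randomized geometry pairs.

**Cantilever.** An end-loaded rectangular beam has stiffness
$k = E\,w\,t^3/(4L^3)$. The default beam (6 mm × 2 mm × 15 µm) with the
standard SU-8 modulus $E = 2.0$ GPa (configurable; SU-8 literature values
range roughly 2–4 GPa) gives $k = 0.015625$ N/m, i.e. the nominal
0.015 N/m. Force conversion is Hookean and exactly invertible:
7.5 nN at 500 nm, 750 nN at 50 µm. Composite (polymer + metal) stiffening
and large-deflection corrections are out of scope.

# Impedance channel

## Equivalent circuit

$$Z(\omega) = R_s + \frac{1}{Q\,(j\omega)^n} +
  \frac{R_p}{1 + j\omega R_p C_p}$$

$R_s$ lumps solution, electrode and connector resistance; the
constant-phase element (CPE) with magnitude $Q$ (S·s$^n$) and exponent
$0 < n \le 1$ models the electrode double layer ($n = 1$ is an ideal
capacitor, which the implementation reproduces to machine precision); the
parallel $R_p \parallel C_p$ branch models the cell–electrode interface.
The topology — CPE in series with the cell branch — is the standard
two-electrode ECIS lumped model; the printed parameter values alone cannot
discriminate alternative placements of the CPE, so this choice is a design
decision, not a measurement. Model invariants: $\mathrm{Re}(Z)$ strictly
decreasing in frequency, $\mathrm{Im}(Z) \le 0$ (capacitive convention
$Z = Z' + jZ''$, $Z'' < 0$), and $\mathrm{Re}(Z) \to R_s$ at high frequency.

The packaged calibration parameter set (`defaultCircuitParams()`) for a
mature monolayer is $R_s = 5.177$ kΩ, $Q = 5.01\times10^{-8}$ S·s$^n$,
$n = 0.705$, $R_p = 40.52$ kΩ, $C_p = 3.29$ nF. $Q$ is treated as the bare
reported number in S·s$^n$; no unit conversion is applied.

## Fitting

`fitCircuit()` minimizes $\sum_i w_i\,|Z_{\mathrm{model}}(f_i) -
Z_i|^2$ with modulus weighting $w_i = 1/|Z_i|^2$ — the usual choice when a
spectrum spans several decades of magnitude, so that every frequency
contributes its *relative* error; unit weighting is available. The five
parameters are optimized in log space ($R_s, Q, R_p, C_p$) and logit space
($n$), which enforces the positivity/range invariants without explicit
constraints, by Levenberg–Marquardt (`minpack.lm`). Standard errors come
from the weighted Jacobian at the optimum, propagated through the
reparameterization by the delta method; a numerically perfect fit therefore
reports (near-)zero errors.

**Initial guess.** The starting point reads the spectrum's structure:
$R_s$ from the highest-frequency real part; then, over a coarse grid of CPE
exponents $n \in \{0.35, 0.40, \dots, 1\}$, $Q$ from the lowest-frequency
modulus (where the double layer dominates), $R_p$ from the largest real
part of the CPE-corrected remainder, and $C_p$ from the frequency of that
remainder's imaginary-part extremum (which sits at $\omega = 1/(R_p C_p)$);
the grid point with the smallest modulus-weighted residual wins. The grid
over $n$ matters: $n$ is the main non-convexity axis of this model, and a
fixed guess for it can strand the optimizer in a local minimum in which the
cell branch collapses. With the profiled guess a *single* LM start
converges on clean spectra across the whole calibration region
($\pm 1$ printed SD on every parameter, 100/100 random draws in the test
suite); multi-start (default 8 starts, deterministic seeded jitter of
0.35 SD in transformed space, ties broken by residual then lexicographic
parameter order) is kept as insurance for noisy or atypical spectra.

Preconditions: at least 10 points spanning at least two decades.
Non-convergence of every start is flagged, never silent.

## ECIS normalizations

The cell index is $CI = (|Z| - |Z_0|)/|Z_0|$ against the pre-seeding
(cell-free) baseline $Z_0$; the adhesion readout is normalized resistance,
$100\,R(t)/R(0)$ at the monitoring frequency. The monitoring frequency
defaults to 5 kHz — inside the assay's sensitive band (~400 Hz to ~50 kHz)
— snapped to the nearest acquisition-grid frequency. Whether the cell index
should use impedance magnitude or resistance is not uniquely determined by
the assay description; this package uses the magnitude at the monitoring
frequency and keeps the resistance channel separate.

# Force channel

## Beat detection

1. **Drift removal.** The slow baseline is estimated by a *morphological
   opening* (sliding minimum, then sliding maximum; O(n) blockwise
   implementation) with a window of 3× the median beat period (estimated by
   a coarse first pass with a 2 s window). For positive-going contraction
   pulses the opening returns the baseline exactly whenever each window
   contains at least one between-beat sample — i.e. at any pulse duty cycle
   below 100%. A running median, the more common choice, becomes
   ill-conditioned when beats occupy ≥ 50% of the cycle (its output sits on
   a knife edge between baseline and pulse values and develops wiggle
   artifacts) and its end taper suppresses beats near the trace edges; the
   opening has neither failure mode. Its one bias — under noise it sits at
   the noise's lower envelope, a constant ≈ $2\sigma$ offset — cancels in
   every reported quantity because amplitudes are peak-minus-baseline
   differences.
2. **Candidate peaks** are strict local maxima of a lightly smoothed copy
   (15 ms running median), kept greedily tallest-first under a 150 ms
   minimum separation (capping detectable rates at ~6.7 Hz, well above
   neonatal cardiomyocyte rates; configurable). Locations are then refined
   to the raw local maximum nearby, so noise-free amplitudes are exact.
3. **Acceptance threshold**: a beat's amplitude above its preceding local
   minimum must reach $\max(3 \times 1.4826\,\mathrm{MAD}(\text{detrended
   trace}),\ \text{noise floor})$, with the instrument floor defaulting to
   120 nm (the vibrometer's resolution limit). The threshold is applied in
   *both* the smoothed and the raw domain: the smoothed amplitude is immune
   to extreme-value inflation of raw noise (which would otherwise let
   ~5.5σ noise excursions pass), and the raw amplitude is immune to any
   residual filter artifact. The 3× multiplier keeps the false-positive
   rate below 1% on the synthetic suite (100-seed check at 50 nm noise)
   while detecting every beat down to the instrument floor.

Per-beat quantities: amplitude above the preceding local minimum (read from
raw samples, so constant offsets cancel and scaling is exactly linear);
duration as the width between the crossings of
$\text{baseline} + f \times \text{amplitude}$ (default $f = 0.1$; linear
interpolation between samples; a beat whose crossing search runs off a
trace edge is flagged missing) — the assay's QT-like repolarization proxy;
and the preceding inter-beat interval.

## Aggregates

`summarizeBeats()` reports the beat count, beating frequency (reciprocal of
the *median* interval — robust to a single missed beat), mean amplitude and
force ($k \times$ amplitude), mean duration, and the interval CV
(sd/mean), the irregularity index used for hERG-block phenotypes. With
fewer than two beats, frequency and CV are reported missing rather than
invented; a beat-free trace has zero amplitude and force, so a fully
suppressed recording reads as 0% force rather than an error.
`relativeForceCourse()` expresses a series of recordings as percent of a
baseline recording — the maturation readout. `averageBeat()` windows beats
around their peaks (window = median interval), refines the alignment by a
least-squares lag search against a reference beat (per-beat localization
noise on a flat pulse apex is several samples and would blur the mean),
re-centers the average on its own peak and anchors it at its resting level.

# Drug-response module

`buildCurve()` normalizes both channels to the *last pre-dosing
measurement* (not an earlier culture-day value, which would conflate
maturation with drug effect) and inserts the $t=0$ point at 100%.
Percentages above 100 are representable (hypercontractility); nothing is
clipped. `recoveryProfile()` reports the minimum over the grid, its time,
the value at the horizon (default 24 h, the standard observation window)
and a recovery flag that requires the horizon value to exceed the minimum
by more than 2 percentage points, so noise-level rebounds are not called
recovery. `hillFit()` fits $R(d) = 100/(1 + (d/IC_{50})^h)$ in log space;
an IC50 outside the tested dose range is flagged as extrapolated, and
responses that *increase* with dose beyond the noise level add a diagnostic
warning without suppressing the fit.

# Synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the analysis chain is validated.

**Spectra.** Forward model plus independent proportional Gaussian noise on
real and imaginary parts (sd $= \text{noiseRel} \times |Z|$); zero noise is
bit-identical to the forward model. The acquisition grid is 60 log-spaced
points over 100 Hz–2 MHz, the instrument's sweep range.

**Adhesion.** Cells attach and spread over ~36 h; the generator rescales
$R_p$ over time so the 5 kHz normalized resistance follows a monotone
piecewise-cubic interpolation of the keyframes (0 h, 100%), (36 h, 118%),
(48 h, 113%), (72 h, 113%) — a near-linear rise to 118% followed by
settling near 113%. The baseline circuit uses a smaller cell branch
($R_p = 5$ kΩ, $C_p = 1$ nF) appropriate for freshly seeded, sparse cells;
it also keeps $\omega R_p C_p < 1$ at 5 kHz so resistance increases
monotonically with the $R_p$ scale and the per-timepoint scale factor is
found by 1-D root finding. Sampling every 3 h for 72 h, noiseless by
default.

**Beating traces.** A sum of asymmetric pulses: raised-cosine upstroke over
the first third of the nominal duration, then an exponential relaxation
(rise:decay 1:2) shifted and truncated to reach exactly zero at the nominal
duration — compact support keeps consecutive beats separable at high rates.
Intervals are $1/f$ perturbed by lognormal jitter with a specified CV
(default 0.05, a physiological beat-to-beat variability for synchronized
monolayers); Gaussian noise defaults to 50 nm, below the 120 nm instrument
floor. Sampling is 500 Hz so 150 ms features are well resolved. The day
4–7 maturation defaults are amplitudes 2.5 / 4.16 / 6.089 / 10.0 µm —
ratios 100 : 166.4 : 243.56 : 400, the calibrated landmark (400% is read as
a ratio of 4.00×, not +400 points) — with frequencies 3.0 / 2.5 / 2.2 /
1.8 Hz and durations 0.25 / 0.30 / 0.35 / 0.40 s. The frequencies and
durations are *synthetic defaults* encoding only the qualitative trends
(rate falls, beat widens with maturation) and must not be read as measured
values.

**Drug exposures.** Effects are encoded as keyframe interpolation, not a
mechanistic PD model: the assay literature reports trajectory landmarks
(minima, recovery values at fixed times), not kinetic parameters, and
keyframes make those landmarks exactly reproducible while keeping the
generator transparent. Per (drug, dose), the force and CI keyframes of
`inst/extdata/drug_keyframes.json` are interpolated by a monotone
piecewise cubic — the keyframe list is split into monotone runs at its
turning points and each run gets Fritsch–Carlson slopes, so the interpolant
never overshoots an anchor (a single monotone-method fit would undershoot
just after the keyframed minimum of a suppression–recovery trajectory).
Beat amplitude is scaled by the force percentage; $R_p$ is rescaled by 1-D
root finding so the 5 kHz cell index hits the CI percentage exactly
(|Z| is monotone in the $R_p$ scale on $[0, 1]$ in the calibrated
parameter region, which suffices because CI keyframes never exceed 100%);
for E-4031 at 30 nmol/L, beat duration is widened (peak factor 1.22 at
12 h — chosen so the widened pulse stays clearly inside the beat period;
a contraction that fills the whole cycle would make the force readout
ill-posed) and inter-beat jitter inflated (5× at 12 h, easing to 2× at
24 h). Calibrated anchors include: verapamil force 300 nmol/L (12 h, 45%),
(24 h, 51%); 500 nmol/L (4 h, 1.5%); 1000 nmol/L (≈0% through 14 h, 5.5%
at 24 h); verapamil CI 300 (12 h, 74%), 1000 (12 h, 65%), (24 h, 75%);
E-4031 CI at 24 h: 80% (5), 72% (10), 66.5% (20), 64% (30), all monotone
(no recovery). The verapamil 150 nmol/L CI minimum (82%) has no stated
time; 12 h is assumed by analogy with the other doses. Recovery extents
not stated anywhere (e.g. verapamil 150/300/500 CI at 24 h) are plausible
synthetic fill-ins. Doses absent from the table are interpolated in
log-dose with a warning; timepoints beyond the last keyframe raise an
error rather than extrapolate.

**Seeding.** Every generator is a pure function of (parameters, seed); a
single global seed fans out to independent per-stream seeds through a
counter-based scheme, so the displacement and impedance channels use
disjoint noise streams and adding a stream never perturbs existing ones.
This implements the physical independence of the two readouts — the test
suite asserts bit-identical impedance output under arbitrary perturbation
of the trace channel's noise, and vice versa.

## What the generator does and does not emulate

It reproduces the landmark trajectories, noise scales and the qualitative
drug phenotypes. It does **not** emulate: biological replicate variability
(the assay's own adhesion SD grows after 18 h across samples), electrode
aging or medium-exchange artifacts, mechanistic ion-channel dynamics,
field-potential readouts, or imaging endpoints. Passing round-trip tests
therefore shows that the *analysis chain* is correct and self-consistent at
realistic signal and noise scales — not that it would be unbiased on any
particular laboratory's raw data.

# Numerical choices and degenerate inputs

* Monotone piecewise-cubic (Fritsch–Carlson) interpolation everywhere a
  keyframed trajectory is evaluated; segmented at turning points (see
  above).
* Root finding for calibration scales: `uniroot` at tolerance $10^{-12}$ on
  brackets where monotonicity is guaranteed analytically; an unreachable
  target (e.g. a resistance above the circuit's achievable maximum) is an
  error, not a clamp.
* Fit preconditions (≥ 10 points, ≥ 2 decades) are hard errors; an all-flat
  trace yields an empty beat table, not an error; NaN samples are an error.
* A spectrum's validity requires strictly ascending positive frequencies;
  time courses require non-decreasing times and a baseline entry.
* Problem sizes used by the test and acceptance suites: 60-point spectra,
  10–26 s traces at 500 Hz, 50-replicate fit Monte Carlo at 1% noise,
  200-replicate IC50 Monte Carlo at 10% noise, 100-seed detection checks —
  sizes at which the Monte-Carlo tolerances (2% median fit bias, 0.3 median
  |log₂| IC50 error, ±3-point noisy anchor reproduction) are comfortably
  stable.

# Known limitations

* Single-CPE electrode model: no Warburg element, no Kramers–Kronig
  validity testing; spectra dominated by diffusion would fit poorly (and
  should — the residual norm reports it).
* Beat detection assumes positive-going contraction pulses; invert the
  trace for the opposite sign convention.
* The duration metric depends on the threshold fraction (default 0.1); the
  assay's QT-like interval has no unique operational definition on a
  displacement waveform.
* Drug trajectories between keyframes are interpolations, not physiology;
  only the anchors carry calibrated meaning.
* Per-sample normalization: curves from different devices are each
  normalized to their own pre-drug state and are not cross-calibrated.
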