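# cardiosens

Analysis toolkit for **dual-readout cardiomyocyte biosensors**: devices that
grow a cardiomyocyte monolayer on a polymer cantilever carrying an
interdigitated electrode (IDE) array, and read out, simultaneously,

* **cell adhesion / viability** by electric cell-substrate impedance sensing
  (ECIS) — impedance spectra between the electrodes and the culture medium,
  and
* **contraction force** by cantilever mechanics — a laser vibrometer measures
  the out-of-plane tip displacement caused by synchronized beating, and
  Hooke's law (F = k·δ) converts it to force.

The package is aimed at in-vitro cardiotoxicity / drug-safety screening
workflows: it quantifies how compounds such as verapamil (L-type calcium
channel blocker) and E-4031 (hERG potassium channel blocker) suppress the two
readouts over time and whether they recover.

## What it computes

**Impedance channel.** The two-electrode system is modelled by the standard
lumped equivalent circuit

```
Z(ω) = R_s + 1/(Q·(jω)^n) + R_p / (1 + jω·R_p·C_p)
```

with series resistance `R_s` (solution + electrode + connector), a
constant-phase element (`Q`, `n`) for the electrode double layer, and a
parallel RC branch (`R_p`, `C_p`) for the cell–electrode interface.
`fitCircuit()` performs complex nonlinear least squares with modulus
weighting (`w_i = 1/|Z_i|²`), optimized in log/logit space by
Levenberg–Marquardt with deterministic multi-start. Derived readouts: the
cell index `CI = (|Z| − |Z₀|)/|Z₀|` against the pre-seeding baseline, and
normalized resistance/CI time courses at a 5 kHz monitoring frequency.
Device geometry enters through the IDE cell constant
`K = 2S / (3·W·L·(N−1))`.

**Force channel.** `detectBeats()` extracts contraction peaks from
displacement traces (morphological-opening drift removal, robust
MAD-plus-instrument-floor thresholding, 150 ms minimum separation), and
`summarizeBeats()` aggregates amplitude, force (`k·δ` with the cantilever
spring constant `k = E·w·t³/(4L³)`), beating frequency, beat duration (a
QT-like repolarization proxy) and inter-beat-interval CV (irregularity).

**Drug response.** `buildCurve()` / `recoveryProfile()` normalize both
channels to their last pre-dosing value and quantify dose-dependent
suppression and time-dependent recovery; `hillFit()` fits an inhibitory Hill
model for IC50 summaries.

**Synthetic device.** Because the physical device is not required,
`simulateSpectrum()`, `simulateAdhesionCourse()`, `simulateBeatingTrace()`
and `applyDrugModel()` generate every input the pipeline consumes, with
seeded randomness and defaults calibrated to landmark values of the assay
(adhesion resistance rising to 118% at 36 h and settling near 113%; day 4–7
contraction force ratios 100 : 166.4 : 243.56 : 400; per-drug, per-dose
suppression/recovery keyframes such as verapamil 300 nmol/L force 45% at
12 h recovering to 51% at 24 h).

## Worked example

```r
library(cardiosens)

## fit the equivalent circuit to a noisy synthetic spectrum
sp  <- simulateSpectrum(defaultCircuitParams(), noiseRel = 0.01, seed = 42)
fitCircuit(sp)
#> Equivalent-circuit fit (modulus weighting, 8 starts, converged)
#>             estimate  std.error
#> R_s (Ohm) 5.1668e+03 1.4231e+01
#> Q (S.s^n) 5.1015e-08 6.4954e-10
#> n         7.0369e-01 1.5822e-03
#> R_p (Ohm) 4.1505e+04 4.8838e+02
#> C_p (F)   3.2978e-09 3.7999e-11
#> weighted residual norm: 0.1101
```

At 1% spectral noise the fit recovers the generating parameters
(R_s = 5.177 kΩ, Q = 5.01e-8, n = 0.705, R_p = 40.52 kΩ, C_p = 3.29 nF)
within roughly one standard error each.

```r
## beat analysis of a mature (day-7-like) trace
tr <- simulateBeatingTrace(amplitude = 10e-6, frequency = 1.8,
                           duration = 0.4, lengthS = 15, seed = 42)
summarizeBeats(tr, detectBeats(tr), k = 0.015)
#> BeatSummary: 27 beats, 1.81 Hz, mean amplitude 10.05 um,
#>   mean force 150.8 nN, mean duration 0.278 s, interval CV 0.065
```

A 10 µm mean deflection on a 0.015 N/m cantilever is a ~150 nN contraction
force; the detected 1.81 Hz rate and 6.5% interval CV match the generator's
nominal 1.8 Hz and 5% beat-to-beat jitter.

```r
## verapamil 300 nmol/L exposure, both channels
exp <- applyDrugModel("verapamil", 300, noiseSd = 0, jitterCV = 0,
                      noiseRel = 0)
crv <- analyzeDrugExperiment(exp)
recoveryProfile(crv, "force")
#> RecoveryProfile: min 45% at 12 h, 51% at 24 h horizon -> recovered
recoveryProfile(crv, "ci")
#> RecoveryProfile: min 74% at 12 h, 82% at 24 h horizon -> recovered
```

Contraction force drops to 45% of its pre-drug value at 12 h and recovers to
51% by 24 h, while the cell index bottoms at 74% — the expected
dose-dependent suppression with partial recovery for a calcium channel
blocker at this dose.

See `vignettes/cardiosens-methods.Rmd` for the model derivations, parameter
choices and generator calibration, and `inst/scripts/cardiosens-cli.R` for a
small command-line wrapper (`simulate`, `fit-eis`, `analyze-beats`).

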