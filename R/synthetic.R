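## Seeded synthetic-data generator emulating the physical device: spectra
## from the equivalent circuit, adhesion time courses, beating traces, and
## drug suppression/recovery experiments.  Every generator is a pure
## function of (parameters, seed); one global seed fans out to independent
## per-stream seeds so adding a stream never perturbs existing ones.

## stream offsets for seed fan-out
.STREAM_TRACE <- 100
.STREAM_SPECTRUM <- 200
.STREAM_COURSE <- 300

#' Simulate a noisy impedance spectrum
#'
#' Forward model plus independent proportional Gaussian perturbation on
#' the real and imaginary parts (sd = `noiseRel * |Z|` each).  With
#' `noiseRel = 0` the output is bit-identical to [circuitImpedance()];
#' a fixed seed is exactly reproducible.
#'
#' @param params a \linkS4class{CircuitParams}
#' @param freqHz frequency grid (Hz); default 60 log-spaced points over
#'   100 Hz to 2 MHz
#' @param noiseRel relative noise level (>= 0)
#' @param seed RNG seed
#' @return an \linkS4class{ImpedanceSpectrum}
#' @export
simulateSpectrum <- function(params, freqHz = defaultFrequencyGrid(),
                             noiseRel = 0, seed = 1L) {
    if (length(noiseRel) != 1L || !is.finite(noiseRel) || noiseRel < 0)
        .stopf("noiseRel must be a single non-negative number")
    sp <- circuitImpedance(params, freqHz)
    if (noiseRel == 0) return(sp)
    m <- Mod(sp@z)
    z <- .withSeed(seed, {
        complex(real = Re(sp@z) + stats::rnorm(length(m), 0, noiseRel * m),
                imaginary = Im(sp@z) + stats::rnorm(length(m), 0, noiseRel * m))
    })
    ImpedanceSpectrum(freqHz, z)
}

#' Default adhesion-course parameters
#'
#' Baseline circuit of a freshly seeded, sparse cardiomyocyte layer
#' (R_p = 5 kOhm, C_p = 1 nF; series and double-layer elements as in
#' [defaultCircuitParams()]) and the calibrated normalized-resistance
#' trajectory: linear-like rise to 118% of the t = 0 value at 36 h,
#' settling near 113% from 48 h onward.  Sampling every 3 h for 72 h,
#' noiseless by default.
#'
#' @param baseline \linkS4class{CircuitParams} at seeding time
#' @param keyframes (time_h, percent) matrix, first row (0, 100)
#' @param samplingIntervalH acquisition spacing (h)
#' @param durationH monitored duration (h)
#' @param noiseRel relative spectral noise
#' @return an \linkS4class{AdhesionCourseParams}
#' @rdname AdhesionCourseParams-class
#' @export
adhesionCourseParams <- function(
        baseline = CircuitParams(rs = 5177, q = 5.01e-8, n = 0.705,
                                 rp = 5000, cp = 1.0e-9),
        keyframes = cbind(time_h = c(0, 36, 48, 72),
                          percent = c(100, 118, 113, 113)),
        samplingIntervalH = 3, durationH = 72, noiseRel = 0) {
    new("AdhesionCourseParams", baseline = baseline, keyframes = keyframes,
        samplingIntervalH = samplingIntervalH, durationH = durationH,
        noiseRel = noiseRel)
}

## impedance of the circuit with the cell branch scaled by s, at one freq
.zScaled <- function(p, s, freqHz) {
    w <- 2 * pi * freqHz
    rp <- p@rp * s
    p@rs + cpeImpedance(p@q, p@n, freqHz) +
        if (s > 0) rp / (1 + 1i * w * rp * p@cp) else 0 + 0i
}

## cell-free (pre-seeding) impedance: series + double layer only
.baselineZ <- function(p, freqHz) {
    p@rs + cpeImpedance(p@q, p@n, freqHz)
}

## Solve for the R_p scale factor s that puts the resistance (real part)
## at `freqHz` on `targetOhm`.  Re(Z) grows with s until
## omega R_p s C_p = 1; the solver works on that monotone branch.
.solveScaleResistance <- function(p, freqHz, targetOhm) {
    w <- 2 * pi * freqHz
    sMax <- 1 / (w * p@rp * p@cp)
    g <- function(s) Re(.zScaled(p, s, freqHz)) - targetOhm
    if (g(sMax) < 0)
        .stopf("target resistance %.4g Ohm unreachable by scaling R_p", targetOhm)
    stats::uniroot(g, c(0, sMax), tol = 1e-12)$root
}

## Solve for the R_p scale s in [0, 1] that puts |Z| at `freqHz` on
## `targetOhm` (|Z| is monotone increasing in s on [0, 1] for the
## calibrated parameter region).
.solveScaleMagnitude <- function(p, freqHz, targetOhm) {
    g <- function(s) Mod(.zScaled(p, s, freqHz)) - targetOhm
    if (g(1) < -1e-9 * targetOhm)
        .stopf("target |Z| %.4g Ohm above the pre-drug value: not representable",
               targetOhm)
    if (g(1) <= 0) return(1)
    stats::uniroot(g, c(0, 1), tol = 1e-12)$root
}

#' Simulate a 72-h adhesion time course
#'
#' Emulates cell attachment and spreading after seeding: the
#' cell-electrode resistance R_p is rescaled over time so that the
#' normalized resistance at the monitoring frequency follows the monotone
#' piecewise-cubic interpolation of the calibration keyframes (default:
#' 100% at 0 h, 118% at 36 h, stable near 113% from 48 h).  Acquisitions
#' are emitted every `samplingIntervalH` hours.
#'
#' @param params an \linkS4class{AdhesionCourseParams}
#' @param monitorFreqHz requested monitoring frequency (Hz, default 5 kHz,
#'   within the sensitive band of the assay); the nearest frequency of
#'   `freqGrid` is used
#' @param freqGrid the acquisition frequency grid (Hz)
#' @param seed RNG seed (used only when `noiseRel > 0`)
#' @return an \linkS4class{ImpedanceTimeCourse}; the monitoring frequency
#'   actually used is available via `freqHz()`
#' @examples
#' course <- simulateAdhesionCourse()
#' nr <- normalizedResistanceCourse(course)
#' nr[nr$time_h %in% c(0, 36, 72), ]
#' @export
simulateAdhesionCourse <- function(params = adhesionCourseParams(),
                                   monitorFreqHz = 5000,
                                   freqGrid = defaultFrequencyGrid(),
                                   seed = 1L) {
    validObject(params)
    fMon <- freqGrid[which.min(abs(freqGrid - monitorFreqHz))]
    times <- seq(0, params@durationH, by = params@samplingIntervalH)
    pct <- .keyframeFun(params@keyframes)(times)
    p <- params@baseline
    r0 <- Re(.zScaled(p, 1, fMon))
    z <- vapply(seq_along(times), function(i) {
        s <- if (times[i] == 0) 1 else
            .solveScaleResistance(p, fMon, pct[i] / 100 * r0)
        zi <- .zScaled(p, s, fMon)
        if (params@noiseRel > 0) {
            zi <- .withSeed(.streamSeed(seed, .STREAM_COURSE + i), {
                m <- Mod(zi)
                complex(real = Re(zi) + stats::rnorm(1, 0, params@noiseRel * m),
                        imaginary = Im(zi) + stats::rnorm(1, 0, params@noiseRel * m))
            })
        }
        zi
    }, complex(1))
    ImpedanceTimeCourse(times, z, fMon, baselineZ = .baselineZ(p, fMon))
}

#' Day-profile defaults for the maturation series
#'
#' Synthetic per-day beating parameters for the post-synchronization
#' maturation window (days 4-7 after seeding): amplitude grows in the
#' calibrated ratios 100 : 166.4 : 243.56 : 400 while the spontaneous rate
#' falls and the beat widens.  The frequencies and durations are synthetic
#' defaults encoding the qualitative trends (rate decreases, duration
#' increases with maturation); only the amplitude ratios are calibrated
#' landmarks.
#'
#' @param day integer 4-7
#' @return list with elements `amplitude` (m), `frequency` (Hz),
#'   `duration` (s)
#' @export
dayProfile <- function(day) {
    profiles <- list(
        `4` = list(amplitude = 2.5e-6, frequency = 3.0, duration = 0.25),
        `5` = list(amplitude = 4.16e-6, frequency = 2.5, duration = 0.30),
        `6` = list(amplitude = 6.089e-6, frequency = 2.2, duration = 0.35),
        `7` = list(amplitude = 10.0e-6, frequency = 1.8, duration = 0.40))
    key <- as.character(day)
    if (is.null(profiles[[key]])) .stopf("dayProfile is defined for days 4-7")
    profiles[[key]]
}

## Asymmetric beat pulse on [0, d]: raised-cosine upstroke over the first
## third, then a truncated-shifted exponential relaxation (rise:decay =
## 1:2) reaching exactly zero at d (compact support).
.beatPulse <- function(tt, d) {
    tr <- d / 3
    tau <- (d - tr) / 3
    y <- numeric(length(tt))
    i1 <- tt >= 0 & tt < tr
    y[i1] <- 0.5 * (1 - cos(pi * tt[i1] / tr))
    i2 <- tt >= tr & tt <= d
    e0 <- exp(-(d - tr) / tau)
    y[i2] <- (exp(-(tt[i2] - tr) / tau) - e0) / (1 - e0)
    y
}

#' Simulate a beating displacement trace
#'
#' Sum of asymmetric beat pulses (raised-cosine upstroke, exponential
#' relaxation, rise:decay 1:2 within the nominal duration) at intervals
#' 1/frequency perturbed by lognormal jitter with the given coefficient of
#' variation, plus additive Gaussian instrument noise.  With
#' `jitterCV = 0` and `noiseSd = 0` the peaks are exactly periodic.
#'
#' @param amplitude peak displacement (m), > 0; see [dayProfile()] for the
#'   maturation-series defaults
#' @param frequency nominal beating rate (Hz), > 0
#' @param duration nominal single-beat duration (s)
#' @param lengthS trace length (s); must cover at least 3 beat periods
#' @param samplingRate sampling rate (Hz), >= 500 so that 150 ms features
#'   are resolved
#' @param noiseSd Gaussian noise sd (m); default 50 nm, typical vibrometer
#'   jitter below the 120 nm resolution floor
#' @param jitterCV lognormal inter-beat-interval CV; default 0.05, a
#'   physiological beat-to-beat variability for synchronized monolayers
#' @param seed RNG seed
#' @param startTime time of the first sample (s)
#' @return a \linkS4class{DisplacementTrace}
#' @export
simulateBeatingTrace <- function(amplitude, frequency, duration = 0.25,
                                 lengthS = 10, samplingRate = 500,
                                 noiseSd = 50e-9, jitterCV = 0.05,
                                 seed = 1L, startTime = 0) {
    if (amplitude <= 0 || frequency <= 0)
        .stopf("amplitude and frequency must be positive")
    if (duration <= 0) .stopf("duration must be positive")
    if (samplingRate < 500)
        .stopf("samplingRate must be >= 500 Hz to resolve 150 ms beat features")
    if (lengthS < 3 / frequency)
        .stopf("trace length must cover at least 3 beat periods")
    n <- as.integer(round(lengthS * samplingRate))
    t <- (seq_len(n) - 1L) / samplingRate
    nBeats <- as.integer(ceiling(lengthS * frequency)) + 1L
    .withSeed(seed, {
        intervals <- if (jitterCV > 0) {
            sdlog <- sqrt(log(1 + jitterCV^2))
            stats::rlnorm(nBeats, meanlog = log(1 / frequency) - sdlog^2 / 2,
                          sdlog = sdlog)
        } else rep(1 / frequency, nBeats)
        starts <- 0.5 / frequency + cumsum(c(0, intervals[-nBeats]))
        y <- numeric(n)
        for (s in starts) {
            if (s > lengthS) break
            idx <- which(t >= s & t <= s + duration)
            y[idx] <- y[idx] + amplitude * .beatPulse(t[idx] - s, duration)
        }
        if (noiseSd > 0) y <- y + stats::rnorm(n, 0, noiseSd)
        DisplacementTrace(samplingRate, y, startTime = startTime)
    })
}

## flat (beat-free) trace with optional noise, for fully suppressed states
.flatTrace <- function(lengthS, samplingRate, noiseSd, seed, startTime = 0) {
    n <- as.integer(round(lengthS * samplingRate))
    y <- if (noiseSd > 0) .withSeed(seed, stats::rnorm(n, 0, noiseSd))
         else numeric(n)
    DisplacementTrace(samplingRate, y, startTime = startTime)
}

#' Simulate a drug exposure experiment
#'
#' Applies calibrated drug-effect keyframes to a pre-drug beating state:
#' at each timepoint the beat amplitude is scaled by the interpolated
#' force percentage, the cell-electrode resistance R_p is rescaled so the
#' cell index at the monitoring frequency follows the interpolated CI
#' percentage, and (where calibrated, e.g. E-4031 30 nmol/L) the beat
#' duration and inter-beat jitter are inflated by their profiles.
#' Timepoint 0 is the unperturbed pre-drug state.  Doses missing from the
#' calibration table are interpolated in log-dose with a warning;
#' timepoints beyond the last keyframe raise an error (no extrapolation).
#'
#' The displacement and impedance channels use independent noise streams:
#' perturbing one channel's noise parameters never changes the other
#' channel's output (the two readouts are physically independent).
#'
#' @param drug `"verapamil"` or `"e4031"`
#' @param doseNmolL dose (nmol/L)
#' @param timepointsH timepoints after dosing (h); must start at 0
#' @param keyframes a \linkS4class{DrugEffectKeyframes}; defaults to the
#'   packaged calibration for `drug`
#' @param predrug pre-drug beating profile (list with `amplitude`,
#'   `frequency`, `duration`), default [dayProfile()] day 7
#' @param circuit pre-drug \linkS4class{CircuitParams}
#' @param monitorFreqHz requested monitoring frequency (Hz); nearest
#'   `freqGrid` point is used
#' @param freqGrid spectrum acquisition grid (Hz)
#' @param lengthS,samplingRate trace length (s) and sampling rate (Hz)
#' @param noiseSd trace noise sd (m); 0 disables
#' @param jitterCV pre-drug inter-beat interval CV
#' @param noiseRel relative spectral noise; 0 disables
#' @param seed global seed, fanned out per stream
#' @return a \linkS4class{DrugExperiment}
#' @examples
#' exp <- applyDrugModel("verapamil", 300, noiseSd = 0, jitterCV = 0)
#' analyzeDrugExperiment(exp)
#' @export
applyDrugModel <- function(drug = c("verapamil", "e4031"), doseNmolL,
                           timepointsH = seq(0, 24, by = 2),
                           keyframes = drugKeyframes(drug),
                           predrug = dayProfile(7),
                           circuit = defaultCircuitParams(),
                           monitorFreqHz = 5000,
                           freqGrid = defaultFrequencyGrid(),
                           lengthS = 15, samplingRate = 500,
                           noiseSd = 50e-9, jitterCV = 0.05,
                           noiseRel = 0.005, seed = 1L) {
    drug <- match.arg(drug)
    validObject(keyframes)
    if (length(timepointsH) < 1L || timepointsH[1] != 0)
        .stopf("timepointsH must start at 0 (the pre-drug state)")
    if (any(diff(timepointsH) <= 0))
        .stopf("timepointsH must be strictly increasing")

    forcePct <- .evalKeyframes(keyframes@force, doseNmolL, timepointsH, "force")
    ciPct <- .evalKeyframes(keyframes@ci, doseNmolL, timepointsH, "ci")
    durFac <- .evalKeyframes(keyframes@durationFactor, doseNmolL, timepointsH,
                             "durationFactor", fallback = 1)
    jitFac <- .evalKeyframes(keyframes@jitterFactor, doseNmolL, timepointsH,
                             "jitterFactor", fallback = 1)

    fMon <- freqGrid[which.min(abs(freqGrid - monitorFreqHz))]
    z0 <- .baselineZ(circuit, fMon)
    ci0 <- (Mod(.zScaled(circuit, 1, fMon)) - Mod(z0)) / Mod(z0)

    traces <- vector("list", length(timepointsH))
    spectra <- vector("list", length(timepointsH))
    zCourse <- complex(length(timepointsH))
    for (i in seq_along(timepointsH)) {
        amp <- predrug$amplitude * forcePct[i] / 100
        tSeed <- .streamSeed(seed, .STREAM_TRACE + i)
        traces[[i]] <- if (amp < predrug$amplitude * 1e-6)
            .flatTrace(lengthS, samplingRate, noiseSd, tSeed)
        else
            simulateBeatingTrace(amp, predrug$frequency,
                                 predrug$duration * durFac[i],
                                 lengthS, samplingRate, noiseSd,
                                 jitterCV * jitFac[i], seed = tSeed)
        targetMod <- Mod(z0) * (1 + ci0 * ciPct[i] / 100)
        s <- if (abs(ciPct[i] - 100) < 1e-12) 1 else
            .solveScaleMagnitude(circuit, fMon, targetMod)
        pScaled <- CircuitParams(circuit@rs, circuit@q, circuit@n,
                                 max(circuit@rp * s, 1e-6), circuit@cp)
        spectra[[i]] <- simulateSpectrum(pScaled, freqGrid, noiseRel,
                                         seed = .streamSeed(seed, .STREAM_SPECTRUM + i))
        iMon <- which.min(abs(freqGrid - fMon))
        zCourse[i] <- spectra[[i]]@z[iMon]
    }
    new("DrugExperiment", drug = drug, doseNmolL = doseNmolL,
        timepointsH = as.numeric(timepointsH), traces = traces,
        spectra = spectra,
        ciCourse = ImpedanceTimeCourse(timepointsH, zCourse, fMon,
                                       baselineZ = z0))
}
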