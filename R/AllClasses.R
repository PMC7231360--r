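#' @import methods
NULL

## ---------------------------------------------------------------------------
## Device geometry
## ---------------------------------------------------------------------------

#' Interdigitated electrode (IDE) geometry
#'
#' Finger dimensions and count of a two-comb interdigitated electrode array.
#' All lengths are in SI meters.  The geometry determines the cell constant
#' (see [cellConstant()]), the reciprocal-length factor that converts a
#' measured resistance into a medium resistivity; low cell constants give
#' high sensitivity in cell-substrate impedance sensing.
#'
#' @slot fingerWidth electrode finger width W (m)
#' @slot fingerSpacing spacing S between adjacent fingers (m)
#' @slot fingerLength finger length L (m)
#' @slot nFingers total number of fingers N (>= 2)
#' @export
setClass("IDEGeometry", representation(
    fingerWidth = "numeric",
    fingerSpacing = "numeric",
    fingerLength = "numeric",
    nFingers = "numeric"
))

setValidity("IDEGeometry", function(object) {
    msg <- character()
    for (s in c("fingerWidth", "fingerSpacing", "fingerLength")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, paste0(s, " must be a single positive finite number"))
    }
    n <- object@nFingers
    if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
        msg <- c(msg, "nFingers must be an integer >= 2 (cell constant divides by N - 1)")
    if (length(msg)) msg else TRUE
})

#' @param fingerWidth,fingerSpacing,fingerLength,nFingers see slots.
#' @return `IDEGeometry()` returns an \linkS4class{IDEGeometry} object.
#' @rdname IDEGeometry-class
#' @examples
#' geom <- IDEGeometry(fingerWidth = 100e-6, fingerSpacing = 100e-6,
#'                     fingerLength = 2e-3, nFingers = 30)
#' cellConstant(geom)
#' @export
IDEGeometry <- function(fingerWidth, fingerSpacing, fingerLength, nFingers) {
    new("IDEGeometry", fingerWidth = as.numeric(fingerWidth),
        fingerSpacing = as.numeric(fingerSpacing),
        fingerLength = as.numeric(fingerLength),
        nFingers = as.numeric(nFingers))
}

#' Rectangular cantilever specification
#'
#' Geometry and material of an end-loaded rectangular cantilever used as the
#' contraction-force transducer.  If `springConstant` is not supplied it is
#' computed from the standard closed form k = E w t^3 / (4 L^3).
#'
#' @slot lengthM cantilever length (m)
#' @slot widthM cantilever width (m)
#' @slot thicknessM cantilever thickness (m)
#' @slot youngsModulus Young's modulus E of the beam material (Pa); defaults
#'   to 2.0 GPa, a standard literature value for SU-8 photoresist.
#' @slot springConstant stiffness k (N/m)
#' @export
setClass("CantileverSpec", representation(
    lengthM = "numeric",
    widthM = "numeric",
    thicknessM = "numeric",
    youngsModulus = "numeric",
    springConstant = "numeric"
))

setValidity("CantileverSpec", function(object) {
    msg <- character()
    for (s in c("lengthM", "widthM", "thicknessM", "youngsModulus", "springConstant")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, paste0(s, " must be a single positive finite number"))
    }
    if (length(msg)) msg else TRUE
})

#' @param lengthM,widthM,thicknessM,youngsModulus,springConstant see slots;
#'   `springConstant` is optional and overrides the beam formula when given.
#' @return `CantileverSpec()` returns a \linkS4class{CantileverSpec} object.
#' @rdname CantileverSpec-class
#' @examples
#' spec <- CantileverSpec(6e-3, 2e-3, 15e-6)
#' springConstant(spec)  # 0.015625 N/m
#' @export
CantileverSpec <- function(lengthM, widthM, thicknessM, youngsModulus = 2.0e9,
                           springConstant = NULL) {
    if (is.null(springConstant)) {
        if (any(c(lengthM, widthM, thicknessM, youngsModulus) <= 0) ||
            any(!is.finite(c(lengthM, widthM, thicknessM, youngsModulus))))
            stop("invalid cantilever geometry: all dimensions and E must be positive")
        springConstant <- youngsModulus * widthM * thicknessM^3 / (4 * lengthM^3)
    }
    new("CantileverSpec", lengthM = as.numeric(lengthM), widthM = as.numeric(widthM),
        thicknessM = as.numeric(thicknessM), youngsModulus = as.numeric(youngsModulus),
        springConstant = as.numeric(springConstant))
}

## ---------------------------------------------------------------------------
## Impedance domain
## ---------------------------------------------------------------------------

#' Equivalent-circuit parameters
#'
#' Lumped parameters of the two-electrode cell-substrate sensing circuit:
#' a series resistance R_s (solution + electrode + connector), a
#' constant-phase element (CPE, magnitude Q and exponent n) for the
#' electrode double layer, and a parallel RC branch (R_p, C_p) for the
#' cell-electrode interface.  The circuit topology used throughout is
#' R_s in series with the CPE in series with (R_p || C_p).
#'
#' @slot rs series resistance (Ohm)
#' @slot q CPE magnitude Q (S s^n)
#' @slot n CPE exponent, 0 < n <= 1 (n = 1 is an ideal capacitor)
#' @slot rp cell-electrode resistance (Ohm)
#' @slot cp cell-electrode capacitance (F)
#' @export
setClass("CircuitParams", representation(
    rs = "numeric", q = "numeric", n = "numeric", rp = "numeric", cp = "numeric"
))

setValidity("CircuitParams", function(object) {
    msg <- character()
    for (s in c("rs", "q", "rp", "cp")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, paste0(s, " must be a single positive finite number"))
    }
    n <- object@n
    if (length(n) != 1L || !is.finite(n) || n <= 0 || n > 1)
        msg <- c(msg, "CPE exponent n must satisfy 0 < n <= 1")
    if (length(msg)) msg else TRUE
})

#' @param rs,q,n,rp,cp see slots.
#' @return `CircuitParams()` returns a \linkS4class{CircuitParams} object.
#' @rdname CircuitParams-class
#' @export
CircuitParams <- function(rs, q, n, rp, cp) {
    new("CircuitParams", rs = as.numeric(rs), q = as.numeric(q),
        n = as.numeric(n), rp = as.numeric(rp), cp = as.numeric(cp))
}

#' One impedance spectrum acquisition
#'
#' Paired frequency / complex-impedance arrays from a single sweep.  The
#' complex convention is Z = Z' + jZ'' with capacitive Z'' < 0; spectra
#' produced by the forward model satisfy Im(Z) <= 0 at every frequency.
#'
#' @slot freqHz strictly ascending frequencies (Hz)
#' @slot z complex impedance (Ohm), same length as `freqHz`
#' @export
setClass("ImpedanceSpectrum", representation(
    freqHz = "numeric", z = "complex"
))

setValidity("ImpedanceSpectrum", function(object) {
    f <- object@freqHz
    msg <- character()
    if (length(f) < 1L) msg <- c(msg, "spectrum must contain at least one point")
    if (any(!is.finite(f)) || any(f <= 0)) msg <- c(msg, "frequencies must be positive and finite")
    if (length(f) > 1L && any(diff(f) <= 0)) msg <- c(msg, "frequencies must be strictly ascending")
    if (length(object@z) != length(f)) msg <- c(msg, "freqHz and z lengths differ")
    if (length(msg)) msg else TRUE
})

#' @param freqHz,z see slots.
#' @return `ImpedanceSpectrum()` returns an \linkS4class{ImpedanceSpectrum}.
#' @rdname ImpedanceSpectrum-class
#' @export
ImpedanceSpectrum <- function(freqHz, z) {
    new("ImpedanceSpectrum", freqHz = as.numeric(freqHz), z = as.complex(z))
}

#' Single-frequency impedance time course
#'
#' Complex impedance at a fixed monitoring frequency sampled over time
#' (hours), together with the pre-seeding (cell-free) baseline impedance
#' Z_0 at the same frequency.  The baseline anchors the cell index
#' CI = (|Z| - |Z_0|) / |Z_0|; the resistance channel is Re(Z).
#'
#' @slot timesH non-decreasing acquisition times (h)
#' @slot z complex impedance at the monitoring frequency (Ohm)
#' @slot monitorFreqHz monitoring frequency (Hz)
#' @slot baselineZ pre-seeding baseline impedance Z_0 (complex Ohm)
#' @export
setClass("ImpedanceTimeCourse", representation(
    timesH = "numeric", z = "complex", monitorFreqHz = "numeric",
    baselineZ = "complex"
))

setValidity("ImpedanceTimeCourse", function(object) {
    msg <- character()
    t <- object@timesH
    if (length(t) < 1L) msg <- c(msg, "time course must contain at least one point")
    if (any(!is.finite(t))) msg <- c(msg, "times must be finite")
    if (length(t) > 1L && any(diff(t) < 0)) msg <- c(msg, "times must be non-decreasing")
    if (length(object@z) != length(t)) msg <- c(msg, "timesH and z lengths differ")
    if (length(object@monitorFreqHz) != 1L || object@monitorFreqHz <= 0)
        msg <- c(msg, "monitorFreqHz must be a single positive number")
    if (length(object@baselineZ) != 1L || Mod(object@baselineZ) <= 0)
        msg <- c(msg, "baselineZ must be a single non-zero complex impedance")
    if (length(msg)) msg else TRUE
})

#' @param timesH,z,monitorFreqHz,baselineZ see slots; `baselineZ` defaults to
#'   the first entry of `z` (a course whose first row is the baseline).
#' @return `ImpedanceTimeCourse()` returns an \linkS4class{ImpedanceTimeCourse}.
#' @rdname ImpedanceTimeCourse-class
#' @export
ImpedanceTimeCourse <- function(timesH, z, monitorFreqHz, baselineZ = z[1]) {
    new("ImpedanceTimeCourse", timesH = as.numeric(timesH), z = as.complex(z),
        monitorFreqHz = as.numeric(monitorFreqHz), baselineZ = as.complex(baselineZ))
}

#' Result of an equivalent-circuit fit
#'
#' @slot params fitted \linkS4class{CircuitParams}
#' @slot stdErrors named per-parameter standard errors (same units as the
#'   parameters), derived from the weighted Jacobian at the optimum
#' @slot residualNorm square root of the weighted sum of squared complex
#'   residuals at the optimum
#' @slot converged whether any start converged
#' @slot nStartsUsed number of optimizer starts performed
#' @slot weighting residual weighting used ("modulus" or "unit")
#' @export
setClass("FitResult", representation(
    params = "CircuitParams", stdErrors = "numeric", residualNorm = "numeric",
    converged = "logical", nStartsUsed = "integer", weighting = "character"
))

setValidity("FitResult", function(object) {
    msg <- character()
    if (length(object@residualNorm) != 1L || !is.finite(object@residualNorm) ||
        object@residualNorm < 0)
        msg <- c(msg, "residualNorm must be a single non-negative number")
    if (!identical(sort(names(object@stdErrors)), sort(c("rs", "q", "n", "rp", "cp"))))
        msg <- c(msg, "stdErrors must be named rs, q, n, rp, cp")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Displacement / beat domain
## ---------------------------------------------------------------------------

#' Cantilever tip displacement trace
#'
#' Uniformly sampled out-of-plane cantilever tip displacement, as measured
#' by a laser vibrometer.  The default `noiseFloor` of 120 nm is the
#' minimum displacement resolvable by the vibrometer readout; beat
#' detection never accepts excursions below it.
#'
#' @slot samplingRate sampling rate (Hz)
#' @slot samples displacement samples (m)
#' @slot startTime time of the first sample (s)
#' @slot noiseFloor instrument noise floor (m)
#' @export
setClass("DisplacementTrace", representation(
    samplingRate = "numeric", samples = "numeric", startTime = "numeric",
    noiseFloor = "numeric"
))

setValidity("DisplacementTrace", function(object) {
    msg <- character()
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a single positive number")
    if (length(object@samples) < 2L)
        msg <- c(msg, "trace must contain at least 2 samples")
    if (length(object@noiseFloor) != 1L || !is.finite(object@noiseFloor) ||
        object@noiseFloor < 0)
        msg <- c(msg, "noiseFloor must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' @param samplingRate,samples,startTime,noiseFloor see slots.
#' @return `DisplacementTrace()` returns a \linkS4class{DisplacementTrace}.
#' @rdname DisplacementTrace-class
#' @export
DisplacementTrace <- function(samplingRate, samples, startTime = 0,
                              noiseFloor = 120e-9) {
    new("DisplacementTrace", samplingRate = as.numeric(samplingRate),
        samples = as.numeric(samples), startTime = as.numeric(startTime),
        noiseFloor = as.numeric(noiseFloor))
}

#' Per-session beat summary
#'
#' Aggregate contraction metrics over one recording: beat count, beating
#' frequency (reciprocal of the median inter-beat interval), mean amplitude
#' above local baseline, mean tip force (spring constant times mean
#' amplitude), mean beat duration at the detection threshold fraction, and
#' the coefficient of variation of inter-beat intervals (an irregularity
#' index).  Frequency and interval CV are `NA` when fewer than two beats
#' were detected; amplitude and force are 0 for a beat-free trace.
#'
#' @slot beatCount number of detected beats
#' @slot beatingFrequency beats per second (Hz), `NA` if < 2 beats
#' @slot meanAmplitude mean beat amplitude (m)
#' @slot meanForce mean contraction force (N)
#' @slot meanDuration mean beat duration (s), `NA` if none measurable
#' @slot intervalCV sd/mean of inter-beat intervals, `NA` if < 2 intervals
#' @export
setClass("BeatSummary", representation(
    beatCount = "integer", beatingFrequency = "numeric", meanAmplitude = "numeric",
    meanForce = "numeric", meanDuration = "numeric", intervalCV = "numeric"
))

#' Dose-response curve for one drug exposure
#'
#' Force and cell-index channels over time after dosing, each expressed as
#' percent of the last pre-dosing measurement (100% at t = 0).  Percentages
#' are not clipped; values above 100 represent hypercontractility.
#'
#' @slot drug drug name
#' @slot doseMolL dose (mol/L)
#' @slot timesH time after dosing (h), starting at 0
#' @slot forcePct contraction force, % of pre-drug
#' @slot ciPct cell index, % of pre-drug
#' @export
setClass("DoseResponseCurve", representation(
    drug = "character", doseMolL = "numeric", timesH = "numeric",
    forcePct = "numeric", ciPct = "numeric"
))

setValidity("DoseResponseCurve", function(object) {
    msg <- character()
    t <- object@timesH
    if (length(t) < 1L || t[1] != 0) msg <- c(msg, "time grid must start at 0")
    if (length(object@forcePct) != length(t) || length(object@ciPct) != length(t))
        msg <- c(msg, "channel lengths must match the time grid")
    if (length(t) >= 1L &&
        (abs(object@forcePct[1] - 100) > 1e-9 || abs(object@ciPct[1] - 100) > 1e-9))
        msg <- c(msg, "both channels must equal 100% at t = 0")
    if (any(stats::na.omit(c(object@forcePct, object@ciPct)) < 0))
        msg <- c(msg, "percentages must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Suppression/recovery profile of one curve channel
#'
#' @slot minimumPct minimum value over the time grid (%)
#' @slot timeOfMinimumH time at which the minimum occurs (h)
#' @slot atHorizonPct value at the recovery horizon (%)
#' @slot horizonH the horizon used (h)
#' @slot recovered `TRUE` when the horizon value exceeds the minimum by more
#'   than the recovery tolerance (2 percentage points by default)
#' @export
setClass("RecoveryProfile", representation(
    minimumPct = "numeric", timeOfMinimumH = "numeric", atHorizonPct = "numeric",
    horizonH = "numeric", recovered = "logical"
))

## ---------------------------------------------------------------------------
## Synthetic-data domain
## ---------------------------------------------------------------------------

#' Drug-effect keyframes
#'
#' Time-anchored per-dose suppression/recovery fractions that the synthetic
#' generator interpolates (monotone piecewise-cubic) to emulate a drug
#' exposure.  `force` and `ci` are named lists keyed by dose in nmol/L;
#' each element is a two-column matrix (time_h, percent) whose first row is
#' (0, 100).  `durationFactor` and `jitterFactor` are optional per-dose
#' profiles (time_h, multiplier) for beat-duration widening (a QT-like
#' prolongation proxy) and inter-beat jitter inflation.
#'
#' @slot drug drug name
#' @slot force named list of (time_h, percent) matrices, one per dose
#' @slot ci named list of (time_h, percent) matrices, one per dose
#' @slot durationFactor named list of (time_h, factor) matrices (may be empty)
#' @slot jitterFactor named list of (time_h, factor) matrices (may be empty)
#' @export
setClass("DrugEffectKeyframes", representation(
    drug = "character", force = "list", ci = "list",
    durationFactor = "list", jitterFactor = "list"
))

.checkKeyframeList <- function(lst, what, requireStart100 = TRUE) {
    msg <- character()
    for (d in names(lst)) {
        m <- lst[[d]]
        if (!is.matrix(m) || ncol(m) != 2L) {
            msg <- c(msg, paste0(what, "[", d, "] must be a 2-column matrix"))
            next
        }
        if (requireStart100 && (m[1, 1] != 0 || m[1, 2] != 100))
            msg <- c(msg, paste0(what, "[", d, "] must start at (0, 100)"))
        if (nrow(m) > 1L && any(diff(m[, 1]) <= 0))
            msg <- c(msg, paste0(what, "[", d, "] times must be strictly increasing"))
        if (any(m[, 2] < 0))
            msg <- c(msg, paste0(what, "[", d, "] values must be >= 0"))
    }
    msg
}

setValidity("DrugEffectKeyframes", function(object) {
    msg <- c(.checkKeyframeList(object@force, "force"),
             .checkKeyframeList(object@ci, "ci"),
             .checkKeyframeList(object@durationFactor, "durationFactor", FALSE),
             .checkKeyframeList(object@jitterFactor, "jitterFactor", FALSE))
    if (length(msg)) msg else TRUE
})

#' Adhesion-course generator parameters
#'
#' Parameters of the 72-h adhesion simulation: a baseline circuit (sparse,
#' freshly seeded cells) whose cell-electrode resistance R_p is rescaled
#' over time so that the normalized resistance at the monitoring frequency
#' follows a monotone piecewise-cubic interpolation of `keyframes`.
#'
#' @slot baseline \linkS4class{CircuitParams} at seeding time
#' @slot keyframes two-column matrix (time_h, percent of t = 0 resistance),
#'   first row (0, 100)
#' @slot samplingIntervalH spacing between acquisitions (h)
#' @slot durationH total monitored duration (h)
#' @slot noiseRel relative spectral noise level (0 = noiseless)
#' @export
setClass("AdhesionCourseParams", representation(
    baseline = "CircuitParams", keyframes = "matrix",
    samplingIntervalH = "numeric", durationH = "numeric", noiseRel = "numeric"
))

setValidity("AdhesionCourseParams", function(object) {
    msg <- character()
    k <- object@keyframes
    if (!is.matrix(k) || ncol(k) != 2L || k[1, 1] != 0 || k[1, 2] != 100)
        msg <- c(msg, "keyframes must be a 2-column matrix starting at (0, 100)")
    else if (nrow(k) > 1L && any(diff(k[, 1]) <= 0))
        msg <- c(msg, "keyframe times must be strictly increasing")
    if (object@samplingIntervalH <= 0) msg <- c(msg, "samplingIntervalH must be > 0")
    if (object@durationH <= 0) msg <- c(msg, "durationH must be > 0")
    if (object@noiseRel < 0) msg <- c(msg, "noiseRel must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Simulated drug exposure experiment
#'
#' Output container of [applyDrugModel()]: one displacement trace and one
#' impedance spectrum per timepoint, plus the cell-index time course at the
#' monitoring frequency.  Timepoint 0 is the pre-drug state.
#'
#' @slot drug drug name
#' @slot doseNmolL dose (nmol/L)
#' @slot timepointsH timepoints after dosing (h), starting at 0
#' @slot traces list of \linkS4class{DisplacementTrace}, one per timepoint
#' @slot spectra list of \linkS4class{ImpedanceSpectrum}, one per timepoint
#' @slot ciCourse \linkS4class{ImpedanceTimeCourse} at the monitoring frequency
#' @export
setClass("DrugExperiment", representation(
    drug = "character", doseNmolL = "numeric", timepointsH = "numeric",
    traces = "list", spectra = "list", ciCourse = "ImpedanceTimeCourse"
))
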