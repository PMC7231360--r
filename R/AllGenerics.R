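#' Accessor generics
#'
#' Small accessor family for the sensing classes: `freqHz()` returns the
#' frequency grid of a spectrum, `zOhm()` the complex impedance, `timesH()`
#' acquisition times in hours, `traceSamples()` the displacement samples,
#' `samplingRateHz()` the trace sampling rate, `circuitParams()` the fitted
#' parameter object of a fit result, `stdErrors()` its standard errors,
#' `residualNorm()` its weighted residual norm and `isConverged()` its
#' convergence flag.
#'
#' @param x an object of one of the sensing classes
#' @return the slot value documented above
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("freqHz", function(x) standardGeneric("freqHz"))

#' @rdname accessors
#' @export
setGeneric("zOhm", function(x) standardGeneric("zOhm"))

#' @rdname accessors
#' @export
setGeneric("timesH", function(x) standardGeneric("timesH"))

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRateHz", function(x) standardGeneric("samplingRateHz"))

#' @rdname accessors
#' @export
setGeneric("circuitParams", function(x) standardGeneric("circuitParams"))

#' @rdname accessors
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname accessors
#' @export
setGeneric("residualNorm", function(x) standardGeneric("residualNorm"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("freqHz", "ImpedanceSpectrum", function(x) x@freqHz)

#' @rdname accessors
#' @export
setMethod("zOhm", "ImpedanceSpectrum", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("timesH", "ImpedanceTimeCourse", function(x) x@timesH)

#' @rdname accessors
#' @export
setMethod("zOhm", "ImpedanceTimeCourse", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("freqHz", "ImpedanceTimeCourse", function(x) x@monitorFreqHz)

#' @rdname accessors
#' @export
setMethod("traceSamples", "DisplacementTrace", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRateHz", "DisplacementTrace", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("circuitParams", "FitResult", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("stdErrors", "FitResult", function(x) x@stdErrors)

#' @rdname accessors
#' @export
setMethod("residualNorm", "FitResult", function(x) x@residualNorm)

#' @rdname accessors
#' @export
setMethod("isConverged", "FitResult", function(x) x@converged)

## show methods -------------------------------------------------------------

setMethod("show", "IDEGeometry", function(object) {
    cat("IDEGeometry: W =", object@fingerWidth * 1e6, "um, S =",
        object@fingerSpacing * 1e6, "um, L =", object@fingerLength * 1e3,
        "mm, N =", object@nFingers, "\n")
    cat("  cell constant K =", format(cellConstant(object), digits = 4), "cm^-1\n")
})

setMethod("show", "CantileverSpec", function(object) {
    cat(sprintf("CantileverSpec: %g mm x %g mm x %g um, E = %g GPa, k = %g N/m\n",
                object@lengthM * 1e3, object@widthM * 1e3, object@thicknessM * 1e6,
                object@youngsModulus * 1e-9, object@springConstant))
})

setMethod("show", "CircuitParams", function(object) {
    cat(sprintf(paste0("CircuitParams: R_s = %.4g Ohm, Q = %.4g S.s^n, ",
                       "n = %.4g, R_p = %.4g Ohm, C_p = %.4g F\n"),
                object@rs, object@q, object@n, object@rp, object@cp))
})

setMethod("show", "ImpedanceSpectrum", function(object) {
    f <- object@freqHz
    cat(sprintf("ImpedanceSpectrum: %d points, %.4g Hz to %.4g Hz, |Z| %.4g to %.4g Ohm\n",
                length(f), min(f), max(f), min(Mod(object@z)), max(Mod(object@z))))
})

setMethod("show", "ImpedanceTimeCourse", function(object) {
    cat(sprintf("ImpedanceTimeCourse: %d points over %.4g h at %.4g Hz (baseline |Z_0| = %.4g Ohm)\n",
                length(object@timesH), max(object@timesH) - min(object@timesH),
                object@monitorFreqHz, Mod(object@baselineZ)))
})

setMethod("show", "FitResult", function(object) {
    cat("Equivalent-circuit fit (", object@weighting, " weighting, ",
        object@nStartsUsed, " starts, ",
        if (object@converged) "converged" else "NOT CONVERGED", ")\n", sep = "")
    p <- object@params
    se <- object@stdErrors
    tab <- data.frame(
        estimate = c(p@rs, p@q, p@n, p@rp, p@cp),
        std.error = se[c("rs", "q", "n", "rp", "cp")],
        row.names = c("R_s (Ohm)", "Q (S.s^n)", "n", "R_p (Ohm)", "C_p (F)"))
    print(format(tab, digits = 5))
    cat("weighted residual norm:", format(object@residualNorm, digits = 4), "\n")
})

setMethod("show", "DisplacementTrace", function(object) {
    n <- length(object@samples)
    cat(sprintf("DisplacementTrace: %d samples at %g Hz (%.3g s), peak-to-peak %.4g um\n",
                n, object@samplingRate, n / object@samplingRate,
                (max(object@samples) - min(object@samples)) * 1e6))
})

setMethod("show", "BeatSummary", function(object) {
    cat(sprintf(paste0("BeatSummary: %d beats, %.3g Hz, mean amplitude %.4g um, ",
                       "mean force %.4g nN, mean duration %.3g s, interval CV %.3g\n"),
                object@beatCount, object@beatingFrequency,
                object@meanAmplitude * 1e6, object@meanForce * 1e9,
                object@meanDuration, object@intervalCV))
})

setMethod("show", "DoseResponseCurve", function(object) {
    cat(sprintf("DoseResponseCurve: %s at %.4g nmol/L, %d timepoints over %g h\n",
                object@drug, object@doseMolL * 1e9, length(object@timesH),
                max(object@timesH)))
    print(data.frame(time_h = object@timesH, force_pct = round(object@forcePct, 2),
                     ci_pct = round(object@ciPct, 2)), row.names = FALSE)
})

setMethod("show", "RecoveryProfile", function(object) {
    cat(sprintf("RecoveryProfile: min %.4g%% at %g h, %.4g%% at %g h horizon -> %s\n",
                object@minimumPct, object@timeOfMinimumH, object@atHorizonPct,
                object@horizonH, if (object@recovered) "recovered" else "not recovered"))
})

setMethod("show", "DrugExperiment", function(object) {
    cat(sprintf("DrugExperiment: %s at %g nmol/L, timepoints %s h\n",
                object@drug, object@doseNmolL,
                paste(object@timepointsH, collapse = ", ")))
})
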