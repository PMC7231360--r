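## File formats.  All tables are plain UTF-8 CSV with '.' decimal:
##   spectrum:     freq_hz, z_real_ohm, z_imag_ohm
##   time course:  time_h, freq_hz, z_real_ohm, z_imag_ohm  (baseline rows
##                 at time_h = 0)
##   trace:        time_s, displacement_m  (uniform grid, 1 ppm tolerance)
## Fit reports round-trip losslessly through JSON.

.requireColumns <- function(df, cols, file) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
        .stopf("%s: missing required column(s): %s", file,
               paste(missing, collapse = ", "))
    for (cl in cols) {
        v <- suppressWarnings(as.numeric(df[[cl]]))
        if (anyNA(v))
            .stopf("%s: column %s row %d is not numeric", file, cl, which(is.na(v))[1])
    }
    invisible(TRUE)
}

#' Read / write an impedance spectrum CSV
#'
#' Schema: header `freq_hz, z_real_ohm, z_imag_ohm`, one row per
#' frequency, strictly ascending.
#'
#' @param path file path
#' @return `readSpectrum()` returns an \linkS4class{ImpedanceSpectrum}.
#' @export
readSpectrum <- function(path) {
    df <- utils::read.csv(path)
    .requireColumns(df, c("freq_hz", "z_real_ohm", "z_imag_ohm"), path)
    ImpedanceSpectrum(df$freq_hz,
                      complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm))
}

#' @param spectrum an \linkS4class{ImpedanceSpectrum}
#' @rdname readSpectrum
#' @return `writeSpectrum()` returns `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
    validObject(spectrum)
    utils::write.csv(data.frame(freq_hz = spectrum@freqHz,
                                z_real_ohm = Re(spectrum@z),
                                z_imag_ohm = Im(spectrum@z)),
                     path, row.names = FALSE)
    invisible(path)
}

#' Read / write an impedance time-course CSV
#'
#' Schema: `time_h, freq_hz, z_real_ohm, z_imag_ohm` at a single
#' monitoring frequency; the first row (t = 0) is the baseline unless a
#' separate baseline is recorded in the optional `baseline_z_real_ohm` /
#' `baseline_z_imag_ohm` columns (constant per file).
#'
#' @param path file path
#' @return `readTimeCourse()` returns an \linkS4class{ImpedanceTimeCourse}.
#' @export
readTimeCourse <- function(path) {
    df <- utils::read.csv(path)
    .requireColumns(df, c("time_h", "freq_hz", "z_real_ohm", "z_imag_ohm"), path)
    if (length(unique(df$freq_hz)) != 1L)
        .stopf("%s: time course must use a single monitoring frequency", path)
    z <- complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm)
    bz <- if (all(c("baseline_z_real_ohm", "baseline_z_imag_ohm") %in% names(df)))
        complex(real = df$baseline_z_real_ohm[1],
                imaginary = df$baseline_z_imag_ohm[1]) else z[1]
    if (df$time_h[1] != 0)
        .stopf("%s: time course must contain a baseline row at time_h = 0", path)
    ImpedanceTimeCourse(df$time_h, z, df$freq_hz[1], baselineZ = bz)
}

#' @param course an \linkS4class{ImpedanceTimeCourse}
#' @rdname readTimeCourse
#' @return `writeTimeCourse()` returns `path`, invisibly.
#' @export
writeTimeCourse <- function(course, path) {
    validObject(course)
    utils::write.csv(data.frame(
        time_h = course@timesH,
        freq_hz = course@monitorFreqHz,
        z_real_ohm = Re(course@z),
        z_imag_ohm = Im(course@z),
        baseline_z_real_ohm = Re(course@baselineZ),
        baseline_z_imag_ohm = Im(course@baselineZ)),
        path, row.names = FALSE)
    invisible(path)
}

#' Read / write a displacement-trace CSV
#'
#' Schema: `time_s, displacement_m` on a uniform time grid; uniformity is
#' enforced on read with a 1 ppm tolerance on the sampling interval.
#'
#' @param path file path
#' @param noiseFloor instrument noise floor (m) to attach on read
#' @return `readTrace()` returns a \linkS4class{DisplacementTrace}.
#' @export
readTrace <- function(path, noiseFloor = 120e-9) {
    df <- utils::read.csv(path)
    .requireColumns(df, c("time_s", "displacement_m"), path)
    dt <- diff(df$time_s)
    if (length(dt) < 1L) .stopf("%s: trace needs at least 2 samples", path)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
        .stopf("%s: time grid is not uniform (1 ppm tolerance)", path)
    DisplacementTrace(1 / dt[1], df$displacement_m, startTime = df$time_s[1],
                      noiseFloor = noiseFloor)
}

#' @param trace a \linkS4class{DisplacementTrace}
#' @rdname readTrace
#' @return `writeTrace()` returns `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
    validObject(trace)
    n <- length(trace@samples)
    utils::write.csv(data.frame(
        time_s = trace@startTime + (seq_len(n) - 1L) / trace@samplingRate,
        displacement_m = trace@samples),
        path, row.names = FALSE)
    invisible(path)
}

#' Read / write an equivalent-circuit fit report
#'
#' JSON serialization of a \linkS4class{FitResult} (parameters, standard
#' errors, residual norm, convergence, settings); reading it back
#' reproduces the object losslessly.
#'
#' @param fit a \linkS4class{FitResult}
#' @param path file path
#' @return `writeFitReport()` returns `path` invisibly;
#'   `readFitReport()` returns a \linkS4class{FitResult}.
#' @export
writeFitReport <- function(fit, path) {
    p <- fit@params
    jsonlite::write_json(list(
        parameters = list(rs_ohm = p@rs, q_s_sn = p@q, n = p@n,
                          rp_ohm = p@rp, cp_f = p@cp),
        std_errors = as.list(fit@stdErrors),
        residual_norm = fit@residualNorm,
        converged = fit@converged,
        n_starts = fit@nStartsUsed,
        weighting = fit@weighting),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeFitReport
#' @export
readFitReport <- function(path) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    se <- unlist(js$std_errors)[.PAR_NAMES]
    new("FitResult",
        params = CircuitParams(js$parameters$rs_ohm, js$parameters$q_s_sn,
                               js$parameters$n, js$parameters$rp_ohm,
                               js$parameters$cp_f),
        stdErrors = se,
        residualNorm = js$residual_norm,
        converged = js$converged,
        nStartsUsed = as.integer(js$n_starts),
        weighting = js$weighting)
}
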