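#' Cell index
#'
#' ECIS cell index CI = (Z_t - Z_0) / Z_0: the cell-induced impedance
#' change relative to the pre-seeding baseline Z_0.  Both arguments are
#' impedance magnitudes at the monitoring frequency; the ratio is invariant
#' under a common rescaling of the two.
#'
#' @param zT impedance magnitude with cells (Ohm), vectorized
#' @param z0 pre-seeding baseline magnitude (Ohm), > 0
#' @return unitless cell index
#' @export
cellIndex <- function(zT, z0) {
    if (length(z0) != 1L || !is.finite(z0) || z0 <= 0)
        .stopf("baseline impedance Z_0 must be a single positive number")
    (zT - z0) / z0
}

#' Normalized resistance time course
#'
#' Resistance (real part of impedance) at the monitoring frequency,
#' expressed as percent of its value at t = 0:
#' value(t) = 100 R(t) / R(0).  This is the standard adhesion readout: as
#' cells attach and spread over the electrodes the resistance rises.
#'
#' @param course an \linkS4class{ImpedanceTimeCourse} whose grid contains
#'   a baseline entry at t = 0
#' @return `data.frame` with columns `time_h` and `percent`;
#'   `percent[time_h == 0]` is exactly 100
#' @export
normalizedResistanceCourse <- function(course) {
    validObject(course)
    i0 <- which(course@timesH == 0)
    if (length(i0) == 0L)
        .stopf("time course has no baseline entry at t = 0")
    r0 <- Re(course@z)[i0[1]]
    if (!is.finite(r0) || r0 <= 0)
        .stopf("baseline resistance at t = 0 must be positive")
    data.frame(time_h = course@timesH, percent = 100 * Re(course@z) / r0)
}

#' Normalized cell-index time course
#'
#' Cell index relative to its last pre-dosing value:
#' percent(t) = 100 CI(t) / CI(t_predrug), where CI is computed against the
#' course's pre-seeding baseline |Z_0|.  This is the impedance channel of a
#' drug-response experiment.
#'
#' @param course an \linkS4class{ImpedanceTimeCourse}
#' @param predrugTime time (h) of the pre-drug reference entry; must exist
#'   in the course grid (default 0)
#' @return `data.frame` with columns `time_h` and `percent`;
#'   `percent[time_h == predrugTime]` is exactly 100
#' @export
normalizedCICourse <- function(course, predrugTime = 0) {
    validObject(course)
    iRef <- which(course@timesH == predrugTime)
    if (length(iRef) == 0L)
        .stopf("predrug time %g h not present in the course grid", predrugTime)
    z0 <- Mod(course@baselineZ)
    ci <- cellIndex(Mod(course@z), z0)
    ciRef <- ci[iRef[1]]
    if (!is.finite(ciRef) || ciRef == 0)
        .stopf("pre-drug cell index is zero (no cells): cannot normalize")
    data.frame(time_h = course@timesH, percent = 100 * ci / ciRef)
}
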