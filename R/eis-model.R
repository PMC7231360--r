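#' Constant-phase-element impedance
#'
#' Z_CPE = 1 / (Q (j omega)^n) with omega = 2 pi f.  The modulus is
#' 1 / (Q omega^n) and the phase is a frequency-independent -n pi/2; n = 1
#' recovers an ideal capacitor of capacitance Q.
#'
#' @param q CPE magnitude Q (S s^n), > 0
#' @param n CPE exponent, 0 < n <= 1
#' @param freqHz frequency (Hz), > 0, vectorized
#' @return complex impedance (Ohm)
#' @export
cpeImpedance <- function(q, n, freqHz) {
    if (length(q) != 1L || !is.finite(q) || q <= 0)
        .stopf("CPE magnitude Q must be a single positive number")
    if (length(n) != 1L || !is.finite(n) || n <= 0 || n > 1)
        .stopf("CPE exponent n must satisfy 0 < n <= 1")
    if (any(!is.finite(freqHz)) || any(freqHz <= 0))
        .stopf("frequencies must be positive and finite")
    w <- 2 * pi * freqHz
    1 / (q * (1i * w)^n)
}

#' Equivalent-circuit forward model
#'
#' Complex impedance of the two-electrode cell-substrate sensing circuit:
#' Z(omega) = R_s + 1/(Q (j omega)^n) + R_p / (1 + j omega R_p C_p).
#' The real part is strictly decreasing in frequency, the imaginary part is
#' capacitive (<= 0) everywhere, and Re(Z) tends to R_s at high frequency.
#'
#' @param params a \linkS4class{CircuitParams}
#' @param freqHz positive, strictly ascending frequencies (Hz)
#' @return an \linkS4class{ImpedanceSpectrum}
#' @examples
#' sp <- circuitImpedance(defaultCircuitParams(), defaultFrequencyGrid())
#' plot(freqHz(sp), Mod(zOhm(sp)), log = "xy", type = "l",
#'      xlab = "f (Hz)", ylab = "|Z| (Ohm)")
#' @export
circuitImpedance <- function(params, freqHz) {
    validObject(params)
    if (length(freqHz) == 0L) .stopf("frequency list must not be empty")
    w <- 2 * pi * freqHz
    z <- params@rs + cpeImpedance(params@q, params@n, freqHz) +
        params@rp / (1 + 1i * w * params@rp * params@cp)
    ImpedanceSpectrum(freqHz, z)
}

#' Default calibration circuit parameters
#'
#' The packaged calibration parameter set for a mature cardiomyocyte layer
#' (synchronized beating stage): R_s = 5.177 kOhm, Q = 5.01e-8 S s^n,
#' n = 0.705, R_p = 40.52 kOhm, C_p = 3.29 nF.  Used as the default truth
#' for fit round-trip checks and as the pre-drug circuit of the drug
#' simulator.
#'
#' @return a \linkS4class{CircuitParams}
#' @export
defaultCircuitParams <- function() {
    CircuitParams(rs = 5177, q = 5.01e-8, n = 0.705, rp = 40520, cp = 3.29e-9)
}

#' Default acquisition frequency grid
#'
#' Log-spaced sweep over the instrument range, 100 Hz to 2 MHz.
#'
#' @param n number of points (default 60)
#' @return frequencies (Hz), strictly ascending
#' @export
defaultFrequencyGrid <- function(n = 60) {
    10^seq(log10(100), log10(2e6), length.out = n)
}
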