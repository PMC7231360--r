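## Fixtures built in code.

## Triangle-pulse trace: symmetric triangular beats with known geometry,
## peaks aligned to the sample grid so amplitudes are exact.
triangleTrace <- function(amplitude = 5e-6, period = 1, baseWidth = 0.5,
                          lengthS = 10, fs = 500, offset = 0) {
    t <- (seq_len(lengthS * fs) - 1) / fs
    peaks <- seq(0.75, by = period, length.out = floor((lengthS - 1) / period) + 1)
    y <- rep(offset, length(t))
    for (p in peaks) {
        y <- y + amplitude * pmax(0, 1 - abs(t - p) / (baseWidth / 2))
    }
    DisplacementTrace(fs, y)
}

## printed-calibration standard deviations, used for parameter draws
calibSds <- c(rs = 1210, q = 0.85e-8, n = 0.02, rp = 7440, cp = 0.56e-9)

drawParams <- function(truth = defaultCircuitParams(), sds = calibSds) {
    CircuitParams(truth@rs + runif(1, -1, 1) * sds[["rs"]],
                  truth@q + runif(1, -1, 1) * sds[["q"]],
                  truth@n + runif(1, -1, 1) * sds[["n"]],
                  truth@rp + runif(1, -1, 1) * sds[["rp"]],
                  truth@cp + runif(1, -1, 1) * sds[["cp"]])
}

paramVec <- function(p) c(rs = p@rs, q = p@q, n = p@n, rp = p@rp, cp = p@cp)

## seeded evaluation that restores the caller's RNG stream
.withSeedTest <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv())) 
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}
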