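truth <- defaultCircuitParams()
cleanSpectrum <- circuitImpedance(truth, defaultFrequencyGrid(60))

test_that("heuristic guess lands within one order of magnitude of truth", {
    g <- paramVec(initialGuess(cleanSpectrum))
    tv <- paramVec(truth)
    ratio <- g / tv
    expect_true(all(ratio > 0.1 & ratio < 10))
})

test_that("heuristic guess handles a flat resistive spectrum", {
    f <- defaultFrequencyGrid(30)
    g <- initialGuess(ImpedanceSpectrum(f, complex(real = rep(800, 30),
                                                   imaginary = rep(-1e-6, 30))))
    expect_equal(g@rs, 800, tolerance = 0.01)
    expect_lt(g@rp, 1)          # floored: no cell branch visible
    expect_true(validObject(g))
})

test_that("noiseless fit recovers the generating parameters to 1e-4", {
    fit <- fitCircuit(cleanSpectrum, nStarts = 8)
    expect_true(isConverged(fit))
    v <- paramVec(circuitParams(fit))
    expect_equal(unname(v), unname(paramVec(truth)), tolerance = 1e-6)
    expect_lt(residualNorm(fit), 1e-8)
    ## standard errors of a perfect fit are numerically zero
    expect_true(all(stdErrors(fit) < paramVec(truth) * 1e-6))
})

test_that("fit started at the truth converges immediately", {
    fit <- fitCircuit(cleanSpectrum, init = truth, nStarts = 1)
    expect_true(isConverged(fit))
    expect_lt(residualNorm(fit), 1e-10)
})

test_that("explicitly passing the heuristic guess reproduces the default fit", {
    f1 <- fitCircuit(cleanSpectrum)
    f2 <- fitCircuit(cleanSpectrum, init = initialGuess(cleanSpectrum))
    expect_identical(paramVec(circuitParams(f1)), paramVec(circuitParams(f2)))
})

test_that("single-start and multi-start agree on clean data", {
    f1 <- fitCircuit(cleanSpectrum, nStarts = 1)
    f8 <- fitCircuit(cleanSpectrum, nStarts = 8)
    expect_equal(paramVec(circuitParams(f1)), paramVec(circuitParams(f8)),
                 tolerance = 1e-8)
})

test_that("noiseless recovery holds across the calibration parameter region", {
    ## draws within +-1 sd of the calibration means, multi-start fit
    set.seed(31)
    grid <- defaultFrequencyGrid(60)
    for (i in 1:100) {
        p <- drawParams()
        fit <- fitCircuit(circuitImpedance(p, grid), nStarts = 8)
        rel <- abs(paramVec(circuitParams(fit)) - paramVec(p)) / paramVec(p)
        expect_lt(max(rel), 1e-3)
    }
})

test_that("noisy fits report meaningful standard errors", {
    sp <- simulateSpectrum(truth, defaultFrequencyGrid(60), noiseRel = 0.01,
                           seed = 99)
    fit <- fitCircuit(sp)
    expect_true(isConverged(fit))
    se <- stdErrors(fit)
    expect_true(all(is.finite(se)) && all(se > 0))
    ## rough scale: errors are a small fraction of the estimates at 1% noise
    expect_true(all(se / paramVec(circuitParams(fit)) < 0.2))
})

test_that("fit preconditions are enforced", {
    few <- ImpedanceSpectrum(defaultFrequencyGrid(8),
                             circuitImpedance(truth, defaultFrequencyGrid(8))@z)
    expect_error(fitCircuit(few), "at least 10")
    narrow <- circuitImpedance(truth, seq(1000, 5000, length.out = 20))
    expect_error(fitCircuit(narrow), "decades")
})

test_that("fit report JSON round-trips losslessly", {
    fit <- fitCircuit(cleanSpectrum)
    path <- tempfile(fileext = ".json")
    writeFitReport(fit, path)
    back <- readFitReport(path)
    expect_equal(paramVec(circuitParams(back)), paramVec(circuitParams(fit)),
                 tolerance = 1e-12)
    expect_equal(back@stdErrors, fit@stdErrors, tolerance = 1e-12)
    expect_identical(back@converged, fit@converged)
    expect_identical(back@nStartsUsed, fit@nStartsUsed)
})
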