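test_that("noise-free synthetic beats are counted and measured exactly", {
    tr <- simulateBeatingTrace(10e-6, 1, 0.3, lengthS = 10,
                               noiseSd = 0, jitterCV = 0)
    tab <- detectBeats(tr)
    expect_equal(nrow(tab), 10)
    ## pulse peaks land on the sample grid: amplitudes are exact
    expect_equal(tab$amplitude, rep(10e-6, 10), tolerance = 1e-9 / 10e-6)
    expect_equal(diff(tab$peakTime), rep(1, 9), tolerance = 1e-9)
})

test_that("detection is exact under instrument-level noise", {
    ## 50 nm noise on 10 um beats: exact count, no spurious detections
    nExact <- sum(vapply(1:100, function(i) {
        tr <- simulateBeatingTrace(10e-6, 1, 0.3, lengthS = 10,
                                   noiseSd = 50e-9, jitterCV = 0, seed = i)
        nrow(detectBeats(tr)) == 10L
    }, logical(1)))
    expect_gte(nExact, 99)
})

test_that("excursions below the vibrometer noise floor are not beats", {
    tr <- simulateBeatingTrace(100e-9, 1, 0.3, lengthS = 10,
                               noiseSd = 0, jitterCV = 0)
    expect_equal(nrow(detectBeats(tr)), 0)
})

test_that("flat traces yield an empty table and NaN samples an error", {
    flat <- DisplacementTrace(500, rep(0, 5000))
    expect_equal(nrow(detectBeats(flat)), 0)
    bad <- DisplacementTrace(500, c(rep(0, 100), NaN, rep(0, 100)))
    expect_error(detectBeats(bad), "NaN")
})

test_that("beat count is exact across the physiological rate sweep", {
    for (f in c(0.2, 0.5, 1, 2, 3, 5)) {
        for (A in c(1e-6, 5e-6, 2e-5)) {
            len <- max(10, 5 / f)
            tr <- simulateBeatingTrace(A, f, min(0.25, 0.8 / f), lengthS = len,
                                       noiseSd = 0, jitterCV = 0)
            expected <- sum(0.5 / f + (0:1000) / f <= len)
            expect_equal(nrow(detectBeats(tr)), expected,
                         info = sprintf("f=%g A=%g", f, A))
        }
    }
})

test_that("amplitude estimates are unbiased within 2% under noise", {
    amps <- vapply(1:100, function(i) {
        tr <- simulateBeatingTrace(10e-6, 1.8, 0.4, lengthS = 15,
                                   noiseSd = 100e-9, jitterCV = 0, seed = i)
        mean(detectBeats(tr)$amplitude)
    }, numeric(1))
    expect_lt(abs(mean(amps) - 10e-6) / 10e-6, 0.02)
})

test_that("metrics are offset-invariant and scale linearly", {
    tr <- simulateBeatingTrace(5e-6, 2, 0.25, lengthS = 10,
                               noiseSd = 0, jitterCV = 0)
    tab <- detectBeats(tr)
    shifted <- DisplacementTrace(500, tr@samples + 3e-5)
    tabS <- detectBeats(shifted)
    expect_equal(tabS$peakTime, tab$peakTime)
    expect_equal(tabS$amplitude, tab$amplitude, tolerance = 1e-12)

    scaled <- DisplacementTrace(500, tr@samples * 2.5)
    tabC <- detectBeats(scaled)
    expect_equal(tabC$amplitude, tab$amplitude * 2.5, tolerance = 1e-9)
})

test_that("beat duration on a triangular pulse matches the closed form", {
    tr <- triangleTrace(amplitude = 5e-6, period = 1, baseWidth = 0.5)
    tab <- detectBeats(tr)
    expect_equal(nrow(tab), 10)
    ## crossing at fraction f of a triangle of base b: width = b (1 - f)
    expect_equal(tab$duration, rep(0.45, 10), tolerance = 2e-3 / 0.45)
    ## threshold -> 0 recovers the full base width
    d01 <- beatDurations(tr, tab, 0.02)
    expect_equal(d01, rep(0.5 * 0.98, 10), tolerance = 2e-3 / 0.49)
})

test_that("a beat truncated by the trace edge gets a missing duration", {
    fs <- 500
    t <- (seq_len(5 * fs) - 1) / fs
    ## second triangle is cut by the end of the trace before returning to base
    y <- 5e-6 * pmax(0, 1 - abs(t - 2) / 0.25) +
         5e-6 * pmax(0, 1 - abs(t - 4.95) / 0.25)
    tab <- detectBeats(DisplacementTrace(fs, y))
    expect_equal(nrow(tab), 2)
    expect_false(is.na(tab$duration[1]))
    expect_true(is.na(tab$duration[2]))
})

test_that("summary aggregates follow their defining arithmetic", {
    tr <- simulateBeatingTrace(5e-6, 2, 0.25, lengthS = 10.2,
                               noiseSd = 0, jitterCV = 0)
    tab <- detectBeats(tr)
    expect_equal(nrow(tab), 20)
    s <- summarizeBeats(tr, tab, k = 0.015)
    expect_equal(s@beatingFrequency, 2, tolerance = 1e-6)
    expect_equal(s@meanForce, 75e-9, tolerance = 1e-3)
    expect_equal(s@intervalCV, 0)  # perfectly periodic

    ## fewer than 2 beats: frequency and CV are missing, not invented
    one <- simulateBeatingTrace(5e-6, 0.35, 0.25, lengthS = 10,
                                noiseSd = 0, jitterCV = 0)
    tabOne <- detectBeats(one)
    sOne <- summarizeBeats(one, tabOne, 0.015)
    if (sOne@beatCount < 2) expect_true(is.na(sOne@intervalCV))

    empty <- summarizeBeats(DisplacementTrace(500, rep(0, 5000)),
                            detectBeats(DisplacementTrace(500, rep(0, 5000))),
                            0.015)
    expect_equal(empty@beatCount, 0L)
    expect_equal(empty@meanForce, 0)
})

test_that("relative force course is a ratio: baseline 100, scale invariant", {
    mk <- function(A) {
        tr <- simulateBeatingTrace(A, 2, 0.25, lengthS = 10,
                                   noiseSd = 0, jitterCV = 0)
        summarizeBeats(tr, detectBeats(tr), 0.015)
    }
    s <- lapply(c(2e-6, 4e-6, 8e-6), mk)
    rf <- relativeForceCourse(s)
    expect_equal(rf, c(100, 200, 400), tolerance = 1e-3)
    expect_equal(relativeForceCourse(list(s[[1]], s[[1]], s[[1]])),
                 rep(100, 3), tolerance = 1e-12)
    ## rescaling every amplitude leaves the course unchanged
    s2 <- lapply(c(2e-6, 4e-6, 8e-6) * 1.7, mk)
    expect_equal(relativeForceCourse(s2), rf, tolerance = 1e-6)
})

test_that("average beat reproduces the template and averages noise down", {
    clean <- simulateBeatingTrace(5e-6, 2, 0.3, lengthS = 26,
                                  noiseSd = 0, jitterCV = 0)
    tabC <- detectBeats(clean)
    avC <- averageBeat(clean, tabC)
    ## noise-free periodic trace: the average equals any single beat
    pk <- tabC$peakIndex[5]
    half <- nrow(avC) %/% 2
    single <- clean@samples[(pk - half):(pk - half + nrow(avC) - 1)]
    expect_equal(avC$displacement_m, single, tolerance = 1e-9 / 5e-6)

    ## sigma = 100 nm, 50 beats: RMS deviation < 3 sigma / sqrt(50)
    noisy <- simulateBeatingTrace(5e-6, 2, 0.3, lengthS = 26,
                                  noiseSd = 100e-9, jitterCV = 0, seed = 4)
    avN <- averageBeat(noisy, detectBeats(noisy))
    m <- min(nrow(avC), nrow(avN)) - 4
    ## the noisy average carries an arbitrary sub-sample alignment offset;
    ## compare at the best integer lag
    rms <- min(vapply(-2:2, function(l) {
        sqrt(mean((avN$displacement_m[(1:m) + 2 + l] -
                   avC$displacement_m[(1:m) + 2])^2))
    }, numeric(1)))
    expect_lt(rms, 3 * 100e-9 / sqrt(50))

    expect_error(averageBeat(clean, tabC[1, ]), "at least 2")
})

test_that("detected rate tracks the nominal frequency across seeds", {
    rates <- vapply(1:100, function(i) {
        tr <- simulateBeatingTrace(10e-6, 1.8, 0.4, lengthS = 15,
                                   noiseSd = 50e-9, jitterCV = 0.05, seed = i)
        summarizeBeats(tr, detectBeats(tr), 0.015)@beatingFrequency
    }, numeric(1))
    expect_lt(abs(mean(rates) - 1.8) / 1.8, 0.02)
})
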