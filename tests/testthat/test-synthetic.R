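test_that("generators are pure functions of (parameters, seed)", {
    p <- defaultCircuitParams()
    s1 <- simulateSpectrum(p, noiseRel = 0.02, seed = 7)
    s2 <- simulateSpectrum(p, noiseRel = 0.02, seed = 7)
    expect_identical(zOhm(s1), zOhm(s2))
    expect_false(identical(zOhm(s1), zOhm(simulateSpectrum(p, noiseRel = 0.02,
                                                           seed = 8))))

    t1 <- simulateBeatingTrace(5e-6, 2, 0.25, seed = 3)
    t2 <- simulateBeatingTrace(5e-6, 2, 0.25, seed = 3)
    expect_identical(traceSamples(t1), traceSamples(t2))

    e1 <- applyDrugModel("e4031", 30, timepointsH = c(0, 12), seed = 5)
    e2 <- applyDrugModel("e4031", 30, timepointsH = c(0, 12), seed = 5)
    expect_identical(traceSamples(e1@traces[[2]]), traceSamples(e2@traces[[2]]))
    expect_identical(zOhm(e1@spectra[[2]]), zOhm(e2@spectra[[2]]))
})

test_that("noise-free spectrum simulation equals the forward model exactly", {
    p <- defaultCircuitParams()
    expect_identical(zOhm(simulateSpectrum(p, noiseRel = 0)),
                     zOhm(circuitImpedance(p, defaultFrequencyGrid())))
    expect_error(simulateSpectrum(p, noiseRel = -0.1), "non-negative")
})

test_that("spectral noise has the requested proportional scale", {
    p <- defaultCircuitParams()
    f <- 10^seq(2, log10(2e6), length.out = 1000)
    model <- circuitImpedance(p, f)
    sim <- simulateSpectrum(p, f, noiseRel = 0.01, seed = 123)
    relRe <- (Re(zOhm(sim)) - Re(zOhm(model))) / Mod(zOhm(model))
    expect_equal(stats::sd(relRe), 0.01, tolerance = 0.1)
})

test_that("adhesion course reproduces the attachment trajectory landmarks", {
    nr <- normalizedResistanceCourse(simulateAdhesionCourse())
    expect_identical(nr$percent[nr$time_h == 0], 100)
    expect_equal(nr$percent[nr$time_h == 36], 118, tolerance = 0.5 / 118)
    expect_equal(nr$percent[nr$time_h == 72], 113, tolerance = 0.5 / 113)
    ## rising phase then plateau
    expect_true(all(diff(nr$percent[nr$time_h <= 36]) > 0))
    expect_true(all(abs(nr$percent[nr$time_h >= 48] - 113) < 0.5))
})

test_that("day-profile amplitudes encode the maturation force ratios", {
    a4 <- dayProfile(4)$amplitude
    expect_equal(dayProfile(5)$amplitude / a4, 1.664, tolerance = 1e-9)
    expect_equal(dayProfile(6)$amplitude / a4, 2.4356, tolerance = 1e-9)
    expect_equal(dayProfile(7)$amplitude / a4, 4.00, tolerance = 1e-9)
    ## rate falls and duration widens with maturation
    expect_true(all(diff(sapply(4:7, function(d) dayProfile(d)$frequency)) < 0))
    expect_true(all(diff(sapply(4:7, function(d) dayProfile(d)$duration)) > 0))
    expect_error(dayProfile(3), "days 4-7")
})

test_that("jitter-free noise-free traces have exactly periodic peaks", {
    tr <- simulateBeatingTrace(5e-6, 2.5, 0.25, lengthS = 10,
                               noiseSd = 0, jitterCV = 0)
    tab <- detectBeats(tr)
    expect_equal(diff(tab$peakTime), rep(0.4, nrow(tab) - 1), tolerance = 1e-9)
    expect_error(simulateBeatingTrace(-1e-6, 2, 0.2), "positive")
    expect_error(simulateBeatingTrace(1e-6, 2, 0.2, samplingRate = 100),
                 ">= 500")
    expect_error(simulateBeatingTrace(1e-6, 0.1, 0.2, lengthS = 10),
                 "3 beat periods")
})

test_that("every packaged drug keyframe anchor round-trips through analysis", {
    for (drug in c("verapamil", "e4031")) {
        kf <- drugKeyframes(drug)
        for (dose in names(kf@force)) {
            anchorsF <- kf@force[[dose]]
            anchorsC <- kf@ci[[dose]]
            tp <- sort(unique(c(0, anchorsF[, 1], anchorsC[, 1])))
            exp <- applyDrugModel(drug, as.numeric(dose), timepointsH = tp,
                                  noiseSd = 0, jitterCV = 0, noiseRel = 0)
            crv <- analyzeDrugExperiment(exp)
            for (r in seq_len(nrow(anchorsF))) {
                got <- crv@forcePct[crv@timesH == anchorsF[r, 1]]
                expect_lt(abs(got - anchorsF[r, 2]), 1,
                          label = sprintf("%s %s force@%gh = %.2f vs %g", drug,
                                          dose, anchorsF[r, 1], got, anchorsF[r, 2]))
            }
            for (r in seq_len(nrow(anchorsC))) {
                got <- crv@ciPct[crv@timesH == anchorsC[r, 1]]
                expect_lt(abs(got - anchorsC[r, 2]), 1,
                          label = sprintf("%s %s ci@%gh = %.2f vs %g", drug,
                                          dose, anchorsC[r, 1], got, anchorsC[r, 2]))
            }
        }
    }
})

test_that("anchors still reproduce within 3 points at default noise levels", {
    vals <- vapply(1:100, function(i) {
        exp <- applyDrugModel("verapamil", 300, timepointsH = c(0, 12), seed = i)
        crv <- analyzeDrugExperiment(exp)
        c(crv@forcePct[2], crv@ciPct[2])
    }, numeric(2))
    expect_lt(abs(mean(vals[1, ]) - 45), 3)
    expect_lt(abs(mean(vals[2, ]) - 74), 3)
})

test_that("null keyframes reproduce the unperturbed pre-drug generator", {
    null <- DrugEffectKeyframes(
        "verapamil",
        force = list(`300` = cbind(c(0, 24), c(100, 100))),
        ci = list(`300` = cbind(c(0, 24), c(100, 100))))
    exp <- applyDrugModel("verapamil", 300, keyframes = null,
                          timepointsH = c(0, 12, 24),
                          noiseSd = 0, jitterCV = 0, noiseRel = 0)
    ref <- simulateBeatingTrace(dayProfile(7)$amplitude, dayProfile(7)$frequency,
                                dayProfile(7)$duration, lengthS = 15,
                                noiseSd = 0, jitterCV = 0)
    for (i in 1:3)
        expect_equal(traceSamples(exp@traces[[i]]), traceSamples(ref),
                     tolerance = 1e-15)
    refZ <- zOhm(circuitImpedance(defaultCircuitParams(), defaultFrequencyGrid()))
    for (i in 1:3) expect_equal(zOhm(exp@spectra[[i]]), refZ, tolerance = 1e-12)
})

test_that("displacement and impedance channels are independent", {
    ## perturbing one channel's noise must leave the other bit-identical
    base <- applyDrugModel("verapamil", 300, timepointsH = c(0, 12),
                           noiseSd = 50e-9, noiseRel = 0.005, seed = 11)
    bigTraceNoise <- applyDrugModel("verapamil", 300, timepointsH = c(0, 12),
                                    noiseSd = 500e-9, noiseRel = 0.005, seed = 11)
    for (i in 1:2) {
        expect_identical(zOhm(bigTraceNoise@spectra[[i]]), zOhm(base@spectra[[i]]))
    }
    expect_identical(zOhm(bigTraceNoise@ciCourse), zOhm(base@ciCourse))

    bigSpecNoise <- applyDrugModel("verapamil", 300, timepointsH = c(0, 12),
                                   noiseSd = 50e-9, noiseRel = 0.05, seed = 11)
    for (i in 1:2) {
        expect_identical(traceSamples(bigSpecNoise@traces[[i]]),
                         traceSamples(base@traces[[i]]))
    }
})

test_that("uncalibrated doses interpolate in log-dose with a warning", {
    exp <- NULL
    w <- capture_warnings(
        exp <- applyDrugModel("e4031", 15, timepointsH = c(0, 24),
                              noiseSd = 0, jitterCV = 0, noiseRel = 0))
    expect_true(any(grepl("interpolating", w)))
    crv <- analyzeDrugExperiment(exp)
    ## between the 10 nmol/L (72%) and 20 nmol/L (66.5%) calibrations
    expect_gt(crv@ciPct[2], 66.5)
    expect_lt(crv@ciPct[2], 72)
    expect_error(applyDrugModel("e4031", 10, timepointsH = c(0, 36),
                                noiseSd = 0, jitterCV = 0, noiseRel = 0),
                 "extrapolation")
    expect_error(suppressWarnings(
        applyDrugModel("e4031", 100, timepointsH = c(0, 12))), "range")
})

test_that("keyframes serialize and reload losslessly", {
    kf <- drugKeyframes("e4031")
    path <- tempfile(fileext = ".json")
    writeKeyframes(kf, path)
    back <- drugKeyframes("e4031", file = path)
    expect_equal(back@force, kf@force)
    expect_equal(back@ci, kf@ci)
    expect_equal(back@durationFactor, kf@durationFactor)
    expect_error(DrugEffectKeyframes("x", force = list(`1` = cbind(c(0, 5), c(90, 80))),
                                     ci = list(`1` = cbind(c(0, 5), c(100, 80)))),
                 "start at")
})

test_that("beat waveforms widen with maturation and hERG block", {
    ## day-7 template is wider than day-4 at the 0.1 threshold
    dur <- vapply(c(4, 7), function(d) {
        p <- dayProfile(d)
        tr <- simulateBeatingTrace(p$amplitude, p$frequency, p$duration,
                                   lengthS = 15, noiseSd = 0, jitterCV = 0)
        tab <- detectBeats(tr)
        mean(tab$duration, na.rm = TRUE)
    }, numeric(1))
    expect_gt(dur[2], dur[1])

    ## E-4031 30 nmol/L at +12 h: wider averaged beat and larger interval CV
    exp <- applyDrugModel("e4031", 30, timepointsH = c(0, 12),
                          noiseSd = 0, jitterCV = 0.05, noiseRel = 0, seed = 7)
    width01 <- function(tr) {
        tab <- detectBeats(tr)
        av <- averageBeat(tr, tab)
        lv <- 0.1 * max(av$displacement_m)
        sum(av$displacement_m > lv) / samplingRateHz(tr)
    }
    expect_gt(width01(exp@traces[[2]]), width01(exp@traces[[1]]))
    cv <- vapply(exp@traces, function(tr)
        summarizeBeats(tr, detectBeats(tr), 0.015)@intervalCV, numeric(1))
    expect_gt(cv[2], cv[1])
})
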