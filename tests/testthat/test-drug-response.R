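mkSummary <- function(force) {
    new("BeatSummary", beatCount = 20L, beatingFrequency = 1.8,
        meanAmplitude = force / 0.015, meanForce = force,
        meanDuration = 0.3, intervalCV = 0.05)
}

test_that("curves normalize to the last pre-dosing measurement", {
    crv <- buildCurve(mkSummary(150e-9), 0.5, c(6, 12, 24),
                      lapply(c(120e-9, 75e-9, 90e-9), mkSummary),
                      c(0.45, 0.40, 0.42), drug = "verapamil",
                      doseMolL = 300e-9)
    expect_equal(crv@timesH, c(0, 6, 12, 24))
    expect_equal(crv@forcePct, c(100, 80, 50, 60))
    expect_equal(crv@ciPct, c(100, 90, 80, 84))
})

test_that("curve construction is scale invariant and guards baselines", {
    t <- c(6, 12, 24)
    f <- c(120e-9, 75e-9, 90e-9)
    ci <- c(0.45, 0.40, 0.42)
    a <- buildCurve(mkSummary(150e-9), 0.5, t, lapply(f, mkSummary), ci)
    b <- buildCurve(mkSummary(150e-9 * 7), 0.5 * 3, t,
                    lapply(f * 7, mkSummary), ci * 3)
    expect_equal(b@forcePct, a@forcePct, tolerance = 1e-12)
    expect_equal(b@ciPct, a@ciPct, tolerance = 1e-12)
    expect_error(buildCurve(mkSummary(0), 0.5, t, lapply(f, mkSummary), ci),
                 "pre-drug force")
    expect_error(buildCurve(mkSummary(1e-9), 0, t, lapply(f, mkSummary), ci),
                 "cell index")
})

test_that("sham dosing keeps both channels at 100%", {
    crv <- buildCurve(mkSummary(150e-9), 0.5, c(6, 12, 24),
                      lapply(rep(150e-9, 3), mkSummary), rep(0.5, 3))
    expect_equal(crv@forcePct, rep(100, 4))
    expect_equal(crv@ciPct, rep(100, 4))
    prof <- recoveryProfile(crv, "force")
    expect_equal(prof@minimumPct, 100)
    expect_false(prof@recovered)
})

test_that("recovery profiles flag rebounds beyond the tolerance only", {
    dip <- new("DoseResponseCurve", drug = "x", doseMolL = 1e-9,
               timesH = c(0, 6, 12, 18, 24),
               forcePct = c(100, 70, 45, 48, 51),
               ciPct = c(100, 90, 65, 70, 75))
    pf <- recoveryProfile(dip, "force")
    expect_equal(pf@minimumPct, 45)
    expect_equal(pf@timeOfMinimumH, 12)
    expect_equal(pf@atHorizonPct, 51)
    expect_true(pf@recovered)

    mono <- new("DoseResponseCurve", drug = "x", doseMolL = 1e-9,
                timesH = c(0, 6, 12, 18, 24),
                forcePct = c(100, 95, 90, 85, 80),
                ciPct = c(100, 90, 82, 76, 72))
    expect_false(recoveryProfile(mono, "ci")@recovered)
    ## minimum of a monotone channel is its last value
    expect_equal(recoveryProfile(mono, "ci")@minimumPct, 72)
    ## a rebound within the 2-point tolerance is not recovery
    flat <- new("DoseResponseCurve", drug = "x", doseMolL = 1e-9,
                timesH = c(0, 6, 12, 24),
                forcePct = c(100, 60, 58, 59.5), ciPct = rep(100, 4))
    expect_false(recoveryProfile(flat, "force")@recovered)

    expect_error(recoveryProfile(dip, "force", horizonH = -1), "precedes")
    two <- new("DoseResponseCurve", drug = "x", doseMolL = 1e-9,
               timesH = c(0, 24), forcePct = c(100, 50), ciPct = c(100, 60))
    expect_error(recoveryProfile(two, "force"), "3 timepoints")
})

test_that("profile minimum bounds every curve value", {
    set.seed(41)
    for (i in 1:20) {
        v <- c(100, pmax(0, 100 - cumsum(runif(4, -10, 30))))
        crv <- new("DoseResponseCurve", drug = "x", doseMolL = 1e-9,
                   timesH = c(0, 3, 6, 12, 24), forcePct = v,
                   ciPct = rep(100, 5))
        expect_true(all(recoveryProfile(crv, "force")@minimumPct <= v))
    }
})

test_that("minimum force is non-increasing in verapamil dose", {
    mins <- vapply(c(150, 300, 500, 1000), function(dose) {
        exp <- applyDrugModel("verapamil", dose, noiseSd = 0, jitterCV = 0,
                              noiseRel = 0)
        min(analyzeDrugExperiment(exp)@forcePct)
    }, numeric(1))
    expect_true(all(diff(mins) <= 0))
})

test_that("Hill fit recovers a noiseless IC50 and flags flat data", {
    d <- c(1, 5, 10, 50, 100) * 1e-9
    r <- 100 / (1 + (d / 10e-9)^1)
    fit <- hillFit(d, r)
    expect_equal(fit$ic50MolL, 10e-9, tolerance = 1e-6)
    expect_equal(fit$hill, 1, tolerance = 1e-6)
    expect_true(fit$reliable)

    flat <- hillFit(d, rep(100, 5))
    expect_false(flat$reliable)
    expect_true(any(grepl("extrapolated", flat$warnings)))
    expect_error(hillFit(d[1:3], r[1:3]), "4 distinct")
})

test_that("Hill fit warns on non-monotone dose response but still returns", {
    d <- c(1, 5, 10, 50, 100) * 1e-9
    r <- c(95, 60, 30, 80, 10)
    fit <- hillFit(d, r)
    expect_true(any(grepl("increase with dose", fit$warnings)))
    expect_true(is.finite(fit$ic50MolL))
})
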