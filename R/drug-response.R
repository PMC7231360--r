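#' Build a dose-response curve from per-timepoint measurements
#'
#' Expresses both readout channels as percent of the last pre-dosing
#' measurement ("base value" = t = 0-, not an earlier culture-day value)
#' and inserts the t = 0 point at 100%.  The construction is
#' scale-invariant: multiplying all raw forces (or all impedances) by a
#' common constant leaves the curve unchanged.  Percentages above 100 are
#' kept (hypercontractility is representable).
#'
#' @param predrugSummary \linkS4class{BeatSummary} of the pre-drug recording
#' @param predrugCI pre-drug cell index (unitless, > 0)
#' @param timesH timepoints after dosing (h), strictly increasing, > 0
#' @param summaries list of per-timepoint \linkS4class{BeatSummary} objects
#' @param cis per-timepoint cell-index values
#' @param drug drug name (label only)
#' @param doseMolL dose in mol/L (label only)
#' @return a \linkS4class{DoseResponseCurve}
#' @export
buildCurve <- function(predrugSummary, predrugCI, timesH, summaries, cis,
                       drug = "", doseMolL = NA_real_) {
    f0 <- predrugSummary@meanForce
    if (!is.finite(f0) || f0 <= 0)
        .stopf("pre-drug force baseline must be positive")
    if (!is.finite(predrugCI) || predrugCI <= 0)
        .stopf("pre-drug cell index must be positive")
    if (length(timesH) != length(summaries) || length(timesH) != length(cis))
        .stopf("timesH, summaries and cis lengths differ")
    if (any(timesH <= 0) || any(diff(timesH) <= 0))
        .stopf("timepoints must be strictly increasing and > 0")
    forces <- vapply(summaries, function(s) s@meanForce, numeric(1))
    new("DoseResponseCurve", drug = drug, doseMolL = doseMolL,
        timesH = c(0, timesH),
        forcePct = c(100, 100 * forces / f0),
        ciPct = c(100, 100 * cis / predrugCI))
}

#' Suppression/recovery profile of a curve channel
#'
#' Locates the minimum of the chosen channel over the time grid, reads the
#' value at the recovery horizon (nearest grid point) and flags recovery
#' when the horizon value exceeds the minimum by more than `tolerancePct`
#' (2 percentage points by default, so noise-level rebounds are not called
#' recovery).
#'
#' @param curve a \linkS4class{DoseResponseCurve}
#' @param channel `"force"` or `"ci"`
#' @param horizonH recovery horizon (h), default 24 (the standard
#'   observation window); must not precede the first timepoint
#' @param tolerancePct recovery tolerance in percentage points
#' @return a \linkS4class{RecoveryProfile}
#' @export
recoveryProfile <- function(curve, channel = c("force", "ci"), horizonH = 24,
                            tolerancePct = 2) {
    channel <- match.arg(channel)
    validObject(curve)
    t <- curve@timesH
    if (length(t) < 3L)
        .stopf("recoveryProfile needs at least 3 timepoints")
    if (horizonH < t[1])
        .stopf("horizon %g h precedes the first timepoint", horizonH)
    v <- if (channel == "force") curve@forcePct else curve@ciPct
    iMin <- which.min(v)
    iHor <- which.min(abs(t - horizonH))
    new("RecoveryProfile", minimumPct = v[iMin], timeOfMinimumH = t[iMin],
        atHorizonPct = v[iHor], horizonH = t[iHor],
        recovered = v[iHor] > v[iMin] + tolerancePct)
}

#' Hill (four-dose) inhibitory fit
#'
#' Least-squares fit of the inhibitory Hill model
#' R(d) = 100 / (1 + (d / IC50)^h) to percent responses at a fixed
#' post-dosing time.  IC50 and h are optimized in log space
#' (Levenberg-Marquardt).  The fit is flagged `reliable` only when the
#' fitted IC50 lies within the tested dose range; otherwise it is an
#' extrapolation.  Non-monotone responses beyond the noise level produce a
#' diagnostic warning string but the fit is still returned.
#'
#' @param dosesMolL at least 4 distinct doses (mol/L)
#' @param responsesPct responses (% of pre-drug) at the same fixed time
#' @return list with elements `ic50MolL`, `hill`, `reliable`,
#'   `residualNorm`, `converged`, `warnings` (character vector)
#' @examples
#' d <- c(1, 5, 10, 50, 100) * 1e-9
#' r <- 100 / (1 + (d / 10e-9))
#' hillFit(d, r)$ic50MolL  # 1e-8
#' @export
hillFit <- function(dosesMolL, responsesPct) {
    if (length(dosesMolL) != length(responsesPct))
        .stopf("doses and responses lengths differ")
    if (length(unique(dosesMolL)) < 4L)
        .stopf("hillFit needs at least 4 distinct doses")
    if (any(dosesMolL <= 0)) .stopf("doses must be positive")
    warn <- character()
    ord <- order(dosesMolL)
    dv <- diff(responsesPct[ord])
    noiseScale <- max(2, stats::mad(dv))
    if (any(dv > noiseScale))
        warn <- c(warn, "responses increase with dose beyond the noise level")

    ## start: dose whose response is nearest 50%, h = 1
    i50 <- which.min(abs(responsesPct - 50))
    th0 <- c(log(dosesMolL[i50]), 0)
    resFn <- function(th) {
        100 / (1 + (dosesMolL / exp(th[1]))^exp(th[2])) - responsesPct
    }
    fit <- minpack.lm::nls.lm(par = th0, fn = resFn,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    ic50 <- exp(fit$par[1])
    h <- exp(fit$par[2])
    reliable <- ic50 >= min(dosesMolL) && ic50 <= max(dosesMolL)
    if (!reliable)
        warn <- c(warn, "fitted IC50 lies outside the tested dose range (extrapolated)")
    list(ic50MolL = ic50, hill = h, reliable = reliable,
         residualNorm = sqrt(fit$deviance), converged = fit$info %in% 1:4,
         warnings = warn)
}

#' Analyze a simulated drug experiment end to end
#'
#' Runs the full analysis chain on a \linkS4class{DrugExperiment}: beat
#' detection and summary per timepoint trace, cell index per timepoint
#' from the impedance course, then [buildCurve()] against the t = 0
#' (pre-drug) measurements.
#'
#' @param experiment a \linkS4class{DrugExperiment} from [applyDrugModel()]
#' @param k cantilever spring constant (N/m)
#' @return a \linkS4class{DoseResponseCurve}
#' @export
analyzeDrugExperiment <- function(experiment, k = 0.015) {
    tp <- experiment@timepointsH
    summaries <- lapply(experiment@traces, function(tr)
        summarizeBeats(tr, detectBeats(tr), k))
    ci <- cellIndex(Mod(experiment@ciCourse@z), Mod(experiment@ciCourse@baselineZ))
    buildCurve(summaries[[1]], ci[1], tp[-1], summaries[-1], ci[-1],
               drug = experiment@drug, doseMolL = experiment@doseNmolL * 1e-9)
}
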