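#' Construct drug-effect keyframes
#'
#' @param drug drug name
#' @param force,ci named lists (dose in nmol/L as name) of two-column
#'   (time_h, percent) matrices, each starting at (0, 100)
#' @param durationFactor,jitterFactor optional named lists of
#'   (time_h, multiplier) matrices for beat-duration widening and
#'   inter-beat jitter inflation
#' @return a \linkS4class{DrugEffectKeyframes}
#' @rdname DrugEffectKeyframes-class
#' @export
DrugEffectKeyframes <- function(drug, force, ci, durationFactor = list(),
                                jitterFactor = list()) {
    new("DrugEffectKeyframes", drug = drug, force = force, ci = ci,
        durationFactor = durationFactor, jitterFactor = jitterFactor)
}

.kfListFromJSON <- function(x) {
    lapply(x, function(m) {
        m <- matrix(as.numeric(unlist(m)), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("time_h", "value")))
        m
    })
}

#' Packaged drug calibration keyframes
#'
#' Loads the packaged calibration table for the two reference compounds:
#' verapamil (L-type calcium channel blocker; dose-dependent suppression
#' of contraction force and cell index with partial time-dependent
#' recovery; doses 150/300/500/1000 nmol/L) and E-4031 (hERG potassium
#' channel blocker; monotone cell-index decline without recovery,
#' beat-duration widening and beat irregularity at 30 nmol/L; doses
#' 5/10/20/30 nmol/L).  The anchors are landmark values of the calibrated
#' suppression-recovery trajectories; the generator interpolates between
#' them with a monotone piecewise cubic.
#'
#' @param drug `"verapamil"` or `"e4031"`
#' @param file optional path to an alternative keyframe JSON file
#' @return a \linkS4class{DrugEffectKeyframes}
#' @seealso [applyDrugModel()], [writeKeyframes()]
#' @export
drugKeyframes <- function(drug = c("verapamil", "e4031"), file = NULL) {
    drug <- match.arg(drug)
    if (is.null(file))
        file <- system.file("extdata", "drug_keyframes.json",
                            package = "cardiosens", mustWork = TRUE)
    js <- jsonlite::read_json(file, simplifyVector = FALSE)
    if (is.null(js[[drug]])) .stopf("drug '%s' not present in %s", drug, file)
    blk <- js[[drug]]
    DrugEffectKeyframes(
        drug = drug,
        force = .kfListFromJSON(blk$force),
        ci = .kfListFromJSON(blk$ci),
        durationFactor = if (is.null(blk$durationFactor)) list()
                         else .kfListFromJSON(blk$durationFactor),
        jitterFactor = if (is.null(blk$jitterFactor)) list()
                       else .kfListFromJSON(blk$jitterFactor))
}

#' Serialize keyframes to JSON
#'
#' Writes a \linkS4class{DrugEffectKeyframes} object in the same JSON
#' schema that [drugKeyframes()] reads, so that custom calibrations
#' round-trip losslessly.
#'
#' @param keyframes a \linkS4class{DrugEffectKeyframes}
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeKeyframes <- function(keyframes, path) {
    validObject(keyframes)
    asList <- function(lst) lapply(lst, function(m)
        lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
    out <- list()
    out[[keyframes@drug]] <- list(
        force = asList(keyframes@force),
        ci = asList(keyframes@ci))
    if (length(keyframes@durationFactor))
        out[[keyframes@drug]]$durationFactor <- asList(keyframes@durationFactor)
    if (length(keyframes@jitterFactor))
        out[[keyframes@drug]]$jitterFactor <- asList(keyframes@jitterFactor)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

## Evaluate a per-dose keyframe list at (dose, times).  Doses absent from
## the table are interpolated linearly in log10-dose between the two
## bracketing calibrated doses (with a warning); times beyond the last
## keyframe raise an error (no extrapolation in time).
.evalKeyframes <- function(kfList, doseNmolL, timesH, what, fallback = NULL) {
    if (length(kfList) == 0L) {
        if (is.null(fallback)) .stopf("no %s keyframes available", what)
        return(rep(fallback, length(timesH)))
    }
    doses <- as.numeric(names(kfList))
    evalOne <- function(m) {
        if (any(timesH > max(m[, 1]) + 1e-9))
            .stopf("timepoint beyond the last %s keyframe (%g h): no extrapolation",
                   what, max(m[, 1]))
        if (any(timesH < min(m[, 1]) - 1e-9))
            .stopf("timepoint before the first %s keyframe", what)
        .keyframeFun(m)(timesH)
    }
    hit <- which(abs(doses - doseNmolL) < 1e-9)
    if (length(hit) == 1L) return(evalOne(kfList[[hit]]))
    if (is.null(fallback)) {
        if (doseNmolL < min(doses) || doseNmolL > max(doses))
            .stopf("dose %g nmol/L outside the calibrated %s range [%g, %g]",
                   doseNmolL, what, min(doses), max(doses))
        warning(sprintf("dose %g nmol/L not calibrated for %s: interpolating in log-dose",
                        doseNmolL, what), call. = FALSE)
        ord <- order(doses)
        lo <- max(which(doses[ord] <= doseNmolL))
        hi <- min(which(doses[ord] >= doseNmolL))
        vLo <- evalOne(kfList[[ord[lo]]])
        vHi <- evalOne(kfList[[ord[hi]]])
        wHi <- (log10(doseNmolL) - log10(doses[ord[lo]])) /
            (log10(doses[ord[hi]]) - log10(doses[ord[lo]]))
        return((1 - wHi) * vLo + wHi * vHi)
    }
    ## optional profiles (duration/jitter) fall back to neutral for
    ## uncalibrated doses
    rep(fallback, length(timesH))
}
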