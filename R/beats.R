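## Beat detection and per-beat contraction metrics.
##
## Detection pipeline: slow drift is removed by subtracting a
## morphological-opening baseline (window = 3x the median beat period,
## estimated by a first coarse pass); peaks are located on a lightly smoothed copy (15 ms
## running median) so that sample-level noise does not split or shift
## beats, then refined to the raw local maximum; the per-beat baseline is
## the preceding local minimum.  A beat is accepted when its amplitude
## above baseline reaches max(3 x robust noise scale, instrument noise
## floor), with a minimum inter-beat separation of 150 ms.

## Sliding-window minimum (centered, odd window), O(n) via the blockwise
## prefix/suffix-minimum decomposition.  Out-of-range positions count as
## +Inf, so windows shrink gracefully at the trace edges.
.runMin <- function(x, w) {
    n <- length(x)
    if (w >= 2L * n) return(rep(min(x), n))
    h <- w %/% 2L
    xp <- c(rep(Inf, h), x, rep(Inf, h))
    m <- length(xp)
    nb <- ceiling(m / w)
    xp <- c(xp, rep(Inf, nb * w - m))
    mat <- matrix(xp, nrow = w)
    pref <- as.vector(apply(mat, 2, cummin))
    suff <- as.vector(apply(mat[w:1, , drop = FALSE], 2, cummin)[w:1, , drop = FALSE])
    i <- seq_len(m - w + 1L)
    pmin(suff[i], pref[i + w - 1L])
}

.runMax <- function(x, w) -.runMin(-x, w)

## Shared preprocessing: drift-removed trace + smoothed copy.  The slow
## baseline is estimated by a morphological opening (sliding minimum then
## sliding maximum) whose window spans several beat periods: for
## positive-going contraction pulses the opening returns the baseline
## exactly whenever each window sees at least one between-beat sample,
## regardless of the pulse duty cycle -- a regime where a running median
## becomes ill-conditioned.
.prepTrace <- function(y, fs, detrendSec) {
    n <- length(y)
    w <- .oddWindow(detrendSec, fs, n)
    detr <- y - .runMax(.runMin(y, w), w)
    kSm <- .oddWindow(0.015, fs, n)
    sm <- stats::runmed(detr, kSm)
    list(detr = detr, sm = sm, kSm = kSm)
}

## strict local maxima (rising into the point, not rising after it)
.localMaxima <- function(x) {
    n <- length(x)
    if (n < 3L) return(integer())
    which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

## One detection pass over a preprocessed trace.  Candidate location uses
## the smoothed drift-removed copy; peak and baseline VALUES are read from
## the raw samples so that the drift filter cannot distort amplitudes
## (constant offsets cancel in the peak-minus-baseline difference).
.detectPass <- function(prep, y, fs, threshold, minSep) {
    detr <- prep$detr
    sm <- prep$sm
    cand <- .localMaxima(sm)
    if (length(cand) == 0L) return(NULL)
    ## greedy minimum-separation selection, tallest first
    cand <- cand[order(sm[cand], decreasing = TRUE)]
    minGap <- as.integer(round(minSep * fs))
    kept <- integer()
    for (i in cand) {
        if (!length(kept) || all(abs(kept - i) >= minGap)) kept <- c(kept, i)
    }
    kept <- sort(kept)
    ## refine each peak to the raw local maximum nearby, remembering the
    ## smoothed candidate it came from
    half <- prep$kSm
    peakLoc <- vapply(kept, function(i) {
        lo <- max(1L, i - half); hi <- min(length(y), i + half)
        lo + which.max(y[lo:hi]) - 1L
    }, integer(1))
    dup <- duplicated(peakLoc)
    peakLoc <- peakLoc[!dup]
    smLoc <- kept[!dup]
    ## amplitude filter against the preceding local minimum; the filter is
    ## applied on the smoothed copy (immune to extreme-value inflation of
    ## raw noise) while the reported amplitude is raw.  Iterate: removing a
    ## sub-threshold peak extends its neighbor's baseline segment.
    repeat {
        nPk <- length(peakLoc)
        if (nPk == 0L) return(NULL)
        baseLoc <- integer(nPk)
        for (j in seq_len(nPk)) {
            lo <- if (j == 1L) 1L else peakLoc[j - 1L] + 1L
            seg <- lo:peakLoc[j]
            baseLoc[j] <- seg[which.min(sm[seg])]
        }
        ## a true beat must clear the threshold in BOTH domains: the
        ## smoothed amplitude (immune to extreme-value inflation of raw
        ## noise) and the raw amplitude (immune to wiggle artifacts of the
        ## drift filter at pathological duty cycles)
        ok <- (sm[smLoc] - sm[baseLoc]) >= threshold &
              (y[peakLoc] - y[baseLoc]) >= threshold
        if (all(ok)) {
            return(data.frame(peakIndex = peakLoc, baseIndex = baseLoc,
                              amplitude = y[peakLoc] - y[baseLoc]))
        }
        peakLoc <- peakLoc[ok]
        smLoc <- smLoc[ok]
    }
}

#' Detect beats in a displacement trace
#'
#' Finds contraction peaks as local maxima whose amplitude above the
#' preceding local minimum reaches
#' `max(promFactor * 1.4826 * MAD(drift-removed trace), noiseFloor)`,
#' with a configurable minimum inter-beat separation (default 150 ms,
#' capping the detectable rate at ~6.7 Hz).  An all-flat trace yields an
#' empty table, not an error.
#'
#' @param trace a \linkS4class{DisplacementTrace}
#' @param thresholdFraction threshold fraction for the per-beat duration
#'   (see [beatDurations()]); default 0.1
#' @param minSeparation minimum inter-beat separation (s)
#' @param promFactor multiplier on the robust noise scale (default 3)
#' @return a beat table: `data.frame` with one row per beat and columns
#'   `peakTime` (s), `peakDisplacement` (m, raw sample at the peak),
#'   `amplitude` (m, above local baseline), `duration` (s, at
#'   `thresholdFraction`; `NA` when truncated by a trace edge) and
#'   `interval` (s, preceding inter-beat interval; `NA` for the first
#'   beat).  Index columns `peakIndex`/`baseIndex` locate each beat and
#'   its baseline in the trace.
#' @examples
#' tr <- simulateBeatingTrace(amplitude = 10e-6, frequency = 1, duration = 0.3,
#'                            lengthS = 10, noiseSd = 0, jitterCV = 0)
#' detectBeats(tr)
#' @export
detectBeats <- function(trace, thresholdFraction = 0.1, minSeparation = 0.15,
                        promFactor = 3) {
    validObject(trace)
    y <- trace@samples
    if (any(is.na(y)) || any(!is.finite(y)))
        .stopf("trace contains NaN/NA samples")
    fs <- trace@samplingRate

    empty <- data.frame(peakTime = numeric(), peakDisplacement = numeric(),
                        amplitude = numeric(), duration = numeric(),
                        interval = numeric(), peakIndex = integer(),
                        baseIndex = integer())

    ## coarse pass with a fixed 2 s detrend window to estimate the beat period
    prep <- .prepTrace(y, fs, 2)
    thr <- max(promFactor * stats::mad(prep$detr), trace@noiseFloor)
    pass1 <- .detectPass(prep, y, fs, thr, minSeparation)
    if (!is.null(pass1) && nrow(pass1) >= 3L) {
        medInt <- stats::median(diff(pass1$peakIndex)) / fs
        prep <- .prepTrace(y, fs, 3 * medInt)
        thr <- max(promFactor * stats::mad(prep$detr), trace@noiseFloor)
        pass1 <- .detectPass(prep, y, fs, thr, minSeparation)
    }
    if (is.null(pass1)) {
        attr(empty, "prep") <- prep
        return(empty)
    }

    tab <- data.frame(
        peakTime = trace@startTime + (pass1$peakIndex - 1L) / fs,
        peakDisplacement = y[pass1$peakIndex],
        amplitude = pass1$amplitude,
        duration = NA_real_,
        interval = NA_real_,
        peakIndex = pass1$peakIndex,
        baseIndex = pass1$baseIndex)
    if (nrow(tab) > 1L) tab$interval[-1L] <- diff(tab$peakTime)
    attr(tab, "prep") <- prep
    tab$duration <- beatDurations(trace, tab, thresholdFraction)
    tab
}

#' Per-beat durations at a threshold fraction
#'
#' Duration of each beat, measured as the time between the upward and
#' downward crossings of `baseline + thresholdFraction * amplitude` around
#' the peak, with linear interpolation between samples.  As the threshold
#' fraction tends to 0 this recovers the full base width of the beat.  A
#' beat whose crossing search runs off a trace edge gets `NA`.  This
#' waveform width is the assay's QT-like repolarization proxy: drugs that
#' prolong repolarization widen the contraction waveform.
#'
#' @param trace the \linkS4class{DisplacementTrace} the table came from
#' @param table a beat table from [detectBeats()]
#' @param thresholdFraction fraction of the beat amplitude (0 < f < 1)
#' @return numeric vector of durations (s), one per beat
#' @export
beatDurations <- function(trace, table, thresholdFraction = 0.1) {
    validObject(trace)
    if (thresholdFraction <= 0 || thresholdFraction >= 1)
        .stopf("thresholdFraction must lie strictly between 0 and 1")
    if (nrow(table) == 0L) return(numeric())
    y <- trace@samples
    fs <- trace@samplingRate
    n <- length(y)

    vapply(seq_len(nrow(table)), function(j) {
        pk <- table$peakIndex[j]
        ## crossing level on the raw samples, anchored to the beat's own
        ## baseline (the drift between baseline and peak of one beat is
        ## negligible at physiological rates)
        level <- y[table$baseIndex[j]] +
            thresholdFraction * (y[pk] - y[table$baseIndex[j]])
        ## upward (left) crossing
        i <- pk
        while (i > 1L && y[i - 1L] >= level) i <- i - 1L
        if (i == 1L && y[1L] >= level) return(NA_real_)
        tLeft <- (i - 1L) - (y[i] - level) / (y[i] - y[i - 1L])
        ## downward (right) crossing
        i <- pk
        while (i < n && y[i + 1L] >= level) i <- i + 1L
        if (i == n && y[n] >= level) return(NA_real_)
        tRight <- (i - 1L) + (y[i] - level) / (y[i] - y[i + 1L])
        (tRight - tLeft) / fs
    }, numeric(1))
}

#' Summarize beats of one recording
#'
#' Aggregates a beat table into a \linkS4class{BeatSummary}: beating
#' frequency is the reciprocal of the median inter-beat interval, mean
#' force is the spring constant times the mean amplitude, and the interval
#' coefficient of variation sd/mean is the irregularity index.  With fewer
#' than two beats, frequency and CV are reported missing (`NA`); an empty
#' table yields zero amplitude and force.
#'
#' @param trace the \linkS4class{DisplacementTrace} the table came from
#' @param table a beat table from [detectBeats()]
#' @param k cantilever spring constant (N/m)
#' @return a \linkS4class{BeatSummary}
#' @export
summarizeBeats <- function(trace, table, k) {
    validObject(trace)
    if (length(k) != 1L || !is.finite(k) || k <= 0)
        .stopf("spring constant k must be a single positive number")
    nb <- nrow(table)
    ints <- table$interval[!is.na(table$interval)]
    freq <- if (length(ints) >= 1L) 1 / stats::median(ints) else NA_real_
    cv <- if (length(ints) >= 2L) stats::sd(ints) / mean(ints) else NA_real_
    amp <- if (nb > 0L) mean(table$amplitude) else 0
    dur <- if (nb > 0L && any(!is.na(table$duration)))
        mean(table$duration, na.rm = TRUE) else NA_real_
    new("BeatSummary", beatCount = as.integer(nb), beatingFrequency = freq,
        meanAmplitude = amp, meanForce = forceFromDisplacement(k, amp),
        meanDuration = dur, intervalCV = cv)
}

#' Relative contraction-force course
#'
#' Expresses the mean force of a sequence of recordings (for example one
#' per culture day) as percent of a baseline recording:
#' percent_i = 100 force_i / force_baseline.  Rescaling every amplitude by
#' a common factor leaves the course unchanged.
#'
#' @param summaries list of \linkS4class{BeatSummary} objects
#' @param baselineIndex index of the baseline summary (default 1)
#' @return numeric vector of percentages; the baseline entry is 100
#' @export
relativeForceCourse <- function(summaries, baselineIndex = 1) {
    forces <- vapply(summaries, function(s) s@meanForce, numeric(1))
    f0 <- forces[baselineIndex]
    if (!is.finite(f0) || f0 <= 0)
        .stopf("baseline recording has zero mean force")
    100 * forces / f0
}

#' Average beat waveform
#'
#' Windows each beat around its peak (window length = the median inter-beat
#' interval), aligns the windows on the peak sample -- refined by a
#' least-squares lag search, since per-beat localization noise would blur
#' the mean -- and returns the pointwise mean of the drift-removed
#' displacement, re-centered on its peak and anchored at its resting
#' level.  Averaging N beats suppresses uncorrelated noise by roughly
#' 1/sqrt(N), so the result approximates the underlying contraction
#' template.
#'
#' @param trace the \linkS4class{DisplacementTrace} the table came from
#' @param table a beat table from [detectBeats()] with at least 2 beats
#' @return `data.frame` with columns `time_s` (offset from the peak) and
#'   `displacement_m` (mean drift-removed displacement)
#' @export
averageBeat <- function(trace, table) {
    validObject(trace)
    if (nrow(table) < 2L)
        .stopf("averageBeat needs at least 2 beats")
    prep <- attr(table, "prep")
    if (is.null(prep)) prep <- .prepTrace(trace@samples, trace@samplingRate, 2)
    detr <- prep$detr
    fs <- trace@samplingRate
    wLen <- as.integer(round(stats::median(diff(table$peakIndex))))
    half <- wLen %/% 2L
    offs <- seq.int(-half, length.out = wLen)
    windows <- lapply(table$peakIndex, function(pk) {
        idx <- pk + offs
        if (idx[1] < 1L || idx[wLen] > length(detr)) return(NULL)
        list(pk = pk, w = detr[idx])
    })
    windows <- windows[!vapply(windows, is.null, logical(1))]
    if (length(windows) < 2L)
        .stopf("averageBeat needs at least 2 beats fully inside the trace")
    ## refine the peak-sample alignment by least-squares lag against the
    ## first full beat (sample-level noise can shift individual raw peak
    ## locations by a sample or two; misalignment would blur the average)
    ref <- windows[[1L]]$w
    maxLag <- prep$kSm
    extract <- function(pk, shift) {
        idx <- pk + shift + offs
        if (idx[1] < 1L || idx[wLen] > length(detr)) NULL else detr[idx]
    }
    lags <- vapply(windows, function(win) {
        sse <- vapply(-maxLag:maxLag, function(l) {
            w <- extract(win$pk, l)
            if (is.null(w)) Inf else sum((w - ref)^2)
        }, numeric(1))
        (-maxLag:maxLag)[which.min(sse)]
    }, integer(1) * 1)
    rows <- mapply(function(win, l) {
        w <- extract(win$pk, l)
        if (is.null(w)) win$w else w
    }, windows, lags, SIMPLIFY = FALSE)
    avg <- colMeans(do.call(rbind, rows))
    ## re-center the output frame on the peak of the low-noise average
    ## (the reference window's own localization error would otherwise
    ## shift the whole waveform)
    off <- which.max(avg) - (half + 1L)
    if (off != 0L) {
        rows <- mapply(function(win, l) {
            w <- extract(win$pk, l + off)
            if (is.null(w)) NULL else w
        }, windows, lags, SIMPLIFY = FALSE)
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows) >= 2L) avg <- colMeans(do.call(rbind, rows))
    }
    ## anchor the waveform at its own resting level: under noise the
    ## drift-filter baseline sits at the noise lower envelope, which would
    ## otherwise offset the whole average by a noise-dependent constant
    avg <- avg - stats::quantile(avg, 0.1, names = FALSE)
    data.frame(time_s = offs / fs, displacement_m = avg)
}
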