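## Internal helpers shared across modules.

## Run `expr` under a deterministic RNG state without disturbing the
## caller's stream.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Counter-based fan-out of one global seed into independent per-stream
## seeds, so adding a stream never perturbs existing ones.  Kept within
## 32-bit integer range.
.streamSeed <- function(seed, stream) {
    s <- (as.numeric(seed) %% 2147483647) + 1
    as.integer((s * 48271 + as.numeric(stream) * 16807) %% 2147483629)
}

## Monotone piecewise-cubic interpolator through keyframes (2-col matrix:
## x, y).  The keyframe list is split into monotone runs at its turning
## points and each run gets a Fritsch-Carlson monotone cubic, so the
## interpolant never overshoots an anchor (suppression-recovery
## trajectories turn at their keyframed minimum).
.keyframeFun <- function(keyframes) {
    x <- keyframes[, 1]
    y <- keyframes[, 2]
    if (length(x) == 1L) return(function(t) rep(y, length(t)))
    if (length(x) == 2L) return(stats::approxfun(x, y, rule = 2))
    dy <- sign(diff(y))
    ## last index of each monotone run (sign changes, treating 0 as neutral)
    turns <- integer()
    for (i in seq_len(length(dy) - 1L)) {
        if (dy[i] != 0 && dy[i + 1L] != 0 && dy[i] != dy[i + 1L])
            turns <- c(turns, i + 1L)
    }
    bounds <- c(1L, turns, length(x))
    segs <- lapply(seq_len(length(bounds) - 1L), function(k) {
        idx <- bounds[k]:bounds[k + 1L]
        if (length(idx) == 2L) stats::approxfun(x[idx], y[idx], rule = 2)
        else stats::splinefun(x[idx], y[idx], method = "monoH.FC")
    })
    starts <- x[bounds[-length(bounds)]]
    function(t) {
        k <- findInterval(t, starts, rightmost.closed = FALSE)
        k[k < 1L] <- 1L
        vapply(seq_along(t), function(i) segs[[k[i]]](t[i]), numeric(1))
    }
}

## Odd window size of roughly `seconds` duration, clamped to the trace.
.oddWindow <- function(seconds, samplingRate, n) {
    w <- max(3L, as.integer(round(seconds * samplingRate)))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > n) w <- if (n %% 2L == 1L) n else n - 1L
    max(w, 3L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
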