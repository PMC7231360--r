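## Reproducible file-level runs.  A run configuration is a named list (or
## JSON file) validated against a fixed schema; every simulation run
## writes its resolved configuration and a checksum manifest beside its
## outputs so a run directory is self-describing.

.CONFIG_KEYS <- list(
    ide = c("W_um", "S_um", "L_mm", "N"),
    cantilever = c("L_mm", "w_mm", "t_um", "E_GPa", "k_N_per_m"),
    circuit = c("rs_ohm", "q_s_sn", "n", "rp_ohm", "cp_f"),
    adhesion = c("sampling_interval_h", "duration_h", "noise_rel"),
    beating = c("day", "amplitude_m", "frequency_hz", "duration_s",
                "length_s", "sampling_rate_hz", "noise_sd_m", "jitter_cv"),
    drug = c("drug", "dose_nmol_L", "timepoints_h", "noise_sd_m",
             "noise_rel", "jitter_cv"),
    analysis = c("monitor_freq_hz", "threshold_fraction", "min_separation_s"),
    seed = NULL)

#' Validate a run configuration
#'
#' Checks a configuration list against the schema used by
#' [runSimulate()]/[runAnalyze()]: only the known blocks (`ide`,
#' `cantilever`, `circuit`, `adhesion`, `beating`, `drug`, `analysis`,
#' `seed`) and their known fields are accepted; unknown keys are rejected,
#' and a `seed` is required whenever a generator block is present.
#'
#' @param config named list, or path to a JSON file
#' @return the configuration list, invisibly, on success; otherwise an error
#' @export
validateRunConfig <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.list(config)) .stopf("config must be a named list or JSON object")
    unknown <- setdiff(names(config), names(.CONFIG_KEYS))
    if (length(unknown))
        .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    for (blk in setdiff(names(config), "seed")) {
        bad <- setdiff(names(config[[blk]]), .CONFIG_KEYS[[blk]])
        if (length(bad))
            .stopf("unknown key(s) in config block '%s': %s", blk,
                   paste(bad, collapse = ", "))
    }
    hasGenerator <- any(c("adhesion", "beating", "drug") %in% names(config))
    if (hasGenerator && is.null(config$seed))
        .stopf("config field 'seed' is required when a generator block is present")
    invisible(config)
}

.configCircuit <- function(config) {
    cc <- config$circuit
    if (is.null(cc)) return(defaultCircuitParams())
    CircuitParams(cc$rs_ohm, cc$q_s_sn, cc$n, cc$rp_ohm, cc$cp_f)
}

#' Simulate the experiment set described by a configuration
#'
#' Runs the generator blocks present in `config` and writes their outputs
#' as CSV files into `outDir`: an `adhesion` block yields
#' `adhesion_course.csv`, a `beating` block yields `trace_day<d>.csv` (or
#' `trace.csv` for explicit parameters), a `drug` block yields
#' `drug_trace_t<h>.csv` and `drug_spectrum_t<h>.csv` per timepoint plus
#' `drug_ci_course.csv`.  The resolved configuration
#' (`resolved_config.json`) and a manifest with the seed, package version
#' and per-file MD5 checksums (`manifest.json`) are written alongside, so
#' a re-run with the same configuration reproduces the directory
#' byte-identically.
#'
#' @param config named list or JSON path (see [validateRunConfig()])
#' @param outDir output directory (created if needed)
#' @return invisibly, the manifest as a list
#' @export
runSimulate <- function(config, outDir) {
    config <- validateRunConfig(config)
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        .stopf("cannot create output directory %s", outDir)
    seed <- config$seed
    files <- character()

    if (!is.null(config$adhesion)) {
        a <- config$adhesion
        ap <- adhesionCourseParams(
            baseline = .configCircuit(config),
            samplingIntervalH = a$sampling_interval_h %||% 3,
            durationH = a$duration_h %||% 72,
            noiseRel = a$noise_rel %||% 0)
        course <- simulateAdhesionCourse(ap, seed = seed)
        f <- file.path(outDir, "adhesion_course.csv")
        writeTimeCourse(course, f)
        files <- c(files, f)
    }
    if (!is.null(config$beating)) {
        b <- config$beating
        prof <- if (!is.null(b$day)) dayProfile(b$day)
                else list(amplitude = b$amplitude_m, frequency = b$frequency_hz,
                          duration = b$duration_s)
        tr <- simulateBeatingTrace(prof$amplitude, prof$frequency, prof$duration,
                                   lengthS = b$length_s %||% 15,
                                   samplingRate = b$sampling_rate_hz %||% 500,
                                   noiseSd = b$noise_sd_m %||% 50e-9,
                                   jitterCV = b$jitter_cv %||% 0.05,
                                   seed = seed)
        f <- file.path(outDir, if (!is.null(b$day))
            sprintf("trace_day%d.csv", as.integer(b$day)) else "trace.csv")
        writeTrace(tr, f)
        files <- c(files, f)
    }
    if (!is.null(config$drug)) {
        d <- config$drug
        exp <- applyDrugModel(d$drug, d$dose_nmol_L,
                              timepointsH = d$timepoints_h %||% seq(0, 24, 2),
                              circuit = .configCircuit(config),
                              noiseSd = d$noise_sd_m %||% 50e-9,
                              jitterCV = d$jitter_cv %||% 0.05,
                              noiseRel = d$noise_rel %||% 0.005,
                              seed = seed)
        for (i in seq_along(exp@timepointsH)) {
            tp <- exp@timepointsH[i]
            f1 <- file.path(outDir, sprintf("drug_trace_t%02d.csv", as.integer(tp)))
            f2 <- file.path(outDir, sprintf("drug_spectrum_t%02d.csv", as.integer(tp)))
            writeTrace(exp@traces[[i]], f1)
            writeSpectrum(exp@spectra[[i]], f2)
            files <- c(files, f1, f2)
        }
        f <- file.path(outDir, "drug_ci_course.csv")
        writeTimeCourse(exp@ciCourse, f)
        files <- c(files, f)
    }

    cfgPath <- file.path(outDir, "resolved_config.json")
    jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA)
    manifest <- list(
        package = "cardiosens",
        version = as.character(utils::packageVersion("cardiosens")),
        seed = seed,
        schema = 1L,
        files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Fit the equivalent circuit to a spectrum file
#'
#' Reads a spectrum CSV, runs [fitCircuit()] and (optionally) writes the
#' fit report JSON.
#'
#' @param spectrumFile spectrum CSV path
#' @param reportFile optional output JSON path
#' @param nStarts,weighting,seed passed to [fitCircuit()]
#' @return the \linkS4class{FitResult}
#' @export
runFitEis <- function(spectrumFile, reportFile = NULL, nStarts = 8,
                      weighting = "modulus", seed = 1L) {
    fit <- fitCircuit(readSpectrum(spectrumFile), nStarts = nStarts,
                      weighting = weighting, seed = seed)
    if (!is.null(reportFile)) writeFitReport(fit, reportFile)
    fit
}

#' Analyze trace / time-course files
#'
#' Runs beat detection and summarization on each trace CSV and the
#' normalized-resistance readout on a time-course CSV, writing tidy
#' long-format results (`beats.csv`: one row per beat;
#' `beat_summaries.csv`: one row per trace; `normalized_resistance.csv`:
#' one row per timepoint) plus a JSON summary.  Output is deterministic
#' given the inputs.
#'
#' @param traceFiles character vector of trace CSV paths (may be empty)
#' @param courseFile optional time-course CSV path
#' @param outDir output directory (created if needed)
#' @param k cantilever spring constant (N/m)
#' @param thresholdFraction beat-duration threshold fraction
#' @return invisibly, a list with the per-trace summaries and the
#'   normalized-resistance table
#' @export
runAnalyze <- function(traceFiles = character(), courseFile = NULL, outDir,
                       k = 0.015, thresholdFraction = 0.1) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        .stopf("cannot create output directory %s", outDir)
    beatRows <- list()
    sumRows <- list()
    summaries <- list()
    for (f in traceFiles) {
        tr <- readTrace(f)
        tab <- detectBeats(tr, thresholdFraction = thresholdFraction)
        s <- summarizeBeats(tr, tab, k)
        summaries[[basename(f)]] <- s
        if (nrow(tab))
            beatRows[[f]] <- cbind(trace = basename(f),
                                   tab[c("peakTime", "peakDisplacement",
                                         "amplitude", "duration", "interval")])
        sumRows[[f]] <- data.frame(
            trace = basename(f), beat_count = s@beatCount,
            frequency_hz = s@beatingFrequency, mean_amplitude_m = s@meanAmplitude,
            mean_force_n = s@meanForce, mean_duration_s = s@meanDuration,
            interval_cv = s@intervalCV)
    }
    if (length(sumRows)) {
        utils::write.csv(do.call(rbind, sumRows),
                         file.path(outDir, "beat_summaries.csv"), row.names = FALSE)
        if (length(beatRows))
            utils::write.csv(do.call(rbind, beatRows),
                             file.path(outDir, "beats.csv"), row.names = FALSE)
    }
    nr <- NULL
    if (!is.null(courseFile)) {
        nr <- normalizedResistanceCourse(readTimeCourse(courseFile))
        utils::write.csv(nr, file.path(outDir, "normalized_resistance.csv"),
                         row.names = FALSE)
    }
    jsonlite::write_json(
        list(n_traces = length(traceFiles),
             beat_counts = lapply(summaries, function(s) s@beatCount),
             course_analyzed = !is.null(courseFile)),
        file.path(outDir, "analysis_summary.json"), auto_unbox = TRUE, digits = NA)
    invisible(list(summaries = summaries, normalizedResistance = nr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
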