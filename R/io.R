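## File formats. The canonical clock is the 0-based sample index at the
## declared rate; time_s is derived on write and checked on read, never used
## as a primary key. CSV dialect: comma-separated, header required, UTF-8,
## no quoting of numeric fields.

#' Write / read a capacitance trace as CSV
#'
#' Columns `sample_index` (0-based, contiguous), `time_s`
#' (`sample_index / sample_rate`), `channel`, `capacitance`. Round-trips are
#' bit-exact for integer capacitance values.
#'
#' @param trace a [CapacitanceTrace].
#' @param path file path.
#' @return `writeTrace`: the path, invisibly. `readTrace`: a
#'   [CapacitanceTrace].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTrace(CapacitanceTrace(c(1000, 1000, 1300)), f)
#' readTrace(f)
#' @export
writeTrace <- function(trace, path) {
    stopifnot(is(trace, "CapacitanceTrace"))
    idx <- seq_along(trace@values) - 1L
    df <- data.frame(sample_index = idx,
                     time_s = idx / trace@sampleRateHz,
                     channel = trace@channelId,
                     capacitance = trace@values)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @param sampleRateHz sampling rate to assume when the file is too short to
#'   infer it from `time_s` (default 100).
#' @rdname writeTrace
#' @export
readTrace <- function(path, sampleRateHz = 100) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_index", "time_s", "channel", "capacitance")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("trace file %s is missing column(s): %s", path,
                     paste(miss, collapse = ", ")))
    if (nrow(df) == 0L) {
        warning(sprintf("trace file %s is empty", path))
        return(CapacitanceTrace(numeric(0), sampleRateHz, "ch1"))
    }
    if (!identical(as.integer(df$sample_index), seq_len(nrow(df)) - 1L)) {
        first <- which(as.integer(df$sample_index) != seq_len(nrow(df)) - 1L)[1L]
        stop(sprintf("non-contiguous sample_index at line %d of %s",
                     first + 1L, path))
    }
    ch <- unique(df$channel)
    if (length(ch) != 1L)
        stop(sprintf("trace file %s mixes channels: %s", path,
                     paste(ch, collapse = ", ")))
    bad <- which(!is.finite(df$capacitance) | df$capacitance < 0)
    if (length(bad))
        stop(sprintf("malformed capacitance at line %d of %s", bad[1L] + 1L,
                     path))
    rate <- if (nrow(df) >= 2L) 1 / (df$time_s[2L] - df$time_s[1L])
            else sampleRateHz
    CapacitanceTrace(df$capacitance, sampleRateHz = round(rate, 6),
                     channelId = as.character(ch))
}

#' Write / read a lighting log as CSV
#'
#' Columns `sample_index` (0-based), `channel`, `led_on` in `{0, 1}`.
#'
#' @param log a [LightingLog].
#' @param path file path.
#' @return `writeLighting`: the path, invisibly; `readLighting`: a
#'   [LightingLog].
#' @export
writeLighting <- function(log, path) {
    stopifnot(is(log, "LightingLog"))
    df <- data.frame(sample_index = seq_along(log@states) - 1L,
                     channel = log@channelId,
                     led_on = as.integer(log@states))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeLighting
#' @export
readLighting <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_index", "channel", "led_on")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("lighting file %s is missing column(s): %s", path,
                     paste(miss, collapse = ", ")))
    if (!all(df$led_on %in% c(0L, 1L)))
        stop(sprintf("'led_on' must be 0 or 1 in %s", path))
    ch <- unique(df$channel)
    if (nrow(df) && length(ch) != 1L)
        stop(sprintf("lighting file %s mixes channels", path))
    LightingLog(df$led_on == 1L,
                channelId = if (nrow(df)) as.character(ch) else "ch1")
}

#' Write / read ground-truth event tables as CSV
#'
#' Columns `channel`, `type` (`sip`/`touch`), `onset_s`, `duration_s`.
#'
#' @param events data.frame of events (see [groundTruth()]).
#' @param path file path.
#' @return `writeEvents`: the path, invisibly; `readEvents`: the events
#'   data.frame.
#' @export
writeEvents <- function(events, path) {
    need <- c("channel", "type", "onset_s", "duration_s")
    stopifnot(is.data.frame(events), all(need %in% names(events)))
    write.csv(events[, need, drop = FALSE], path, row.names = FALSE,
              quote = FALSE)
    invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("channel", "type", "onset_s", "duration_s")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("event file %s is missing column(s): %s", path,
                     paste(miss, collapse = ", ")))
    if (nrow(df) && !all(df$type %in% c("sip", "touch")))
        stop(sprintf("unknown event type in %s", path))
    df
}

MANIFEST_SCHEMA_VERSION <- 1L

#' Write / read an experiment manifest as JSON
#'
#' The manifest records the schema version, global parameters (sample rate,
#' duration, light channel) and one entry per fly (id, seed, file paths,
#' metadata), so a directory of per-fly CSVs is self-describing.
#'
#' @param manifest a list with elements `global` (named list) and `flies`
#'   (data.frame or list of per-fly entries with unique `fly_id`).
#' @param path file path.
#' @return `writeManifest`: the path, invisibly; `readManifest`: the
#'   manifest list.
#' @export
writeManifest <- function(manifest, path) {
    stopifnot(is.list(manifest))
    manifest$schema_version <- MANIFEST_SCHEMA_VERSION
    ids <- if (is.data.frame(manifest$flies)) manifest$flies$fly_id
           else vapply(manifest$flies, function(x) x$fly_id, character(1))
    if (anyDuplicated(ids))
        stop("fly_ids in the manifest must be unique")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(m$schema_version) ||
        m$schema_version != MANIFEST_SCHEMA_VERSION)
        stop(sprintf("unsupported manifest schema version in %s", path))
    m
}

#' Read simulation parameters from a JSON configuration file
#'
#' The document mirrors the parameter fields in snake_case, grouped under
#' `fly`, `opto` and `noise` (all groups and fields optional; omitted fields
#' keep their defaults).
#'
#' @param path JSON file path.
#' @return List with elements `fly` ([FlyParams]), `opto` ([OptoParams]) and
#'   `noise` ([NoiseParams]).
#' @export
readConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    pick <- function(group, map, ctor) {
        args <- list()
        for (nm in names(map)) {
            val <- cfg[[group]][[nm]]
            if (!is.null(val)) args[[map[[nm]]]] <- val
        }
        do.call(ctor, args)
    }
    flyMap <- c(bout_rate_per_min = "boutRatePerMin",
                continuation_prob = "continuationProb",
                sip_shape = "sipShape", sip_mean_s = "sipMeanS",
                sip_min_s = "sipMinS", intersip_mean_s = "intersipMeanS",
                touch_rate_per_min = "touchRatePerMin",
                touch_min_s = "touchMinS", touch_max_s = "touchMaxS",
                starvation_gain = "starvationGain",
                starvation_valence_gain = "starvationValenceGain",
                palatability1 = "palatability1",
                palatability2 = "palatability2")
    optoMap <- c(valence = "valence", intensity = "intensity",
                 hill_k = "hillK", hill_h = "hillH",
                 learning_rate = "learningRate",
                 feedback_gain = "feedbackGain")
    noiseMap <- c(baseline_level = "baselineLevel", drift_sd = "driftSd",
                  noise_sd = "noiseSd", sip_amp_min = "sipAmpMin",
                  sip_amp_max = "sipAmpMax", touch_amp_min = "touchAmpMin",
                  touch_amp_max = "touchAmpMax")
    list(fly = pick("fly", flyMap, FlyParams),
         opto = pick("opto", optoMap, OptoParams),
         noise = pick("noise", noiseMap, NoiseParams))
}

#' Write a simulated experiment to a directory
#'
#' Writes per-channel trace CSVs, the ground-truth event CSV, the lighting
#' CSV and a JSON manifest for one fly.
#'
#' @param exp a [SimulatedExperiment].
#' @param dir output directory (created if needed).
#' @param flyId identifier used in file names (default `"fly001"`).
#' @return The manifest list, invisibly.
#' @export
writeExperiment <- function(exp, dir, flyId = "fly001") {
    stopifnot(is(exp, "SimulatedExperiment"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        trace_ch1 = file.path(dir, sprintf("%s_trace_ch1.csv", flyId)),
        trace_ch2 = file.path(dir, sprintf("%s_trace_ch2.csv", flyId)),
        events = file.path(dir, sprintf("%s_events.csv", flyId)),
        lighting = file.path(dir, sprintf("%s_lighting.csv", flyId)))
    writeTrace(exp@traces[[1L]], paths$trace_ch1)
    writeTrace(exp@traces[[2L]], paths$trace_ch2)
    writeEvents(exp@groundTruth, paths$events)
    writeLighting(exp@lighting, paths$lighting)
    manifest <- list(
        global = list(sample_rate_hz = sampleRate(exp@traces[[1L]]),
                      duration_s = exp@durationS,
                      light_channel = exp@lightChannel),
        flies = list(list(fly_id = flyId, seed = exp@seed,
                          files = lapply(paths, basename),
                          metadata = list(
                              valence = exp@optoParams@valence,
                              intensity = exp@optoParams@intensity,
                              starvation_gain = exp@flyParams@starvationGain))))
    writeManifest(manifest, file.path(dir, sprintf("%s_manifest.json", flyId)))
    invisible(manifest)
}
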