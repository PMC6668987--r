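## Real-time closed-loop trigger: a running-minimum filter over the
## preceding window. The contract is defined sample-by-sample; the batch
## implementation is a vectorised equivalent and is checked against a
## brute-force recomputation in the test suite.

#' Advance the closed-loop trigger by one capacitance sample
#'
#' The streaming form of the trigger. The LED is commanded on exactly when
#' at least one preceding sample exists and the current sample exceeds the
#' minimum of the preceding window by strictly more than the threshold.
#' Before the window has filled, the minimum is taken over however many
#' preceding samples exist, so the very first sample can never trigger.
#' Because the window slides, a sustained plateau stops triggering once the
#' window contains only plateau values: the LED follows the falling edge or
#' shuts off after one full window on a plateau, whichever comes sooner.
#'
#' @param sample a single finite, non-negative capacitance reading.
#' @param state the running state returned by the previous call, or `NULL`
#'   to start a fresh stream.
#' @param config a [ControllerConfig].
#' @return A list with elements `ledOn` (logical) and `state` (opaque
#'   running state to pass to the next call).
#' @examples
#' cfg <- ControllerConfig()
#' st <- controllerStep(1000, NULL, cfg)       # first sample never triggers
#' st$ledOn
#' controllerStep(1300, st$state, cfg)$ledOn   # 300 > 100 above window min
#' @seealso [runController()] for whole traces.
#' @export
controllerStep <- function(sample, state = NULL, config = ControllerConfig()) {
    stopifnot(is(config, "ControllerConfig"))
    if (length(sample) != 1L || !is.numeric(sample) || !is.finite(sample) ||
        sample < 0)
        stop("'sample' must be a single finite, non-negative capacitance reading")
    if (is.null(state))
        state <- list(window = numeric(0))
    w <- state$window
    ledOn <- length(w) > 0L && (sample - min(w)) > config@threshold
    w <- c(w, sample)
    if (length(w) > config@windowSamples)
        w <- w[(length(w) - config@windowSamples + 1L):length(w)]
    list(ledOn = ledOn, state = list(window = w))
}

#' Run the closed-loop trigger over a whole capacitance trace
#'
#' Batch equivalent of feeding every sample through [controllerStep()] in
#' order; the two are bit-identical. `states[i]` is `TRUE` iff
#' `values[i] - min(values[max(1, i - w) : (i - 1)]) > threshold`, with
#' `w = windowSamples(config)`.
#'
#' @param trace a [CapacitanceTrace].
#' @param config a [ControllerConfig]; its sample rate should match the
#'   trace's (a mismatch only affects time-unit bookkeeping, not the
#'   sample-domain rule).
#' @return A [LightingLog] of the same length as the trace.
#' @examples
#' tr <- CapacitanceTrace(c(rep(1000, 20), rep(1300, 20)))
#' log <- runController(tr)
#' sum(ledStates(log))  # plateau rule: at most one window of on-samples
#' @export
runController <- function(trace, config = ControllerConfig()) {
    stopifnot(is(trace, "CapacitanceTrace"), is(config, "ControllerConfig"))
    v <- trace@values
    n <- length(v)
    if (n == 0L)
        return(LightingLog(logical(0), channelId = trace@channelId))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
        stop(sprintf("malformed capacitance value at sample %d", bad[1L]))
    prevMin <- rep(Inf, n)
    for (k in seq_len(min(config@windowSamples, n - 1L))) {
        prevMin[(k + 1L):n] <- pmin(prevMin[(k + 1L):n], v[1L:(n - k)])
    }
    LightingLog((v - prevMin) > config@threshold, channelId = trace@channelId)
}

#' Extract interaction events from a lighting log
#'
#' Each maximal run of on-samples is one LED activation, i.e. one food
#' "interaction" of the assay (a superset of sips that includes brief leg
#' touches). Events are returned as an [IRanges::IRanges] over 1-based
#' sample indices, ordered by onset; widths are the event durations in
#' samples.
#'
#' @param log a [LightingLog].
#' @return An `IRanges`; `S4Vectors::metadata()` carries the channel id.
#' @examples
#' log <- LightingLog(c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
#' illuminationEvents(log)  # runs at samples 2-3 and 6
#' @export
illuminationEvents <- function(log) {
    stopifnot(is(log, "LightingLog"))
    s <- log@states
    if (!length(s) || !any(s)) {
        ev <- IRanges::IRanges()
    } else {
        r <- rle(s)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values
        ev <- IRanges::IRanges(start = starts[keep], end = ends[keep])
    }
    S4Vectors::metadata(ev) <- list(channelId = log@channelId)
    ev
}

#' Count interactions (LED activations) in a lighting log
#'
#' @param log a [LightingLog].
#' @return Integer count of maximal on-runs.
#' @examples
#' countInteractions(LightingLog(c(TRUE, TRUE, FALSE, TRUE)))
#' @export
countInteractions <- function(log) {
    length(illuminationEvents(log))
}

#' Interaction onset times in seconds
#'
#' Convenience used by the analytics layer: onsets of the maximal on-runs of
#' a lighting log, converted to seconds on the trace clock (sample index /
#' rate, 0-based).
#'
#' @param log a [LightingLog].
#' @param sampleRateHz samples per second of the source trace.
#' @return Numeric vector of onset times in seconds.
#' @export
interactionOnsets <- function(log, sampleRateHz = 100) {
    ev <- illuminationEvents(log)
    (IRanges::start(ev) - 1) / sampleRateHz
}
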