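## Accessor generics. Kept deliberately small: parameter objects are read
## through these rather than by slot access.

#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))
#' @export
setGeneric("ledStates", function(x) standardGeneric("ledStates"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setGeneric("lightingLog", function(x) standardGeneric("lightingLog"))
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))
#' @export
setGeneric("lightChannel", function(x) standardGeneric("lightChannel"))
#' @export
setGeneric("experimentSeed", function(x) standardGeneric("experimentSeed"))
#' @export
setGeneric("experimentDuration", function(x) standardGeneric("experimentDuration"))

#' Accessors for trace, log and experiment objects
#'
#' @param x a [CapacitanceTrace], [LightingLog] or [SimulatedExperiment].
#' @return `traceValues`: numeric vector of capacitance readings;
#'   `sampleRate`: samples per second; `channelId`: channel identifier;
#'   `ledStates`: logical per-sample LED states; `traces`: list of traces;
#'   `groundTruth`: ground-truth event data.frame; `lightingLog`: the
#'   [LightingLog]; `lightChannel`: index of the light-paired channel;
#'   `experimentSeed` / `experimentDuration`: the seed and duration used.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("traceValues", "CapacitanceTrace", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CapacitanceTrace", function(x) x@sampleRateHz)
#' @rdname accessors
#' @export
setMethod("channelId", "CapacitanceTrace", function(x) x@channelId)
#' @rdname accessors
#' @export
setMethod("channelId", "LightingLog", function(x) x@channelId)
#' @rdname accessors
#' @export
setMethod("ledStates", "LightingLog", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("traces", "SimulatedExperiment", function(x) x@traces)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedExperiment", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("lightingLog", "SimulatedExperiment", function(x) x@lighting)
#' @rdname accessors
#' @export
setMethod("lightChannel", "SimulatedExperiment", function(x) x@lightChannel)
#' @rdname accessors
#' @export
setMethod("experimentSeed", "SimulatedExperiment", function(x) x@seed)
#' @rdname accessors
#' @export
setMethod("experimentDuration", "SimulatedExperiment", function(x) x@durationS)

#' @rdname accessors
#' @export
setMethod("length", "CapacitanceTrace", function(x) length(x@values))
#' @rdname accessors
#' @export
setMethod("length", "LightingLog", function(x) length(x@states))

setMethod("show", "CapacitanceTrace", function(object) {
    cat(sprintf("CapacitanceTrace '%s': %d samples @ %g Hz (%.1f s)\n",
                object@channelId, length(object@values),
                object@sampleRateHz,
                length(object@values) / object@sampleRateHz))
    if (length(object@values))
        cat(sprintf("  range: [%g, %g] capacitance units\n",
                    min(object@values), max(object@values)))
})

setMethod("show", "LightingLog", function(object) {
    n <- length(object@states)
    on <- sum(object@states)
    cat(sprintf("LightingLog '%s': %d samples, %d on (%.2f%%), %d interaction(s)\n",
                object@channelId, n, on,
                if (n) 100 * on / n else 0,
                countInteractions(object)))
})

setMethod("show", "ControllerConfig", function(object) {
    cat(sprintf(
        "ControllerConfig: window %d samples (%.0f ms @ %g Hz), threshold %g units\n",
        object@windowSamples,
        1000 * object@windowSamples / object@sampleRateHz,
        object@sampleRateHz, object@threshold))
})

setMethod("show", "BinnedComparison", function(object) {
    cat(sprintf("BinnedComparison: %d bins, %d included\n",
                length(object@sipCounts), length(object@includedBins)))
    cat(sprintf("  R^2 = %.3f, OLS slope = %.3f, illuminations/sips = %.3f\n",
                object@rSquared, object@olsSlope, object@totalRatio))
})

setMethod("show", "SimulatedExperiment", function(object) {
    gt <- object@groundTruth
    cat(sprintf("SimulatedExperiment: %.0f s @ %g Hz, seed %d\n",
                object@durationS, sampleRate(object@traces[[1L]]),
                object@seed))
    cat(sprintf("  ground truth: %d sip(s), %d touch(es); light channel: %d\n",
                sum(gt$type == "sip"), sum(gt$type == "touch"),
                object@lightChannel))
    cat(sprintf("  valence %g at %g mW/cm2; %d LED interaction(s)\n",
                object@optoParams@valence, object@optoParams@intensity,
                countInteractions(object@lighting)))
})
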