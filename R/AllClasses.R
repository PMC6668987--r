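#' @import methods
#' @importFrom stats rexp rgamma rnorm rpois runif runmed sd lm median var coef
#' @importFrom utils read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Controller-side classes
## ---------------------------------------------------------------------------

#' Configuration of the real-time closed-loop trigger
#'
#' The trigger keeps a running minimum over the `windowSamples` samples
#' preceding the current one and switches the LED on whenever the current
#' capacitance reading exceeds that minimum by more than `threshold`
#' capacitance units. At the default 100 Hz sampling rate the default window
#' of 10 samples spans 100 ms, so a sustained plateau can keep the LED on for
#' at most 100 ms.
#'
#' @slot windowSamples integer(1), number of preceding samples in the
#'   running-minimum window (default 10).
#' @slot threshold numeric(1), positive trigger threshold in capacitance
#'   units (default 100).
#' @slot sampleRateHz numeric(1), samples per second (default 100).
#' @export
setClass("ControllerConfig",
    representation(windowSamples = "integer",
                   threshold = "numeric",
                   sampleRateHz = "numeric"))

setValidity("ControllerConfig", function(object) {
    msg <- character()
    if (length(object@windowSamples) != 1L || is.na(object@windowSamples) ||
        object@windowSamples < 1L)
        msg <- c(msg, "'windowSamples' must be a single integer >= 1")
    if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
        object@threshold <= 0)
        msg <- c(msg, "'threshold' must be a single positive finite number")
    if (length(object@sampleRateHz) != 1L || !is.finite(object@sampleRateHz) ||
        object@sampleRateHz < 1)
        msg <- c(msg, "'sampleRateHz' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param windowSamples,threshold,sampleRateHz see slots.
#' @return A `ControllerConfig` object.
#' @rdname ControllerConfig-class
#' @examples
#' ControllerConfig()
#' @export
ControllerConfig <- function(windowSamples = 10L, threshold = 100,
                             sampleRateHz = 100) {
    new("ControllerConfig", windowSamples = as.integer(windowSamples),
        threshold = as.numeric(threshold),
        sampleRateHz = as.numeric(sampleRateHz))
}

#' A uniformly sampled capacitance trace for one arena channel
#'
#' @slot channelId character(1) channel identifier.
#' @slot sampleRateHz numeric(1) samples per second.
#' @slot values numeric vector of finite, non-negative capacitance readings
#'   (integer capacitance-to-digital codes are canonical; real values are
#'   accepted).
#' @export
setClass("CapacitanceTrace",
    representation(channelId = "character",
                   sampleRateHz = "numeric",
                   values = "numeric"))

setValidity("CapacitanceTrace", function(object) {
    msg <- character()
    if (length(object@channelId) != 1L)
        msg <- c(msg, "'channelId' must be a single string")
    if (length(object@sampleRateHz) != 1L || !is.finite(object@sampleRateHz) ||
        object@sampleRateHz < 1)
        msg <- c(msg, "'sampleRateHz' must be >= 1")
    bad <- which(!is.finite(object@values) | object@values < 0)
    if (length(bad))
        msg <- c(msg, sprintf(
            "capacitance values must be finite and >= 0; first offending sample index: %d",
            bad[1L]))
    if (length(msg)) msg else TRUE
})

#' @param values numeric vector of capacitance readings.
#' @param sampleRateHz samples per second.
#' @param channelId channel identifier.
#' @return A `CapacitanceTrace`.
#' @rdname CapacitanceTrace-class
#' @examples
#' tr <- CapacitanceTrace(rep(1000, 100))
#' length(traceValues(tr))
#' @export
CapacitanceTrace <- function(values, sampleRateHz = 100, channelId = "ch1") {
    new("CapacitanceTrace", channelId = as.character(channelId),
        sampleRateHz = as.numeric(sampleRateHz),
        values = as.numeric(values))
}

#' Per-sample LED state produced by the closed-loop trigger
#'
#' One logical value per input sample; `TRUE` means the LED was on at that
#' sample. Maximal runs of `TRUE` are the "interactions" of the assay
#' (see [illuminationEvents()]).
#'
#' @slot channelId character(1) source channel.
#' @slot states logical vector, same length as the source trace.
#' @export
setClass("LightingLog",
    representation(channelId = "character",
                   states = "logical"))

setValidity("LightingLog", function(object) {
    msg <- character()
    if (length(object@channelId) != 1L)
        msg <- c(msg, "'channelId' must be a single string")
    if (anyNA(object@states))
        msg <- c(msg, "'states' must not contain NA")
    if (length(msg)) msg else TRUE
})

#' @param states logical vector of per-sample LED states.
#' @param channelId source channel identifier.
#' @return A `LightingLog`.
#' @rdname LightingLog-class
#' @export
LightingLog <- function(states, channelId = "ch1") {
    new("LightingLog", channelId = as.character(channelId),
        states = as.logical(states))
}

## ---------------------------------------------------------------------------
## Sip caller
## ---------------------------------------------------------------------------

#' Configuration of the post hoc sip caller
#'
#' The caller estimates a rolling-median baseline, finds segments more than
#' `amplitudeThreshold` units above it, merges segments separated by gaps
#' shorter than `mergeGapMs`, and keeps segments whose duration lies within
#' `[minDurationMs, maxDurationMs]`. The duration filter is what makes called
#' sips a subset of the real-time trigger's interactions: brief leg touches
#' illuminate the LED but are rejected here.
#'
#' @slot baselineWindowS rolling-median window for baseline estimation,
#'   seconds (default 2).
#' @slot amplitudeThreshold units above baseline to count as contact
#'   (default 100).
#' @slot minDurationMs minimum sip duration, ms (default 100).
#' @slot maxDurationMs maximum sip duration, ms (default 5000).
#' @slot mergeGapMs gaps strictly shorter than this between supra-threshold
#'   segments are merged, ms (default 20).
#' @export
setClass("SipCallerConfig",
    representation(baselineWindowS = "numeric",
                   amplitudeThreshold = "numeric",
                   minDurationMs = "numeric",
                   maxDurationMs = "numeric",
                   mergeGapMs = "numeric"))

setValidity("SipCallerConfig", function(object) {
    msg <- character()
    vals <- c(object@baselineWindowS, object@amplitudeThreshold,
              object@minDurationMs, object@maxDurationMs, object@mergeGapMs)
    if (length(vals) != 5L || !all(is.finite(vals)) || any(vals <= 0))
        msg <- c(msg, "all sip-caller parameters must be single positive numbers")
    else if (object@minDurationMs >= object@maxDurationMs)
        msg <- c(msg, "'minDurationMs' must be < 'maxDurationMs'")
    if (length(msg)) msg else TRUE
})

#' @param baselineWindowS,amplitudeThreshold,minDurationMs,maxDurationMs,mergeGapMs
#'   see slots.
#' @return A `SipCallerConfig`.
#' @rdname SipCallerConfig-class
#' @export
SipCallerConfig <- function(baselineWindowS = 2, amplitudeThreshold = 100,
                            minDurationMs = 100, maxDurationMs = 5000,
                            mergeGapMs = 20) {
    new("SipCallerConfig", baselineWindowS = as.numeric(baselineWindowS),
        amplitudeThreshold = as.numeric(amplitudeThreshold),
        minDurationMs = as.numeric(minDurationMs),
        maxDurationMs = as.numeric(maxDurationMs),
        mergeGapMs = as.numeric(mergeGapMs))
}

#' Binned comparison between called sips and LED illuminations
#'
#' Result of [compareAlgorithms()]: sip and illumination counts per time bin,
#' the indices of bins retained for analysis (bins with zero counts in both
#' series are excluded — times when the fly was not interacting with the
#' food), the ordinary least-squares fit of illuminations on sips, and the
#' ratio of total illuminations to total sips over the retained bins.
#'
#' @slot sipCounts,illuminationCounts integer count vectors per bin.
#' @slot includedBins integer indices (1-based) of retained bins.
#' @slot rSquared,olsSlope,olsIntercept OLS fit of illuminations on sips.
#' @slot totalRatio sum(illuminations)/sum(sips) over retained bins.
#' @export
setClass("BinnedComparison",
    representation(sipCounts = "integer",
                   illuminationCounts = "integer",
                   includedBins = "integer",
                   rSquared = "numeric",
                   olsSlope = "numeric",
                   olsIntercept = "numeric",
                   totalRatio = "numeric"))

setValidity("BinnedComparison", function(object) {
    msg <- character()
    if (length(object@sipCounts) != length(object@illuminationCounts))
        msg <- c(msg, "count vectors must have equal length")
    if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
        msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulator parameter classes
## ---------------------------------------------------------------------------

#' Behavioral parameters of a simulated fly
#'
#' The simulated fly alternates between idle periods and feeding bouts
#' (a semi-Markov renewal process). Idle waits are exponential with rate
#' `boutRatePerMin * starvationGain` per minute. Each bout happens on one of
#' the two channels, chosen with probability proportional to additive choice
#' weights (intrinsic palatability plus, on the light-paired channel, the
#' experienced optogenetic valence; see [OptoParams()]). Within a bout, sips
#' follow a geometric continuation rule; sip durations are gamma distributed
#' and truncated below so that every sip outlasts the trigger's 100 ms
#' plateau window. Brief non-sip leg touches occur within bouts and never
#' count as sips in the ground truth.
#'
#' @slot boutRatePerMin baseline bout initiation rate, per minute (default 1.5).
#' @slot continuationProb per-sip probability of another sip in the bout
#'   (default 0.8).
#' @slot sipShape gamma shape of the sip-duration distribution (default 4).
#' @slot sipMeanS mean of the untruncated sip duration, seconds (default 0.25).
#' @slot sipMinS lower truncation of sip duration, seconds (default 0.11).
#' @slot intersipMeanS mean exponential inter-sip interval, seconds
#'   (default 0.5).
#' @slot touchRatePerMin rate of brief non-sip touches per minute of bout
#'   time (default 0.6).
#' @slot touchMinS,touchMaxS uniform touch-duration bounds, seconds
#'   (defaults 0.03, 0.08).
#' @slot starvationGain multiplier on the bout rate (default 1; > 1 models
#'   starvation).
#' @slot starvationValenceGain multiplier applied to appetitive (positive)
#'   valence only (default 1).
#' @slot palatability1,palatability2 intrinsic attractiveness of the
#'   light-paired (channel 1) and unpaired (channel 2) foods (defaults 1, 1).
#' @export
setClass("FlyParams",
    representation(boutRatePerMin = "numeric",
                   continuationProb = "numeric",
                   sipShape = "numeric",
                   sipMeanS = "numeric",
                   sipMinS = "numeric",
                   intersipMeanS = "numeric",
                   touchRatePerMin = "numeric",
                   touchMinS = "numeric",
                   touchMaxS = "numeric",
                   starvationGain = "numeric",
                   starvationValenceGain = "numeric",
                   palatability1 = "numeric",
                   palatability2 = "numeric"))

setValidity("FlyParams", function(object) {
    msg <- character()
    pos <- c(boutRatePerMin = object@boutRatePerMin,
             sipShape = object@sipShape, sipMeanS = object@sipMeanS,
             sipMinS = object@sipMinS, intersipMeanS = object@intersipMeanS,
             touchMinS = object@touchMinS, touchMaxS = object@touchMaxS,
             starvationGain = object@starvationGain,
             starvationValenceGain = object@starvationValenceGain)
    if (!all(vapply(pos, function(x) length(x) == 1L && is.finite(x) && x > 0,
                    logical(1))))
        msg <- c(msg, "rate, duration and gain parameters must be single positive numbers")
    if (length(object@continuationProb) != 1L ||
        !is.finite(object@continuationProb) ||
        object@continuationProb < 0 || object@continuationProb >= 1)
        msg <- c(msg, "'continuationProb' must lie in [0, 1)")
    if (length(object@touchRatePerMin) != 1L ||
        !is.finite(object@touchRatePerMin) || object@touchRatePerMin < 0)
        msg <- c(msg, "'touchRatePerMin' must be >= 0")
    if (isTRUE(object@touchMinS > object@touchMaxS))
        msg <- c(msg, "'touchMinS' must be <= 'touchMaxS'")
    if (isTRUE(object@sipMinS <= 0.1))
        msg <- c(msg, "'sipMinS' must exceed 0.1 s so every sip outlasts the 100 ms plateau window")
    for (p in c(object@palatability1, object@palatability2))
        if (length(p) != 1L || !is.finite(p) || p < 0)
            msg <- c(msg, "palatabilities must be single non-negative numbers")
    if (length(msg)) msg else TRUE
})

#' @param boutRatePerMin,continuationProb,sipShape,sipMeanS,sipMinS see slots.
#' @param intersipMeanS,touchRatePerMin,touchMinS,touchMaxS see slots.
#' @param starvationGain,starvationValenceGain,palatability1,palatability2
#'   see slots.
#' @return A `FlyParams` object.
#' @rdname FlyParams-class
#' @examples
#' FlyParams(starvationGain = 2)  # a starved fly
#' @export
FlyParams <- function(boutRatePerMin = 1.5, continuationProb = 0.8,
                      sipShape = 4, sipMeanS = 0.25, sipMinS = 0.11,
                      intersipMeanS = 0.5, touchRatePerMin = 0.6,
                      touchMinS = 0.03, touchMaxS = 0.08,
                      starvationGain = 1, starvationValenceGain = 1,
                      palatability1 = 1, palatability2 = 1) {
    new("FlyParams", boutRatePerMin = as.numeric(boutRatePerMin),
        continuationProb = as.numeric(continuationProb),
        sipShape = as.numeric(sipShape), sipMeanS = as.numeric(sipMeanS),
        sipMinS = as.numeric(sipMinS),
        intersipMeanS = as.numeric(intersipMeanS),
        touchRatePerMin = as.numeric(touchRatePerMin),
        touchMinS = as.numeric(touchMinS), touchMaxS = as.numeric(touchMaxS),
        starvationGain = as.numeric(starvationGain),
        starvationValenceGain = as.numeric(starvationValenceGain),
        palatability1 = as.numeric(palatability1),
        palatability2 = as.numeric(palatability2))
}

#' Optogenetic stimulation parameters
#'
#' `valence` is the signed behavioral effect of activating the targeted
#' neurons: positive for appetitive populations (e.g. sweet gustatory
#' receptor neurons, PAM dopaminergic neurons), negative for aversive ones
#' (bitter GRNs, PPL1), and 0 for non-retinal controls. The effective drive
#' scales with light intensity through a saturating Hill response
#' (see [intensityResponse()]). `learningRate` sets how fast the
#' experienced-valence weight relaxes toward its asymptote across bouts,
#' producing the ramp-then-plateau preference seen over the first 10-15 min
#' of an experiment. `feedbackGain` models command-neuron-like populations
#' (e.g. Fdg) whose offset immediately re-triggers a sip, trapping the fly
#' in a feeding loop.
#'
#' @slot valence signed real; + appetitive, - aversive, 0 control.
#' @slot intensity light intensity, mW/cm2; the assay's standard grid is
#'   0, 0.12, 1.85, 6.56, 11.26, 16.44.
#' @slot hillK half-maximal intensity, mW/cm2 (default 1.85).
#' @slot hillH Hill coefficient (default 2).
#' @slot learningRate per-bout approach rate of the experienced-valence
#'   weight, in `[0, 1]` (default 0.15).
#' @slot feedbackGain probability that LED offset immediately re-initiates a
#'   sip on the light-paired channel, in `[0, 1)` (default 0).
#' @export
setClass("OptoParams",
    representation(valence = "numeric",
                   intensity = "numeric",
                   hillK = "numeric",
                   hillH = "numeric",
                   learningRate = "numeric",
                   feedbackGain = "numeric"))

setValidity("OptoParams", function(object) {
    msg <- character()
    if (length(object@valence) != 1L || !is.finite(object@valence))
        msg <- c(msg, "'valence' must be a single finite number")
    if (length(object@intensity) != 1L || !is.finite(object@intensity) ||
        object@intensity < 0)
        msg <- c(msg, "'intensity' must be >= 0")
    if (length(object@hillK) != 1L || !is.finite(object@hillK) ||
        object@hillK <= 0)
        msg <- c(msg, "'hillK' must be > 0")
    if (length(object@hillH) != 1L || !is.finite(object@hillH) ||
        object@hillH <= 0)
        msg <- c(msg, "'hillH' must be > 0")
    if (length(object@learningRate) != 1L ||
        !is.finite(object@learningRate) ||
        object@learningRate < 0 || object@learningRate > 1)
        msg <- c(msg, "'learningRate' must lie in [0, 1]")
    if (length(object@feedbackGain) != 1L ||
        !is.finite(object@feedbackGain) ||
        object@feedbackGain < 0 || object@feedbackGain >= 1)
        msg <- c(msg, "'feedbackGain' must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @param valence,intensity,hillK,hillH,learningRate,feedbackGain see slots.
#' @return An `OptoParams` object.
#' @rdname OptoParams-class
#' @examples
#' OptoParams(valence = 2, intensity = 11.26)   # strong appetitive drive
#' OptoParams(valence = -2, intensity = 11.26)  # strong aversive drive
#' @export
OptoParams <- function(valence = 0, intensity = 11.26, hillK = 1.85,
                       hillH = 2, learningRate = 0.15, feedbackGain = 0) {
    new("OptoParams", valence = as.numeric(valence),
        intensity = as.numeric(intensity), hillK = as.numeric(hillK),
        hillH = as.numeric(hillH), learningRate = as.numeric(learningRate),
        feedbackGain = as.numeric(feedbackGain))
}

#' Signal-synthesis parameters for simulated capacitance traces
#'
#' Traces are a baseline random walk plus white noise; during each
#' ground-truth event an amplitude drawn per event (uniform within the
#' type-specific bounds) is added with single-sample rise and fall. Default
#' amplitudes strictly exceed the trigger threshold so every real contact can
#' illuminate the LED; the published recordings do not characterise amplitude
#' distributions, so these defaults are package choices.
#'
#' @slot baselineLevel starting capacitance, units (default 1000).
#' @slot driftSd per-sample random-walk step s.d., units (default 0.5).
#' @slot noiseSd white-noise s.d., units (default 5).
#' @slot sipAmpMin,sipAmpMax uniform sip-amplitude bounds, units
#'   (defaults 200, 500).
#' @slot touchAmpMin,touchAmpMax uniform touch-amplitude bounds, units
#'   (defaults 120, 250).
#' @export
setClass("NoiseParams",
    representation(baselineLevel = "numeric",
                   driftSd = "numeric",
                   noiseSd = "numeric",
                   sipAmpMin = "numeric",
                   sipAmpMax = "numeric",
                   touchAmpMin = "numeric",
                   touchAmpMax = "numeric"))

setValidity("NoiseParams", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && is.finite(x)
    if (!one(object@baselineLevel) || object@baselineLevel < 0)
        msg <- c(msg, "'baselineLevel' must be >= 0")
    if (!one(object@driftSd) || object@driftSd < 0 ||
        !one(object@noiseSd) || object@noiseSd < 0)
        msg <- c(msg, "noise standard deviations must be >= 0")
    amps <- c(object@sipAmpMin, object@sipAmpMax,
              object@touchAmpMin, object@touchAmpMax)
    if (!all(vapply(amps, one, logical(1))) || any(amps <= 0))
        msg <- c(msg, "amplitude bounds must be positive")
    else {
        if (object@sipAmpMin > object@sipAmpMax ||
            object@touchAmpMin > object@touchAmpMax)
            msg <- c(msg, "amplitude lower bounds must not exceed upper bounds")
    }
    if (length(msg)) msg else TRUE
})

#' @param baselineLevel,driftSd,noiseSd,sipAmpMin,sipAmpMax see slots.
#' @param touchAmpMin,touchAmpMax see slots.
#' @return A `NoiseParams` object.
#' @rdname NoiseParams-class
#' @export
NoiseParams <- function(baselineLevel = 1000, driftSd = 0.5, noiseSd = 5,
                        sipAmpMin = 200, sipAmpMax = 500,
                        touchAmpMin = 120, touchAmpMax = 250) {
    new("NoiseParams", baselineLevel = as.numeric(baselineLevel),
        driftSd = as.numeric(driftSd), noiseSd = as.numeric(noiseSd),
        sipAmpMin = as.numeric(sipAmpMin), sipAmpMax = as.numeric(sipAmpMax),
        touchAmpMin = as.numeric(touchAmpMin),
        touchAmpMax = as.numeric(touchAmpMax))
}

#' A complete simulated two-channel closed-loop experiment
#'
#' Emitted by [simulateFly()]: one capacitance trace per channel, the
#' ground-truth event table (channel, type sip/touch, onset and duration in
#' seconds), the lighting log obtained by running the closed-loop trigger on
#' the light-paired channel's trace, and the full parameter set plus seed so
#' the experiment can be regenerated bit-exactly. The LED is always paired
#' with channel 1 (Food 1, the left side).
#'
#' @slot traces list of two [CapacitanceTrace] objects.
#' @slot groundTruth data.frame with columns `channel`, `type`, `onset_s`,
#'   `duration_s`.
#' @slot lighting [LightingLog] for the light-paired channel.
#' @slot lightChannel integer(1), index of the light-paired channel (1).
#' @slot flyParams,optoParams,noiseParams the generating parameters.
#' @slot controllerConfig the in-loop [ControllerConfig].
#' @slot durationS experiment duration, seconds.
#' @slot seed integer seed of the per-fly random stream.
#' @export
setClass("SimulatedExperiment",
    representation(traces = "list",
                   groundTruth = "data.frame",
                   lighting = "LightingLog",
                   lightChannel = "integer",
                   flyParams = "FlyParams",
                   optoParams = "OptoParams",
                   noiseParams = "NoiseParams",
                   controllerConfig = "ControllerConfig",
                   durationS = "numeric",
                   seed = "integer"))

setValidity("SimulatedExperiment", function(object) {
    msg <- character()
    if (length(object@traces) != 2L ||
        !all(vapply(object@traces, is, logical(1), "CapacitanceTrace")))
        msg <- c(msg, "'traces' must be a list of two CapacitanceTrace objects")
    need <- c("channel", "type", "onset_s", "duration_s")
    if (!all(need %in% names(object@groundTruth)))
        msg <- c(msg, sprintf("'groundTruth' must have columns %s",
                              paste(need, collapse = ", ")))
    if (!identical(object@lightChannel, 1L))
        msg <- c(msg, "'lightChannel' must be 1 (the LED is paired with Food 1)")
    if (length(msg)) msg else TRUE
})
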