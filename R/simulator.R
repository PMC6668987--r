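## Agent-based closed-loop feeding simulator.
##
## A fly alternates between idle periods and feeding bouts on one of two
## channels (semi-Markov renewal). The light-paired channel (channel 1)
## carries an experienced-valence weight u that relaxes across bouts toward
## valence * Hill(intensity) * starvation-valence-gain; channel choice uses
## additive weights w1 = max(p1 + u, EPS_WEIGHT), w2 = max(p2, EPS_WEIGHT).
## Illuminated sips modulate the within-bout continuation probability, and a
## feedback gain can re-trigger sips at LED offset (command-neuron regime).
## Traces are synthesised from the event schedule and the closed-loop
## trigger is run on the light channel's trace to produce the lighting log.

## floor on choice weights (keeps the aversive side reachable, so shared
## unpalatability drives preference toward 0)
EPS_WEIGHT <- 0.05

## minimum spacing between consecutive events on a channel, seconds.
## Guarantees >= 2 baseline samples between events at 100 Hz, so the trigger
## sees a falling edge between them and every real contact can illuminate.
MIN_GAP_S <- 0.025

#' Saturating Hill response of optogenetic drive to light intensity
#'
#' `I^h / (I^h + K^h)`: 0 at zero intensity, 0.5 at `I = K`, approaching 1
#' at high intensity. Models the observed behavior of light-side preference
#' being absent without light and relatively stable above a threshold
#' intensity. Deliberately monotone: the drop in interaction counts seen for
#' sweet-neuron activation at very high intensities is not modelled.
#'
#' @param I light intensity, mW/cm2 (vectorised; must be >= 0).
#' @param K half-maximal intensity, mW/cm2 (> 0).
#' @param h Hill coefficient (> 0).
#' @return Effect fraction in `[0, 1)`.
#' @examples
#' intensityResponse(c(0, 1.85, 11.26))
#' @export
intensityResponse <- function(I, K = 1.85, h = 2) {
    if (!is.numeric(I) || anyNA(I) || any(I < 0))
        stop("'I' must be non-negative")
    if (length(K) != 1L || !is.finite(K) || K <= 0) stop("'K' must be > 0")
    if (length(h) != 1L || !is.finite(h) || h <= 0) stop("'h' must be > 0")
    I^h / (I^h + K^h)
}

#' Draw sip durations from the simulator's sip-duration distribution
#'
#' Gamma(shape, mean/shape scale) truncated below at `minS` by rejection, so
#' that every simulated sip outlasts the trigger's 100 ms plateau window —
#' sips generally last longer than 100 ms. Defaults: shape 4, mean 250 ms,
#' truncation 110 ms.
#'
#' @param n number of draws.
#' @param shape gamma shape parameter.
#' @param meanS mean of the untruncated distribution, seconds.
#' @param minS lower truncation point, seconds.
#' @return Numeric vector of `n` durations in seconds, all `>= minS`.
#' @examples
#' set.seed(1); median(rSipDuration(1000)) * 1000  # ms, comfortably > 100
#' @export
rSipDuration <- function(n, shape = 4, meanS = 0.25, minS = 0.11) {
    stopifnot(n >= 0, shape > 0, meanS > 0, minS >= 0)
    out <- numeric(0)
    while (length(out) < n) {
        d <- rgamma(n - length(out), shape = shape, scale = meanS / shape)
        out <- c(out, d[d >= minS])
    }
    out
}

rSipDuration1 <- function(fly) {
    repeat {
        d <- rgamma(1L, shape = fly@sipShape, scale = fly@sipMeanS / fly@sipShape)
        if (d >= fly@sipMinS) return(d)
    }
}

#' Synthesize a capacitance trace from ground-truth events
#'
#' The trace is a baseline random walk (per-sample Gaussian steps of s.d.
#' `driftSd`) plus white noise of s.d. `noiseSd`. For each event an
#' amplitude is drawn uniformly within the type-specific bounds of `noise`
#' and added over the event's samples with single-sample rise and fall.
#' Event times are continuous; samples are mapped by
#' `floor(time * sampleRateHz)` with half-open event intervals
#' `[onset, onset + duration)`. Values are rounded to integer capacitance
#' codes and clamped at zero.
#'
#' @param events data.frame with columns `type` (`"sip"` or `"touch"`),
#'   `onset_s`, `duration_s`; events must be disjoint and inside
#'   `[0, durationS]`.
#' @param noise a [NoiseParams].
#' @param durationS trace duration, seconds.
#' @param sampleRateHz samples per second (default 100).
#' @param seed integer seed for drift, noise and amplitude draws.
#' @param channelId channel identifier for the returned trace.
#' @return A [CapacitanceTrace] of `round(durationS * sampleRateHz)` samples.
#' @examples
#' ev <- data.frame(type = "sip", onset_s = 1, duration_s = 0.3)
#' quiet <- NoiseParams(driftSd = 0, noiseSd = 0, sipAmpMin = 400, sipAmpMax = 400)
#' tr <- synthesizeTrace(ev, quiet, durationS = 3, seed = 1)
#' sum(traceValues(tr) > 1000)  # exactly 30 elevated samples at 100 Hz
#' @export
synthesizeTrace <- function(events, noise = NoiseParams(), durationS,
                            sampleRateHz = 100, seed = 1L,
                            channelId = "ch1") {
    stopifnot(is(noise, "NoiseParams"), durationS > 0, sampleRateHz >= 1)
    events <- as.data.frame(events)
    if (nrow(events)) {
        need <- c("type", "onset_s", "duration_s")
        if (!all(need %in% names(events)))
            stop("'events' must have columns type, onset_s, duration_s")
        o <- order(events$onset_s)
        events <- events[o, , drop = FALSE]
        if (any(events$onset_s < 0) ||
            any(events$onset_s + events$duration_s > durationS + 1e-9))
            stop("events must lie inside [0, durationS]")
        if (nrow(events) > 1L) {
            ends <- events$onset_s + events$duration_s
            if (any(events$onset_s[-1L] < ends[-nrow(events)] - 1e-12))
                stop("overlapping events on one channel")
        }
    }
    n <- as.integer(round(durationS * sampleRateHz))
    set.seed(as.integer(seed))
    drift <- c(0, cumsum(rnorm(n - 1L, 0, noise@driftSd)))
    vals <- noise@baselineLevel + drift + rnorm(n, 0, noise@noiseSd)
    if (nrow(events)) {
        for (i in seq_len(nrow(events))) {
            amp <- if (events$type[i] == "touch")
                runif(1L, noise@touchAmpMin, noise@touchAmpMax)
            else runif(1L, noise@sipAmpMin, noise@sipAmpMax)
            i0 <- floor(events$onset_s[i] * sampleRateHz)
            i1 <- floor((events$onset_s[i] + events$duration_s[i]) * sampleRateHz)
            if (i1 <= i0) i1 <- i0 + 1L  # sub-sample event: one elevated sample
            idx <- (i0 + 1L):min(i1, n)
            idx <- idx[idx >= 1L]
            vals[idx] <- vals[idx] + amp
        }
    }
    CapacitanceTrace(pmax(round(vals), 0), sampleRateHz = sampleRateHz,
                     channelId = channelId)
}

## Generate the ground-truth event schedule for one fly. Consumes the
## current RNG stream; draw order is documented in the methods vignette.
generateEvents <- function(fly, opto, durationS) {
    fI <- intensityResponse(opto@intensity, opto@hillK, opto@hillH)
    svp <- if (opto@valence > 0) fly@starvationValenceGain else 1
    uTarget <- opto@valence * fI * svp
    pLight <- min(max(fly@continuationProb *
                      exp(0.25 * opto@valence * fI), 0), 0.99)
    boutRateSec <- fly@boutRatePerMin * fly@starvationGain / 60

    u <- 0
    t <- 0
    ch <- integer(0); type <- character(0)
    onset <- numeric(0); dur <- numeric(0)

    addEvent <- function(channel, what, t0, d) {
        d <- min(d, durationS - t0)
        if (d <= 0) return(FALSE)
        ch[[length(ch) + 1L]] <<- channel
        type[[length(type) + 1L]] <<- what
        onset[[length(onset) + 1L]] <<- t0
        dur[[length(dur) + 1L]] <<- d
        TRUE
    }

    repeat {
        t <- t + max(rexp(1L, rate = boutRateSec), MIN_GAP_S)
        if (t >= durationS) break
        w1 <- max(fly@palatability1 + u, EPS_WEIGHT)
        w2 <- max(fly@palatability2, EPS_WEIGHT)
        onLight <- runif(1L) < w1 / (w1 + w2)
        channel <- if (onLight) 1L else 2L
        boutStart <- t
        boutSips <- list()
        repeat {
            d <- rSipDuration1(fly)
            if (!addEvent(channel, "sip", t, d)) break
            boutSips[[length(boutSips) + 1L]] <- c(t, min(d, durationS - t))
            t <- t + d
            if (t >= durationS) break
            if (onLight && opto@feedbackGain > 0 &&
                runif(1L) < opto@feedbackGain) {
                ## LED offset immediately re-initiates a sip
                t <- t + MIN_GAP_S + 0.005
                next
            }
            pCont <- if (onLight) pLight else fly@continuationProb
            if (runif(1L) < pCont) {
                t <- t + max(rexp(1L, rate = 1 / fly@intersipMeanS), MIN_GAP_S)
                if (t >= durationS) break
            } else break
        }
        boutEnd <- min(t, durationS)
        ## brief non-sip touches within the bout window, placed in inter-sip
        ## gaps (rejection on overlap, with a margin that preserves a
        ## detectable falling edge between events)
        boutMin <- (boutEnd - boutStart) / 60
        nTouch <- rpois(1L, fly@touchRatePerMin * boutMin)
        if (nTouch > 0L) {
            for (k in seq_len(nTouch)) {
                t0 <- runif(1L, boutStart, boutEnd)
                d <- runif(1L, fly@touchMinS, fly@touchMaxS)
                lo <- t0 - MIN_GAP_S
                hi <- t0 + d + MIN_GAP_S
                clash <- any(vapply(boutSips, function(s)
                    lo < s[1L] + s[2L] && s[1L] < hi, logical(1)))
                if (!clash && hi <= durationS) {
                    addEvent(channel, "touch", t0, d)
                    boutSips[[length(boutSips) + 1L]] <- c(t0, d)
                }
            }
        }
        if (onLight)
            u <- u + opto@learningRate * (uTarget - u)
        if (t >= durationS) break
    }
    ev <- data.frame(channel = as.integer(unlist(ch, use.names = FALSE)),
                     type = as.character(unlist(type, use.names = FALSE)),
                     onset_s = as.numeric(unlist(onset, use.names = FALSE)),
                     duration_s = as.numeric(unlist(dur, use.names = FALSE)),
                     stringsAsFactors = FALSE)
    if (nrow(ev)) ev[order(ev$channel, ev$onset_s), , drop = FALSE] else ev
}

#' Simulate one fly in a two-channel closed-loop arena
#'
#' Runs the semi-Markov feeding model for `durationS` seconds, synthesizes a
#' capacitance trace per channel from the resulting ground-truth events, and
#' runs the closed-loop trigger on the light-paired channel's trace to
#' obtain the lighting log. The LED is always paired with channel 1 (Food 1,
#' left side). The whole experiment is a deterministic function of the
#' parameters and `seed`.
#'
#' @param fly a [FlyParams].
#' @param opto an [OptoParams].
#' @param noise a [NoiseParams].
#' @param durationS experiment duration in seconds (canonical assay: 3600,
#'   i.e. 1 h).
#' @param seed integer seed of the per-fly random stream.
#' @param config the in-loop [ControllerConfig].
#' @return A [SimulatedExperiment].
#' @examples
#' exp <- simulateFly(FlyParams(), OptoParams(valence = 2), NoiseParams(),
#'                    durationS = 120, seed = 7)
#' exp
#' @export
simulateFly <- function(fly = FlyParams(), opto = OptoParams(),
                        noise = NoiseParams(), durationS = 3600,
                        seed = 1L, config = ControllerConfig()) {
    stopifnot(is(fly, "FlyParams"), is(opto, "OptoParams"),
              is(noise, "NoiseParams"), is(config, "ControllerConfig"))
    validObject(fly); validObject(opto); validObject(noise)
    if (length(durationS) != 1L || !is.finite(durationS) || durationS <= 0)
        stop("'durationS' must be a single positive number")
    seed <- as.integer(seed)
    set.seed(seed)
    ev <- generateEvents(fly, opto, durationS)
    subSeeds <- sample.int(.Machine$integer.max - 1L, 2L)
    rate <- config@sampleRateHz
    tr1 <- synthesizeTrace(ev[ev$channel == 1L, , drop = FALSE], noise,
                           durationS, rate, subSeeds[1L], "ch1")
    tr2 <- synthesizeTrace(ev[ev$channel == 2L, , drop = FALSE], noise,
                           durationS, rate, subSeeds[2L], "ch2")
    lighting <- runController(tr1, config)
    new("SimulatedExperiment", traces = list(tr1, tr2), groundTruth = ev,
        lighting = lighting, lightChannel = 1L, flyParams = fly,
        optoParams = opto, noiseParams = noise, controllerConfig = config,
        durationS = as.numeric(durationS), seed = seed)
}

#' Simulate a cohort of flies
#'
#' Fly `i` of `nFlies` uses seed `baseSeed + i`, so cohorts are reproducible
#' and per-fly experiments independent.
#'
#' @param nFlies number of flies (>= 1).
#' @param fly,opto,noise,durationS,config passed to [simulateFly()].
#' @param baseSeed integer; fly `i` is seeded with `baseSeed + i`.
#' @return A list of [SimulatedExperiment] objects.
#' @examples
#' cohort <- simulateCohort(2, durationS = 60, baseSeed = 10)
#' length(cohort)
#' @export
simulateCohort <- function(nFlies, fly = FlyParams(), opto = OptoParams(),
                           noise = NoiseParams(), durationS = 3600,
                           baseSeed = 0L, config = ControllerConfig()) {
    stopifnot(nFlies >= 1)
    lapply(seq_len(nFlies), function(i)
        simulateFly(fly, opto, noise, durationS,
                    seed = as.integer(baseSeed) + i, config = config))
}

#' Interaction counts on the light-paired and unpaired channels
#'
#' The light channel's count comes from the stored lighting log; the dark
#' channel has no LED, so its interactions are what the same trigger would
#' have counted on its trace (the assay counts "interactions with Food 2"
#' with identical detection).
#'
#' @param exp a [SimulatedExperiment].
#' @return Named integer vector `c(light = , dark = )`.
#' @export
interactionCounts <- function(exp) {
    stopifnot(is(exp, "SimulatedExperiment"))
    darkLog <- runController(exp@traces[[2L]], exp@controllerConfig)
    c(light = countInteractions(exp@lighting),
      dark = countInteractions(darkLog))
}

#' Per-fly results table for a simulated cohort
#'
#' One row per fly: interaction counts per side, the preference index, and
#' the metadata the analytics layer groups by (valence, intensity,
#' starvation gain, seed).
#'
#' @param cohort a list of [SimulatedExperiment] objects.
#' @return data.frame with columns `fly_id`, `seed`, `n_light`, `n_dark`,
#'   `pi`, `valence`, `intensity`, `starvation_gain`, `duration_s`.
#' @seealso [excludeLowInteractionFlies()], [doseResponseTable()]
#' @export
cohortResults <- function(cohort) {
    stopifnot(length(cohort) >= 1L,
              all(vapply(cohort, is, logical(1), "SimulatedExperiment")))
    rows <- lapply(seq_along(cohort), function(i) {
        exp <- cohort[[i]]
        cnt <- interactionCounts(exp)
        data.frame(fly_id = sprintf("fly%03d", i),
                   seed = exp@seed,
                   n_light = unname(cnt["light"]),
                   n_dark = unname(cnt["dark"]),
                   pi = preferenceIndex(cnt["light"], cnt["dark"]),
                   valence = exp@optoParams@valence,
                   intensity = exp@optoParams@intensity,
                   starvation_gain = exp@flyParams@starvationGain,
                   duration_s = exp@durationS,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
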