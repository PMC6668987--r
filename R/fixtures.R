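## Canonical seeded fixtures used throughout the test suite. Each fixture is
## generated in code and regenerating it is bit-exact.

FIXTURE_NAMES <- c("five_sips", "plateau_step", "touch_only", "mixed_hour")

## quiet, fixed-amplitude signal model for the deterministic fixtures
quietNoise <- function(sipAmp = 400, touchAmp = 200) {
    NoiseParams(driftSd = 0, noiseSd = 0,
                sipAmpMin = sipAmp, sipAmpMax = sipAmp,
                touchAmpMin = touchAmp, touchAmpMax = touchAmp)
}

#' Canonical test fixtures
#'
#' Named, seeded, bit-reproducible inputs used by the test suite and useful
#' as worked examples:
#' \describe{
#'   \item{`five_sips`}{five 300 ms sips of fixed amplitude 400, 5 s apart,
#'     noiseless, 30 s trace; the trigger yields exactly 5 interactions.}
#'   \item{`plateau_step`}{2 s of baseline then a single sustained step of
#'     amplitude 300 held for 5 s; the plateau rule limits the trigger to a
#'     single interaction of one window (100 ms).}
#'   \item{`touch_only`}{one 50 ms touch of amplitude 200 in a 10 s trace;
#'     the trigger fires once but the sip caller's duration filter calls no
#'     sip — the mechanism behind LED activations outnumbering sips.}
#'   \item{`mixed_hour`}{a full 60 min simulated fly with default
#'     behavioral parameters and touches enabled (seed 42), for
#'     sip-vs-illumination comparisons.}
#' }
#'
#' `fixtureExperiment` builds the fixture in memory; [makeFixture()] writes
#' it to files.
#'
#' @param name one of `"five_sips"`, `"plateau_step"`, `"touch_only"`,
#'   `"mixed_hour"`.
#' @return A [SimulatedExperiment].
#' @examples
#' countInteractions(lightingLog(fixtureExperiment("five_sips")))
#' @export
fixtureExperiment <- function(name = FIXTURE_NAMES) {
    name <- match.arg(name)
    cfg <- ControllerConfig()
    buildDeterministic <- function(events, noise, durationS, seed) {
        tr1 <- synthesizeTrace(events[events$channel == 1L, , drop = FALSE],
                               noise, durationS, cfg@sampleRateHz, seed, "ch1")
        tr2 <- synthesizeTrace(events[events$channel == 2L, , drop = FALSE],
                               noise, durationS, cfg@sampleRateHz, seed + 1L,
                               "ch2")
        new("SimulatedExperiment", traces = list(tr1, tr2),
            groundTruth = events, lighting = runController(tr1, cfg),
            lightChannel = 1L, flyParams = FlyParams(),
            optoParams = OptoParams(), noiseParams = noise,
            controllerConfig = cfg, durationS = durationS,
            seed = as.integer(seed))
    }
    switch(name,
        five_sips = {
            ev <- data.frame(channel = 1L, type = "sip",
                             onset_s = c(5, 10, 15, 20, 25),
                             duration_s = 0.3, stringsAsFactors = FALSE)
            buildDeterministic(ev, quietNoise(), durationS = 30, seed = 101L)
        },
        plateau_step = {
            ev <- data.frame(channel = 1L, type = "sip", onset_s = 2,
                             duration_s = 5, stringsAsFactors = FALSE)
            buildDeterministic(ev, quietNoise(sipAmp = 300), durationS = 7,
                               seed = 102L)
        },
        touch_only = {
            ev <- data.frame(channel = 1L, type = "touch", onset_s = 5,
                             duration_s = 0.05, stringsAsFactors = FALSE)
            buildDeterministic(ev, quietNoise(), durationS = 10, seed = 103L)
        },
        mixed_hour = simulateFly(FlyParams(), OptoParams(), NoiseParams(),
                                 durationS = 3600, seed = 42L, config = cfg))
}

#' Write a canonical fixture to files
#'
#' Writes the fixture's traces, ground-truth events, lighting log and
#' manifest into `outdir` via [writeExperiment()].
#'
#' @param name fixture name (see [fixtureExperiment()]).
#' @param outdir output directory.
#' @return The manifest list, invisibly.
#' @export
makeFixture <- function(name, outdir) {
    if (!name %in% FIXTURE_NAMES)
        stop(sprintf("unknown fixture '%s'; available: %s", name,
                     paste(FIXTURE_NAMES, collapse = ", ")))
    exp <- fixtureExperiment(name)
    writeExperiment(exp, outdir, flyId = name)
}
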