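## Post hoc sip calling on recorded traces, and the binned comparison of
## called sips against the real-time trigger's LED activations.
##
## The published FlyPAD classifier applies proprietary shape/duration
## criteria; the caller here is a transparent stand-in (rolling-median
## baseline, amplitude threshold, gap merging, duration filter) whose role
## is comparative, not classifier fidelity.

#' Call sips post hoc on a recorded capacitance trace
#'
#' Baseline is the rolling median over `baselineWindowS` (robust to the
#' contact pulses themselves). Samples more than `amplitudeThreshold` units
#' above baseline form supra-threshold segments; segments separated by gaps
#' strictly shorter than `mergeGapMs` are merged; segments with duration
#' outside `[minDurationMs, maxDurationMs]` are discarded. The duration
#' filter is why the real-time trigger counts more interactions than there
#' are called sips: brief leg touches illuminate the LED but are rejected
#' here.
#'
#' @param trace a [CapacitanceTrace] at least as long as the baseline
#'   window.
#' @param config a [SipCallerConfig].
#' @return An [IRanges::IRanges] of called sips over 1-based sample indices
#'   (half-open on the sample grid: `start` is the onset sample, `end` the
#'   last in-contact sample); metadata column `peakAmplitude` gives the
#'   maximum excursion above baseline, and `S4Vectors::metadata()` carries
#'   the channel id.
#' @examples
#' ev <- data.frame(type = "sip", onset_s = c(2, 4), duration_s = 0.3)
#' quiet <- NoiseParams(driftSd = 0, noiseSd = 0, sipAmpMin = 400, sipAmpMax = 400)
#' tr <- synthesizeTrace(ev, quiet, durationS = 8, seed = 1)
#' callSips(tr)
#' @export
callSips <- function(trace, config = SipCallerConfig()) {
    stopifnot(is(trace, "CapacitanceTrace"), is(config, "SipCallerConfig"))
    v <- trace@values
    rate <- trace@sampleRateHz
    k <- as.integer(round(config@baselineWindowS * rate))
    if (k %% 2L == 0L) k <- k + 1L
    if (length(v) < k)
        stop(sprintf("trace (%d samples) is shorter than the baseline window (%d samples)",
                     length(v), k))
    baseline <- runmed(v, k, endrule = "median")
    above <- (v - baseline) > config@amplitudeThreshold

    empty <- function() {
        ev <- IRanges::IRanges()
        S4Vectors::mcols(ev) <- S4Vectors::DataFrame(peakAmplitude = numeric(0))
        S4Vectors::metadata(ev) <- list(channelId = trace@channelId)
        ev
    }
    if (!any(above)) return(empty())

    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segStart <- starts[r$values]
    segEnd <- ends[r$values]
    ## merge gaps strictly shorter than mergeGapMs
    gapSamples <- config@mergeGapMs / 1000 * rate
    if (length(segStart) > 1L) {
        keepNew <- c(TRUE, (segStart[-1L] - segEnd[-length(segEnd)] - 1L) >=
                           gapSamples)
        grp <- cumsum(keepNew)
        segStart <- tapply(segStart, grp, min)
        segEnd <- tapply(segEnd, grp, max)
    }
    durMs <- (segEnd - segStart + 1L) / rate * 1000
    keep <- durMs >= config@minDurationMs & durMs <= config@maxDurationMs
    if (!any(keep)) return(empty())
    segStart <- as.integer(segStart[keep])
    segEnd <- as.integer(segEnd[keep])
    peak <- vapply(seq_along(segStart), function(i) {
        idx <- segStart[i]:segEnd[i]
        max(v[idx] - baseline[idx])
    }, numeric(1))
    ev <- IRanges::IRanges(start = segStart, end = segEnd)
    S4Vectors::mcols(ev) <- S4Vectors::DataFrame(peakAmplitude = peak)
    S4Vectors::metadata(ev) <- list(channelId = trace@channelId)
    ev
}

#' Onset times of called sips, in seconds
#'
#' @param sips an `IRanges` from [callSips()].
#' @param sampleRateHz samples per second of the source trace.
#' @return Numeric vector of onset times (0-based sample index / rate).
#' @export
sipOnsets <- function(sips, sampleRateHz = 100) {
    (IRanges::start(sips) - 1) / sampleRateHz
}

#' Count event onsets in consecutive time bins
#'
#' Half-open bins `[k*w, (k+1)*w)` covering `[0, durationS)`; the counts sum
#' to the number of events. The assay's standard binning is 1 min bins
#' across a 1 h experiment.
#'
#' @param onsets event onset times in seconds, within `[0, durationS)`.
#' @param durationS total duration covered, seconds.
#' @param binWidthS bin width, seconds (default 60).
#' @return Integer vector of `ceiling(durationS / binWidthS)` counts.
#' @examples
#' binCounts(c(0, 59.9, 60), durationS = 120)  # c(2, 1)
#' @export
binCounts <- function(onsets, durationS, binWidthS = 60) {
    if (length(binWidthS) != 1L || !is.finite(binWidthS) || binWidthS <= 0)
        stop("'binWidthS' must be a single positive number")
    stopifnot(durationS > 0)
    if (length(onsets) && (any(onsets < 0) || any(onsets >= durationS)))
        stop("onsets must lie within [0, durationS)")
    nBins <- as.integer(ceiling(durationS / binWidthS))
    tabulate(floor(onsets / binWidthS) + 1, nbins = nBins)
}

#' Compare called sips with LED illuminations in matched time bins
#'
#' Bins with zero counts in both series are excluded (times when the fly was
#' not interacting with the food). On the retained bins the function fits an
#' ordinary least-squares regression of illuminations on sips (with
#' intercept) and reports its R-squared and slope, plus the ratio of total
#' illuminations to total sips. The ratio is reported separately from the
#' regression because the two summarise different things: the published
#' observation that LED activations exceed called sips by roughly 1.4x is a
#' ratio-of-totals statement.
#'
#' Fewer than 2 retained bins, zero total sips, or zero variance in the sip
#' counts make the comparison incomputable and raise an error. With exactly
#' 2 retained bins the OLS fit is saturated and its R-squared is trivially 1.
#'
#' @param sipBins,illumBins equal-length integer count vectors (e.g. from
#'   [binCounts()]).
#' @return A [BinnedComparison].
#' @examples
#' compareAlgorithms(c(2, 0, 4), c(3, 0, 6))  # bin 2 excluded; ratio 1.5
#' @export
compareAlgorithms <- function(sipBins, illumBins) {
    if (length(sipBins) != length(illumBins))
        stop("'sipBins' and 'illumBins' must have equal length")
    sipBins <- as.integer(sipBins)
    illumBins <- as.integer(illumBins)
    inc <- which(!(sipBins == 0L & illumBins == 0L))
    s <- sipBins[inc]
    i <- illumBins[inc]
    if (length(inc) < 2L)
        stop("incomputable: fewer than 2 bins with any sips or illuminations")
    if (sum(s) == 0L || stats::var(s) == 0)
        stop("incomputable: zero variance in sip counts over included bins")
    fit <- lm(i ~ s)
    ## summary.lm warns on a saturated/perfect fit; r.squared is still defined
    r2 <- suppressWarnings(summary(fit)$r.squared)
    new("BinnedComparison",
        sipCounts = sipBins, illuminationCounts = illumBins,
        includedBins = as.integer(inc),
        rSquared = as.numeric(r2),
        olsSlope = unname(coef(fit)[2L]),
        olsIntercept = unname(coef(fit)[1L]),
        totalRatio = sum(i) / sum(s))
}

#' @rdname BinnedComparison-class
#' @param object a `BinnedComparison`.
#' @return `rSquared()`, `olsSlope()`, `totalRatio()`: the corresponding
#'   scalar summaries; `includedBins()`: 1-based indices of retained bins.
#' @export
rSquared <- function(object) object@rSquared
#' @rdname BinnedComparison-class
#' @export
olsSlope <- function(object) object@olsSlope
#' @rdname BinnedComparison-class
#' @export
totalRatio <- function(object) object@totalRatio
#' @rdname BinnedComparison-class
#' @export
includedBins <- function(object) object@includedBins
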