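quiet <- NoiseParams(driftSd = 0, noiseSd = 0,
                     sipAmpMin = 400, sipAmpMax = 400,
                     touchAmpMin = 200, touchAmpMax = 200)

test_that("intensity response is a Hill curve", {
    expect_identical(intensityResponse(0), 0)
    expect_equal(intensityResponse(1.85), 0.5)
    v <- intensityResponse(11.26, K = 1.85, h = 2)
    expect_equal(v, 11.26^2 / (11.26^2 + 1.85^2))
    expect_gt(v, 0.9); expect_lt(v, 1)
    grid <- intensityResponse(c(0, 0.12, 1.85, 6.56, 11.26, 16.44))
    expect_true(all(diff(grid) > 0))
    expect_error(intensityResponse(-1), "non-negative")
})

test_that("sip durations are truncated gamma and outlast the plateau window", {
    set.seed(2)
    d <- rSipDuration(5000)
    expect_true(all(d >= 0.11))
    expect_gt(median(d), 0.1)
    # truncated mean must exceed the untruncated 250 ms mean
    expect_gt(mean(d), 0.25)
})

test_that("trace synthesis rasterizes events exactly", {
    # no events, no noise: constant at baseline
    tr <- synthesizeTrace(data.frame(), quiet, durationS = 2, seed = 1)
    expect_identical(traceValues(tr), rep(1000, 200))

    # one 300 ms sip of amplitude 400: exactly 30 elevated samples at 100 Hz
    ev <- data.frame(type = "sip", onset_s = 0.5, duration_s = 0.3)
    tr <- synthesizeTrace(ev, quiet, durationS = 2, seed = 1)
    expect_identical(which(traceValues(tr) == 1400), 51:80)
    expect_identical(sum(traceValues(tr) != 1000), 30L)

    # overlapping events are rejected
    bad <- data.frame(type = "sip", onset_s = c(0.5, 0.6), duration_s = 0.3)
    expect_error(synthesizeTrace(bad, quiet, 2, seed = 1), "overlap")

    # five noiseless sips drive the trigger exactly five times
    fx <- fixtureExperiment("five_sips")
    expect_identical(countInteractions(lightingLog(fx)), 5L)
})

test_that("simulated experiments are bit-reproducible from their seed", {
    a <- simulateFly(FlyParams(), OptoParams(valence = 1), NoiseParams(),
                     durationS = 120, seed = 9)
    b <- simulateFly(FlyParams(), OptoParams(valence = 1), NoiseParams(),
                     durationS = 120, seed = 9)
    expect_identical(traceValues(traces(a)[[1]]), traceValues(traces(b)[[1]]))
    expect_identical(traceValues(traces(a)[[2]]), traceValues(traces(b)[[2]]))
    expect_identical(groundTruth(a), groundTruth(b))
    expect_identical(ledStates(lightingLog(a)), ledStates(lightingLog(b)))

    co1 <- simulateCohort(3, durationS = 60, baseSeed = 50)
    co2 <- simulateCohort(3, durationS = 60, baseSeed = 50)
    expect_identical(lapply(co1, groundTruth), lapply(co2, groundTruth))
    # cohort fly i is simulateFly with seed baseSeed + i
    solo <- simulateFly(FlyParams(), OptoParams(), NoiseParams(),
                        durationS = 60, seed = 51)
    expect_identical(groundTruth(co1[[1]]), groundTruth(solo))
})

test_that("the lighting log derives exactly from the light channel's trace", {
    exp <- simulateFly(FlyParams(), OptoParams(valence = 2), NoiseParams(),
                       durationS = 300, seed = 4)
    rerun <- runController(traces(exp)[[1]], ControllerConfig())
    expect_identical(ledStates(lightingLog(exp)), ledStates(rerun))
})

test_that("noiseless ground truth and illuminations correspond one-to-one", {
    noNoise <- NoiseParams(driftSd = 0, noiseSd = 0)
    for (seed in c(21, 22, 23)) {
        exp <- simulateFly(FlyParams(), OptoParams(valence = 1), noNoise,
                           durationS = 600, seed = seed)
        gt <- groundTruth(exp)
        gt1 <- gt[gt$channel == 1, , drop = FALSE]
        ev <- illuminationEvents(lightingLog(exp))
        onS <- (IRanges::start(ev) - 1) / 100
        offS <- IRanges::end(ev) / 100
        # every ground-truth event of >= 2 samples produces an illumination
        for (i in seq_len(nrow(gt1))) {
            if (gt1$duration_s[i] >= 0.02)
                expect_true(any(onS < gt1$onset_s[i] + gt1$duration_s[i] &
                                offS > gt1$onset_s[i]))
        }
        # every illumination overlaps a ground-truth event
        for (j in seq_along(onS)) {
            expect_true(any(gt1$onset_s < offS[j] &
                            gt1$onset_s + gt1$duration_s > onS[j]))
        }
    }
})

test_that("a symmetric control cohort shows no side preference", {
    co <- simulateCohort(60, FlyParams(), OptoParams(valence = 0),
                         NoiseParams(), durationS = 600, baseSeed = 300)
    p <- cohortPIs(co); p <- p[!is.na(p)]
    sem <- sd(p) / sqrt(length(p))
    expect_lt(abs(mean(p)), 3 * sem)
})

test_that("valence sign drives preference direction at moderate cohort size", {
    app <- simulateCohort(25, FlyParams(), OptoParams(valence = 2),
                          NoiseParams(), durationS = 600, baseSeed = 400)
    av <- simulateCohort(25, FlyParams(), OptoParams(valence = -2),
                         NoiseParams(), durationS = 600, baseSeed = 400)
    pApp <- cohortPIs(app); pAv <- cohortPIs(av)
    expect_gt(mean(pApp, na.rm = TRUE), 0.5)
    expect_lt(mean(pAv, na.rm = TRUE), -0.5)
    # appetitive drive also shifts raw counts toward the light side
    rApp <- cohortResults(app)
    expect_gt(mean(rApp$n_light), mean(rApp$n_dark))
})

test_that("zero intensity gates the feedback off regardless of valence", {
    co <- simulateCohort(40, FlyParams(), OptoParams(valence = 2, intensity = 0),
                         NoiseParams(), durationS = 600, baseSeed = 500)
    p <- cohortPIs(co); p <- p[!is.na(p)]
    sem <- sd(p) / sqrt(length(p))
    expect_lt(abs(mean(p)), 3 * sem)
})

test_that("starvation scales feeding drive, and its valence gain only appetitive drive", {
    fed <- simulateCohort(30, FlyParams(), OptoParams(valence = 1),
                          NoiseParams(), durationS = 600, baseSeed = 600)
    starved <- simulateCohort(30, FlyParams(starvationGain = 2),
                              OptoParams(valence = 1), NoiseParams(),
                              durationS = 600, baseSeed = 600)
    rFed <- cohortResults(fed); rSt <- cohortResults(starved)
    expect_gt(mean(rSt$n_light + rSt$n_dark),
              mean(rFed$n_light + rFed$n_dark))

    hungryVal <- simulateCohort(30, FlyParams(starvationGain = 2,
                                              starvationValenceGain = 2),
                                OptoParams(valence = 1), NoiseParams(),
                                durationS = 600, baseSeed = 600)
    expect_gt(mean(cohortPIs(hungryVal), na.rm = TRUE),
              mean(cohortPIs(starved), na.rm = TRUE))

    # starvation-valence gain must not deepen aversion (it applies only when
    # valence is positive)
    avPlain <- simulateCohort(20, FlyParams(), OptoParams(valence = -2),
                              NoiseParams(), durationS = 600, baseSeed = 700)
    avGain <- simulateCohort(20, FlyParams(starvationValenceGain = 3),
                             OptoParams(valence = -2), NoiseParams(),
                             durationS = 600, baseSeed = 700)
    expect_identical(vapply(avPlain, function(e) nrow(groundTruth(e)), integer(1)),
                     vapply(avGain, function(e) nrow(groundTruth(e)), integer(1)))
    expect_equal(mean(cohortPIs(avPlain), na.rm = TRUE),
                 mean(cohortPIs(avGain), na.rm = TRUE))
})

test_that("making both foods unpalatable collapses aversion toward indifference", {
    pis <- function(p) {
        co <- simulateCohort(30, FlyParams(palatability1 = p, palatability2 = p),
                             OptoParams(valence = -2), NoiseParams(),
                             durationS = 1800, baseSeed = 800)
        cohortPIs(co)
    }
    grid <- c(1, 0.5, 0.2, 0.05)
    mat <- vapply(grid, pis, numeric(30))
    means <- colMeans(abs(mat), na.rm = TRUE)
    # robust endpoint: near-floor shared palatability halves the aversion
    expect_lt(means[4], 0.6 * means[1])
    # no significant increase anywhere along the grid (paired cohorts)
    for (k in 1:3) {
        d <- abs(mat[, k + 1]) - abs(mat[, k])
        d <- d[!is.na(d)]
        expect_lt(mean(d), 3 * sd(d) / sqrt(length(d)))
    }
})

test_that("cohort-mean cumulative preference settles early for appetitive drive", {
    curves <- vapply(1:10, function(s) {
        exp <- simulateFly(FlyParams(), OptoParams(valence = 2), NoiseParams(),
                           durationS = 3600, seed = 100 + s)
        lo <- interactionOnsets(lightingLog(exp))
        do <- interactionOnsets(runController(traces(exp)[[2]],
                                              ControllerConfig()))
        piTimecourse(lo, do, 3600)$pi
    }, numeric(3600))
    curve <- rowMeans(curves, na.rm = TRUE)
    final <- curve[length(curve)]
    expect_true(all(abs(curve[901:3600] - final) < 0.1))
    # aversive preference settles more slowly (valence updates only on rare
    # light-side bouts) but stays within a coarser band
    curvesAv <- vapply(1:10, function(s) {
        exp <- simulateFly(FlyParams(), OptoParams(valence = -2), NoiseParams(),
                           durationS = 3600, seed = 100 + s)
        lo <- interactionOnsets(lightingLog(exp))
        do <- interactionOnsets(runController(traces(exp)[[2]],
                                              ControllerConfig()))
        piTimecourse(lo, do, 3600)$pi
    }, numeric(3600))
    curveAv <- rowMeans(curvesAv, na.rm = TRUE)
    expect_true(all(abs(curveAv[901:3600] - curveAv[3600]) < 0.2,
                    na.rm = TRUE))
})

test_that("invalid parameters are rejected before simulation", {
    expect_error(FlyParams(continuationProb = 1.2), "continuationProb")
    expect_error(FlyParams(sipMinS = 0.05), "100 ms")
    expect_error(OptoParams(intensity = -1), "intensity")
    expect_error(OptoParams(feedbackGain = 1), "feedbackGain")
    expect_error(NoiseParams(driftSd = -1), "standard deviations")
    expect_error(simulateFly(durationS = 0), "positive")
})
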