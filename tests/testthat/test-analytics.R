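test_that("preference index is the signed fraction of light-side interactions", {
    expect_equal(preferenceIndex(100, 0), 1)
    expect_equal(preferenceIndex(50, 50), 0)
    expect_equal(preferenceIndex(70, 30), 0.4)
    expect_true(is.na(preferenceIndex(0, 0)))
    expect_error(preferenceIndex(-1, 5), "non-negative")

    # antisymmetry and bounds on random counts
    set.seed(61)
    a <- rpois(200, 40); b <- rpois(200, 40)
    ok <- a + b > 0
    expect_equal(preferenceIndex(a, b)[ok], -preferenceIndex(b, a)[ok])
    expect_true(all(abs(preferenceIndex(a, b)[ok]) <= 1))
})

test_that("minimum-interaction exclusion keeps the boundary fly and is idempotent", {
    d <- data.frame(fly_id = c("f1", "f2", "f3", "f4"),
                    n_light = c(10, 10, 0, 40),
                    n_dark = c(4, 5, 0, 2))
    res <- excludeLowInteractionFlies(d)
    expect_identical(res$kept$fly_id, c("f2", "f4"))       # 15 passes, 14 fails
    expect_identical(res$excluded$fly_id, c("f1", "f3"))   # 14 and 0 excluded
    expect_match(res$excluded$reason[1], "14 < minimum 15")
    # idempotent and order-independent
    again <- excludeLowInteractionFlies(res$kept)
    expect_identical(again$kept, res$kept)
    shuffled <- excludeLowInteractionFlies(d[c(3, 1, 4, 2), ])
    expect_setequal(shuffled$kept$fly_id, res$kept$fly_id)
})

test_that("cumulative preference timecourse pools per second and starts undefined", {
    tc <- piTimecourse(10, 20, durationS = 30)
    expect_true(all(is.na(tc$pi[tc$time_s < 10])))
    expect_true(all(tc$pi[tc$time_s >= 10 & tc$time_s < 20] == 1))
    expect_true(all(tc$pi[tc$time_s >= 20] == 0))

    # all events on the light channel: constantly 1 after the first event
    tc2 <- piTimecourse(c(3, 7, 9), numeric(0), durationS = 12)
    expect_true(all(tc2$pi[tc2$time_s >= 3] == 1))
    expect_true(all(is.na(tc2$pi[tc2$time_s < 3])))

    # final value equals the preference index of the totals
    set.seed(62)
    lo <- runif(37, 0, 100); do <- runif(21, 0, 100)
    tc3 <- piTimecourse(lo, do, 100)
    expect_equal(tc3$pi[nrow(tc3)], preferenceIndex(37, 21))
})

test_that("cumulative interaction counts are a non-decreasing step series", {
    ci <- cumulativeInteractions(numeric(0), 10)
    expect_true(all(ci$count == 0))
    ci2 <- cumulativeInteractions(c(1, 2, 3), 5)
    expect_identical(ci2$count, c(0L, 1L, 2L, 3L, 3L))
    fx <- fixtureExperiment("five_sips")
    on <- interactionOnsets(lightingLog(fx))
    ci3 <- cumulativeInteractions(on, experimentDuration(fx))
    expect_true(all(diff(ci3$count) >= 0))
    expect_identical(ci3$count[nrow(ci3)], 5L)
})

test_that("dye scoring is by light-association and swap-invariant", {
    rec <- data.frame(fly_id = c("a", "b", "c", "d"),
                      abdomen_color = c("blue", "both", "red", "none"),
                      light_color = "blue",
                      stringsAsFactors = FALSE)
    res <- dyePreference(rec)
    expect_identical(res$scores$score, c(1, 0, -1))
    expect_identical(res$excluded, "d")

    # swapping the dye on the light channel together with abdomen colors
    # leaves scores unchanged (counterbalanced replicates)
    swap <- c(blue = "red", red = "blue", both = "both", none = "none")
    rec2 <- rec
    rec2$abdomen_color <- unname(swap[rec$abdomen_color])
    rec2$light_color <- "red"
    expect_identical(dyePreference(rec2)$scores$score, res$scores$score)

    expect_equal(mean(c(1, 1, -1, 0)), 0.25)  # worked group mean
    expect_error(dyePreference(transform(rec, abdomen_color = "green")),
                 "unknown abdomen color")
})

test_that("group summaries report mean and sample-sd SEM", {
    expect_equal(groupSummary(c(1, 1, 1)),
                 data.frame(n = 3L, mean_pi = 1, sem = 0))
    s <- groupSummary(c(1, -1))
    expect_equal(s$mean_pi, 0); expect_equal(s$sem, 1)
    s2 <- groupSummary(c(0.4, 0.2, 0.6))
    expect_equal(s2$mean_pi, 0.4)
    expect_equal(s2$sem, 0.2 / sqrt(3))
    expect_error(groupSummary(numeric(0)), "no values")
    expect_true(is.na(groupSummary(0.5)$sem))
})

test_that("dose-response tables group, exclude and order deterministically", {
    d <- data.frame(fly_id = sprintf("f%02d", 1:8),
                    n_light = c(30, 28, 5, 40, 44, 2, 33, 29),
                    n_dark = c(10, 12, 4, 9, 8, 1, 12, 10),
                    intensity = c(1.85, 1.85, 1.85, 11.26, 11.26, 11.26,
                                  0.12, 0.12))
    tab <- doseResponseTable(d, "intensity")
    expect_identical(tab$group, c(0.12, 1.85, 11.26))  # ordered by value
    expect_identical(tab$n, c(2L, 2L, 2L))             # low-count flies dropped
    one <- doseResponseTable(d[d$intensity == 0.12, ], "intensity")
    expect_equal(one$mean_pi,
                 groupSummary(preferenceIndex(c(33, 29), c(12, 10)))$mean_pi)
    expect_warning(
        doseResponseTable(rbind(d, data.frame(fly_id = "f99", n_light = 3,
                                              n_dark = 2, intensity = 16.44)),
                          "intensity"),
        "empty")
})

test_that("a simulated intensity sweep rises from indifference to a stable plateau", {
    grid <- c(0, 0.12, 1.85, 6.56, 11.26, 16.44)
    cohorts <- lapply(grid, function(I)
        simulateCohort(40, FlyParams(), OptoParams(valence = 2, intensity = I),
                       NoiseParams(), durationS = 600, baseSeed = 900))
    results <- do.call(rbind, lapply(cohorts, cohortResults))
    tab <- doseResponseTable(results, "intensity")
    expect_identical(tab$group, grid)
    # no light, no preference; sub-threshold intensity near indifference
    expect_lt(abs(tab$mean_pi[1]), 3 * tab$sem_pi[1])
    # at and above the half-max intensity preference is high and stable
    expect_true(all(tab$mean_pi[3:6] > 0.7))
    # the rise from dark to half-max is strongly significant
    expect_gt(tab$mean_pi[3] - tab$mean_pi[1],
              3 * sqrt(tab$sem_pi[3]^2 + tab$sem_pi[1]^2))
    # and no significant decrease anywhere along the grid (paired cohorts)
    for (k in 1:5)
        expect_gt(tab$mean_pi[k + 1] - tab$mean_pi[k],
                  -3 * sqrt(tab$sem_pi[k + 1]^2 + tab$sem_pi[k]^2))
})
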