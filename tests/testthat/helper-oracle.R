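# Independent brute-force oracle for the closed-loop trigger: per-sample
# recomputation of the minimum over the preceding window, straight from the
# rule's definition. Deliberately naive and kept separate from the
# vectorised implementation it checks.
bruteForceStates <- function(values, windowSamples = 10L, threshold = 100) {
    n <- length(values)
    out <- logical(n)
    for (i in seq_len(n)) {
        lo <- max(1L, i - windowSamples)
        if (i > 1L)
            out[i] <- (values[i] - min(values[lo:(i - 1L)])) > threshold
    }
    out
}

# Random test trace: integer random walk with occasional spikes, clamped
# non-negative.
randomTrace <- function(n, spikeRate = 0.01) {
    v <- 1000 + cumsum(sample(c(-30:30), n, replace = TRUE))
    nSpike <- rpois(1, spikeRate * n)
    if (nSpike > 0) {
        at <- sample.int(n, min(nSpike, n))
        v[at] <- v[at] + sample(50:500, length(at), replace = TRUE)
    }
    pmax(v, 0)
}

# Interaction counts with the dark channel decoded by the same trigger.
flyPI <- function(exp) {
    cnt <- interactionCounts(exp)
    preferenceIndex(cnt["light"], cnt["dark"])
}

# Per-fly PI vector for a cohort under the standard exclusion rule,
# NA where a fly was excluded (keeps per-seed alignment for paired
# comparisons across parameter grids).
cohortPIs <- function(cohort, minTotal = 15) {
    res <- cohortResults(cohort)
    res$pi[res$n_light + res$n_dark < minTotal] <- NA
    res$pi
}
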