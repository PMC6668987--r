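## Behavioral analytics: preference indices, cumulative timecourses,
## exclusion rules, dye-ingestion scoring and dose-response summaries.

#' Two-choice preference index
#'
#' `(n_light - n_dark) / (n_light + n_dark)`: +1 means all interactions were
#' with the light-paired food (Food 1, left side), -1 all with the unpaired
#' food. Vectorised. A fly with zero interactions on both sides has no
#' defined preference; the index is returned as `NA` (such flies are
#' excluded upstream by the minimum-interaction rule anyway).
#'
#' @param nLight,nDark non-negative interaction counts on the light-paired
#'   and unpaired channels.
#' @return Numeric in `[-1, 1]`, or `NA` where both counts are zero.
#' @examples
#' preferenceIndex(70, 30)  # 0.4
#' @export
preferenceIndex <- function(nLight, nDark) {
    if (any(nLight < 0, na.rm = TRUE) || any(nDark < 0, na.rm = TRUE))
        stop("interaction counts must be non-negative")
    total <- nLight + nDark
    out <- ifelse(total > 0, (nLight - nDark) / total, NA_real_)
    unname(out)
}

#' Exclude flies below the minimum-interaction threshold
#'
#' Flies whose total interaction count (both channels) is below `minTotal`
#' are removed before group statistics; a fly with exactly `minTotal`
#' interactions passes. The default of 15 is the assay's standard exclusion
#' threshold. Idempotent.
#'
#' @param results data.frame with columns `fly_id`, `n_light`, `n_dark`
#'   (e.g. from [cohortResults()]).
#' @param minTotal minimum total interactions to retain a fly (default 15).
#' @return A list with `kept` (filtered data.frame) and `excluded`
#'   (data.frame of `fly_id`, `total`, `reason`).
#' @examples
#' d <- data.frame(fly_id = c("a", "b"), n_light = c(10, 2), n_dark = c(5, 2))
#' excludeLowInteractionFlies(d)$excluded
#' @export
excludeLowInteractionFlies <- function(results, minTotal = 15) {
    stopifnot(is.data.frame(results),
              all(c("fly_id", "n_light", "n_dark") %in% names(results)))
    total <- results$n_light + results$n_dark
    drop <- total < minTotal
    excluded <- data.frame(
        fly_id = results$fly_id[drop],
        total = total[drop],
        reason = sprintf("total interactions %d < minimum %d",
                         as.integer(total[drop]), as.integer(minTotal)),
        stringsAsFactors = FALSE)
    list(kept = results[!drop, , drop = FALSE], excluded = excluded)
}

#' Cumulative preference-index timecourse
#'
#' Events are pooled within `poolS`-second periods; at the end of each
#' period the index is computed from the cumulative interaction counts so
#' far. Before the first event on either channel the preference is
#' undefined and reported as `NA` rather than fabricated neutrality.
#'
#' @param lightOnsets,darkOnsets interaction onset times in seconds, within
#'   `[0, durationS)`.
#' @param durationS experiment duration, seconds.
#' @param poolS pooling period, seconds (default 1).
#' @return data.frame with `time_s` (end-exclusive period start,
#'   `0, poolS, 2*poolS, ...`) and `pi`.
#' @examples
#' tc <- piTimecourse(10, 20, durationS = 30)
#' tc$pi[tc$time_s %in% c(10, 19, 20)]  # 1, 1, 0
#' @export
piTimecourse <- function(lightOnsets, darkOnsets, durationS, poolS = 1) {
    stopifnot(durationS > 0, poolS > 0)
    edges <- seq(poolS, by = poolS, length.out = ceiling(durationS / poolS))
    nL <- cumsum(binCounts(lightOnsets, durationS, poolS))
    nD <- cumsum(binCounts(darkOnsets, durationS, poolS))
    data.frame(time_s = edges - poolS,
               pi = preferenceIndex(nL, nD))
}

#' Cumulative interaction-count timecourse
#'
#' @param onsets interaction onset times in seconds, within `[0, durationS)`.
#' @param durationS experiment duration, seconds.
#' @param poolS pooling period, seconds (default 1).
#' @return data.frame with `time_s` and non-decreasing `count`; the final
#'   count equals the total number of events.
#' @export
cumulativeInteractions <- function(onsets, durationS, poolS = 1) {
    stopifnot(durationS > 0, poolS > 0)
    counts <- cumsum(binCounts(onsets, durationS, poolS))
    data.frame(time_s = seq(0, by = poolS,
                            length.out = length(counts)),
               count = counts)
}

#' Score a dye-ingestion two-choice assay
#'
#' Each fly's abdomen color is scored +1 if it matches the dye on the
#' light-paired channel, -1 if it matches the dye on the unpaired channel,
#' and 0 for both colors. Scoring is by light-association rather than raw
#' color, so dye-swap counterbalancing (half the replicates run with the
#' dyes swapped) is handled by construction. Flies with no dye in the
#' abdomen did not eat and are excluded with a report.
#'
#' @param records data.frame with columns `fly_id`, `abdomen_color` (one of
#'   `"blue"`, `"red"`, `"both"`, `"none"`) and `light_color` (`"blue"` or
#'   `"red"`: which dye was on the light-paired channel).
#' @return List with `scores` (data.frame `fly_id`, `score`), `summary`
#'   (from [groupSummary()]) and `excluded` (fly ids with color "none").
#' @examples
#' rec <- data.frame(fly_id = 1:3,
#'                   abdomen_color = c("blue", "both", "red"),
#'                   light_color = c("blue", "blue", "blue"))
#' dyePreference(rec)$scores$score  # 1, 0, -1
#' @export
dyePreference <- function(records) {
    stopifnot(is.data.frame(records),
              all(c("fly_id", "abdomen_color", "light_color") %in%
                  names(records)))
    okColor <- c("blue", "red", "both", "none")
    if (!all(records$abdomen_color %in% okColor))
        stop("unknown abdomen color label; expected blue/red/both/none")
    if (!all(records$light_color %in% c("blue", "red")))
        stop("'light_color' must be 'blue' or 'red'")
    eaten <- records$abdomen_color != "none"
    excluded <- records$fly_id[!eaten]
    rec <- records[eaten, , drop = FALSE]
    score <- ifelse(rec$abdomen_color == "both", 0,
             ifelse(rec$abdomen_color == rec$light_color, 1, -1))
    scores <- data.frame(fly_id = rec$fly_id, score = score,
                         stringsAsFactors = FALSE)
    list(scores = scores,
         summary = if (nrow(scores)) groupSummary(scores$score) else NULL,
         excluded = excluded)
}

#' Group mean and standard error of a set of preference indices
#'
#' SEM uses the sample standard deviation (n - 1 denominator); for a single
#' fly the SEM is undefined and reported as `NA`.
#'
#' @param values numeric vector of per-fly indices (NAs are dropped).
#' @return data.frame with `n`, `mean_pi`, `sem`.
#' @examples
#' groupSummary(c(0.4, 0.2, 0.6))  # mean 0.4, SEM 0.2/sqrt(3)
#' @export
groupSummary <- function(values) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n == 0L) stop("no values to summarise")
    data.frame(n = n, mean_pi = mean(values),
               sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_)
}

#' Dose-response summary table over a grouping variable
#'
#' Applies the minimum-interaction exclusion, then reports per group the
#' mean +/- SEM of the preference index and of the per-side interaction
#' counts. Rows are ordered by group value. Groups left empty after
#' exclusion are omitted with a warning.
#'
#' @param results per-fly data.frame (see [cohortResults()]) containing the
#'   grouping column.
#' @param groupKey name of the metadata column to group by (e.g.
#'   `"intensity"`).
#' @param minTotal minimum-interaction threshold passed to
#'   [excludeLowInteractionFlies()].
#' @return data.frame with one row per group: `group`, `n`, `mean_pi`,
#'   `sem_pi`, `mean_light`, `sem_light`, `mean_dark`, `sem_dark`.
#' @export
doseResponseTable <- function(results, groupKey, minTotal = 15) {
    stopifnot(is.data.frame(results), groupKey %in% names(results))
    groupsAll <- sort(unique(results[[groupKey]]))
    kept <- excludeLowInteractionFlies(results, minTotal)$kept
    rows <- lapply(groupsAll, function(g) {
        sub <- kept[kept[[groupKey]] == g, , drop = FALSE]
        if (!nrow(sub)) {
            warning(sprintf("group %s = %s is empty after exclusion; omitted",
                            groupKey, format(g)))
            return(NULL)
        }
        semOf <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
        pis <- preferenceIndex(sub$n_light, sub$n_dark)
        data.frame(group = g, n = nrow(sub),
                   mean_pi = mean(pis, na.rm = TRUE),
                   sem_pi = semOf(pis[!is.na(pis)]),
                   mean_light = mean(sub$n_light), sem_light = semOf(sub$n_light),
                   mean_dark = mean(sub$n_dark), sem_dark = semOf(sub$n_dark),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        stop("no groups left after exclusion")
    rownames(out) <- NULL
    out
}
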