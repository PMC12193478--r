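## Baseline cohort summaries: binned demographic counts/percentages and
## per-trial score/duration descriptives.

#' Default demographic bin specifications
#'
#' The binning used for baseline reporting: age 60-80 vs over 80 years
#' (the boundary value 80 belongs to the lower bin), height 145-155 /
#' 155-165 / 165-175 / >= 175 cm, weight 40-50 / 50-60 / 60-70 / >= 85 kg.
#' The weight bins deliberately leave a 70-85 kg gap; subjects falling in a
#' gap are reported in an "unbinned" bucket, never silently dropped.
#'
#' @return named list of bin specs, each a list with `variable`, `breaks`
#'   (left-closed, right-open except as labelled) and `labels`
#' @seealso [summarizeBaseline()]
#' @export
defaultBins <- function() {
  list(
    age = list(variable = "age",
               lower = c(60, 80), upper = c(80, Inf),
               lower_closed = c(TRUE, FALSE), upper_closed = c(TRUE, FALSE),
               labels = c("60-80 years", "over 80 years")),
    height_cm = list(variable = "height_cm",
                     lower = c(145, 155, 165, 175),
                     upper = c(155, 165, 175, Inf),
                     lower_closed = c(TRUE, TRUE, TRUE, TRUE),
                     upper_closed = c(FALSE, FALSE, FALSE, FALSE),
                     labels = c("145-155 cm", "155-165 cm", "165-175 cm",
                                ">= 175 cm")),
    weight_kg = list(variable = "weight_kg",
                     lower = c(40, 50, 60, 85),
                     upper = c(50, 60, 70, Inf),
                     lower_closed = c(TRUE, TRUE, TRUE, TRUE),
                     upper_closed = c(FALSE, FALSE, FALSE, FALSE),
                     labels = c("40-50 kg", "50-60 kg", "60-70 kg",
                                ">= 85 kg")))
}

#' Baseline counts and percentages per demographic bin
#'
#' Counts cohort records per bin and reports percentages as
#' `100 * count / n`, rounded half away from zero to one decimal. Records
#' outside every bin of a variable land in an `"unbinned"` row; gender (or
#' any categorical column named in `categoricals`) is tabulated by level.
#'
#' @param cohort cohort data.frame (see [simulateCohort()] for the layout)
#' @param bins list of bin specs as produced by [defaultBins()]
#' @param categoricals character vector of categorical columns to tabulate
#' @return data.frame with columns `variable`, `bin`, `count`, `percent`
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_subjects = 19, seed = 5))
#' summarizeBaseline(sim$cohort)
#' @export
summarizeBaseline <- function(cohort, bins = defaultBins(),
                              categoricals = "gender") {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0L)
  n <- nrow(cohort)
  pct <- function(k) roundHalfUp(100 * k / n, 1L)
  rows <- list()
  for (cc in intersect(categoricals, names(cohort))) {
    tab <- table(cohort[[cc]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = cc, bin = names(tab),
      count = as.integer(tab), percent = pct(as.integer(tab)))
  }
  for (b in bins) {
    v <- cohort[[b$variable]]
    if (is.null(v)) next
    assigned <- rep(FALSE, n)
    counts <- integer(length(b$labels))
    for (i in seq_along(b$labels)) {
      lo_ok <- if (b$lower_closed[i]) v >= b$lower[i] else v > b$lower[i]
      hi_ok <- if (b$upper_closed[i]) v <= b$upper[i] else v < b$upper[i]
      inbin <- lo_ok & hi_ok & !assigned
      counts[i] <- sum(inbin, na.rm = TRUE)
      assigned <- assigned | (inbin & !is.na(inbin))
    }
    df <- data.frame(variable = b$variable, bin = b$labels,
                     count = counts, percent = pct(counts))
    n_out <- sum(!assigned)
    if (n_out > 0L)
      df <- rbind(df, data.frame(variable = b$variable, bin = "unbinned",
                                 count = n_out, percent = pct(n_out)))
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-trial score and duration descriptives with paired differences
#'
#' Summarizes the two walking trials: mean, median and SD of the ordinal
#' scores and durations per trial, and the per-subject trial-1 minus
#' trial-2 paired differences (positive mean duration difference indicates
#' the first test takes longer).
#'
#' @param cohort cohort data.frame with columns `score2_1`, `score2_2`,
#'   `duration1`, `duration2`
#' @return list with `per_trial` (data.frame of descriptives), `paired`
#'   (per-subject differences) and `paired_summary` (mean/median
#'   differences); subjects with missing trial data are listed in
#'   `incomplete`
#' @export
summarizeScoresDurations <- function(cohort) {
  need <- c("score2_1", "score2_2", "duration1", "duration2")
  miss_col <- setdiff(need, names(cohort))
  if (length(miss_col))
    stop("cohort lacks column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  incomplete <- cohort$subject_id[!stats::complete.cases(cohort[, need])]
  cc <- cohort[stats::complete.cases(cohort[, need]), ]
  desc <- function(x) c(mean = mean(x), median = stats::median(x),
                        sd = stats::sd(x))
  per_trial <- data.frame(
    trial = c("test2_1", "test2_2"),
    rbind(c(desc(cc$score2_1), desc(cc$duration1)),
          c(desc(cc$score2_2), desc(cc$duration2))))
  names(per_trial)[2:7] <- c("score_mean", "score_median", "score_sd",
                             "duration_mean", "duration_median", "duration_sd")
  paired <- data.frame(
    subject_id = cc$subject_id,
    score_diff = cc$score2_1 - cc$score2_2,
    duration_diff = cc$duration1 - cc$duration2)
  list(per_trial = per_trial,
       paired = paired,
       paired_summary = c(
         mean_score_diff = mean(paired$score_diff),
         mean_duration_diff = mean(paired$duration_diff),
         median_duration_diff = stats::median(paired$duration_diff)),
       incomplete = as.character(incomplete))
}
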