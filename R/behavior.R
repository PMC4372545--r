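#' Delayed match-to-sample accuracy
#'
#' Percent correct overall and split by match / non-match condition. A
#' trial is correct when a match trial receives "yes" or a non-match trial
#' receives "no". Trials with a missing response are excluded and counted.
#'
#' @param records data.frame with `condition` (`"match"`/`"nonmatch"`) and
#'   either a logical `dms_correct` or a `dms_response` (`"yes"`/`"no"`)
#'   column; [simulate_behavior()]'s `$trials` works directly.
#' @return List: `percent_correct`, `by_condition` (named numeric),
#'   `n_trials`, `n_missing`.
#' @export
dms_accuracy <- function(records) {
  if (inherits(records, "behavior_record")) records <- records$trials
  stopifnot(is.data.frame(records), "condition" %in% names(records))
  if ("dms_response" %in% names(records)) {
    correct <- ifelse(records$condition == "match",
                      records$dms_response == "yes",
                      records$dms_response == "no")
  } else if ("dms_correct" %in% names(records)) {
    correct <- records$dms_correct
  } else stop("records need a dms_response or dms_correct column")
  missing <- is.na(correct)
  if (any(missing))
    message(sum(missing), " trial(s) without a response excluded")
  correct <- correct[!missing]
  cond <- records$condition[!missing]
  list(percent_correct = 100 * mean(correct),
       by_condition = vapply(c(match = "match", nonmatch = "nonmatch"),
                             function(cn) 100 * mean(correct[cond == cn]),
                             numeric(1)),
       n_trials = length(correct), n_missing = sum(missing))
}

.OLD_ENDORSEMENTS <- c("3", "4", "R")

#' Subsequent-memory test score
#'
#' Binarizes the five-point confidence scale into old endorsements
#' ({3, 4, R}) vs new ({1, 2}), computes the true-positive rate over
#' studied items and the false-positive rate over lures, and reports
#' corrected accuracy = TPR - FPR (chance 0). By default only studied items
#' from correct working-memory trials enter the TPR.
#'
#' @param records Studied-item records: a `behavior_record` or data.frame
#'   with `smt_rating` (and `dms_correct` when filtering).
#' @param lure_ratings Character vector of lure ratings, or a data.frame
#'   with an `smt_rating` column.
#' @param correct_trials_only Restrict studied items to correct DMS trials.
#' @return An `smt_score` list: `true_positive_rate`,
#'   `false_positive_rate`, `corrected_accuracy`, `response_distribution`
#'   (ratings x {old, lure} counts), `n_old`, `n_lure`.
#' @export
smt_score <- function(records, lure_ratings, correct_trials_only = TRUE) {
  if (inherits(records, "behavior_record")) {
    if (missing(lure_ratings)) lure_ratings <- records$lure_ratings
    records <- records$trials
  }
  if (is.data.frame(lure_ratings)) lure_ratings <- lure_ratings$smt_rating
  stopifnot("smt_rating" %in% names(records))
  old <- records$smt_rating
  if (correct_trials_only && "dms_correct" %in% names(records))
    old <- old[records$dms_correct]
  if (length(old) == 0) stop("no studied items to score")
  if (length(lure_ratings) == 0) stop("no lure items to score")
  bad <- setdiff(unique(c(old, lure_ratings)), .RATING_LEVELS)
  if (length(bad) > 0)
    stop("unknown rating(s): ", paste(bad, collapse = ", "))
  tpr <- mean(old %in% .OLD_ENDORSEMENTS)
  fpr <- mean(lure_ratings %in% .OLD_ENDORSEMENTS)
  dist <- rbind(old = table(factor(old, levels = .RATING_LEVELS)),
                lure = table(factor(lure_ratings, levels = .RATING_LEVELS)))
  structure(list(true_positive_rate = tpr, false_positive_rate = fpr,
                 corrected_accuracy = tpr - fpr,
                 response_distribution = t(dist),
                 n_old = length(old), n_lure = length(lure_ratings)),
            class = "smt_score")
}

#' @export
print.smt_score <- function(x, ...) {
  cat(sprintf("SMT: TPR %.3f, FPR %.3f, corrected accuracy %.3f\n",
              x$true_positive_rate, x$false_positive_rate,
              x$corrected_accuracy))
  invisible(x)
}

#' Cohort behavioral summary
#'
#' Median and range of DMS percent correct and SMT corrected accuracy over
#' a list of participants, mirroring the reporting style for group
#' behavior.
#'
#' @param participants List of `participant` objects.
#' @return data.frame with one row per measure: `median`, `min`, `max`.
#' @export
behavior_summary <- function(participants) {
  dms <- vapply(participants, function(p)
    dms_accuracy(p$behavior)$percent_correct, numeric(1))
  smt <- vapply(participants, function(p)
    100 * smt_score(p$behavior)$corrected_accuracy, numeric(1))
  data.frame(measure = c("dms_percent_correct", "smt_corrected_accuracy"),
             median = c(stats::median(dms), stats::median(smt)),
             min = c(min(dms), min(smt)), max = c(max(dms), max(smt)))
}
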