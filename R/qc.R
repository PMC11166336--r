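# Preregistered participant-level data-quality exclusions. All thresholds are
# strict inequalities exactly as preregistered: a participant at exactly 20%
# (or 75%) is retained.

#' Apply the preregistered exclusion rules
#'
#' Flags participants who meet any of five criteria:
#' \describe{
#'   \item{missing_gt20}{more than 20% of expected task trials absent across
#'     the two computer tasks;}
#'   \item{search_err_gt20}{errors on more than 20% of visual-search trials;}
#'   \item{search_rt_oob_gt20}{more than 20% of search RTs below 0.250 s or
#'     above 10 s;}
#'   \item{invariant_gt75}{the same button on more than 75% of valuation test
#'     trials;}
#'   \item{valuation_rt_oob_gt20}{more than 20% of valuation test RTs below
#'     0.250 s or above 10 s.}
#' }
#' A participant is retained only if no flag is set. A participant with no
#' recorded trials at all is flagged `missing_gt20`.
#'
#' @param choices Valuation test-phase table: `participant_id`, `choice`
#'   (`"left"`/`"right"`), `rt` (seconds); one row per completed trial.
#' @param search Visual-search table: `participant_id`, `rt` (seconds),
#'   `error` (logical); one row per completed trial.
#' @param expected_choice_trials,expected_search_trials Expected trial counts
#'   per participant; the missing-data fraction is `1 -` completed/expected
#'   pooled over both tasks.
#' @param rt_bounds Lower/upper RT bounds in seconds (default `c(0.250, 10)`).
#' @param missing_threshold,error_threshold,rt_oob_threshold,invariant_threshold
#'   Exclusion thresholds (strict), defaults .20, .20, .20, .75.
#' @return Data.frame with one row per participant: `participant_id`, one
#'   logical column per flag, `n_flags`, and `retained`.
#' @export
apply_exclusions <- function(choices, search,
                             expected_choice_trials = 120L,
                             expected_search_trials = 252L,
                             rt_bounds = c(0.250, 10),
                             missing_threshold = 0.20,
                             error_threshold = 0.20,
                             rt_oob_threshold = 0.20,
                             invariant_threshold = 0.75) {
  check_columns(choices, c("participant_id", "choice", "rt"), "choices")
  check_columns(search, c("participant_id", "rt", "error"), "search")
  ids <- sort(unique(c(choices$participant_id, search$participant_id)))
  rows <- lapply(ids, function(id) {
    ch <- choices[choices$participant_id == id, , drop = FALSE]
    se <- search[search$participant_id == id, , drop = FALSE]
    n_done <- nrow(ch) + nrow(se)
    n_expected <- expected_choice_trials + expected_search_trials
    missing_frac <- 1 - n_done / n_expected
    oob <- function(rt) rt < rt_bounds[1] | rt > rt_bounds[2]

    missing_gt20 <- missing_frac > missing_threshold || n_done == 0L
    search_err_gt20 <- nrow(se) > 0L && mean(se$error) > error_threshold
    search_rt_oob_gt20 <- nrow(se) > 0L && mean(oob(se$rt)) > rt_oob_threshold
    invariant_gt75 <- nrow(ch) > 0L &&
      max(mean(ch$choice == "left"), mean(ch$choice == "right")) >
        invariant_threshold
    valuation_rt_oob_gt20 <- nrow(ch) > 0L &&
      mean(oob(ch$rt)) > rt_oob_threshold

    flags <- c(missing_gt20 = missing_gt20,
               search_err_gt20 = search_err_gt20,
               search_rt_oob_gt20 = search_rt_oob_gt20,
               invariant_gt75 = invariant_gt75,
               valuation_rt_oob_gt20 = valuation_rt_oob_gt20)
    data.frame(participant_id = id, t(flags), n_flags = sum(flags),
               retained = !any(flags), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize an exclusion report
#'
#' Counts participants per exclusion category, splitting single-category from
#' multi-category exclusions (the single-category counts plus the
#' multi-category count partition the excluded set).
#'
#' @param report Output of [apply_exclusions()].
#' @return Named integer vector: one count per flag (participants excluded by
#'   that flag alone), `multiple` and `retained`.
#' @export
summarize_exclusions <- function(report) {
  flags <- c("missing_gt20", "search_err_gt20", "search_rt_oob_gt20",
             "invariant_gt75", "valuation_rt_oob_gt20")
  check_columns(report, c(flags, "n_flags", "retained"), "report")
  single <- vapply(flags, function(f) {
    sum(report[[f]] & report$n_flags == 1L)
  }, integer(1))
  c(single, multiple = sum(report$n_flags > 1L),
    retained = sum(report$retained))
}
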