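# Trial schedules for the computerized tasks. All three builders produce the
# exact design multisets (180 exposure, 120 test, 252 search trials) in an
# order randomized by `seed`.

#' Build the exposure-phase schedule
#'
#' Each of the six faces is viewed 30 times (180 trials) in randomized order.
#'
#' @param contingencies Face contingency table, see [face_contingencies()].
#' @param seed Integer seed controlling the shuffle.
#' @param n_per_face Viewings per face (default 30).
#' @return A data.frame with columns `trial`, `face_id`.
#' @export
build_exposure_schedule <- function(contingencies = face_contingencies(),
                                    seed = 1L, n_per_face = 30L) {
  validate_contingencies(contingencies)
  faces <- rep(contingencies$face_id, each = n_per_face)
  set.seed(child_seed(seed, 101L))
  faces <- sample(faces)
  data.frame(trial = seq_along(faces), face_id = faces,
             stringsAsFactors = FALSE)
}

#' Build the test-phase (player pairing) schedule
#'
#' All choose-2 pairings of the six faces (15 pairs) are shown
#' `n_per_pair` times each (default 8, i.e. 120 trials); within each pair,
#' each face occupies the left position on exactly half of its trials.
#'
#' @inheritParams build_exposure_schedule
#' @param n_per_pair Repetitions per unordered pair; must be even so left and
#'   right placements balance.
#' @return A data.frame with columns `trial`, `left_face`, `right_face`.
#' @export
build_test_schedule <- function(contingencies = face_contingencies(),
                                seed = 1L, n_per_pair = 8L) {
  check_columns(contingencies, "face_id", "contingencies")
  if (nrow(contingencies) < 2L) abort("need at least 2 faces to form pairs")
  if (n_per_pair %% 2L != 0L) abort("n_per_pair must be even for left/right balance")
  pairs <- utils::combn(contingencies$face_id, 2L)
  half <- n_per_pair / 2L
  left  <- c(rep(pairs[1L, ], each = half), rep(pairs[2L, ], each = half))
  right <- c(rep(pairs[2L, ], each = half), rep(pairs[1L, ], each = half))
  set.seed(child_seed(seed, 102L))
  ord <- sample(length(left))
  data.frame(trial = seq_along(ord), left_face = left[ord],
             right_face = right[ord], stringsAsFactors = FALSE)
}

#' Build the visual search schedule
#'
#' 252 trials: each of the six reward-associated faces appears as a distractor
#' in 36 trials, plus 36 trials in which all three distractors are novel. The
#' search target appears in each screen quadrant with equal frequency
#' (63 trials per quadrant; each condition is itself balanced 9 per quadrant).
#'
#' @param seed Integer seed controlling the shuffle.
#' @param n_per_condition Trials per distractor condition (default 36; must be
#'   divisible by 4 to balance quadrants).
#' @return A data.frame with columns `trial`, `condition` (one of
#'   `genuine_hi`, `genuine_lo`, `polite_hi`, `polite_lo`, `neutral_hi`,
#'   `neutral_lo`, `all_novel`) and `target_quadrant` (1-4).
#' @export
build_search_schedule <- function(seed = 1L, n_per_condition = 36L) {
  if (n_per_condition %% 4L != 0L) {
    abort("n_per_condition must be divisible by 4 to balance target quadrants")
  }
  conditions <- search_conditions()
  cond <- rep(conditions, each = n_per_condition)
  quad <- rep(rep(1:4, each = n_per_condition / 4L), times = length(conditions))
  set.seed(child_seed(seed, 103L))
  ord <- sample(length(cond))
  data.frame(trial = seq_along(ord), condition = cond[ord],
             target_quadrant = quad[ord], stringsAsFactors = FALSE)
}

#' Distractor condition labels of the visual search task
#'
#' @param familiar_only If `TRUE`, drop the `all_novel` condition and return
#'   only the six reward-associated (familiar distractor) conditions.
#' @return Character vector of condition labels.
#' @export
search_conditions <- function(familiar_only = FALSE) {
  fam <- c("genuine_hi", "genuine_lo", "polite_hi", "polite_lo",
           "neutral_hi", "neutral_lo")
  if (familiar_only) fam else c(fam, "all_novel")
}
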