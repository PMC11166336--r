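#' Face reward contingencies for the smile valuation task
#'
#' The valuation task uses six faces crossing social display type (genuine
#' smile, polite smile, neutral with text feedback) with monetary value: each
#' social type appears once as a high-value face (2 cents won on 80% of
#' trials, expected value 1.6 cents/trial) and once as a low-value face
#' (2 cents on 60% of trials, expected value 1.2 cents/trial).
#'
#' @param win_amount Reward magnitude in cents (default 2).
#' @return A data.frame with one row per face and columns `face_id`,
#'   `social_type` (`genuine`/`polite`/`neutral`), `win_prob` (.80 or .60),
#'   `win_amount` (cents) and `ev` (expected value in cents per trial).
#' @examples
#' face_contingencies()
#' @export
face_contingencies <- function(win_amount = 2) {
  df <- data.frame(
    face_id     = paste0("f", 1:6),
    social_type = rep(c("genuine", "polite", "neutral"), each = 2L),
    win_prob    = rep(c(0.80, 0.60), times = 3L),
    win_amount  = win_amount,
    stringsAsFactors = FALSE
  )
  df$ev <- df$win_prob * df$win_amount
  df
}

# internal: validate a contingency table against the task's invariants
validate_contingencies <- function(contingencies) {
  check_columns(contingencies, c("face_id", "social_type", "win_prob", "ev"),
                "contingencies")
  if (nrow(contingencies) != 6L) {
    abort("contingencies must describe exactly 6 faces, got ",
          nrow(contingencies))
  }
  if (anyDuplicated(contingencies$face_id)) {
    abort("face_id values must be unique")
  }
  tab <- table(contingencies$social_type, contingencies$win_prob)
  if (!identical(sort(rownames(tab)), c("genuine", "neutral", "polite")) ||
      !all(tab == 1L) || ncol(tab) != 2L) {
    abort("each social type must appear exactly twice, once per win probability")
  }
  invisible(contingencies)
}
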