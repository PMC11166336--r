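# Value-driven attentional capture: per-participant mean-centered condition
# means, the genuine-vs-neutral capture composite, and the 2 (monetary value)
# x 3 (social value) repeated-measures ANOVA over the six familiar-distractor
# conditions. Positive centered values mean search was slowed relative to the
# participant's own grand-average response time.

#' Per-participant mean-centered condition means
#'
#' Error trials are discarded; each participant's grand-average RT is computed
#' over all retained trials (including all-novel trials) and subtracted from
#' the per-condition mean RTs.
#'
#' @param trials Data.frame with columns `participant_id`, `condition`, `rt`
#'   (seconds) and `error` (logical).
#' @return Data.frame with one row per participant: `participant_id`,
#'   `grand_mean`, one column per condition (centered mean, seconds) and
#'   `composite` (see [capture_composite()]). Conditions with no retained
#'   trials are `NA`.
#' @export
centered_condition_means <- function(trials) {
  check_columns(trials, c("participant_id", "condition", "rt", "error"),
                "trials")
  conds <- search_conditions()
  unknown <- setdiff(unique(trials$condition), conds)
  if (length(unknown) > 0L) {
    abort("unknown search condition(s): ", paste(unknown, collapse = ", "))
  }
  kept <- trials[!trials$error, , drop = FALSE]
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    d <- kept[kept$participant_id == id, , drop = FALSE]
    row <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(conds)),
                                                 conds)))
    gm <- NA_real_
    if (nrow(d) > 0L) {
      gm <- mean(d$rt)
      cm <- tapply(d$rt, factor(d$condition, levels = conds), mean)
      row[1, ] <- as.numeric(cm) - gm
    }
    cbind(data.frame(participant_id = id, grand_mean = gm,
                     stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  out$composite <- capture_composite(out)
  rownames(out) <- NULL
  out
}

#' Genuine-smile attentional capture composite
#'
#' The average of the mean-centered genuine-smile distractor conditions minus
#' the average of the mean-centered neutral (non-smiling familiar) distractor
#' conditions. Positive values mean genuine-smile-associated faces slowed
#' search more than neutral familiar faces. Missing if any of the four inputs
#' is missing.
#'
#' @param scores Data.frame with columns `genuine_hi`, `genuine_lo`,
#'   `neutral_hi`, `neutral_lo` (from [centered_condition_means()]).
#' @return Numeric vector of composites, one per row of `scores`.
#' @export
capture_composite <- function(scores) {
  check_columns(scores, c("genuine_hi", "genuine_lo", "neutral_hi",
                          "neutral_lo"), "scores")
  (scores$genuine_hi + scores$genuine_lo) / 2 -
    (scores$neutral_hi + scores$neutral_lo) / 2
}

#' Two-by-three repeated-measures ANOVA on capture scores
#'
#' Fully within-participants ANOVA of the mean-centered condition means over
#' the six familiar-distractor cells: monetary value (high/low) x social value
#' (genuine/polite/neutral), one observation per cell. The all-novel condition
#' is not part of the factorial design and is ignored. Each effect is tested
#' against its own effect-by-participant interaction and reported with partial
#' omega-squared. Pairwise Bonferroni-corrected paired t post-hocs compare the
#' social-value levels (averaged over monetary value) and the monetary-value
#' levels within each social type. Participants with any missing cell are
#' removed listwise.
#'
#' @param scores Output of [centered_condition_means()] (wide, one row per
#'   participant).
#' @return A list of class `rm_anova` with `anova` (data.frame: effect, df1,
#'   df2, F, p_value, omega_sq), `posthoc` (data.frame of paired contrasts)
#'   and `n_participants`.
#' @export
rm_anova_2x3 <- function(scores) {
  cells <- search_conditions(familiar_only = TRUE)
  check_columns(scores, c("participant_id", cells), "scores")
  complete <- stats::complete.cases(scores[, cells])
  scores <- scores[complete, , drop = FALSE]
  n <- nrow(scores)
  if (n < 2L) abort("need at least 2 participants with complete cells")

  Y <- as.matrix(scores[, cells])        # n x 6, columns ordered hi/lo x social
  money <- rep(c("hi", "lo"), times = 3L)
  social <- rep(c("genuine", "polite", "neutral"), each = 2L)

  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_money <- tapply(colMeans(Y), money, mean)[c("hi", "lo")]
  m_social <- tapply(colMeans(Y), social, mean)[c("genuine", "polite", "neutral")]
  m_cell <- colMeans(Y)

  # per-subject marginal means
  subj_money <- sapply(c("hi", "lo"), function(l) rowMeans(Y[, money == l]))
  subj_social <- sapply(c("genuine", "polite", "neutral"),
                        function(l) rowMeans(Y[, social == l]))

  ss_money <- 3 * n * sum((m_money - grand)^2)
  ss_social <- 2 * n * sum((m_social - grand)^2)
  cell_int <- m_cell - m_money[money] - m_social[social] + grand
  ss_int <- n * sum(cell_int^2)

  ss_money_err <- 3 * sum((subj_money - outer(m_subj, rep(1, 2)) -
                             outer(rep(1, n), m_money) + grand)^2)
  ss_social_err <- 2 * sum((subj_social - outer(m_subj, rep(1, 3)) -
                              outer(rep(1, n), m_social) + grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_subj <- 6 * sum((m_subj - grand)^2)
  ss_int_err <- ss_total - ss_subj - ss_money - ss_social - ss_int -
    ss_money_err - ss_social_err

  eff <- function(name, ss, df1, ss_err, df_err) {
    F <- (ss / df1) / (ss_err / df_err)
    # F-based partial omega-squared for within-participant effects
    om <- df1 * (F - 1) / (df1 * (F - 1) + n)
    data.frame(effect = name, df1 = df1, df2 = df_err, F = F,
               p_value = stats::pf(F, df1, df_err, lower.tail = FALSE),
               omega_sq = max(0, om), stringsAsFactors = FALSE)
  }
  anova_tab <- rbind(
    eff("money", ss_money, 1, ss_money_err, n - 1),
    eff("social", ss_social, 2, ss_social_err, 2 * (n - 1)),
    eff("money:social", ss_int, 2, ss_int_err, 2 * (n - 1))
  )

  # post-hocs: social pairwise (3 tests, Bonferroni within family) and
  # money hi vs lo within each social type (3 tests, Bonferroni within family)
  ph <- list()
  contrast_row <- function(family, label, a, b) {
    t <- tryCatch(paired_t_cohens_d(a, b), error = function(e) NULL)
    if (is.null(t)) {
      # degenerate contrast (zero-variance differences): reported as NA
      return(data.frame(family = family, contrast = label,
                        mean_diff = mean(a - b), ci_low = NA_real_,
                        ci_high = NA_real_, t = NA_real_,
                        df = length(a) - 1, p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(family = family, contrast = label, mean_diff = t$mean_diff,
               ci_low = t$mean_diff_ci[1], ci_high = t$mean_diff_ci[2],
               t = t$statistic, df = t$df, p_raw = t$p_value,
               stringsAsFactors = FALSE)
  }
  socials <- c("genuine", "polite", "neutral")
  pairs <- utils::combn(socials, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ph[[length(ph) + 1L]] <- contrast_row("social", paste(a, "vs", b),
                                          subj_social[, a], subj_social[, b])
  }
  for (s in socials) {
    ph[[length(ph) + 1L]] <- contrast_row("money_within_social",
                                          paste0(s, ": hi vs lo"),
                                          Y[, paste0(s, "_hi")],
                                          Y[, paste0(s, "_lo")])
  }
  posthoc <- do.call(rbind, ph)
  posthoc$p_bonferroni <- NA_real_
  for (fam in unique(posthoc$family)) {
    idx <- posthoc$family == fam
    posthoc$p_bonferroni[idx] <- stats::p.adjust(posthoc$p_raw[idx],
                                                 method = "bonferroni")
  }

  structure(list(anova = anova_tab, posthoc = posthoc, n_participants = n),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("2 (money) x 3 (social) repeated-measures ANOVA, n =",
      x$n_participants, "\n")
  print(transform(x$anova, F = round(F, 3), p_value = signif(p_value, 4),
                  omega_sq = round(omega_sq, 4)), row.names = FALSE)
  cat("\nBonferroni post-hocs:\n")
  print(transform(x$posthoc, mean_diff = round(mean_diff, 4),
                  t = round(t, 3), p_bonferroni = signif(p_bonferroni, 4)),
        row.names = FALSE)
  invisible(x)
}
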