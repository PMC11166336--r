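make_trials <- function(id, rt_by_cond, n_each = 36L, error = FALSE) {
  conds <- names(rt_by_cond)
  data.frame(participant_id = id,
             condition = rep(conds, each = n_each),
             rt = rep(unlist(rt_by_cond), each = n_each),
             error = error, stringsAsFactors = FALSE)
}

test_that("mean-centering obeys the centering identity", {
  # constant RT everywhere -> all centered means 0
  flat <- make_trials("p1", setNames(as.list(rep(1, 7)), search_conditions()))
  sc <- centered_condition_means(flat)
  expect_true(all(abs(sc[, search_conditions()]) < 1e-12))
  # genuine conditions slowed to 1.1 s, all five others 1.0 s, equal counts:
  # grand mean 7.2/7, genuine centered +0.5/7, others -0.2/7
  rts <- setNames(as.list(rep(1.0, 7)), search_conditions())
  rts$genuine_hi <- 1.1; rts$genuine_lo <- 1.1
  sc2 <- centered_condition_means(make_trials("p1", rts))
  expect_equal(sc2$genuine_hi, 0.5 / 7, tolerance = 1e-12)
  expect_equal(sc2$neutral_lo, -0.2 / 7, tolerance = 1e-12)
  # trial-count-weighted deviations sum to zero over retained trials
  expect_equal(sum(unlist(sc2[, search_conditions()]) * 36), 0,
               tolerance = 1e-10)
})

test_that("error trials are discarded and empty conditions go missing", {
  tr <- make_trials("p1", setNames(as.list(1:7 / 10), search_conditions()))
  tr$error[tr$condition == "polite_hi"] <- TRUE
  sc <- centered_condition_means(tr)
  expect_true(is.na(sc$polite_hi))
  expect_false(anyNA(sc[, setdiff(search_conditions(), "polite_hi")]))
  expect_true(is.na(sc$composite) ||
                !anyNA(sc[, c("genuine_hi", "genuine_lo", "neutral_hi",
                              "neutral_lo")]))
})

test_that("capture composite arithmetic and invariances", {
  sc <- data.frame(genuine_hi = .10, genuine_lo = .12,
                   neutral_hi = -.02, neutral_lo = 0)
  expect_equal(capture_composite(sc), .12)
  # swapping genuine and neutral inputs flips the sign
  sw <- data.frame(genuine_hi = -.02, genuine_lo = 0,
                   neutral_hi = .10, neutral_lo = .12)
  expect_equal(capture_composite(sw), -.12)
  # all equal -> 0
  eq <- data.frame(genuine_hi = .3, genuine_lo = .3, neutral_hi = .3,
                   neutral_lo = .3)
  expect_equal(capture_composite(eq), 0)
  # composite invariant to adding a constant to all of a participant's RTs
  tp <- true_participants(1, seed = 44)
  sch <- build_search_schedule(seed = 44)
  tr <- simulate_search(tp[1, ], sch)
  tr2 <- tr
  tr2$rt <- tr$rt + 5
  expect_equal(centered_condition_means(tr)$composite,
               centered_condition_means(tr2)$composite, tolerance = 1e-10)
})

test_that("RM-ANOVA matches aov() error strata on simulated cohorts", {
  tp <- true_participants(14, seed = 51)
  sch <- build_search_schedule(seed = 51)
  search <- do.call(rbind, lapply(1:14, function(i) {
    simulate_search(tp[i, ], sch)
  }))
  sc <- centered_condition_means(search)
  got <- rm_anova_2x3(sc)

  cells <- search_conditions(familiar_only = TRUE)
  long <- do.call(rbind, lapply(cells, function(cc) {
    data.frame(id = sc$participant_id, y = sc[[cc]],
               money = sub(".*_", "", cc), social = sub("_.*", "", cc))
  }))
  long$id <- factor(long$id)
  long$money <- factor(long$money)
  long$social <- factor(long$social)
  fit <- stats::aov(y ~ money * social + Error(id / (money * social)),
                    data = long)
  s <- summary(fit)
  f_money <- s[["Error: id:money"]][[1]]["money", "F value"]
  f_social <- s[["Error: id:social"]][[1]]["social", "F value"]
  f_int <- s[["Error: id:money:social"]][[1]]["money:social", "F value"]
  a <- got$anova
  expect_equal(a$F[a$effect == "money"], f_money, tolerance = 1e-8)
  expect_equal(a$F[a$effect == "social"], f_social, tolerance = 1e-8)
  expect_equal(a$F[a$effect == "money:social"], f_int, tolerance = 1e-8)
  expect_equal(a$df1, c(1, 2, 2))
  expect_equal(a$df2, c(13, 26, 26))
})

test_that("RM-ANOVA matches a hand-worked two-participant decomposition", {
  sc <- data.frame(participant_id = c("a", "b"),
                   genuine_hi = c(4, 6), genuine_lo = c(3, 5),
                   polite_hi = c(2, 5), polite_lo = c(2, 4),
                   neutral_hi = c(1, 3), neutral_lo = c(0, 2))
  got <- rm_anova_2x3(sc)$anova
  Y <- as.matrix(sc[, -1])
  money <- rep(c("hi", "lo"), 3)
  social <- rep(c("genuine", "polite", "neutral"), each = 2)
  grand <- mean(Y)
  # explicit sums of squares from marginal means
  ss <- function(means, mult) mult * sum((means - grand)^2)
  ss_money <- ss(tapply(colMeans(Y), money, mean), 3 * 2)
  ss_social <- ss(tapply(colMeans(Y), social, mean), 2 * 2)
  subj_money <- t(apply(Y, 1, function(r) tapply(r, money, mean)))
  ss_ms <- 3 * sum((subj_money - rowMeans(Y) -
                      rep(tapply(colMeans(Y), money, mean), each = 2) +
                      grand)^2)
  F_money <- (ss_money / 1) / (ss_ms / 1)
  expect_equal(got$F[got$effect == "money"], F_money, tolerance = 1e-10)
  expect_equal(got$df2[got$effect == "money"], 1)
  subj_social <- t(apply(Y, 1, function(r) tapply(r, social, mean)))
  ss_ss <- 2 * sum((subj_social - rowMeans(Y) -
                      rep(tapply(colMeans(Y), social, mean), each = 2) +
                      grand)^2)
  F_social <- (ss_social / 2) / (ss_ss / 2)
  expect_equal(got$F[got$effect == "social"], F_social, tolerance = 1e-10)
})

test_that("ANOVA detects a generated social-value ordering, post-hocs agree", {
  shifts <- default_capture_shifts()
  tp <- true_participants(24, seed = 61, capture_shifts = shifts)
  sch <- build_search_schedule(seed = 61)
  search <- do.call(rbind, lapply(1:24, function(i) {
    simulate_search(tp[i, ], sch)
  }))
  got <- rm_anova_2x3(centered_condition_means(search))
  a <- got$anova
  expect_lt(a$p_value[a$effect == "social"], 0.001)
  ph <- got$posthoc
  gvn <- ph[ph$contrast == "genuine vs neutral", ]
  expect_gt(gvn$mean_diff, 0)
  expect_lt(gvn$p_bonferroni, 0.01)
  pvn <- ph[ph$contrast == "polite vs neutral", ]
  expect_gt(pvn$mean_diff, 0)
})
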