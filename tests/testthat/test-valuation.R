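faces <- face_contingencies()

test_that("trial coding follows the printed rules and is antisymmetric", {
  hi_gen <- faces[faces$social_type == "genuine" & faces$ev == 1.6, ]
  lo_neu <- faces[faces$social_type == "neutral" & faces$ev == 1.2, ]
  expect_equal(code_trial(hi_gen, lo_neu), c(x1 = .40, x2 = 1, x3 = 0))
  expect_equal(code_trial(lo_neu, hi_gen), c(x1 = -.40, x2 = -1, x3 = 0))
  # both genuine -> x2 = 0; money code reflects EV difference only
  lo_gen <- faces[faces$social_type == "genuine" & faces$ev == 1.2, ]
  expect_equal(code_trial(hi_gen, lo_gen), c(x1 = .40, x2 = 0, x3 = 0))
  # polite coded in the same manner
  hi_pol <- faces[faces$social_type == "polite" & faces$ev == 1.6, ]
  expect_equal(code_trial(hi_pol, lo_neu), c(x1 = .40, x2 = 0, x3 = 1))
  expect_error(code_trial(hi_gen, hi_gen), "differ")
})

test_that("coding a schedule is antisymmetric under a global left/right swap", {
  sch <- build_test_schedule(seed = 2)
  coded <- code_trials(sch, faces)
  swapped <- sch
  swapped$left_face <- sch$right_face
  swapped$right_face <- sch$left_face
  coded_sw <- code_trials(swapped, faces)
  expect_equal(coded_sw$x1, -coded$x1)
  expect_equal(coded_sw$x2, -coded$x2)
  expect_equal(coded_sw$x3, -coded$x3)
})

test_that("IRLS fit matches glm on well-behaved data and the grid oracle", {
  tp <- true_participants(4, seed = 21)
  sch <- build_test_schedule(seed = 21)
  for (i in 1:4) {
    ch <- simulate_choices(tp[i, ], sch)
    fit <- fit_utilities(ch)
    if (fit$converged) {
      g <- suppressWarnings(stats::glm(y ~ x1 + x2 + x3, binomial, data = ch))
      expect_equal(c(fit$beta0, fit$beta_money, fit$beta_genuine,
                     fit$beta_polite),
                   unname(coef(g)), tolerance = 1e-3)
    }
    grid <- oracle_logit_grid(ch)
    expect_lt(max(abs(c(fit$beta0, fit$beta_money, fit$beta_genuine,
                        fit$beta_polite) - grid)), 1e-2)
  }
})

test_that("left/right swap of all trials leaves utilities invariant up to the intercept sign", {
  tp <- true_participants(1, seed = 31)
  sch <- build_test_schedule(seed = 31)
  ch <- simulate_choices(tp[1, ], sch)
  fit <- fit_utilities(ch)
  sw <- ch
  sw$x1 <- -ch$x1; sw$x2 <- -ch$x2; sw$x3 <- -ch$x3; sw$y <- 1L - ch$y
  fit_sw <- fit_utilities(sw)
  expect_equal(fit_sw$beta0, -fit$beta0, tolerance = 1e-6)
  expect_equal(fit_sw$beta_money, fit$beta_money, tolerance = 1e-6)
  expect_equal(fit_sw$beta_genuine, fit$beta_genuine, tolerance = 1e-6)
  expect_equal(fit_sw$beta_polite, fit$beta_polite, tolerance = 1e-6)
})

test_that("separation is capped and flagged", {
  sch <- build_test_schedule(seed = 4)
  coded <- code_trials(sch, faces)
  # deterministic money-driven chooser: y = 1 whenever left EV is higher,
  # ties split by x2 -> perfect separation on x1
  coded$y <- ifelse(coded$x1 > 0, 1L, ifelse(coded$x1 < 0, 0L, NA))
  coded <- coded[!is.na(coded$y), ]
  fit <- fit_utilities(coded)
  expect_false(fit$converged)
  expect_equal(abs(fit$beta_money), 10)
  # all-left responder: intercept at the cap, reward terms near zero
  coded2 <- code_trials(sch, faces)
  coded2$y <- 1L
  fit2 <- fit_utilities(coded2)
  expect_false(fit2$converged)
  expect_equal(fit2$beta0, 10)
  expect_lt(max(abs(c(fit2$beta_money, fit2$beta_genuine,
                      fit2$beta_polite))), 0.5)
})

test_that("constant regressor is reported as missing", {
  # pairs drawn only among neutral faces: x2 and x3 never vary
  neutral <- faces[faces$social_type == "neutral", ]
  sch <- build_test_schedule(neutral, seed = 1)
  coded <- code_trials(sch, neutral)
  set.seed(1)
  coded$y <- rbinom(nrow(coded), 1, 0.5)
  fit <- fit_utilities(coded)
  expect_true(is.na(fit$beta_genuine))
  expect_true(is.na(fit$beta_polite))
  expect_false(is.na(fit$beta_money))
})

test_that("group tests recover the Wilcoxon example and symmetric null", {
  est <- data.frame(beta_money = c(1, 2, 3, 4, 5, 6),
                    beta_genuine = c(-2, -1, 1, 2, 3, -3),
                    beta_polite = c(1, -1, 2, -2, 3, -3))
  out <- group_utility_tests(est, n_boot = 0)
  # beta_money all positive: V = n(n+1)/2 = 21, r_rbs = 1
  expect_equal(out$V[out$term == "beta_money"], 21)
  expect_equal(out$r_rbs[out$term == "beta_money"], 1)
  # symmetric +/- pairs: rank-biserial 0
  expect_equal(out$r_rbs[out$term == "beta_polite"], 0)
})

test_that("split-half reliability is 1 for duplicated halves and near 0 for noise", {
  sch <- build_test_schedule(seed = 6)
  tp <- true_participants(24, seed = 6)
  choices <- do.call(rbind, lapply(1:24, function(i) {
    simulate_choices(tp[i, ], sch)
  }))
  # duplicate odd trials into even slots -> identical halves
  dup <- do.call(rbind, lapply(split(choices, choices$participant_id),
    function(d) {
      d[seq(2, nrow(d), by = 2), c("x1", "x2", "x3", "y")] <-
        d[seq(1, nrow(d), by = 2), c("x1", "x2", "x3", "y")]
      d
    }))
  rel <- split_half_reliability(dup)
  expect_true(all(rel$reliability > 0.999))
  # pure-noise choices carry no stable individual signal
  noise <- choices
  set.seed(99)
  noise$y <- rbinom(nrow(noise), 1, 0.5)
  rel_noise <- split_half_reliability(noise)
  expect_true(all(abs(rel_noise$reliability) < 0.5))
  # real heterogeneous participants: positive reliability
  rel_true <- split_half_reliability(choices)
  expect_true(all(rel_true$reliability > 0.2))
})
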