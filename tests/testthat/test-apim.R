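test_that("interaction-quality scoring flips reverse-keyed items", {
  items <- matrix(7, nrow = 5, ncol = 9)
  out <- score_interaction_quality(items, reverse_keyed = integer(0))
  expect_equal(out$ratings, rep(7, 5))
  # a reverse-keyed response of 1 contributes 7 after flipping
  items2 <- matrix(4, nrow = 5, ncol = 9)
  items2[, 2] <- 1
  out2 <- score_interaction_quality(items2, reverse_keyed = 2L)
  expect_equal(out2$ratings, rep((8 * 4 + 7) / 9, 5))
  expect_error(score_interaction_quality(items[, 1:8]), "9")
  expect_error(score_interaction_quality(items * 2), "1-7")
})

test_that("noise-free unit-loading items give alpha = 1 after reverse-scoring", {
  set.seed(2)
  latent <- pmin(7, pmax(1, round(rnorm(40, 4, 1))))
  items <- matrix(latent, nrow = 40, ncol = 9)
  items[, c(2, 7)] <- 8 - items[, c(2, 7)]   # stored reverse-keyed
  out <- score_interaction_quality(items)
  expect_equal(out$alpha$alpha, 1)
  expect_equal(out$ratings, latent)
})

test_that("complete-data closed form agrees with generic FIML optimization", {
  d <- simulate_apim_dyads(80, actor = 0.15, partner = -0.25, seed = 5)
  m_complete <- fit_apim(d, n_boot = 0)
  # knock one outcome out: forces the FIML optimizer path end-to-end
  d_miss <- d
  d_miss$y_2[1] <- NA
  m_fiml <- fit_apim(d_miss, n_boot = 0)
  expect_true(m_fiml$fit$fiml)
  expect_false(m_complete$fit$fiml)
  # one dyad out of 80 barely moves the estimates
  expect_equal(m_fiml$paths$estimate, m_complete$paths$estimate,
               tolerance = 0.05)
  # and on complete data, forcing the optimizer reproduces the closed form
  d2 <- d
  d2$y_2[1] <- d$y_2[1]    # unchanged; fit via internal FIML start
  Z <- as.matrix(d2[, c("x_1", "x_2", "y_1", "y_2")])
  cf <- smileval:::apim_closed_form(Z)
  nll <- function(par) {
    mom <- smileval:::apim_moments(par)
    -smileval:::mvn_loglik(Z, mom$mu, mom$Sigma)
  }
  opt <- stats::optim(smileval:::apim_pack(cf), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_equal(-opt$value, smileval:::apim_point_fit(Z)$log_lik,
               tolerance = 1e-6)
  mom <- smileval:::apim_moments(opt$par)
  expect_equal(c(mom$a, mom$p), c(cf$a, cf$p), tolerance = 1e-4)
})

test_that("member relabelling leaves the APIM unchanged (indistinguishability)", {
  d <- simulate_apim_dyads(60, actor = 0.1, partner = -0.2, seed = 9)
  sw <- data.frame(x_1 = d$x_2, x_2 = d$x_1, y_1 = d$y_2, y_2 = d$y_1)
  m1 <- fit_apim(d, n_boot = 0)
  m2 <- fit_apim(sw, n_boot = 0)
  expect_equal(m1$paths$estimate, m2$paths$estimate, tolerance = 1e-10)
  expect_equal(m1$fit$chi_sq, m2$fit$chi_sq, tolerance = 1e-8)
})

test_that("degenerate inputs raise informative errors", {
  d <- simulate_apim_dyads(40, seed = 3)
  d$x_1 <- 1; d$x_2 <- 1
  expect_error(fit_apim(d, n_boot = 0), "variance")
  # perfectly collinear members
  set.seed(4)
  x <- rnorm(30); y <- 1 + x + rnorm(30, 0, .3)
  toy <- data.frame(x_1 = x, x_2 = x, y_1 = y, y_2 = y)
  expect_error(fit_apim(toy, n_boot = 0), "singular|collinear")
  expect_error(fit_apim(simulate_apim_dyads(5, seed = 1), n_boot = 0),
               "10 dyads")
})

test_that("APIM recovers generating actor and partner paths", {
  d <- simulate_apim_dyads(400, actor = 0.1, partner = -0.3, seed = 17)
  m <- fit_apim(d, n_boot = 100, seed = 2)
  expect_lt(abs(m$paths$estimate[m$paths$effect == "actor"] - 0.1), 0.08)
  expect_lt(abs(m$paths$estimate[m$paths$effect == "partner"] + 0.3), 0.08)
  # bootstrap CIs bracket the estimates
  expect_true(all(m$paths$ci_low < m$paths$estimate &
                    m$paths$estimate < m$paths$ci_high))
  # fit of the (correctly specified) model is acceptable
  expect_gt(m$fit$p_value, 0.001)
  expect_lt(m$fit$srmr, 0.10)
})

test_that("alternate-predictor models isolate the carrying predictor", {
  set.seed(23)
  d <- simulate_apim_dyads(300, actor = 0, partner = -0.35, seed = 23)
  # a second predictor unrelated to the outcomes
  d$junk_1 <- rnorm(300)
  d$junk_2 <- rnorm(300)
  d$speed_1 <- d$x_1
  d$speed_2 <- d$x_2
  out <- fit_alternate_models(d, c("speed", "junk"), n_boot = 100, seed = 5)
  tab <- out$table
  speed_p <- tab[tab$predictor == "speed" & tab$effect == "partner", ]
  junk_p <- tab[tab$predictor == "junk" & tab$effect == "partner", ]
  expect_lt(speed_p$p_value, 0.01)
  expect_gt(junk_p$p_value, 0.05)
  # predictor identical to the primary gives the identical fit
  prim <- fit_apim(d, n_boot = 0)
  again <- fit_alternate_models(d, "speed", n_boot = 0)
  expect_equal(again$models$speed$paths$estimate, prim$paths$estimate,
               tolerance = 1e-10)
})
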