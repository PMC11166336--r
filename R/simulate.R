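# Synthetic-data generators with known ground truth. Every dataset the
# pipeline consumes (choice tables, search tables, AU frame series, ratings)
# can be simulated under the study's design (6 faces, 30 exposures, 15
# pairings x 8, 252 search trials, 5-minute interactions at 15 fps) so that
# each analysis stage is testable by parameter recovery. All generators are
# reproducible given (parameters, seed); per-unit child seeds make subsets
# reproducible on their own.

#' Default attentional-capture RT shifts per search condition
#'
#' Seconds added to a participant's baseline RT when the given distractor
#' condition is present. Defaults reflect the magnitude ordering genuine >
#' polite > neutral, with a monetary-value effect only among neutral faces
#' and a genuine-vs-neutral composite of 0.125 s.
#'
#' @return Named numeric vector over [search_conditions()].
#' @export
default_capture_shifts <- function() {
  c(genuine_hi = 0.160, genuine_lo = 0.150,
    polite_hi = 0.123, polite_lo = 0.115,
    neutral_hi = 0.060, neutral_lo = 0.000,
    all_novel = -0.050)
}

#' Generate ground-truth participant parameters
#'
#' Draws per-participant utility weights from the population spread reported
#' for this task (money mean .665, SD 1.095; genuine smiles mean 1.042,
#' SD 1.565), baseline search RTs, per-condition capture shifts and error
#' rates. Genuine-smile capture shifts are weakly coupled to genuine-smile
#' utility (`capture_coupling`), emulating value-driven capture.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param beta_means,beta_sds Population means/SDs for
#'   `(beta0, beta_money, beta_genuine, beta_polite)`.
#' @param rt_baseline_mean,rt_baseline_sd Baseline search RT (seconds).
#' @param capture_shifts Named shift vector, see [default_capture_shifts()].
#' @param capture_coupling Seconds of extra genuine-condition shift per SD of
#'   genuine-smile utility (default 0.03).
#' @param error_rate Search error probability (default 0.03).
#' @return Data.frame with one row per participant (columns `participant_id`,
#'   `beta0`, `beta_money`, `beta_genuine`, `beta_polite`, `rt_baseline`,
#'   `error_rate`, `seed` and one `shift_<condition>` column per condition).
#' @export
true_participants <- function(n, seed = 1L,
                              beta_means = c(0, 0.665, 1.042, 0.3),
                              beta_sds = c(0.3, 1.095, 1.565, 1.0),
                              rt_baseline_mean = 1.0, rt_baseline_sd = 0.15,
                              capture_shifts = default_capture_shifts(),
                              capture_coupling = 0.03,
                              error_rate = 0.03) {
  set.seed(child_seed(seed, 1L))
  b0 <- stats::rnorm(n, beta_means[1], beta_sds[1])
  bm <- stats::rnorm(n, beta_means[2], beta_sds[2])
  bg <- stats::rnorm(n, beta_means[3], beta_sds[3])
  bp <- stats::rnorm(n, beta_means[4], beta_sds[4])
  rt0 <- pmax(0.4, stats::rnorm(n, rt_baseline_mean, rt_baseline_sd))
  g_z <- if (n > 1L && stats::sd(bg) > 0) as.numeric(scale(bg)) else rep(0, n)
  shifts <- matrix(rep(capture_shifts[search_conditions()], each = n),
                   nrow = n,
                   dimnames = list(NULL, paste0("shift_",
                                                search_conditions())))
  shifts[, "shift_genuine_hi"] <- shifts[, "shift_genuine_hi"] +
    capture_coupling * g_z
  shifts[, "shift_genuine_lo"] <- shifts[, "shift_genuine_lo"] +
    capture_coupling * g_z
  data.frame(participant_id = sprintf("p%03d", seq_len(n)),
             beta0 = b0, beta_money = bm, beta_genuine = bg, beta_polite = bp,
             rt_baseline = rt0, error_rate = error_rate,
             seed = vapply(seq_len(n), function(i) child_seed(seed, 1000L + i),
                           integer(1)),
             shifts, stringsAsFactors = FALSE)
}

#' Simulate test-phase choices for one participant
#'
#' Codes the schedule, computes `theta` from the participant's true weights,
#' and draws each left-face choice as Bernoulli(plogis(theta)). RTs are
#' lognormal and independent of the choice.
#'
#' @param participant One row of [true_participants()] (or any list with
#'   `participant_id`, `beta0`, `beta_money`, `beta_genuine`, `beta_polite`,
#'   `seed`).
#' @param schedule Test schedule from [build_test_schedule()].
#' @param contingencies Face contingency table.
#' @param rt_meanlog,rt_sdlog Lognormal RT parameters (default log(0.9),
#'   0.35).
#' @return Data.frame of choice trials with columns `participant_id`,
#'   `trial`, `left_face`, `right_face`, `x1`, `x2`, `x3`, `y`, `choice`,
#'   `rt`.
#' @export
simulate_choices <- function(participant, schedule,
                             contingencies = face_contingencies(),
                             rt_meanlog = log(0.9), rt_sdlog = 0.35) {
  coded <- code_trials(schedule, contingencies)
  theta <- participant$beta0 + participant$beta_money * coded$x1 +
    participant$beta_genuine * coded$x2 + participant$beta_polite * coded$x3
  set.seed(participant$seed)
  y <- stats::rbinom(nrow(coded), 1L, stats::plogis(theta))
  coded$participant_id <- participant$participant_id
  coded$y <- y
  coded$choice <- ifelse(y == 1L, "left", "right")
  coded$rt <- stats::rlnorm(nrow(coded), rt_meanlog, rt_sdlog)
  coded[, c("participant_id", "trial", "left_face", "right_face",
            "x1", "x2", "x3", "y", "choice", "rt")]
}

#' Simulate visual-search trials for one participant
#'
#' RT = baseline + condition shift + lognormal noise; errors are Bernoulli.
#' Optionally a stated fraction of trials is contaminated with out-of-bounds
#' RTs (below 0.25 s or above 10 s), for exercising the QC filters.
#'
#' @param participant One row of [true_participants()].
#' @param schedule Search schedule from [build_search_schedule()].
#' @param noise_meanlog,noise_sdlog Lognormal RT-noise parameters (default
#'   log(0.25), 0.5: right-skewed, mean about 0.28 s).
#' @param contamination_rate Fraction of trials given out-of-bounds RTs
#'   (default 0).
#' @return Data.frame with columns `participant_id`, `trial`, `condition`,
#'   `target_quadrant`, `rt`, `error`.
#' @export
simulate_search <- function(participant, schedule,
                            noise_meanlog = log(0.25), noise_sdlog = 0.5,
                            contamination_rate = 0) {
  check_columns(schedule, c("trial", "condition", "target_quadrant"),
                "schedule")
  n <- nrow(schedule)
  shift <- unlist(participant[paste0("shift_", schedule$condition)],
                  use.names = FALSE)
  set.seed(child_seed(participant$seed, 2L))
  rt <- participant$rt_baseline + shift + stats::rlnorm(n, noise_meanlog,
                                                        noise_sdlog)
  error <- stats::runif(n) < participant$error_rate
  if (contamination_rate > 0) {
    bad <- stats::runif(n) < contamination_rate
    rt[bad] <- ifelse(stats::runif(sum(bad)) < 0.5,
                      stats::runif(sum(bad), 0.01, 0.2),
                      stats::runif(sum(bad), 10.5, 20))
  }
  data.frame(participant_id = participant$participant_id,
             trial = schedule$trial, condition = schedule$condition,
             target_quadrant = schedule$target_quadrant,
             rt = rt, error = error, stringsAsFactors = FALSE)
}

#' Generate ground-truth dyad parameters
#'
#' Each dyad carries per-member smile rates, type-specific reciprocation
#' probabilities and lag distributions, and dyad-level actor/partner effects
#' of genuine reciprocity speed on the interaction-quality rating. Defaults
#' (documented in the vignette): 1.2 genuine and 0.8 polite smiles per
#' minute; reciprocation probabilities .72 (genuine) and .57 (polite); lag
#' means 14 frames (genuine) and 21 frames (polite), member lag means varying
#' across people.
#'
#' @param n Number of dyads.
#' @param seed Integer seed.
#' @param rate_genuine,rate_polite Spontaneous smile rates (events/minute).
#' @param recip_prob_genuine,recip_prob_polite Reciprocation probabilities.
#' @param lag_mean_genuine,lag_mean_polite Population mean lags (frames).
#' @param lag_between_sd Between-person SD of the member mean lag (frames).
#' @param lag_within_sd Within-person lag SD (frames).
#' @param actor_effect,partner_effect Standardized effects of own/partner
#'   genuine reciprocity speed on the latent interaction-quality rating.
#' @param rating_noise_sd SD of the latent rating residual.
#' @return Data.frame, one row per dyad, member-level columns suffixed
#'   `_1`/`_2`.
#' @export
true_dyads <- function(n, seed = 1L,
                       rate_genuine = 1.2, rate_polite = 0.8,
                       recip_prob_genuine = 0.72, recip_prob_polite = 0.57,
                       lag_mean_genuine = 14, lag_mean_polite = 21,
                       lag_between_sd = 3, lag_within_sd = 5,
                       actor_effect = -0.08, partner_effect = -0.20,
                       rating_noise_sd = NULL) {
  set.seed(child_seed(seed, 3L))
  if (is.null(rating_noise_sd)) {
    rating_noise_sd <- sqrt(max(0.1, 1 - actor_effect^2 - partner_effect^2))
  }
  member_lag <- function(mu) {
    matrix(rtruncnorm(2L * n, mu, lag_between_sd, 2, 55), ncol = 2L)
  }
  lg <- member_lag(lag_mean_genuine)
  lp <- member_lag(lag_mean_polite)
  data.frame(
    dyad_id = sprintf("d%03d", seq_len(n)),
    rate_genuine = rate_genuine, rate_polite = rate_polite,
    recip_prob_genuine = recip_prob_genuine,
    recip_prob_polite = recip_prob_polite,
    lag_genuine_1 = lg[, 1], lag_genuine_2 = lg[, 2],
    lag_polite_1 = lp[, 1], lag_polite_2 = lp[, 2],
    lag_within_sd = lag_within_sd,
    actor_effect = actor_effect, partner_effect = partner_effect,
    rating_noise_sd = rating_noise_sd,
    seed = vapply(seq_len(n), function(i) child_seed(seed, 2000L + i),
                  integer(1)),
    stringsAsFactors = FALSE)
}

#' Simulate one dyad's AU frame series
#'
#' Spontaneous smile episodes are placed by a Poisson process per member and
#' type; each spontaneous episode is reciprocated by the partner (same type)
#' with the dyad's type-specific probability, at a lag drawn from a truncated
#' normal on `[1, 60]` frames (lag 0 is never generated, so the initiator is
#' always well defined). Episode durations are uniform on 8-45 frames;
#' overlapping same-member episodes are merged, the merge being genuine if
#' any constituent was. AU12 is active during any smile and AU06 additionally
#' during genuine smiles.
#'
#' @param dyad One row of [true_dyads()].
#' @param duration_frames Session length (default 4500 frames = 5 minutes at
#'   15 fps).
#' @param activation Activation level written into active AU frames
#'   (default 0.9).
#' @return List with `au` (list of two AU series data.frames: `frame_index`,
#'   `au06`, `au12`), `truth` (data.frame of generated initiations:
#'   `member`, `onset`, `type`, `reciprocated`, `lag`) and `dyad_id`.
#' @export
simulate_dyad <- function(dyad, duration_frames = 4500L, activation = 0.9) {
  stopifnot(duration_frames > 0L)
  set.seed(dyad$seed)
  minutes <- duration_frames / (au_fps() * 60)
  lag_sd <- dyad$lag_within_sd

  spont <- list()
  for (m in 1:2) {
    for (ty in c("genuine", "polite")) {
      rate <- dyad[[paste0("rate_", ty)]]
      k <- stats::rpois(1L, rate * minutes)
      if (k > 0L) {
        spont[[length(spont) + 1L]] <- data.frame(
          member = m, onset = sort(sample.int(duration_frames, k) - 1L),
          type = ty, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(spont) == 0L) {
    empty_series <- data.frame(frame_index = 0:(duration_frames - 1L),
                               au06 = 0, au12 = 0)
    return(list(au = list(empty_series, empty_series),
                truth = data.frame(member = integer(), onset = integer(),
                                   type = character(),
                                   reciprocated = logical(), lag = integer(),
                                   stringsAsFactors = FALSE),
                dyad_id = dyad$dyad_id))
  }
  truth <- do.call(rbind, spont)
  truth <- truth[order(truth$onset), , drop = FALSE]
  n_init <- nrow(truth)
  durations <- function(k) sample(8:45, k, replace = TRUE)
  truth$duration <- durations(n_init)
  truth$reciprocated <- FALSE
  truth$lag <- NA_integer_

  responses <- list()
  for (i in seq_len(n_init)) {
    ty <- truth$type[i]
    responder <- 3L - truth$member[i]
    if (stats::runif(1L) < dyad[[paste0("recip_prob_", ty)]]) {
      mu <- dyad[[paste0("lag_", ty, "_", responder)]]
      lag <- round(rtruncnorm(1L, mu, lag_sd, 0.5, 60.49))
      lag <- max(1L, min(60L, as.integer(lag)))
      onset <- truth$onset[i] + lag
      if (onset < duration_frames) {
        truth$reciprocated[i] <- TRUE
        truth$lag[i] <- lag
        responses[[length(responses) + 1L]] <- data.frame(
          member = responder, onset = onset, type = ty,
          duration = durations(1L), stringsAsFactors = FALSE)
      }
    }
  }
  episodes <- rbind(truth[, c("member", "onset", "type", "duration")],
                    if (length(responses)) do.call(rbind, responses))

  series <- lapply(1:2, function(m) {
    au06 <- numeric(duration_frames)
    au12 <- numeric(duration_frames)
    ep <- episodes[episodes$member == m, , drop = FALSE]
    for (j in seq_len(nrow(ep))) {
      idx <- (ep$onset[j] + 1L):min(duration_frames, ep$onset[j] + ep$duration[j])
      au12[idx] <- activation
      if (ep$type[j] == "genuine") au06[idx] <- activation
    }
    data.frame(frame_index = 0:(duration_frames - 1L), au06 = au06,
               au12 = au12)
  })
  list(au = series,
       truth = truth[, c("member", "onset", "type", "reciprocated", "lag")],
       dyad_id = dyad$dyad_id)
}

#' Simulate 9-item interaction-quality ratings for a set of dyads
#'
#' Each member's latent rating is
#' `intercept + actor_effect * own_speed_z + partner_effect * partner_speed_z
#' + noise`; the latent value is expressed through nine items (per-item
#' loading 1 plus item noise), thresholded onto the 1-7 Likert scale, with
#' items 2 and 7 stored reverse-keyed.
#'
#' @param dyads [true_dyads()] table (uses `actor_effect`, `partner_effect`,
#'   `rating_noise_sd`, `seed`).
#' @param speed_1,speed_2 Genuine reciprocity speed (any unit) for members 1
#'   and 2 of each dyad; z-scored internally across all members.
#' @param intercept Latent intercept on the 1-7 scale (default 5).
#' @param item_noise_sd SD of per-item noise (default 0.8, chosen so the
#'   9-item scale shows internal consistency near the alpha = .93 reported
#'   for the instrument).
#' @param reverse_keyed Indices of reverse-keyed items (default 2 and 7).
#' @return Data.frame with columns `dyad_id`, `member` and `item1`-`item9`
#'   (as stored, i.e. reverse-keyed items still flipped).
#' @export
simulate_ratings <- function(dyads, speed_1, speed_2, intercept = 5,
                             item_noise_sd = 0.8, reverse_keyed = c(2L, 7L)) {
  n <- nrow(dyads)
  stopifnot(length(speed_1) == n, length(speed_2) == n)
  z <- scale(c(speed_1, speed_2))
  z1 <- z[seq_len(n)]; z2 <- z[n + seq_len(n)]
  set.seed(child_seed(dyads$seed[1], 4L))
  noise <- matrix(stats::rnorm(2L * n, 0, dyads$rating_noise_sd), ncol = 2L)
  latent1 <- intercept + dyads$actor_effect * z1 +
    dyads$partner_effect * z2 + noise[, 1]
  latent2 <- intercept + dyads$actor_effect * z2 +
    dyads$partner_effect * z1 + noise[, 2]
  latent <- c(rbind(latent1, latent2))
  k <- 9L
  items <- matrix(latent, nrow = 2L * n, ncol = k) +
    matrix(stats::rnorm(2L * n * k, 0, item_noise_sd), ncol = k)
  items <- pmin(pmax(round(items), 1L), 7L)
  items[, reverse_keyed] <- 8L - items[, reverse_keyed]
  out <- data.frame(dyad_id = rep(dyads$dyad_id, each = 2L),
                    member = rep(1:2, times = n), stringsAsFactors = FALSE)
  colnames(items) <- paste0("item", seq_len(k))
  cbind(out, as.data.frame(items))
}

#' Simulate a full cohort for the end-to-end pipeline
#'
#' Generates participants, their choice and search tables, pairs them into
#' dyads, simulates the dyads' AU series and post-interaction ratings.
#' Member genuine-smile lag means are coupled to genuine-smile utility
#' (`speed_coupling` frames per SD of utility), emulating the link between
#' lab-measured value and naturalistic responsiveness.
#'
#' @param n_dyads Number of dyads (2 participants each).
#' @param seed Integer seed.
#' @param speed_coupling Frames of faster genuine reciprocity per SD of
#'   genuine-smile utility (default 2).
#' @param duration_frames Interaction length in frames.
#' @param ... Passed to [true_participants()].
#' @return List with `participants`, `dyads` (truth tables), `choices`,
#'   `search`, `au` (list per dyad), `reciprocity_truth`, `ratings`.
#' @export
simulate_cohort <- function(n_dyads = 20L, seed = 1L, speed_coupling = 2,
                            duration_frames = 4500L, ...) {
  n <- 2L * n_dyads
  participants <- true_participants(n, seed = seed, ...)
  contingencies <- face_contingencies()
  test_sched <- build_test_schedule(contingencies, seed = seed)
  search_sched <- build_search_schedule(seed = seed)
  choices <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_choices(participants[i, ], test_sched, contingencies)
  }))
  search <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_search(participants[i, ], search_sched)
  }))
  dyads <- true_dyads(n_dyads, seed = seed)
  g_z <- as.numeric(scale(participants$beta_genuine))
  dyads$lag_genuine_1 <- pmax(2, dyads$lag_genuine_1 -
                                speed_coupling * g_z[seq(1L, n, by = 2L)])
  dyads$lag_genuine_2 <- pmax(2, dyads$lag_genuine_2 -
                                speed_coupling * g_z[seq(2L, n, by = 2L)])
  sims <- lapply(seq_len(n_dyads), function(i) {
    simulate_dyad(dyads[i, ], duration_frames = duration_frames)
  })
  truth <- do.call(rbind, lapply(seq_len(n_dyads), function(i) {
    tr <- sims[[i]]$truth
    if (nrow(tr) == 0L) return(NULL)
    tr$dyad_id <- dyads$dyad_id[i]
    tr
  }))
  # member mean genuine reciprocation speed (frames) from the truth log
  speed <- function(i, m) {
    tr <- sims[[i]]$truth
    lags <- tr$lag[tr$member == (3L - m) & tr$type == "genuine" &
                     tr$reciprocated]
    if (length(lags) == 0L) NA_real_ else mean(lags)
  }
  sp1 <- vapply(seq_len(n_dyads), speed, numeric(1), m = 1L)
  sp2 <- vapply(seq_len(n_dyads), speed, numeric(1), m = 2L)
  ratings <- simulate_ratings(dyads, sp1, sp2)
  list(participants = participants, dyads = dyads, choices = choices,
       search = search, au = lapply(sims, `[[`, "au"),
       reciprocity_truth = truth, ratings = ratings,
       true_speed = data.frame(dyad_id = dyads$dyad_id, speed_1 = sp1,
                               speed_2 = sp2, stringsAsFactors = FALSE))
}

#' Simulate a cohort with injected data-quality violators
#'
#' Builds choice and search tables for a cohort in which stated numbers of
#' participants violate each preregistered exclusion rule, for validating the
#' QC filters against known truth.
#'
#' @param n_clean Participants with clean data.
#' @param n_invariant Participants pressing the same button on >75% of
#'   valuation trials.
#' @param n_fast Participants with >20% out-of-bounds valuation RTs.
#' @param n_search_err Participants with >20% search errors.
#' @param n_mixed Participants violating both the invariant and fast rules.
#' @param seed Integer seed.
#' @return List with `choices`, `search` and `truth` (participant_id,
#'   category).
#' @export
simulate_contaminated_cohort <- function(n_clean = 20L, n_invariant = 10L,
                                         n_fast = 12L, n_search_err = 0L,
                                         n_mixed = 11L, seed = 1L) {
  n <- n_clean + n_invariant + n_fast + n_search_err + n_mixed
  participants <- true_participants(n, seed = seed)
  category <- rep(c("clean", "invariant", "fast", "search_err", "mixed"),
                  times = c(n_clean, n_invariant, n_fast, n_search_err,
                            n_mixed))
  contingencies <- face_contingencies()
  test_sched <- build_test_schedule(contingencies, seed = seed)
  search_sched <- build_search_schedule(seed = seed)
  choices <- list(); search <- list()
  for (i in seq_len(n)) {
    ch <- simulate_choices(participants[i, ], test_sched, contingencies)
    se <- simulate_search(participants[i, ], search_sched)
    set.seed(child_seed(participants$seed[i], 5L))
    if (category[i] %in% c("invariant", "mixed")) {
      ch$choice <- "left"   # 100% same button > 75%
      ch$y <- 1L
    }
    if (category[i] %in% c("fast", "mixed")) {
      k <- ceiling(0.25 * nrow(ch))  # 25% of trials out of bounds
      idx <- sample.int(nrow(ch), k)
      ch$rt[idx] <- stats::runif(k, 0.05, 0.2)
    }
    if (category[i] == "search_err") {
      k <- ceiling(0.25 * nrow(se))
      se$error[sample.int(nrow(se), k)] <- TRUE
    }
    choices[[i]] <- ch
    search[[i]] <- se
  }
  list(choices = do.call(rbind, choices), search = do.call(rbind, search),
       truth = data.frame(participant_id = participants$participant_id,
                          category = category, stringsAsFactors = FALSE))
}

#' Simulate dyad-level APIM data directly
#'
#' Generates predictor z-scores with within-dyad correlation `rho_x`, latent
#' outcomes from stated standardized actor/partner effects, and observed
#' ratings through the 9-item Likert instrument. Used for APIM parameter
#' recovery and bootstrap-coverage checks.
#'
#' @param n_dyads Number of dyads.
#' @param actor,partner Standardized actor and partner effects.
#' @param rho_x Within-dyad predictor correlation (default 0.2).
#' @param rho_e Within-dyad residual correlation (default 0.3).
#' @param seed Integer seed.
#' @param item_noise_sd Per-item noise SD, see [simulate_ratings()].
#' @param intercept Latent intercept; the default 4 (scale midpoint) keeps
#'   the latent distribution clear of the 1 and 7 Likert floors/ceilings so
#'   the standardized paths are not attenuated by censoring.
#' @return Data.frame `dyad_id`, `x_1`, `x_2`, `y_1`, `y_2` plus the latent
#'   truth columns `latent_1`, `latent_2`.
#' @export
simulate_apim_dyads <- function(n_dyads, actor = 0, partner = -0.2,
                                rho_x = 0.2, rho_e = 0.3, seed = 1L,
                                item_noise_sd = 0.8, intercept = 4) {
  set.seed(child_seed(seed, 6L))
  n <- n_dyads
  # correlated predictor pair
  u <- stats::rnorm(n); v1 <- stats::rnorm(n); v2 <- stats::rnorm(n)
  x1 <- sqrt(rho_x) * u + sqrt(1 - rho_x) * v1
  x2 <- sqrt(rho_x) * u + sqrt(1 - rho_x) * v2
  s2e <- max(0.05, 1 - actor^2 - partner^2 - 2 * actor * partner * rho_x)
  w <- stats::rnorm(n); e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  eps1 <- sqrt(s2e) * (sqrt(rho_e) * w + sqrt(1 - rho_e) * e1)
  eps2 <- sqrt(s2e) * (sqrt(rho_e) * w + sqrt(1 - rho_e) * e2)
  latent1 <- intercept + actor * x1 + partner * x2 + eps1
  latent2 <- intercept + actor * x2 + partner * x1 + eps2
  # express through the 9-item instrument
  k <- 9L
  score_member <- function(latent) {
    items <- matrix(latent, nrow = n, ncol = k) +
      matrix(stats::rnorm(n * k, 0, item_noise_sd), ncol = k)
    items <- pmin(pmax(round(items), 1L), 7L)
    rowMeans(items)
  }
  y1 <- score_member(latent1)
  y2 <- score_member(latent2)
  data.frame(dyad_id = sprintf("d%04d", seq_len(n)),
             x_1 = x1, x_2 = x2, y_1 = y1, y_2 = y2,
             latent_1 = latent1, latent_2 = latent2,
             stringsAsFactors = FALSE)
}

#' Join pipeline reciprocity matches to a dyad's ground-truth log
#'
#' Runs the full detection pipeline (classify, detect, match) on a simulated
#' dyad and aligns the resulting matches with the generator's truth log of
#' spontaneous initiations, for parameter-recovery checks. Truth initiations
#' absorbed into a merged episode (whose detected onset or type differs) are
#' marked undetected and excluded from recovery proportions.
#'
#' @param sim Output of [simulate_dyad()].
#' @param window_frames,threshold Passed to the detection pipeline.
#' @return Data.frame, one row per truth initiation: `member`, `onset`,
#'   `type`, `truth_reciprocated`, `truth_lag`, `detected`,
#'   `pipeline_reciprocated`, `pipeline_lag`.
#' @export
reciprocity_recovery <- function(sim, window_frames = 60L, threshold = 0) {
  rec <- dyad_reciprocity(sim$au[[1]], sim$au[[2]],
                          member_ids = c("1", "2"), threshold = threshold,
                          window_frames = window_frames)
  tr <- sim$truth
  if (nrow(tr) == 0L) {
    return(cbind(tr, detected = logical(), pipeline_reciprocated = logical(),
                 pipeline_lag = numeric()))
  }
  ev <- rec$events
  mt <- rec$matches
  detected <- logical(nrow(tr))
  p_rec <- logical(nrow(tr))
  p_lag <- rep(NA_real_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    m_id <- as.character(tr$member[i])
    hit <- ev$member_id == m_id & ev$onset_frame == tr$onset[i] &
      ev$type == tr$type[i]
    if (!any(hit)) next
    detected[i] <- TRUE
    mm <- mt$initiator_member == m_id & mt$initiator_onset == tr$onset[i] &
      mt$type == tr$type[i]
    if (any(mm)) {
      p_rec[i] <- TRUE
      p_lag[i] <- mt$lag_frames[which(mm)[1L]]
    }
  }
  data.frame(member = tr$member, onset = tr$onset, type = tr$type,
             truth_reciprocated = tr$reciprocated, truth_lag = tr$lag,
             detected = detected, pipeline_reciprocated = p_rec,
             pipeline_lag = p_lag, stringsAsFactors = FALSE)
}
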