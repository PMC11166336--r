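test_that("frame classification follows the AU06/AU12 rule", {
  s <- data.frame(frame_index = 0:3,
                  au06 = c(0.7, 0.0, 0.9, 0.0),
                  au12 = c(0.8, 0.8, 0.0, 0.0))
  expect_equal(classify_frames(s, threshold = 0.1),
               c("genuine", "polite", "none", "none"))
  # threshold is strict: activation equal to tau does not count as active
  s2 <- data.frame(frame_index = 0:0, au06 = 0.1, au12 = 0.8)
  expect_equal(classify_frames(s2, threshold = 0.1), "polite")
  bad <- data.frame(frame_index = 0:1, au06 = c(0, 1.2), au12 = c(0, 0))
  expect_error(classify_frames(bad), "\\[0, 1\\]")
  unsorted <- data.frame(frame_index = c(1, 0), au06 = 0, au12 = 0)
  expect_error(classify_frames(unsorted), "increasing")
})

test_that("event detection finds maximal runs, genuine dominating", {
  labels <- c("none", "polite", "polite", "none")
  ev <- detect_events(labels)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_frame, 1L)
  expect_equal(ev$offset_frame, 2L)
  expect_equal(ev$type, "polite")
  # polite -> genuine -> polite run is one genuine event by default
  run <- c("polite", "genuine", "polite")
  ev2 <- detect_events(run)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$type, "genuine")
  # the alternative splits at type changes
  ev3 <- detect_events(run, split_on_type_change = TRUE)
  expect_equal(nrow(ev3), 3L)
  expect_equal(ev3$type, c("polite", "genuine", "polite"))
  # empty input, minimum duration filter
  expect_equal(nrow(detect_events(character(0))), 0L)
  expect_equal(nrow(detect_events(c("polite", "none"), min_duration = 2L)),
               0L)
})

test_that("matcher reproduces the worked lag example and the window bound", {
  a <- data.frame(member_id = "m1", onset_frame = 30L, offset_frame = 40L,
                  type = "genuine")
  b <- data.frame(member_id = "m2", onset_frame = 42L, offset_frame = 50L,
                  type = "genuine")
  m <- match_reciprocity(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$lag_frames, 12L)
  # onset 95: lag 65 exceeds the 60-frame window -> unmatched
  b2 <- transform(b, onset_frame = 95L)
  expect_equal(nrow(match_reciprocity(a, b2)), 0L)
  # exactly 60 frames is inside the window (inclusive upper bound)
  b3 <- transform(b, onset_frame = 90L)
  expect_equal(match_reciprocity(a, b3)$lag_frames, 60L)
  # same-frame onsets are never reciprocation
  b4 <- transform(b, onset_frame = 30L)
  expect_equal(nrow(match_reciprocity(a, b4)), 0L)
  # wrong type is not matched
  b5 <- transform(b, type = "polite")
  expect_equal(nrow(match_reciprocity(a, b5)), 0L)
})

test_that("matching equals the independent rule-application oracle on random sets", {
  set.seed(14)
  for (rep in 1:40) {
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    on_a <- sort(sample(0:300, na))
    on_b <- sort(sample(0:300, nb))
    ty_a <- sample(c("genuine", "polite"), na, replace = TRUE)
    ty_b <- sample(c("genuine", "polite"), nb, replace = TRUE)
    ev_a <- data.frame(member_id = rep("A", na), onset_frame = on_a,
                       offset_frame = on_a, type = ty_a,
                       stringsAsFactors = FALSE)
    ev_b <- data.frame(member_id = rep("B", nb), onset_frame = on_b,
                       offset_frame = on_b, type = ty_b,
                       stringsAsFactors = FALSE)
    got <- match_reciprocity(ev_a, ev_b)
    want <- oracle_match(on_a, ty_a, on_b, ty_b)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0L) {
      expect_equal(got$initiator_onset, want$init_on)
      expect_equal(got$lag_frames, want$lag)
    }
    # role symmetry: swapping members preserves the total match count
    swapped <- match_reciprocity(ev_b, ev_a)
    expect_equal(nrow(swapped), nrow(got))
  }
})

test_that("summaries report proportions and ms lags on a constructed dyad", {
  # episodes spaced > window apart so no cross-chains form
  s_a <- make_au_series(c(30, 200, 370), rep("genuine", 3), n_frames = 500)
  s_b <- make_au_series(c(42, 212, 382), rep("genuine", 3), n_frames = 500)
  rec <- dyad_reciprocity(s_a, s_b, member_ids = c("A", "B"))
  expect_equal(nrow(rec$matches), 3L)
  expect_true(all(rec$matches$lag_frames == 12L))
  s <- summarize_reciprocity(rec$matches, rec$events)
  b_gen <- s[s$member_id == "B" & s$type == "genuine", ]
  expect_equal(b_gen$proportion, 1.0)
  expect_equal(b_gen$mean_lag_frames, 12)
  expect_equal(b_gen$mean_lag_ms, 800, tolerance = 1e-10)
  expect_true(is.na(s$proportion[s$member_id == "B" & s$type == "polite"]))
})

test_that("dyad simulation round-trips through the pipeline against its truth log", {
  # deterministic reciprocation at fixed lag, sparse smiles
  td <- true_dyads(1, seed = 8, recip_prob_genuine = 1, recip_prob_polite = 0,
                   rate_genuine = 0.8, rate_polite = 0,
                   lag_mean_genuine = 12, lag_between_sd = 1e-6,
                   lag_within_sd = 1e-6)
  td$lag_genuine_1 <- 12; td$lag_genuine_2 <- 12
  sim <- simulate_dyad(td[1, ])
  rec <- reciprocity_recovery(sim)
  det <- rec[rec$detected, ]
  expect_gt(nrow(det), 0L)
  expect_true(all(det$pipeline_reciprocated))
  expect_true(all(det$pipeline_lag == 12L))
  # zero smile rate -> empty truth and all-inactive AU series
  td0 <- true_dyads(1, seed = 9, rate_genuine = 0, rate_polite = 0)
  sim0 <- simulate_dyad(td0[1, ])
  expect_equal(nrow(sim0$truth), 0L)
  expect_true(all(sim0$au[[1]]$au12 == 0))
  # genuine-only dyad -> no polite events detected
  tdg <- true_dyads(1, seed = 10, rate_polite = 0, recip_prob_polite = 0)
  simg <- simulate_dyad(tdg[1, ])
  recg <- dyad_reciprocity(simg$au[[1]], simg$au[[2]])
  expect_true(all(recg$events$type == "genuine"))
})

test_that("group comparison finds faster, more frequent genuine reciprocity", {
  td <- true_dyads(30, seed = 12)
  per <- list()
  for (i in 1:30) {
    sim <- simulate_dyad(td[i, ])
    rec <- dyad_reciprocity(sim$au[[1]], sim$au[[2]],
                            member_ids = paste0("d", i, "_m", 1:2))
    if (nrow(rec$events) == 0L) next
    per[[length(per) + 1L]] <- summarize_reciprocity(rec$matches, rec$events)
  }
  per <- do.call(rbind, per)
  tests <- reciprocity_group_tests(per)
  expect_gt(tests$proportion$mean_diff, 0)     # genuine reciprocated more
  expect_lt(tests$speed_ms$mean_diff, 0)       # and faster
  expect_lt(tests$speed_ms$p_value, 0.01)
})
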