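# Smile classification from facial action units and windowed reciprocity
# matching. A frame shows a genuine (Duchenne) smile when both the lip-corner
# puller (AU12, zygomaticus major) and the cheek raiser (AU06, orbicularis
# oculi) are active, and a polite smile when AU12 is active without AU06.
# Partners' series share a common 15 fps frame clock; a smile counts as
# reciprocated when the partner produces a same-type smile onset within a
# 4-second (60-frame) window of the initiating onset.

#' Classify frames into smile types
#'
#' @param series Data.frame with columns `frame_index`, `au06`, `au12`
#'   (activations in `[0, 1]`).
#' @param threshold Activation threshold above which an AU counts as active
#'   (default 0: any positive activation).
#' @return Character vector (one label per frame) in
#'   `{"genuine", "polite", "none"}`.
#' @export
classify_frames <- function(series, threshold = 0) {
  check_columns(series, c("frame_index", "au06", "au12"), "series")
  if (is.unsorted(series$frame_index, strictly = TRUE)) {
    abort("frame_index must be strictly increasing")
  }
  if (any(series$au06 < 0 | series$au06 > 1 | series$au12 < 0 |
            series$au12 > 1, na.rm = TRUE)) {
    abort("AU activations must lie in [0, 1]")
  }
  au12_on <- series$au12 > threshold
  au06_on <- series$au06 > threshold
  ifelse(au12_on & au06_on, "genuine",
         ifelse(au12_on, "polite", "none"))
}

#' Detect smile events from frame labels
#'
#' Maximal runs of smiling frames become events; a run containing any genuine
#' frame is one genuine event (set `split_on_type_change = TRUE` to instead
#' split a run at every type change). The onset is the first smiling frame of
#' the run.
#'
#' @param labels Character vector from [classify_frames()].
#' @param frame_index Frame indices matching `labels` (default `0:(n-1)`).
#' @param member_id Identifier attached to the events.
#' @param min_duration Minimum event length in frames (default 1: no
#'   debouncing).
#' @param split_on_type_change Split runs at genuine/polite transitions.
#' @return Data.frame with columns `member_id`, `onset_frame`, `offset_frame`,
#'   `type`.
#' @export
detect_events <- function(labels, frame_index = seq_along(labels) - 1L,
                          member_id = "m1", min_duration = 1L,
                          split_on_type_change = FALSE) {
  if (length(labels) == 0L) {
    return(data.frame(member_id = character(), onset_frame = integer(),
                      offset_frame = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(length(frame_index) == length(labels))
  smiling <- labels != "none"
  key <- if (split_on_type_change) labels else ifelse(smiling, "smile", "none")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none" & r$lengths >= min_duration
  if (!any(keep)) {
    return(data.frame(member_id = character(), onset_frame = integer(),
                      offset_frame = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- starts[keep]; ends <- ends[keep]
  type <- vapply(seq_along(starts), function(i) {
    if (any(labels[starts[i]:ends[i]] == "genuine")) "genuine" else "polite"
  }, character(1))
  data.frame(member_id = member_id,
             onset_frame = frame_index[starts],
             offset_frame = frame_index[ends],
             type = type, stringsAsFactors = FALSE)
}

#' Match reciprocated smiles between two partners
#'
#' Every smile event of either member is scanned as a potential initiation.
#' An initiation is reciprocated if the partner has a same-type event with
#' onset strictly after the initiating onset and no more than `window_frames`
#' later (same-frame onsets never count: a responder cannot react in zero
#' frames). Each responder event answers at most one initiation; when several
#' initiations compete, the earliest unmatched initiation wins, and each
#' initiation takes the earliest available responder event. The lag is the
#' responder onset minus the initiator onset, in frames.
#'
#' @param events_a,events_b Event tables from [detect_events()] for the two
#'   members, each sorted by onset.
#' @param window_frames Reciprocity window (default 60 frames = 4 s at
#'   15 fps).
#' @return Data.frame of matches: `initiator_member`, `responder_member`,
#'   `initiator_onset`, `responder_onset`, `type`, `lag_frames`.
#' @export
match_reciprocity <- function(events_a, events_b, window_frames = 60L) {
  for (ev in list(events_a, events_b)) {
    check_columns(ev, c("member_id", "onset_frame", "type"), "events")
    if (is.unsorted(ev$onset_frame)) abort("events must be sorted by onset")
  }
  empty <- data.frame(initiator_member = character(),
                      responder_member = character(),
                      initiator_onset = integer(), responder_onset = integer(),
                      type = character(), lag_frames = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(events_a) == 0L || nrow(events_b) == 0L) return(empty)
  a_id <- events_a$member_id[1]
  b_id <- events_b$member_id[1]
  all_ev <- rbind(
    data.frame(member = "a", onset = events_a$onset_frame,
               type = events_a$type, stringsAsFactors = FALSE),
    data.frame(member = "b", onset = events_b$onset_frame,
               type = events_b$type, stringsAsFactors = FALSE)
  )
  all_ev <- all_ev[order(all_ev$onset, all_ev$member), , drop = FALSE]
  used_a <- rep(FALSE, nrow(events_a))  # used as responder
  used_b <- rep(FALSE, nrow(events_b))
  out <- list()
  for (i in seq_len(nrow(all_ev))) {
    init <- all_ev[i, ]
    if (init$member == "a") {
      cand_tab <- events_b; used <- used_b
    } else {
      cand_tab <- events_a; used <- used_a
    }
    cand <- which(!used &
                    cand_tab$type == init$type &
                    cand_tab$onset_frame > init$onset &
                    cand_tab$onset_frame <= init$onset + window_frames)
    if (length(cand) == 0L) next
    j <- cand[which.min(cand_tab$onset_frame[cand])]
    if (init$member == "a") used_b[j] <- TRUE else used_a[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      initiator_member = if (init$member == "a") a_id else b_id,
      responder_member = if (init$member == "a") b_id else a_id,
      initiator_onset = init$onset,
      responder_onset = cand_tab$onset_frame[j],
      type = init$type,
      lag_frames = cand_tab$onset_frame[j] - init$onset,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Detect both members' events and match reciprocity for one dyad
#'
#' Convenience wrapper: classify frames, detect events and match reciprocity
#' for a dyad given its two AU series.
#'
#' @param series_a,series_b AU frame series (`frame_index`, `au06`, `au12`)
#'   for the two members.
#' @param member_ids Character vector of length 2 with the member
#'   identifiers.
#' @param threshold AU activation threshold, see [classify_frames()].
#' @param window_frames Reciprocity window in frames.
#' @param ... Passed to [detect_events()].
#' @return List with `events` (both members) and `matches`.
#' @export
dyad_reciprocity <- function(series_a, series_b,
                             member_ids = c("m1", "m2"), threshold = 0,
                             window_frames = 60L, ...) {
  ev_a <- detect_events(classify_frames(series_a, threshold),
                        frame_index = series_a$frame_index,
                        member_id = member_ids[1], ...)
  ev_b <- detect_events(classify_frames(series_b, threshold),
                        frame_index = series_b$frame_index,
                        member_id = member_ids[2], ...)
  list(events = rbind(ev_a, ev_b),
       matches = match_reciprocity(ev_a, ev_b, window_frames))
}

#' Summarize reciprocity per member and smile type
#'
#' For each member and smile type: how many of the partner's smiles they
#' could have reciprocated (the partner's initiations), how many they did
#' reciprocate, the proportion, and the mean lag in frames and milliseconds
#' (one frame = 1000/15 ms).
#'
#' @param matches Match table from [match_reciprocity()].
#' @param events Combined event table for both members.
#' @return Data.frame with columns `member_id`, `type`, `n_partner_smiles`,
#'   `n_reciprocated`, `proportion`, `mean_lag_frames`, `mean_lag_ms`.
#' @export
summarize_reciprocity <- function(matches, events) {
  check_columns(events, c("member_id", "onset_frame", "type"), "events")
  members <- unique(events$member_id)
  if (length(members) != 2L) abort("events must contain exactly 2 members")
  rows <- list()
  for (m in members) {
    partner <- setdiff(members, m)
    for (ty in c("genuine", "polite")) {
      n_init <- sum(events$member_id == partner & events$type == ty)
      got <- matches[matches$responder_member == m & matches$type == ty, ,
                     drop = FALSE]
      n_rec <- nrow(got)
      prop <- if (n_init > 0L) n_rec / n_init else NA_real_
      mlf <- if (n_rec > 0L) mean(got$lag_frames) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        member_id = m, type = ty, n_partner_smiles = n_init,
        n_reciprocated = n_rec, proportion = prop,
        mean_lag_frames = mlf, mean_lag_ms = mlf * frame_duration_ms(),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group-level genuine vs polite reciprocity comparison
#'
#' Paired t-tests (with Cohen's d) comparing genuine against polite smiles
#' within participant, on the proportion reciprocated and on the reciprocity
#' speed. Participants missing either type are excluded from the relevant
#' contrast.
#'
#' @param per_member Data.frame stacking [summarize_reciprocity()] rows over
#'   dyads (columns `member_id`, `type`, `proportion`, `mean_lag_ms`).
#' @return List with `proportion` and `speed_ms` `test_summary` objects and
#'   the wide per-participant table `wide`.
#' @export
reciprocity_group_tests <- function(per_member) {
  check_columns(per_member, c("member_id", "type", "proportion",
                              "mean_lag_ms"), "per_member")
  g <- per_member[per_member$type == "genuine", ]
  p <- per_member[per_member$type == "polite", ]
  wide <- merge(g[, c("member_id", "proportion", "mean_lag_ms")],
                p[, c("member_id", "proportion", "mean_lag_ms")],
                by = "member_id", suffixes = c("_genuine", "_polite"))
  ok_p <- stats::complete.cases(wide$proportion_genuine,
                                wide$proportion_polite)
  ok_s <- stats::complete.cases(wide$mean_lag_ms_genuine,
                                wide$mean_lag_ms_polite)
  list(
    proportion = paired_t_cohens_d(wide$proportion_genuine[ok_p],
                                   wide$proportion_polite[ok_p]),
    speed_ms = paired_t_cohens_d(wide$mean_lag_ms_genuine[ok_s],
                                 wide$mean_lag_ms_polite[ok_s]),
    wide = wide
  )
}
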