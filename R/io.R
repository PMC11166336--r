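# Readers, writers and the end-to-end pipeline. CSV (UTF-8, header row,
# 0-based frame indices) is the interchange format for tabular data; reports
# are written as JSON.

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s (%s) is missing column(s): %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  df
}

#' Read a choice, search, AU-series or ratings table
#'
#' Each reader validates the column contract and fails with the offending
#' column named.
#'
#' @param path Path to a CSV file.
#' @return A data.frame.
#' @export
read_choices <- function(path) {
  read_table_checked(path, c("participant_id", "left_face", "right_face",
                             "y", "choice", "rt"), "choices table")
}

#' @rdname read_choices
#' @export
read_search <- function(path) {
  df <- read_table_checked(path, c("participant_id", "condition", "rt",
                                   "error"), "search table")
  df$error <- as.logical(df$error)
  df
}

#' @rdname read_choices
#' @export
read_au_series <- function(path) {
  df <- read_table_checked(path, c("frame_index", "au06", "au12"),
                           "AU series")
  if (is.unsorted(df$frame_index, strictly = TRUE)) {
    abort("AU series frame_index must be strictly increasing: ", path)
  }
  df
}

#' @rdname read_choices
#' @export
read_ratings <- function(path) {
  read_table_checked(path, c("dyad_id", "member", paste0("item", 1:9)),
                     "ratings table")
}

#' Write a data.frame as UTF-8 CSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort (or accepts one from [simulate_cohort()]), then runs
#' every stage: QC exclusions, per-participant utility estimation with group
#' tests and split-half reliability, capture scoring with the 2x3
#' repeated-measures ANOVA, dyadic reciprocity detection with group
#' comparisons, interaction-quality scoring with Cronbach's alpha, and the
#' APIM (primary predictor: genuine reciprocity speed; alternates: proportion
#' of genuine smiles reciprocated and polite reciprocity speed). Idempotent
#' for a fixed seed.
#'
#' @param n_dyads Number of dyads to simulate (ignored when `cohort` given).
#' @param seed Integer seed driving all randomness.
#' @param cohort Optional pre-built cohort from [simulate_cohort()].
#' @param n_boot Bootstrap resamples for the APIM.
#' @param out_dir Optional directory; when given, writes `report.json` plus
#'   the main CSV tables there.
#' @return A list report with elements `seed`, `qc`, `utilities`,
#'   `group_tests`, `reliability`, `capture`, `anova`, `reciprocity`,
#'   `alpha`, `apim`, `apim_alternates`, `correlations`.
#' @export
run_pipeline <- function(n_dyads = 40L, seed = 1L, cohort = NULL,
                         n_boot = 200L, out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(n_dyads = n_dyads,
                                                 seed = seed)
  # --- qc ---
  qc <- apply_exclusions(cohort$choices, cohort$search)
  keep <- qc$participant_id[qc$retained]
  choices <- cohort$choices[cohort$choices$participant_id %in% keep, ]
  search <- cohort$search[cohort$search$participant_id %in% keep, ]

  # --- valuation ---
  utilities <- fit_utilities_by_participant(choices)
  grp <- group_utility_tests(utilities, seed = child_seed(seed, 11L))
  reliability <- split_half_reliability(choices)

  # --- visual search ---
  capture <- centered_condition_means(search)
  anova <- rm_anova_2x3(capture)

  # --- reciprocity ---
  n_dy <- length(cohort$au)
  per_member <- list()
  for (i in seq_len(n_dy)) {
    ids <- paste0(cohort$dyads$dyad_id[i], "_m", 1:2)
    rec <- dyad_reciprocity(cohort$au[[i]][[1]], cohort$au[[i]][[2]],
                            member_ids = ids)
    if (nrow(rec$events) == 0L) next
    s <- summarize_reciprocity(rec$matches, rec$events)
    s$dyad_id <- cohort$dyads$dyad_id[i]
    s$member <- match(s$member_id, ids)
    per_member[[length(per_member) + 1L]] <- s
  }
  per_member <- do.call(rbind, per_member)
  rec_tests <- reciprocity_group_tests(per_member)

  # --- ratings / APIM ---
  scored <- score_interaction_quality(
    cohort$ratings[, paste0("item", 1:9)])
  ratings <- data.frame(dyad_id = cohort$ratings$dyad_id,
                        member = cohort$ratings$member,
                        rating = scored$ratings, stringsAsFactors = FALSE)
  wide_of <- function(df, col, ty) {
    d <- df[df$type == ty, c("dyad_id", "member", col)]
    stats::reshape(d, idvar = "dyad_id", timevar = "member",
                   direction = "wide", sep = "_")
  }
  sp_g <- wide_of(per_member, "mean_lag_frames", "genuine")
  names(sp_g) <- c("dyad_id", "x_1", "x_2")
  pr_g <- wide_of(per_member, "proportion", "genuine")
  names(pr_g) <- c("dyad_id", "prop_1", "prop_2")
  sp_p <- wide_of(per_member, "mean_lag_frames", "polite")
  names(sp_p) <- c("dyad_id", "polite_speed_1", "polite_speed_2")
  y_w <- stats::reshape(ratings, idvar = "dyad_id", timevar = "member",
                        direction = "wide", sep = "_")
  names(y_w) <- c("dyad_id", "y_1", "y_2")
  dyads <- Reduce(function(a, b) merge(a, b, by = "dyad_id"),
                  list(sp_g, pr_g, sp_p, y_w))
  apim <- fit_apim(dyads, n_boot = n_boot, seed = child_seed(seed, 12L))
  alternates <- fit_alternate_models(dyads, c("prop", "polite_speed"),
                                     n_boot = n_boot,
                                     seed = child_seed(seed, 13L))

  # --- cross-task correlations (lab value vs naturalistic behaviour) ---
  speed_by_participant <- data.frame(
    participant_id = cohort$participants$participant_id,
    speed = c(rbind(dyads$x_1[match(cohort$dyads$dyad_id, dyads$dyad_id)],
                    dyads$x_2[match(cohort$dyads$dyad_id, dyads$dyad_id)])),
    stringsAsFactors = FALSE)
  linked <- merge(merge(utilities, capture[, c("participant_id", "composite")],
                        by = "participant_id"),
                  speed_by_participant, by = "participant_id")
  corrs <- list(
    utility_vs_capture = correlations(linked$beta_genuine, linked$composite,
                                      method = "spearman",
                                      seed = child_seed(seed, 14L)),
    utility_vs_speed = if (sum(stats::complete.cases(linked$beta_genuine,
                                                     linked$speed)) >= 4L) {
      correlations(linked$beta_genuine, linked$speed, method = "pearson")
    } else NULL)

  report <- list(seed = seed, n_dyads = n_dy,
                 qc = qc, exclusion_counts = summarize_exclusions(qc),
                 utilities = utilities, group_tests = grp,
                 reliability = reliability, capture = capture,
                 anova = anova, reciprocity = per_member,
                 reciprocity_tests = rec_tests[c("proportion", "speed_ms")],
                 alpha = scored$alpha, apim = apim,
                 apim_alternates = alternates$table, correlations = corrs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(qc, file.path(out_dir, "exclusions.csv"))
    write_table(utilities, file.path(out_dir, "utilities.csv"))
    write_table(capture, file.path(out_dir, "capture.csv"))
    write_table(anova$anova, file.path(out_dir, "anova.csv"))
    write_table(per_member, file.path(out_dir, "reciprocity.csv"))
    jsonlite::write_json(
      list(seed = seed,
           exclusion_counts = as.list(summarize_exclusions(qc)),
           group_tests = grp, reliability = reliability,
           anova = anova$anova, alpha = scored$alpha,
           apim_paths = apim$paths, apim_fit = apim$fit,
           apim_alternates = alternates$table),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}
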