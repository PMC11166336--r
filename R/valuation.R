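# Choice-utility estimation: trial coding, the per-participant logistic choice
# model, group-level nonparametric tests and split-half reliability.
#
# The model: the probability of choosing the left face of a pair is
#   P(left) = exp(theta) / (1 + exp(theta)),
#   theta   = b0 + b_money * X1 + b_genuine * X2 + b_polite * X3,
# where X1 codes the expected-monetary-value difference (+.40 if the left face
# is the high-value player, -.40 if the right one is, 0 if tied), X2 codes
# genuine smiles (+1 left-only, -1 right-only, 0 if both or neither) and X3
# codes polite smiles the same way. The fitted weights are the participant's
# subjective utilities of money, genuine smiles and polite smiles.

#' Code a single test-phase pairing
#'
#' @param left_face,right_face One-row data.frames (or lists) carrying
#'   `face_id`, `social_type` and `ev` for the two paired faces.
#' @return Named numeric vector `c(x1, x2, x3)`. Swapping the two faces
#'   negates all three codes.
#' @examples
#' faces <- face_contingencies()
#' code_trial(faces[1, ], faces[6, ])  # high-EV genuine vs low-EV neutral
#' @export
code_trial <- function(left_face, right_face) {
  if (identical(left_face$face_id, right_face$face_id)) {
    abort("left and right face must differ")
  }
  c(x1 = 0.40 * sign(left_face$ev - right_face$ev),
    x2 = as.numeric(left_face$social_type == "genuine") -
         as.numeric(right_face$social_type == "genuine"),
    x3 = as.numeric(left_face$social_type == "polite") -
         as.numeric(right_face$social_type == "polite"))
}

#' Code a full test schedule
#'
#' Vectorized [code_trial()] over a schedule from [build_test_schedule()].
#'
#' @param schedule Data.frame with `left_face`, `right_face` columns.
#' @param contingencies Face contingency table.
#' @return `schedule` with added columns `x1`, `x2`, `x3`.
#' @export
code_trials <- function(schedule, contingencies = face_contingencies()) {
  check_columns(schedule, c("left_face", "right_face"), "schedule")
  il <- match(schedule$left_face, contingencies$face_id)
  ir <- match(schedule$right_face, contingencies$face_id)
  if (anyNA(il) || anyNA(ir)) abort("schedule contains unknown face_id values")
  if (any(il == ir)) abort("a trial pairs a face with itself")
  schedule$x1 <- 0.40 * sign(contingencies$ev[il] - contingencies$ev[ir])
  schedule$x2 <- as.numeric(contingencies$social_type[il] == "genuine") -
                 as.numeric(contingencies$social_type[ir] == "genuine")
  schedule$x3 <- as.numeric(contingencies$social_type[il] == "polite") -
                 as.numeric(contingencies$social_type[ir] == "polite")
  schedule
}

#' Fit per-participant reward utilities by penalized IRLS
#'
#' Maximum-likelihood fit of the four-term logistic choice model to one
#' participant's coded test trials, by iteratively re-weighted least squares.
#' A small ridge penalty (`lambda`) keeps estimates finite under complete or
#' quasi-complete separation, and estimates are capped at `cap` in absolute
#' value; a fit that hits the cap or fails to converge is flagged
#' `converged = FALSE`. A regressor that is constant across trials carries no
#' information and its weight is reported as `NA`.
#'
#' @param coded Data.frame with columns `x1`, `x2`, `x3` and `y` (1 = left
#'   face chosen).
#' @param lambda Ridge penalty (default 1e-4).
#' @param cap Absolute bound on estimates (default 10).
#' @param max_iter,tol IRLS iteration controls.
#' @return A list of class `utility_fit` with elements `beta0`, `beta_money`,
#'   `beta_genuine`, `beta_polite`, `converged`, `n_trials`, `log_lik`.
#' @export
fit_utilities <- function(coded, lambda = 1e-4, cap = 10,
                          max_iter = 100L, tol = 1e-10) {
  check_columns(coded, c("x1", "x2", "x3", "y"), "coded")
  y <- as.numeric(coded$y)
  if (!all(y %in% c(0, 1))) abort("y must be 0/1 (left face chosen)")
  X_full <- cbind(b0 = 1, x1 = coded$x1, x2 = coded$x2, x3 = coded$x3)
  keep <- c(TRUE, apply(X_full[, -1, drop = FALSE], 2, function(v) {
    stats::var(v) > 0
  }))
  X <- X_full[, keep, drop = FALSE]
  p <- ncol(X)
  n <- nrow(X)
  if (n < p) abort("need at least ", p, " trials to fit ", p, " terms")

  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta))) - lambda * sum(beta^2)
  }
  beta <- rep(0, p)
  ll <- pen_loglik(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - 2 * lambda * beta
    H <- crossprod(X * w, X) + diag(2 * lambda, p)
    step <- solve(H, grad)
    # step-halving with projection onto the cap box keeps the penalized
    # likelihood monotone even under separation
    alpha <- 1
    repeat {
      cand <- pmin(pmax(beta + alpha * step, -cap), cap)
      ll_new <- pen_loglik(cand)
      if (ll_new >= ll - 1e-12 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    ll <- ll_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  at_cap <- any(abs(beta) >= cap - 1e-8)
  out <- c(b0 = NA_real_, x1 = NA_real_, x2 = NA_real_, x3 = NA_real_)
  out[colnames(X)] <- beta
  structure(list(beta0 = unname(out["b0"]),
                 beta_money = unname(out["x1"]),
                 beta_genuine = unname(out["x2"]),
                 beta_polite = unname(out["x3"]),
                 converged = converged && !at_cap,
                 n_trials = n,
                 log_lik = ll + lambda * sum(beta^2)),
            class = "utility_fit")
}

#' @export
print.utility_fit <- function(x, ...) {
  cat("Logistic choice-utility fit (", x$n_trials, " trials, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(c(beta0 = x$beta0, beta_money = x$beta_money,
                beta_genuine = x$beta_genuine, beta_polite = x$beta_polite), 4))
  invisible(x)
}

#' Fit utilities for every participant in a choice table
#'
#' @param choices Data.frame with columns `participant_id`, `x1`, `x2`, `x3`,
#'   `y` (coded trials; see [code_trials()]), or raw `left_face`/`right_face`
#'   columns plus `contingencies` to code on the fly.
#' @param contingencies Face contingency table used when `choices` is uncoded.
#' @param ... Passed to [fit_utilities()].
#' @return Data.frame with one row per participant: `participant_id`,
#'   `beta0`, `beta_money`, `beta_genuine`, `beta_polite`, `converged`,
#'   `n_trials`.
#' @export
fit_utilities_by_participant <- function(choices,
                                         contingencies = face_contingencies(),
                                         ...) {
  check_columns(choices, c("participant_id", "y"), "choices")
  if (!all(c("x1", "x2", "x3") %in% names(choices))) {
    choices <- code_trials(choices, contingencies)
  }
  ids <- unique(choices$participant_id)
  rows <- lapply(ids, function(id) {
    fit <- fit_utilities(choices[choices$participant_id == id, , drop = FALSE],
                         ...)
    data.frame(participant_id = id, beta0 = fit$beta0,
               beta_money = fit$beta_money, beta_genuine = fit$beta_genuine,
               beta_polite = fit$beta_polite, converged = fit$converged,
               n_trials = fit$n_trials, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level tests of the utility estimates
#'
#' Wilcoxon signed-rank tests of whether each reward utility differs from
#' zero across participants, with matched-pairs rank-biserial effect sizes,
#' plus the within-participant comparison of genuine-smile utility against
#' money utility.
#'
#' @param estimates Output of [fit_utilities_by_participant()].
#' @param ... Passed to [wilcoxon_signed_rank()] (e.g. `n_boot` for the
#'   effect-size CI).
#' @return Data.frame with one row per test (`beta_money`, `beta_genuine`,
#'   `beta_polite`, `genuine_vs_money`): `V`, `p_value`, `r_rbs` and its CI,
#'   `n`.
#' @export
group_utility_tests <- function(estimates, ...) {
  check_columns(estimates, c("beta_money", "beta_genuine", "beta_polite"),
                "estimates")
  if (nrow(estimates) < 6L) abort("need at least 6 participants")
  one <- function(label, diffs) {
    w <- wilcoxon_signed_rank(diffs, ...)
    data.frame(term = label, V = w$statistic, p_value = w$p_value,
               r_rbs = w$effect_size, r_ci_low = w$effect_ci_low,
               r_ci_high = w$effect_ci_high, n = w$n,
               stringsAsFactors = FALSE)
  }
  rbind(one("beta_money", estimates$beta_money),
        one("beta_genuine", estimates$beta_genuine),
        one("beta_polite", estimates$beta_polite),
        one("genuine_vs_money",
            estimates$beta_genuine - estimates$beta_money))
}

#' Split-half reliability of the utility estimates
#'
#' Splits each participant's coded test trials into odd- and even-indexed
#' halves (preserving pair-type balance), refits the choice model per half,
#' and correlates the half-estimates across participants. Participants whose
#' half-fits fail to converge are dropped from the correlation.
#'
#' @param choices Coded per-participant choice table (as in
#'   [fit_utilities_by_participant()]).
#' @param contingencies Face contingency table used when `choices` is uncoded.
#' @param spearman_brown Apply the Spearman-Brown step-up correction
#'   (default `FALSE`).
#' @param ... Passed to [fit_utilities()].
#' @return Data.frame with rows `beta_money`, `beta_genuine`, `beta_polite`
#'   and columns `reliability`, `n_participants`.
#' @export
split_half_reliability <- function(choices,
                                   contingencies = face_contingencies(),
                                   spearman_brown = FALSE, ...) {
  check_columns(choices, c("participant_id", "y"), "choices")
  if (!all(c("x1", "x2", "x3") %in% names(choices))) {
    choices <- code_trials(choices, contingencies)
  }
  ids <- unique(choices$participant_id)
  halves <- lapply(ids, function(id) {
    d <- choices[choices$participant_id == id, , drop = FALSE]
    odd <- d[seq_len(nrow(d)) %% 2L == 1L, , drop = FALSE]
    even <- d[seq_len(nrow(d)) %% 2L == 0L, , drop = FALSE]
    if (nrow(odd) < 4L || nrow(even) < 4L) return(NULL)
    f1 <- fit_utilities(odd, ...)
    f2 <- fit_utilities(even, ...)
    if (!f1$converged || !f2$converged) return(NULL)
    data.frame(m1 = f1$beta_money, g1 = f1$beta_genuine, p1 = f1$beta_polite,
               m2 = f2$beta_money, g2 = f2$beta_genuine, p2 = f2$beta_polite)
  })
  halves <- do.call(rbind, halves)
  if (is.null(halves) || nrow(halves) < 4L) {
    abort("too few participants with fittable halves")
  }
  rel <- function(a, b) {
    r <- stats::cor(a, b)
    if (spearman_brown) 2 * r / (1 + r) else r
  }
  data.frame(
    term = c("beta_money", "beta_genuine", "beta_polite"),
    reliability = c(rel(halves$m1, halves$m2), rel(halves$g1, halves$g2),
                    rel(halves$p1, halves$p2)),
    n_participants = nrow(halves),
    stringsAsFactors = FALSE
  )
}
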