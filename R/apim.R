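# Actor-partner interdependence model (APIM) for indistinguishable dyads.
#
# Model, per dyad with members 1 and 2 (exchangeable):
#   y1 = a0 + a * x1 + p * x2 + e1
#   y2 = a0 + a * x2 + p * x1 + e2
# with x1, x2 ~ N(mx, vx), cov(x1, x2) = cxx, var(e) = ve for both members,
# cov(e1, e2) = cee. Actor paths, partner paths, intercepts, predictor
# moments and residual variances are constrained equal across members
# (indistinguishability). Estimation is maximum likelihood on the dyad-level
# 4-variate Gaussian (x1, x2, y1, y2): in closed form for complete data via
# the swap-invariance projection of the saturated moments, and by numerical
# full-information ML (casewise likelihood) when outcomes are missing.
# Inference on the standardized paths uses a bias-corrected bootstrap with
# the dyad as the resampling unit.

# ---- multivariate normal log-likelihood with missing entries -------------

mvn_loglik <- function(Z, mu, Sigma) {
  n <- nrow(Z)
  miss <- is.na(Z)
  pat <- apply(miss, 1L, function(m) paste(as.integer(m), collapse = ""))
  ll <- 0
  for (pp in unique(pat)) {
    idx <- which(pat == pp)
    obs <- !miss[idx[1L], ]
    if (!any(obs)) next
    mu_o <- mu[obs]
    S_o <- Sigma[obs, obs, drop = FALSE]
    ch <- tryCatch(chol(S_o), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    X <- Z[idx, obs, drop = FALSE]
    cent <- sweep(X, 2L, mu_o)
    q <- backsolve(ch, t(cent), transpose = TRUE)
    ll <- ll - 0.5 * length(idx) * (sum(obs) * log(2 * pi) +
                                      2 * sum(log(diag(ch)))) -
      0.5 * sum(q^2)
  }
  ll
}

# ---- parameter plumbing ---------------------------------------------------

apim_moments <- function(par) {
  # par: mx, a0, a, p, lvx, zx, lve, ze
  mx <- par[1]; a0 <- par[2]; a <- par[3]; p <- par[4]
  vx <- exp(par[5]); cxx <- vx * tanh(par[6])
  ve <- exp(par[7]); cee <- ve * tanh(par[8])
  my <- a0 + (a + p) * mx
  vy <- (a^2 + p^2) * vx + 2 * a * p * cxx + ve
  c_same <- a * vx + p * cxx       # cov(x1, y1)
  c_cross <- p * vx + a * cxx      # cov(x1, y2)
  cyy <- (a^2 + p^2) * cxx + 2 * a * p * vx + cee
  mu <- c(mx, mx, my, my)
  Sigma <- matrix(c(vx,      cxx,     c_same,  c_cross,
                    cxx,     vx,      c_cross, c_same,
                    c_same,  c_cross, vy,      cyy,
                    c_cross, c_same,  cyy,     vy), 4L, 4L)
  list(mu = mu, Sigma = Sigma, mx = mx, a0 = a0, a = a, p = p, vx = vx,
       cxx = cxx, ve = ve, cee = cee, vy = vy)
}

# closed-form complete-data MLE: project the saturated moments onto the
# swap-invariant (exchangeable) set, then re-read the APIM parameters
apim_closed_form <- function(Z) {
  n <- nrow(Z)
  mx <- mean(Z[, 1:2]); my <- mean(Z[, 3:4])
  mu_hat <- c(mx, mx, my, my)
  cent <- sweep(Z, 2L, mu_hat)
  S <- crossprod(cent) / n
  P <- matrix(0, 4, 4); P[1, 2] <- P[2, 1] <- P[3, 4] <- P[4, 3] <- 1
  S_sym <- (S + P %*% S %*% t(P)) / 2
  vx <- S_sym[1, 1]; cxx <- S_sym[1, 2]
  c_same <- S_sym[1, 3]; c_cross <- S_sym[1, 4]
  vy <- S_sym[3, 3]; cyy <- S_sym[3, 4]
  if (vx <= 0) abort("zero predictor variance: APIM not identified")
  M <- matrix(c(vx, cxx, cxx, vx), 2L, 2L)
  if (abs(det(M)) < 1e-12 * vx^2) {
    abort("predictor moments are singular (x1 and x2 collinear across dyads)")
  }
  ap <- solve(M, c(c_same, c_cross))
  a <- ap[1]; p <- ap[2]
  ve <- vy - (a^2 + p^2) * vx - 2 * a * p * cxx
  cee <- cyy - (a^2 + p^2) * cxx - 2 * a * p * vx
  if (ve <= 0) abort("non-positive residual variance in APIM fit")
  list(mx = mx, a0 = my - (a + p) * mx, a = a, p = p, vx = vx, cxx = cxx,
       ve = ve, cee = cee)
}

apim_pack <- function(est) {
  c(est$mx, est$a0, est$a, est$p, log(est$vx),
    atanh(max(-0.999, min(0.999, est$cxx / est$vx))),
    log(est$ve),
    atanh(max(-0.999, min(0.999, est$cee / est$ve))))
}

apim_point_fit <- function(Z) {
  complete <- !anyNA(Z)
  cc <- Z[stats::complete.cases(Z), , drop = FALSE]
  if (nrow(cc) < 5L) abort("too few complete dyads to start the APIM fit")
  est <- apim_closed_form(cc)
  if (complete) {
    mom <- apim_moments(apim_pack(est))
    ll <- mvn_loglik(Z, mom$mu, mom$Sigma)
    return(list(est = est, log_lik = ll, fiml = FALSE))
  }
  nll <- function(par) -mvn_loglik(Z, apim_moments(par)$mu,
                                   apim_moments(par)$Sigma)
  opt <- stats::optim(apim_pack(est), nll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  mom <- apim_moments(opt$par)
  list(est = list(mx = mom$mx, a0 = mom$a0, a = mom$a, p = mom$p,
                  vx = mom$vx, cxx = mom$cxx, ve = mom$ve, cee = mom$cee),
       log_lik = -opt$value, fiml = TRUE)
}

apim_standardize <- function(est) {
  vy <- (est$a^2 + est$p^2) * est$vx + 2 * est$a * est$p * est$cxx + est$ve
  c(actor = est$a * sqrt(est$vx / vy), partner = est$p * sqrt(est$vx / vy))
}

# saturated (14-parameter) log-likelihood; closed form when data complete,
# otherwise FIML by optimization over a Cholesky parameterization
saturated_loglik <- function(Z) {
  if (!anyNA(Z)) {
    n <- nrow(Z)
    mu <- colMeans(Z)
    S <- crossprod(sweep(Z, 2L, mu)) / n
    return(mvn_loglik(Z, mu, S))
  }
  cc <- Z[stats::complete.cases(Z), , drop = FALSE]
  mu0 <- colMeans(cc)
  L0 <- t(chol(crossprod(sweep(cc, 2L, mu0)) / nrow(cc)))
  pack <- c(mu0, log(diag(L0)), L0[lower.tri(L0)])
  unpack <- function(par) {
    mu <- par[1:4]
    L <- diag(exp(par[5:8]))
    L[lower.tri(L)] <- par[9:14]
    list(mu = mu, Sigma = L %*% t(L))
  }
  nll <- function(par) {
    m <- unpack(par)
    -mvn_loglik(Z, m$mu, m$Sigma)
  }
  opt <- stats::optim(pack, nll, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  -opt$value
}

# ---- public fitting interface --------------------------------------------

#' Fit the APIM for indistinguishable dyads
#'
#' See the package vignette for the model. Dyads with one missing outcome
#' enter through the casewise (full-information) likelihood; dyads missing
#' the predictor for a member are likewise handled casewise. Fit statistics
#' compare the 8-parameter model against the fully saturated 4-variate
#' Gaussian (14 parameters), giving 6 degrees of freedom; the baseline for
#' CFI/TLI is the independence model. Standardization uses model-implied
#' variances.
#'
#' @param dyads Data.frame with columns `x_1`, `x_2` (predictor per member)
#'   and `y_1`, `y_2` (outcome per member); optionally `dyad_id`.
#' @param n_boot Bootstrap resamples for bias-corrected CIs (default 1000;
#'   0 skips the bootstrap, leaving SEs and CIs `NA`).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level for the bootstrap CIs.
#' @return An object of class `apim`: `paths` (data.frame with standardized
#'   actor/partner estimates, bootstrap SEs, z, p and BC CIs),
#'   `unstandardized` (a, p, a0), `params` (all eight model parameters),
#'   `fit` (chi_sq, df, p, rmsea, cfi, tli, srmr, log_lik), `n_dyads`,
#'   `n_boot`.
#' @export
fit_apim <- function(dyads, n_boot = 1000L, seed = 1L, conf_level = 0.95) {
  check_columns(dyads, c("x_1", "x_2", "y_1", "y_2"), "dyads")
  Z <- as.matrix(dyads[, c("x_1", "x_2", "y_1", "y_2")])
  storage.mode(Z) <- "double"
  Z <- Z[rowSums(!is.na(Z)) > 0L, , drop = FALSE]
  n <- nrow(Z)
  if (n < 10L) abort("need at least 10 dyads")
  xs <- c(Z[, 1], Z[, 2])
  if (stats::var(xs, na.rm = TRUE) == 0) {
    abort("zero predictor variance: APIM not identified")
  }

  fit <- apim_point_fit(Z)
  std <- apim_standardize(fit$est)

  # fit statistics vs the fully saturated model (df = 14 - 8 = 6)
  ll_sat <- saturated_loglik(Z)
  chi_sq <- max(0, 2 * (ll_sat - fit$log_lik))
  df <- 6L
  p_chi <- stats::pchisq(chi_sq, df, lower.tail = FALSE)
  rmsea <- sqrt(max(0, chi_sq - df) / (df * n))
  # independence baseline: free means and variances, zero covariances
  cc <- Z[stats::complete.cases(Z), , drop = FALSE]
  mu_i <- colMeans(cc)
  v_i <- apply(cc, 2L, function(col) mean((col - mean(col))^2))
  ll_base <- mvn_loglik(Z, mu_i, diag(v_i))
  chi_b <- max(0, 2 * (ll_sat - ll_base)); df_b <- 6L
  cfi <- 1 - max(chi_sq - df, 0) / max(chi_b - df_b, chi_sq - df, 0)
  tli <- if (chi_b > df_b) {
    (chi_b / df_b - chi_sq / df) / (chi_b / df_b - 1)
  } else NA_real_
  # SRMR over the standardized covariance residuals (complete cases)
  S <- crossprod(sweep(cc, 2L, colMeans(cc))) / nrow(cc)
  mom <- apim_moments(apim_pack(fit$est))
  dS <- sqrt(diag(S))
  res <- (S - mom$Sigma) / outer(dS, dS)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))

  # bias-corrected bootstrap over dyads
  se <- z <- pval <- c(actor = NA_real_, partner = NA_real_)
  ci_lo <- ci_hi <- c(actor = NA_real_, partner = NA_real_)
  if (n_boot > 0L) {
    set.seed(child_seed(seed, 7L))
    boot <- matrix(NA_real_, n_boot, 2L,
                   dimnames = list(NULL, c("actor", "partner")))
    for (b in seq_len(n_boot)) {
      Zb <- Z[sample.int(n, n, replace = TRUE), , drop = FALSE]
      est_b <- tryCatch(apim_point_fit(Zb)$est, error = function(e) NULL)
      if (!is.null(est_b)) boot[b, ] <- apim_standardize(est_b)
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
    if (nrow(boot) >= 50L) {
      alpha <- (1 - conf_level) / 2
      for (k in c("actor", "partner")) {
        bb <- boot[, k]
        se[k] <- stats::sd(bb)
        z[k] <- std[k] / se[k]
        pval[k] <- 2 * stats::pnorm(-abs(z[k]))
        prop <- mean(bb < std[k])
        prop <- min(max(prop, 1 / (nrow(boot) + 1)),
                    nrow(boot) / (nrow(boot) + 1))
        z0 <- stats::qnorm(prop)
        q_lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
        q_hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
        ci_lo[k] <- stats::quantile(bb, q_lo, names = FALSE)
        ci_hi[k] <- stats::quantile(bb, q_hi, names = FALSE)
      }
    }
  }

  structure(list(
    paths = data.frame(
      effect = c("actor", "partner"),
      estimate = unname(std), se = unname(se), z = unname(z),
      p_value = unname(pval), ci_low = unname(ci_lo),
      ci_high = unname(ci_hi), stringsAsFactors = FALSE),
    unstandardized = c(actor = fit$est$a, partner = fit$est$p,
                       intercept = fit$est$a0),
    params = fit$est,
    fit = list(chi_sq = chi_sq, df = df, p_value = p_chi, rmsea = rmsea,
               cfi = cfi, tli = tli, srmr = srmr, log_lik = fit$log_lik,
               fiml = fit$fiml),
    n_dyads = n, n_boot = n_boot), class = "apim")
}

#' @export
print.apim <- function(x, ...) {
  cat("APIM for indistinguishable dyads (n =", x$n_dyads, "dyads",
      if (x$fit$fiml) "FIML;" else "ML;", x$n_boot, "bootstrap resamples)\n")
  cat("Standardized paths:\n")
  print(transform(x$paths, estimate = round(estimate, 3),
                  se = round(se, 3), z = round(z, 3),
                  p_value = signif(p_value, 4), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3)), row.names = FALSE)
  cat(sprintf("Fit: chi-sq(%d) = %.3f, p = %.3f; RMSEA = %.3f; CFI = %.3f; SRMR = %.3f\n",
              x$fit$df, x$fit$chi_sq, x$fit$p_value, x$fit$rmsea,
              x$fit$cfi, x$fit$srmr))
  invisible(x)
}

#' Fit alternate-predictor APIMs
#'
#' Refits the APIM with each of a set of alternate dyad-level predictors
#' (e.g. proportion of genuine smiles reciprocated; polite-smile reciprocity
#' speed) against the same outcomes, and tabulates actor and partner paths
#' side by side.
#'
#' @param dyads Data.frame carrying `y_1`, `y_2` and, for every predictor
#'   name in `predictors`, columns `<name>_1` and `<name>_2`.
#' @param predictors Character vector of predictor base names.
#' @param ... Passed to [fit_apim()].
#' @return List with `models` (named list of `apim` objects) and `table`
#'   (data.frame: predictor, effect, estimate, se, z, p_value, ci_low,
#'   ci_high).
#' @export
fit_alternate_models <- function(dyads, predictors, ...) {
  check_columns(dyads, c("y_1", "y_2"), "dyads")
  models <- list()
  rows <- list()
  for (pr in predictors) {
    cols <- paste0(pr, c("_1", "_2"))
    check_columns(dyads, cols, "dyads")
    d <- data.frame(x_1 = dyads[[cols[1]]], x_2 = dyads[[cols[2]]],
                    y_1 = dyads$y_1, y_2 = dyads$y_2)
    m <- fit_apim(d, ...)
    models[[pr]] <- m
    tab <- m$paths
    tab <- cbind(data.frame(predictor = pr, stringsAsFactors = FALSE), tab)
    rows[[pr]] <- tab
  }
  list(models = models, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Score the interaction-quality questionnaire
#'
#' Reverse-keyed items are flipped (`8 - x` on the 1-7 scale), the per-person
#' rating is the mean of the nine items, and internal consistency is
#' Cronbach's alpha with a Feldt confidence interval.
#'
#' @param items Matrix or data.frame of item responses (rows = respondents,
#'   9 columns, values 1-7).
#' @param reverse_keyed Integer indices of the reverse-keyed items
#'   (default items 2 and 7).
#' @return List with `ratings` (numeric vector) and `alpha`
#'   (see [cronbach_alpha()]).
#' @export
score_interaction_quality <- function(items, reverse_keyed = c(2L, 7L)) {
  items <- as.matrix(items)
  if (ncol(items) != 9L) abort("expected 9 questionnaire items, got ",
                               ncol(items))
  if (any(items < 1 | items > 7, na.rm = TRUE)) {
    abort("item responses must lie on the 1-7 scale")
  }
  if (length(reverse_keyed) > 0L) {
    items[, reverse_keyed] <- 8 - items[, reverse_keyed]
  }
  list(ratings = rowMeans(items), alpha = cronbach_alpha(items))
}
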