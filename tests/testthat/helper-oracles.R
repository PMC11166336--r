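# Independent oracles used to cross-check the package's estimators. These
# deliberately avoid the implementation paths they validate.

# Coordinate grid-search maximizer of the (ridge-penalized) Bernoulli
# log-likelihood of the logistic choice model. Derivative-free: repeatedly
# scans a shrinking grid per coordinate.
oracle_logit_grid <- function(coded, lambda = 1e-4, rounds = 60L,
                              width0 = 8, grid_n = 21L) {
  X <- cbind(1, coded$x1, coded$x2, coded$x3)
  y <- coded$y
  ll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta))) - lambda * sum(beta^2)
  }
  beta <- rep(0, 4)
  width <- width0
  for (r in seq_len(rounds)) {
    for (j in 1:4) {
      grid <- beta[j] + seq(-width, width, length.out = grid_n)
      vals <- vapply(grid, function(g) {
        b <- beta; b[j] <- g; ll(b)
      }, numeric(1))
      beta[j] <- grid[which.max(vals)]
    }
    width <- width * 0.7
  }
  beta
}

# Naive reciprocity matcher: a from-scratch application of the matching rules
# (chronological initiators, earliest unused same-type partner onset in the
# half-open window), written over plain onset vectors.
oracle_match <- function(on_a, ty_a, on_b, ty_b, window = 60L) {
  evs <- rbind(data.frame(m = rep("a", length(on_a)), on = on_a, ty = ty_a),
               data.frame(m = rep("b", length(on_b)), on = on_b, ty = ty_b))
  evs <- evs[order(evs$on, evs$m), ]
  free_a <- rep(TRUE, length(on_a))
  free_b <- rep(TRUE, length(on_b))
  lags <- list()
  for (i in seq_len(nrow(evs))) {
    if (evs$m[i] == "a") {
      pool_on <- on_b; pool_ty <- ty_b; free <- free_b
    } else {
      pool_on <- on_a; pool_ty <- ty_a; free <- free_a
    }
    ok <- which(free & pool_ty == evs$ty[i] & pool_on > evs$on[i] &
                  pool_on <= evs$on[i] + window)
    if (length(ok) == 0L) next
    j <- ok[order(pool_on[ok])][1L]
    if (evs$m[i] == "a") free_b[j] <- FALSE else free_a[j] <- FALSE
    lags[[length(lags) + 1L]] <- data.frame(
      init_m = evs$m[i], init_on = evs$on[i], resp_on = pool_on[j],
      ty = evs$ty[i], lag = pool_on[j] - evs$on[i])
  }
  if (length(lags) == 0L) {
    return(data.frame(init_m = character(), init_on = integer(),
                      resp_on = integer(), ty = character(),
                      lag = integer()))
  }
  do.call(rbind, lags)
}

# Exact Wilcoxon signed-rank p-value by full 2^n sign enumeration.
oracle_wilcoxon_enum <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- drop(signs %*% r)
  p_ge <- mean(Vs >= V_obs)
  p_le <- mean(Vs <= V_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Event series builder for matcher tests: AU table with smiles painted at
# given 0-based onsets.
make_au_series <- function(onsets, types, n_frames = 200L, dur = 10L,
                           level = 0.9) {
  s <- data.frame(frame_index = 0:(n_frames - 1L), au06 = 0, au12 = 0)
  for (i in seq_along(onsets)) {
    idx <- (onsets[i] + 1L):min(n_frames, onsets[i] + dur)
    s$au12[idx] <- level
    if (types[i] == "genuine") s$au06[idx] <- level
  }
  s
}
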