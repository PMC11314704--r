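# Shared fixtures, all generated in code at test time.

# Random stable VAR coefficient set wrapped as a var_model-shaped object
# (identities of the spectral measures hold for any stable coefficients, no
# fitting required).
random_var_model <- function(n, p, seed, radius = 0.9) {
  set.seed(seed)
  A <- array(stats::rnorm(n * n * p, sd = 0.4), dim = c(n, n, p))
  m <- structure(list(A = A, n = n, p = p, resid_cov = diag(n),
                      labels = paste0("ch", seq_len(n)), fs = 1),
                 class = "var_model")
  sr <- var_spectral_radius(m)
  s <- radius / max(sr, radius)
  for (l in seq_len(p)) m$A[, , l] <- m$A[, , l] * s^l
  m
}

# AR(1)-persistent linear chain x -> y -> z, for TE/DTE motifs.
gen_chain_series <- function(seed, T = 2000) {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), T))
  y <- numeric(T); z <- numeric(T)
  for (t in 2:T) {
    y[t] <- 0.7 * y[t - 1] + 0.8 * x[t - 1] + 0.5 * stats::rnorm(1)
    z[t] <- 0.7 * z[t - 1] + 0.8 * y[t - 1] + 0.5 * stats::rnorm(1)
  }
  mv_series(rbind(x, y, z), fs = 1, labels = c("x", "y", "z"))
}

# Independent AR(1) channels (null network).
gen_null_series <- function(seed, n = 5, T = 2000, ar = 0.5) {
  set.seed(seed)
  v <- vapply(seq_len(n), function(i) as.numeric(stats::arima.sim(list(ar = ar), T)),
              numeric(T))
  mv_series(t(v), fs = 1)
}

# 12-node epoch-switching network with two designated source nodes, used by
# the sliding-window source-localization experiments.
switching_demo_spec <- function() {
  edges <- rbind(
    data.frame(from = 1, to = c(3, 4, 5, 6), lag = 1, strength = 0.35),
    data.frame(from = 2, to = c(7, 8, 9, 10), lag = 1, strength = 0.35),
    data.frame(from = 3, to = 11, lag = 1, strength = 0.12),
    data.frame(from = 7, to = 12, lag = 1, strength = 0.12),
    data.frame(from = 11, to = 12, lag = 1, strength = 0.10))
  ep <- data.frame(name = c("preictal", "ictal", "postictal"),
                   start_s = c(0, 20, 40), end_s = c(20, 40, 60),
                   multiplier = c(0.5, 1.6, 0.8))
  ground_truth(12, edges, root = c(1, 2), epochs = ep)
}

# 5-node VAR(2) network with 8 true directed edges for recovery experiments.
recovery_spec <- function() {
  edges <- data.frame(
    from = c(1, 1, 2, 2, 3, 4, 5, 5),
    to   = c(2, 3, 3, 4, 5, 5, 1, 2),
    lag  = c(1, 2, 1, 1, 2, 1, 1, 2),
    strength = c(0.4, 0.35, 0.4, 0.35, 0.4, 0.35, 0.3, 0.3))
  ground_truth(5, edges, root = 1)
}

fast_surrogates <- function(n_pairs = 100, multiplier = 3, seed = 17)
  surrogate_config(n_pairs = n_pairs, method = "iaaft",
                   multiplier = multiplier, seed = seed)
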