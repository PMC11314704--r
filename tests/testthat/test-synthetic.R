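test_that("generators are deterministic under a fixed seed", {
  spec <- recovery_spec()
  a <- gen_var_network(spec, T = 500, seed = 9)
  b <- gen_var_network(spec, T = 500, seed = 9)
  expect_identical(a$series$values, b$series$values)
  c1 <- gen_coupled_logistic(seed = 4, T = 500)
  c2 <- gen_coupled_logistic(seed = 4, T = 500)
  expect_identical(c1$x, c2$x)
  sw1 <- gen_switching_network(switching_demo_spec(), fs = 250, T = 15000,
                               seed = 2)
  sw2 <- gen_switching_network(switching_demo_spec(), fs = 250, T = 15000,
                               seed = 2)
  expect_identical(sw1$series$values, sw2$series$values)
})

test_that("empty edge set yields independent AR channels", {
  spec <- ground_truth(3, data.frame(from = integer(0), to = integer(0),
                                     lag = integer(0), strength = numeric(0)))
  sim <- gen_var_network(spec, T = 3000, seed = 5)
  cc <- cor(t(sim$series$values))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("ground-truth invariants are enforced", {
  expect_error(ground_truth(3, data.frame(from = 1, to = 1, lag = 1,
                                          strength = 0.5)), "self")
  expect_error(ground_truth(3, data.frame(from = 1, to = 2, lag = 0,
                                          strength = 0.5)), "lag")
  expect_error(ground_truth(2, data.frame(from = 1, to = 5, lag = 1,
                                          strength = 0.5)), "range")
})

test_that("unstable specifications are rescaled to stability", {
  edges <- data.frame(from = c(1, 2), to = c(2, 1), lag = 1, strength = 2.5)
  sim <- gen_var_network(ground_truth(2, edges), T = 2000, seed = 1)
  expect_true(all(is.finite(sim$series$values)))
  m <- fit_var(sim$series, 1)
  expect_lt(var_spectral_radius(m), 1)
})

test_that("the oscillatory network reproduces the 48 h @ 20 s record length", {
  edges <- data.frame(from = 1, to = 2, lag = 2, strength = 0.8)
  sim <- gen_oscillatory_network(ground_truth(2, edges, root = 1), seed = 2)
  expect_equal(n_samples(sim$series), 8640)
  expect_equal(sim$series$fs, 0.05)
})

test_that("all oscillatory channels share the root's spectral peak", {
  edges <- rbind(data.frame(from = 1, to = 2, lag = 3, strength = 0.9),
                 data.frame(from = 2, to = 3, lag = 4, strength = 0.8))
  sim <- gen_oscillatory_network(ground_truth(3, edges, root = 1),
                                 osc_period_s = 6250, seed = 3)
  f0 <- 1 / 6250
  for (ch in 1:3) {
    sp <- spec.pgram(ts(sim$series$values[ch, ], frequency = 0.05),
                     plot = FALSE, taper = 0)
    expect_lt(abs(sp$freq[which.max(sp$spec)] - f0), 2 * diff(sp$freq[1:2]))
  }
  # non-DAG edge set is rejected
  cyc <- rbind(edges, data.frame(from = 3, to = 1, lag = 1, strength = 0.5))
  expect_error(gen_oscillatory_network(ground_truth(3, cyc, root = 1),
                                       seed = 1), "DAG")
})

test_that("root node attains maximal spectrum-weighted outflow at the peak", {
  edges <- rbind(
    data.frame(from = 1, to = 2, lag = 3, strength = 0.9),
    data.frame(from = 1, to = 3, lag = 5, strength = 0.8),
    data.frame(from = 2, to = 4, lag = 4, strength = 0.7))
  sim <- gen_oscillatory_network(ground_truth(4, edges, root = 1),
                                 osc_period_s = 6250, seed = 4)
  s <- standardize(sim$series)
  sm <- var_to_spectral(fit_var(s, 8), fs = s$fs,
                        freqs = seq(0, s$fs / 2, length.out = 257))
  band <- band_spec(0, s$fs / 2)
  os <- outflow_spectrum(spectrum_weighted(dtf(sm), sm, band))
  k0 <- which.min(abs(attr(os, "freqs") - 1 / 6250))
  expect_equal(unname(which.max(os[, k0])), 1)
})

test_that("logistic map couplings are bounded and labeled in the truth", {
  lg <- gen_coupled_logistic(beta_xy = 0.4, beta_yx = 0.2, T = 1000, seed = 6)
  expect_true(all(lg$x > 0 & lg$x < 1))
  expect_true(all(lg$y > 0 & lg$y < 1))
  expect_equal(nrow(lg$truth$edges), 2)
  expect_error(gen_coupled_logistic(beta_xy = 1.2), "couplings")
})

test_that("switching network is stationary within epochs, not globally", {
  spec <- switching_demo_spec()
  sim <- gen_switching_network(spec, fs = 250, T = 15000, seed = 7)
  v <- sim$series$values
  seg <- function(a, b) v[, (a * 250 + 1):(b * 250)]
  sd_pre <- apply(seg(0, 20), 1, sd)
  sd_ict <- apply(seg(20, 40), 1, sd)
  # driven nodes get visibly more power when the sources strengthen
  driven <- unique(spec$edges$to[spec$edges$from %in% spec$root])
  expect_true(all(sd_ict[driven] > sd_pre[driven]))
  # epochs must tile the recording
  bad <- spec
  bad$epochs$end_s[3] <- 50
  expect_error(gen_switching_network(bad, fs = 250, T = 15000, seed = 1),
               "tile")
})

test_that("identical multipliers reduce the switching net to a stationary VAR", {
  spec <- switching_demo_spec()
  spec$epochs$multiplier <- c(1, 1, 1)
  sim <- gen_switching_network(spec, fs = 250, T = 15000, seed = 8)
  v <- sim$series$values
  half1 <- apply(v[, 1:7500], 1, sd)
  half2 <- apply(v[, 7501:15000], 1, sd)
  expect_lt(max(abs(half1 - half2) / half1), 0.25)
})
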