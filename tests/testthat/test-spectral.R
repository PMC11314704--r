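test_that("DTF row and PDC column normalization identities hold exactly", {
  for (seed in 1:25) {
    set.seed(seed)
    m <- random_var_model(n = sample(2:6, 1), p = sample(1:4, 1), seed = seed)
    sm <- var_to_spectral(m, fs = 1, freqs = seq(0, 0.5, length.out = 33))
    d <- dtf(sm); p <- pdc(sm)
    expect_lt(max(abs(apply(d$values^2, c(1, 3), sum) - 1)), 1e-10)
    expect_lt(max(abs(apply(p$values^2, c(2, 3), sum) - 1)), 1e-10)
    expect_true(all(d$values >= 0 & d$values <= 1 + 1e-12))
    expect_true(all(p$values >= 0 & p$values <= 1 + 1e-12))
  }
})

test_that("transfer function inverts the coefficient transform", {
  m <- random_var_model(3, 2, seed = 7)
  sm <- var_to_spectral(m, fs = 1, freqs = seq(0, 0.5, length.out = 64))
  for (k in c(1, 20, 64)) {
    prod <- sm$Hf[, , k] %*% sm$Af[, , k]
    expect_lt(max(Mod(prod - diag(3))), 1e-8)
  }
})

test_that("univariate closed form: A(0) = 1 - a1, H(0) its reciprocal", {
  m <- structure(list(A = array(0.5, c(1, 1, 1)), n = 1L, p = 1L,
                      resid_cov = matrix(1), labels = "x", fs = 1),
                 class = "var_model")
  sm <- var_to_spectral(m, fs = 1, freqs = 0)
  expect_equal(Re(sm$Af[1, 1, 1]), 0.5, tolerance = 1e-12)
  expect_equal(Re(sm$Hf[1, 1, 1]), 2, tolerance = 1e-12)
})

test_that("uncoupled VAR gives diagonal H and vanishing off-diagonal measures", {
  A <- array(0, c(3, 3, 1)); diag(A[, , 1]) <- c(0.5, -0.3, 0.7)
  m <- structure(list(A = A, n = 3L, p = 1L, resid_cov = diag(3),
                      labels = paste0("ch", 1:3), fs = 1), class = "var_model")
  sm <- var_to_spectral(m, fs = 1)
  offdiag <- function(x) x[row(x) != col(x)]
  for (k in c(1, 60, 129))
    expect_lt(max(Mod(offdiag(sm$Hf[, , k]))), 1e-8)
  d <- dtf(sm); p <- pdc(sm)
  expect_lt(max(apply(d$values, 3, offdiag)), 1e-8)
  expect_lt(max(apply(p$values, 3, offdiag)), 1e-8)
  ff <- ffdtf(sm, band_spec(0.05, 0.45))
  expect_lt(max(apply(ff$values, 3, offdiag)), 1e-8)
})

test_that("PDC shows only direct links on a chain while DTF cascades", {
  edges <- data.frame(from = c(1, 2), to = c(2, 3), lag = 1, strength = 0.5)
  sim <- gen_var_network(ground_truth(3, edges, root = 1), T = 8000, seed = 5)
  sm <- var_to_spectral(fit_var(sim$series, 2), fs = 1)
  d <- band_aggregate(dtf(sm)); p <- band_aggregate(pdc(sm))
  # from -> to orientation: indirect 1 -> 3
  expect_gt(d$values["ch1", "ch3"], 10 * p$values["ch1", "ch3"])
  expect_gt(p$values["ch1", "ch2"], 5 * p$values["ch1", "ch3"])
})

test_that("ffDTF pools its denominator over the band", {
  m <- random_var_model(4, 2, seed = 11)
  sm <- var_to_spectral(m, fs = 1, freqs = seq(0, 0.5, length.out = 65))
  band <- band_spec(0.1, 0.4)
  ff <- ffdtf(sm, band)
  # per-target row: squared values sum to 1 over sources and frequencies
  expect_lt(max(abs(apply(ff$values^2, 1, sum) - 1)), 1e-10)
  # single-frequency band reduces to DTF at that frequency
  f1 <- sm$freqs[20]
  ff1 <- ffdtf(sm, band_spec(f1, f1 + 1e-9))
  d <- dtf(sm)
  expect_equal(ff1$values[, , 1], d$values[, , 20], tolerance = 1e-10)
})

test_that("spectrum weighting: weights sum to one; flat spectrum is proportional", {
  m <- random_var_model(3, 2, seed = 13)
  sm <- var_to_spectral(m, fs = 1, freqs = seq(0, 0.5, length.out = 65))
  band <- band_spec(0, 0.5)
  psd <- parametric_psd(sm)
  w <- psd / rowSums(psd)
  expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-12)
  # white noise (p -> 0 coefficients): flat PSD, swDTF proportional to DTF
  m0 <- structure(list(A = array(0, c(2, 2, 1)), n = 2L, p = 1L,
                       resid_cov = diag(2), labels = c("a", "b"), fs = 1),
                  class = "var_model")
  sm0 <- var_to_spectral(m0, fs = 1, freqs = seq(0, 0.5, length.out = 33))
  sw0 <- spectrum_weighted(dtf(sm0), sm0, band_spec(0, 0.5))
  d0 <- dtf(sm0)
  ratio <- sw0$values / d0$values
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-10)
})

test_that("a narrowband driver concentrates spectrum-weighted outflow at its peak", {
  set.seed(21)
  fs <- 100; T <- 6000
  f0 <- 10
  tt <- seq_len(T) / fs
  # resonant AR(2) driver near f0 feeding a second channel
  r <- 0.95; phi <- 2 * pi * f0 / fs
  x <- as.numeric(arima.sim(list(ar = c(2 * r * cos(phi), -r^2)), T))
  y <- c(0, 0.8 * x[-T]) + rnorm(T)
  s <- mv_series(rbind(x, y), fs = fs, labels = c("x", "y"))
  sm <- var_to_spectral(fit_var(s, 6), fs = fs)
  band <- band_spec(1, 40)
  sw <- spectrum_weighted(dtf(sm), sm, band)
  os <- outflow_spectrum(sw)
  fpk <- attr(os, "freqs")[which.max(os["x", ])]
  expect_lt(abs(fpk - f0), 2)
})

test_that("band aggregation is additive over disjoint sub-bands", {
  m <- random_var_model(3, 2, seed = 17)
  sm <- var_to_spectral(m, fs = 1, freqs = seq(0, 0.5, length.out = 101))
  d <- dtf(sm)
  whole <- band_aggregate(d, band_spec(0.1, 0.4))
  left <- band_aggregate(d, band_spec(0.1, 0.25))
  right <- band_aggregate(d, band_spec(0.2505, 0.4))
  expect_equal(whole$values, left$values + right$values, tolerance = 1e-12)
  # single-frequency band equals that slice off-diagonal (transposed to
  # from -> to; the aggregate zeroes the undefined self-causality diagonal)
  one <- band_aggregate(d, band_spec(sm$freqs[30], sm$freqs[30] + 1e-9))
  slice <- t(d$values[, , 30]); diag(slice) <- 0
  expect_equal(one$values, slice, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("permuting channels permutes the causality matrices consistently", {
  spec <- recovery_spec()
  sim <- gen_var_network(spec, T = 3000, seed = 3)
  perm <- c(3, 5, 1, 4, 2)
  agg1 <- band_aggregate(dtf(var_to_spectral(fit_var(sim$series, 2), fs = 1)))
  s2 <- select_channels(sim$series, perm)
  agg2 <- band_aggregate(dtf(var_to_spectral(fit_var(s2, 2), fs = 1)))
  expect_equal(agg2$values, agg1$values[perm, perm], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("unstable models are rejected", {
  A <- array(1.05, c(1, 1, 1))
  m <- structure(list(A = A, n = 1L, p = 1L, resid_cov = matrix(1),
                      labels = "x", fs = 1), class = "var_model")
  expect_error(var_to_spectral(m, fs = 1), "unstable")
})
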