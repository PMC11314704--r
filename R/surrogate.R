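# Monte-Carlo surrogate-data significance.
#
# Surrogates preserve selected null properties of each channel (amplitude
# distribution, power spectrum) while destroying the cross-channel and
# nonlinear temporal dependence that the causality measures detect. The
# measure evaluated on many independently surrogated couples yields a null
# sample; mean + k*SD of that sample is the significance threshold.

#' Surrogate-data configuration
#'
#' @param n_pairs number of surrogate couples (the field default is 3000;
#'   reduced counts are appropriate for desk-scale runs).
#' @param method \code{"iaaft"} (iterated amplitude-adjusted Fourier:
#'   preserves spectrum and amplitude distribution — the appropriate null
#'   for oscillatory data), \code{"phase_randomize"} (preserves the
#'   spectrum), or \code{"shuffle"} (preserves only the marginal).
#' @param multiplier k in the threshold mean + k*SD (3 for time-domain
#'   measures, 2 for spectral DTF/PDC).
#' @param seed RNG seed making the surrogate ensemble reproducible.
#' @return a \code{surrogate_config}.
#' @export
surrogate_config <- function(n_pairs = 3000L,
                             method = c("iaaft", "phase_randomize", "shuffle"),
                             multiplier = 3, seed = NULL) {
  method <- match.arg(method)
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  if (multiplier <= 0) stop("multiplier must be positive")
  structure(list(n_pairs = as.integer(n_pairs), method = method,
                 multiplier = multiplier, seed = seed),
            class = "surrogate_config")
}

phase_randomize_one <- function(x) {
  T <- length(x)
  X <- stats::fft(x)
  half <- (T - 1L) %/% 2L
  ph <- stats::runif(half, 0, 2 * pi)
  rot <- rep(1 + 0i, T)
  if (half > 0) {
    rot[2:(half + 1L)] <- exp(1i * ph)
    rot[T:(T - half + 1L)] <- exp(-1i * ph)
  }
  Re(stats::fft(X * rot, inverse = TRUE)) / T
}

iaaft_one <- function(x, max_iter = 30L) {
  amp <- Mod(stats::fft(x))
  sorted <- sort(x)
  s <- sample(x)
  prev_rank <- NULL
  for (it in seq_len(max_iter)) {
    sf <- stats::fft(s)
    phase <- sf / ifelse(Mod(sf) == 0, 1, Mod(sf))
    s2 <- Re(stats::fft(amp * phase, inverse = TRUE)) / length(x)
    r <- rank(s2, ties.method = "first")
    s <- sorted[r]
    if (!is.null(prev_rank) && identical(r, prev_rank)) break
    prev_rank <- r
  }
  s
}

#' Generate surrogate copies of a recording
#'
#' Each surrogate replicate surrogates every channel independently, so any
#' cross-channel dependence is destroyed while each channel's own null
#' properties are retained. Deterministic under a fixed config seed.
#'
#' @param series an \code{\link{mv_series}} (or numeric vector).
#' @param config a \code{\link{surrogate_config}}; \code{n_surrogates}
#'   overrides \code{config$n_pairs} when given.
#' @param n_surrogates number of replicates to generate.
#' @return list of surrogate \code{mv_series} (or vectors, matching input).
#' @export
make_surrogates <- function(series, config, n_surrogates = config$n_pairs) {
  vec_in <- !inherits(series, "mv_series")
  v <- if (vec_in) matrix(as.numeric(series), nrow = 1L) else series$values
  if (ncol(v) < 32L) stop("series shorter than 32 samples")
  if (!is.null(config$seed)) set.seed(config$seed)
  gen <- switch(config$method,
                iaaft = iaaft_one,
                phase_randomize = phase_randomize_one,
                shuffle = function(x) sample(x))
  lapply(seq_len(n_surrogates), function(r) {
    sv <- t(apply(v, 1L, gen))
    if (vec_in) drop(sv)
    else { out <- series; out$values <- sv; rownames(out$values) <- series$labels; out }
  })
}

#' Surrogate significance threshold for a pairwise measure
#'
#' Evaluates the measure on \code{n_pairs} independently surrogated couples
#' of the two channels and returns mean + multiplier * SD of the null
#' sample. The observed value is significant when it exceeds the threshold.
#'
#' @param metric function(x, y) returning a scalar causality value.
#' @param x,y the original channels.
#' @param config a \code{\link{surrogate_config}}.
#' @return threshold value; attribute \code{"null"} carries the null sample.
#' @export
surrogate_threshold <- function(metric, x, y, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_unseeded <- config; cfg_unseeded$seed <- NULL
  sx <- make_surrogates(x, cfg_unseeded, config$n_pairs)
  sy <- make_surrogates(y, cfg_unseeded, config$n_pairs)
  null_vals <- vapply(seq_len(config$n_pairs), function(r) {
    val <- tryCatch(metric(sx[[r]], sy[[r]]),
                    error = function(e) stop("metric failed on surrogate couple ",
                                             r, ": ", conditionMessage(e)))
    as.numeric(val)
  }, 0)
  thr <- mean(null_vals) + config$multiplier * stats::sd(null_vals)
  if (is.na(thr)) thr <- mean(null_vals)  # degenerate SD (constant metric)
  attr(thr, "null") <- null_vals
  thr
}

#' Per-frequency surrogate thresholds for DTF / PDC
#'
#' Builds \code{n_pairs} full surrogate copies of the recording, refits the
#' MVAR on each, recomputes the spectral measure, and returns per ordered
#' pair per frequency mean + multiplier * SD threshold curves. An observed
#' curve is significant at f where it exceeds its threshold curve.
#'
#' @param method \code{"dtf"} or \code{"pdc"}.
#' @param series an \code{\link{mv_series}}.
#' @param config a \code{\link{surrogate_config}} (spectral default
#'   multiplier is 2).
#' @param p MVAR order for the surrogate fits.
#' @param freqs frequency grid (default as \code{\link{var_to_spectral}}).
#' @return list with \code{threshold} (n x n x F array), \code{freqs}.
#' @export
spectral_threshold <- function(method = c("dtf", "pdc"), series, config, p,
                               freqs = NULL) {
  method <- match.arg(method)
  fun <- if (method == "dtf") dtf else pdc
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_unseeded <- config; cfg_unseeded$seed <- NULL
  surr <- make_surrogates(series, cfg_unseeded, config$n_pairs)
  acc <- NULL; acc2 <- NULL; fgrid <- NULL
  for (s in surr) {
    sm <- var_to_spectral(fit_var(s, p), fs = series$fs, freqs = freqs)
    vals <- fun(sm)$values
    fgrid <- sm$freqs
    if (is.null(acc)) { acc <- vals; acc2 <- vals^2 }
    else { acc <- acc + vals; acc2 <- acc2 + vals^2 }
  }
  m <- acc / config$n_pairs
  sd_arr <- sqrt(pmax(acc2 / config$n_pairs - m^2, 0) *
                   config$n_pairs / (config$n_pairs - 1L))
  list(threshold = m + config$multiplier * sd_arr, freqs = fgrid,
       method = toupper(method), multiplier = config$multiplier)
}
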