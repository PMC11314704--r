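# Time-delay and phase-based directionality.
#
# CCF: the lag tau_hat maximizing |cor(x(t), y(t + tau))| gives both the
# delay and (by its sign) the direction; tau_hat > 0 means x leads y.
# PSI: the imaginary part of sum_f C*(f) C(f + df) of the complex coherency
# C_XY(f) = S_XY(f)/sqrt(S_XX S_YY). A consistent phase slope across the
# band (as produced by a fixed transmission delay) yields a nonzero value
# whose sign gives the direction, while instantaneous (zero-lag) mixing
# contributes nothing in expectation.

#' Cross-correlation directionality
#'
#' Computes \code{rho_XY(tau) = cor(x(t), y(t + tau))} for every integer lag
#' in \code{[tau_min, tau_max]}, picks the lag with maximal absolute
#' correlation (ties toward the smallest |tau|), and reads the direction off
#' the sign: positive means x leads (x causes y).
#'
#' @param x,y numeric vectors of equal length.
#' @param tau_min,tau_max lag range in samples, \code{tau_min < 0 < tau_max}.
#' @return a \code{lag_result}: \code{tau_hat}, \code{rho_at_tau},
#'   \code{direction} (\code{"x_causes_y"}, \code{"y_causes_x"},
#'   \code{"undetermined"}), and the full \code{lags}/\code{rho} profile.
#' @export
ccf_direction <- function(x, y, tau_min = -20L, tau_max = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  if (!(tau_min < 0 && 0 < tau_max)) stop("need tau_min < 0 < tau_max")
  T <- length(x)
  if (T <= 2L * max(abs(tau_min), tau_max)) stop("series too short for lag range")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant channel")
  lags <- tau_min:tau_max
  rho <- vapply(lags, function(tau) {
    if (tau >= 0) stats::cor(x[1:(T - tau)], y[(1 + tau):T])
    else stats::cor(x[(1 - tau):T], y[1:(T + tau)])
  }, 0)
  best <- order(-abs(rho), abs(lags))[1L]   # max |rho|, ties toward small |tau|
  tau_hat <- lags[best]
  direction <- if (tau_hat > 0) "x_causes_y"
               else if (tau_hat < 0) "y_causes_x" else "undetermined"
  structure(list(tau_hat = tau_hat, rho_at_tau = rho[best],
                 direction = direction, lags = lags, rho = rho),
            class = "lag_result")
}

# Welch cross-spectral estimate: Hann taper, 50% overlap. Returns per-segment
# raw cross-periodograms so callers can jackknife.
welch_cross <- function(x, y, fs, segment_len) {
  T <- length(x)
  step <- segment_len %/% 2L
  starts <- seq(1L, T - segment_len + 1L, by = step)
  if (length(starts) < 2L) stop("series too short for segment length")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment_len) / (segment_len + 1))
  nf <- segment_len %/% 2L + 1L
  segs <- lapply(starts, function(s) {
    xs <- x[s:(s + segment_len - 1L)] * w
    ys <- y[s:(s + segment_len - 1L)] * w
    X <- stats::fft(xs)[seq_len(nf)]
    Y <- stats::fft(ys)[seq_len(nf)]
    list(sxy = X * Conj(Y), sxx = Mod(X)^2, syy = Mod(Y)^2)
  })
  list(freqs = (seq_len(nf) - 1L) * fs / segment_len, segs = segs)
}

psi_from_segs <- function(segs, in_band, keep = seq_along(segs)) {
  sxy <- Reduce(`+`, lapply(segs[keep], `[[`, "sxy")) / length(keep)
  sxx <- Reduce(`+`, lapply(segs[keep], `[[`, "sxx")) / length(keep)
  syy <- Reduce(`+`, lapply(segs[keep], `[[`, "syy")) / length(keep)
  C <- sxy / sqrt(sxx * syy)
  f1 <- in_band[-length(in_band)]
  f2 <- in_band[-1L]
  Im(sum(Conj(C[f1]) * C[f2]))
}

#' Phase slope index
#'
#' Estimates the complex coherency with Hann-tapered, 50%-overlapping
#' segments, then sums \code{Im(C*(f) C(f + df))} over grid frequencies in
#' the band (\code{df} = grid spacing). The normalized variant divides by
#' the jackknife (leave-one-segment-out) standard deviation. The sign
#' convention is fixed so that a sender leading a delayed copy yields a
#' positive value for the x-to-y orientation.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param band a \code{\link{band_spec}} within the Nyquist range.
#' @param segment_len segment length in samples; default 1 s worth.
#' @return a \code{psi_result}: raw \code{psi}, \code{psi_normalized},
#'   \code{band}, \code{delta_f}, number of segments.
#' @export
psi <- function(x, y, fs, band, segment_len = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  check_band(band, fs)
  segment_len <- as.integer(segment_len %||% round(fs))
  if (length(x) < 4L * segment_len)
    stop("series shorter than 4 segments; reduce segment_len")
  wc <- welch_cross(x, y, fs, segment_len)
  if (length(wc$segs) < 4L) stop("need at least 4 segments for normalization")
  in_band <- which(wc$freqs >= band$f_lo - 1e-12 & wc$freqs <= band$f_hi + 1e-12)
  if (length(in_band) < 2L) stop("band contains fewer than 2 grid frequencies")
  raw <- psi_from_segs(wc$segs, in_band)
  m <- length(wc$segs)
  loo <- vapply(seq_len(m), function(i)
    psi_from_segs(wc$segs, in_band, keep = setdiff(seq_len(m), i)), 0)
  jk_sd <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  structure(list(psi = raw,
                 psi_normalized = if (jk_sd > 0) raw / jk_sd else 0,
                 band = band, delta_f = fs / segment_len, n_segments = m),
            class = "psi_result")
}
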