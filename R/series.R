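#' Multichannel uniformly sampled time series
#'
#' The container consumed by every causality estimator in the package: an
#' \code{n_channels x n_samples} numeric matrix plus its sampling rate and
#' channel labels. Rows are channels, columns are time points.
#'
#' @param values numeric matrix, channels in rows, samples in columns. A plain
#'   vector is treated as a single channel.
#' @param fs sampling rate in Hz (samples per second); must be positive.
#' @param labels character vector of unique channel identifiers; defaults to
#'   \code{ch1, ch2, ...}.
#' @param region optional character vector of per-channel group tags (e.g.
#'   brain region); recycled checks are not performed, length must match.
#' @param t0 time of the first sample in seconds.
#' @return an object of class \code{mv_series}.
#' @export
mv_series <- function(values, fs, labels = NULL, region = NULL, t0 = 0) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("series values must all be finite")
  if (ncol(values) < 1L) stop("series must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  n <- nrow(values)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per channel")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.null(region) && length(region) != n)
    stop("region must have one entry per channel")
  rownames(values) <- labels
  structure(list(values = values, fs = fs, labels = labels,
                 region = region, t0 = t0),
            class = "mv_series")
}

#' @export
print.mv_series <- function(x, ...) {
  cat(sprintf("<mv_series> %d channels x %d samples @ %g Hz (%.4g s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat("  labels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname mv_series
#' @param x an \code{mv_series}.
#' @export
n_channels <- function(x) nrow(x$values)

#' @rdname mv_series
#' @export
n_samples <- function(x) ncol(x$values)

#' Sliding-window specification
#'
#' @param width_s window width in seconds.
#' @param step_s step between consecutive window starts in seconds.
#' @return a \code{window_spec} object.
#' @export
window_spec <- function(width_s, step_s) {
  if (width_s <= 0 || step_s <= 0) stop("width_s and step_s must be positive")
  structure(list(width_s = width_s, step_s = step_s), class = "window_spec")
}

#' Frequency band specification
#'
#' @param f_lo,f_hi band edges in Hz, \code{0 <= f_lo < f_hi}.
#' @return a \code{band_spec} object.
#' @export
band_spec <- function(f_lo, f_hi) {
  if (f_lo < 0 || f_hi <= f_lo) stop("need 0 <= f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

check_band <- function(band, fs) {
  if (band$f_hi > fs / 2 + 1e-12)
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz", band$f_hi, fs / 2))
  invisible(band)
}

#' Read a multichannel recording from disk
#'
#' Two on-disk formats are supported: a delimited numeric matrix (samples in
#' rows, channels in columns, first row a header of channel labels) and EDF
#' (European Data Format), the standard container for intracranial EEG. CSV
#' carries no sampling rate, so \code{fs} is required for it; EDF headers carry
#' their own rate, which must be identical across signals.
#'
#' @param path file to read.
#' @param format \code{"csv"} or \code{"edf"}.
#' @param fs sampling rate in Hz, required for CSV input.
#' @return an \code{\link{mv_series}}.
#' @export
read_series <- function(path, format = c("csv", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    if (is.null(fs)) stop("fs must be supplied for CSV input (format carries none)")
    dat <- utils::read.csv(path, check.names = FALSE)
    labels <- colnames(dat)
    if (anyDuplicated(labels)) stop("duplicate column names in ", path)
    m <- t(as.matrix(dat))
    if (!is.numeric(m)) stop("non-numeric values in ", path)
    mv_series(m, fs = fs, labels = labels)
  } else {
    read_edf(path)
  }
}

#' Write a multichannel recording to disk
#'
#' @param series an \code{\link{mv_series}}.
#' @param path destination file.
#' @param format \code{"csv"} or \code{"edf"}.
#' @export
write_series <- function(series, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "csv") {
    dat <- as.data.frame(t(series$values))
    colnames(dat) <- series$labels
    utils::write.csv(dat, path, row.names = FALSE)
  } else {
    write_edf(series, path)
  }
  invisible(path)
}

#' Standardize each channel to zero mean, unit variance
#'
#' Puts channels with different physical units on a common scale so that
#' scale-sensitive measures (transfer entropy bins, CCM distances,
#' cross-correlation) compare fairly across pairs.
#'
#' @param series an \code{\link{mv_series}}.
#' @return the standardized \code{mv_series}.
#' @export
standardize <- function(series) {
  v <- series$values
  sds <- apply(v, 1L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop("constant channel(s): ", paste(series$labels[bad], collapse = ", "))
  series$values <- (v - rowMeans(v)) / sds
  series
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering so that no
#' frequency-dependent delay is introduced; a one-pass filter's group delay
#' would masquerade as causal lag in every delay-sensitive estimator
#' downstream. A band touching 0 Hz degenerates to a low-pass.
#'
#' @param series an \code{\link{mv_series}}.
#' @param band a \code{\link{band_spec}}; must lie within the Nyquist range.
#' @param order Butterworth order per pass.
#' @return the filtered \code{mv_series}.
#' @export
bandpass <- function(series, band, order = 4L) {
  check_band(band, series$fs)
  nyq <- series$fs / 2
  if (band$f_lo <= 0) {
    flt <- signal::butter(order, band$f_hi / nyq, type = "low")
  } else {
    flt <- signal::butter(order, c(band$f_lo, band$f_hi) / nyq, type = "pass")
  }
  series$values <- t(apply(series$values, 1L, function(ch)
    signal::filtfilt(flt, ch)))
  series
}

#' Segment a recording into sliding windows
#'
#' Window \code{k} (0-based) covers samples
#' \code{[round(k*step_s*fs), round(k*step_s*fs) + round(width_s*fs))},
#' half-open; every window has the same sample count and a trailing partial
#' window is discarded.
#'
#' @param series an \code{\link{mv_series}}.
#' @param spec a \code{\link{window_spec}}.
#' @return list of \code{mv_series} windows, ordered by start time; each
#'   carries its own \code{t0}.
#' @export
sliding_windows <- function(series, spec) {
  w <- round(spec$width_s * series$fs)
  s <- round(spec$step_s * series$fs)
  if (w < 2) stop("window shorter than 2 samples")
  if (s < 1) stop("step shorter than 1 sample")
  T <- n_samples(series)
  if (w > T) stop("window longer than series")
  n_win <- (T - w) %/% s + 1L
  lapply(seq_len(n_win) - 1L, function(k) {
    i0 <- k * s
    out <- series
    out$values <- series$values[, (i0 + 1L):(i0 + w), drop = FALSE]
    out$t0 <- series$t0 + i0 / series$fs
    out
  })
}

#' Subset channels of a series
#'
#' @param series an \code{\link{mv_series}}.
#' @param channels integer indices or label names.
#' @return an \code{mv_series} with the selected channels, in the given order.
#' @export
select_channels <- function(series, channels) {
  if (is.character(channels)) channels <- match(channels, series$labels)
  if (anyNA(channels)) stop("unknown channel")
  mv_series(series$values[channels, , drop = FALSE], fs = series$fs,
            labels = series$labels[channels],
            region = series$region[channels], t0 = series$t0)
}
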