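# Minimal EDF (European Data Format) reader/writer.
# EDF: 256-byte fixed ASCII header, 256 ASCII bytes per signal, then data
# records of 16-bit little-endian two's-complement integers, mapped linearly
# from the digital to the physical range signal by signal. Only continuous
# recordings with a common sampling rate across signals are supported; annex
# extensions (EDF+ annotations, discontinuous records) are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

read_ascii <- function(con, nbytes) {
  raw <- readBin(con, "raw", n = nbytes)
  trimws(rawToChar(raw))
}

#' Read an EDF recording
#'
#' Parses the fixed-width EDF header and converts the 16-bit digital samples
#' to physical units with each signal's calibration. All signals must share
#' one sampling rate; EDF files mixing rates are rejected as non-uniform.
#'
#' @param path an EDF file.
#' @return an \code{\link{mv_series}} with labels from the signal headers.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (version != "0") stop("unsupported EDF version: ", version)
  invisible(readBin(con, "raw", 80L + 80L))          # patient + recording id
  invisible(readBin(con, "raw", 8L + 8L))            # start date + time
  header_bytes <- as.integer(read_ascii(con, 8L))
  invisible(readBin(con, "raw", 44L))                # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  record_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header")
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16L)
  invisible(field(80L))                              # transducer
  invisible(field(8L))                               # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  invisible(field(80L))                              # prefiltering
  spr <- as.integer(field(8L))                       # samples per record
  invisible(field(32L))                              # reserved
  if (length(unique(spr)) != 1L)
    stop("non-uniform sampling across EDF signals is not supported")
  seek(con, header_bytes)
  total <- n_records * sum(spr)
  dig <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dig) < total) stop("truncated EDF data section")
  vals <- matrix(0, nrow = ns, ncol = n_records * spr[1L])
  idx <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- dig[(idx + 1L):(idx + spr[s])]
      gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      vals[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        phys_min[s] + (seg - dig_min[s]) * gain
      idx <- idx + spr[s]
    }
  }
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  fs <- spr[1L] / record_dur
  mv_series(vals, fs = fs, labels = labels)
}

#' Write an EDF recording
#'
#' Emits a continuous EDF file with one-second data records (the trailing
#' partial second is dropped, matching the format's record structure).
#' Physical and digital ranges are set per channel from the data so the
#' 16-bit quantization error is minimal; integer-valued channels within
#' [-32768, 32767] round-trip exactly.
#'
#' @param series an \code{\link{mv_series}} whose \code{fs} is a positive
#'   integer number of samples per second.
#' @param path destination file.
#' @export
write_edf <- function(series, path) {
  fs <- series$fs
  if (abs(fs - round(fs)) > 1e-9 || fs < 1)
    stop("EDF writer requires an integer sampling rate >= 1 Hz")
  fs <- as.integer(round(fs))
  n <- n_channels(series)
  n_records <- n_samples(series) %/% fs
  if (n_records < 1L) stop("series shorter than one EDF record (1 s)")
  v <- series$values[, seq_len(n_records * fs), drop = FALSE]
  dig_min <- -32768; dig_max <- 32767
  phys_min <- numeric(n); phys_max <- numeric(n); dig <- matrix(0L, n, ncol(v))
  for (s in seq_len(n)) {
    lo <- min(v[s, ]); hi <- max(v[s, ])
    if (hi == lo) hi <- lo + 1
    is_int <- all(v[s, ] == round(v[s, ])) && lo >= dig_min && hi <= dig_max
    if (is_int) {                       # identity calibration: exact round-trip
      phys_min[s] <- dig_min; phys_max[s] <- dig_max
      dig[s, ] <- as.integer(v[s, ])
    } else {
      phys_min[s] <- lo; phys_max[s] <- hi
      dig[s, ] <- as.integer(round(dig_min +
        (v[s, ] - lo) / (hi - lo) * (dig_max - dig_min)))
    }
  }
  header_bytes <- 256L + 256L * n
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  put("0", 8L)
  put("X X X X", 80L); put("Startdate X X X X", 80L)
  put("01.01.00", 8L); put("00.00.00", 8L)
  put(header_bytes, 8L); put("", 44L)
  put(n_records, 8L); put("1", 8L); put(n, 4L)
  for (s in seq_len(n)) put(series$labels[s], 16L)
  for (s in seq_len(n)) put("", 80L)
  for (s in seq_len(n)) put("uV", 8L)
  for (s in seq_len(n)) put(format(phys_min[s], digits = 7), 8L)
  for (s in seq_len(n)) put(format(phys_max[s], digits = 7), 8L)
  for (s in seq_len(n)) put(dig_min, 8L)
  for (s in seq_len(n)) put(dig_max, 8L)
  for (s in seq_len(n)) put("", 80L)
  for (s in seq_len(n)) put(fs, 8L)
  for (s in seq_len(n)) put("", 32L)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(n))
      writeBin(dig[s, cols], con, size = 2L, endian = "little")
  }
  invisible(path)
}
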