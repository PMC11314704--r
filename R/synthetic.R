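# Synthetic network generators with known ground truth.
#
# Every generator is deterministic under a fixed seed and returns the data
# together with its ground-truth edge list, so each detection family has a
# labeled test bed: linear VAR networks for Granger/DTF/PDC, a plant-wide
# oscillation with a stiction-like limit cycle at a common frequency for the
# spectral outflow analysis, coupled logistic maps for CCM, and an
# epoch-switching network with designated sources for the sliding-window
# seizure-onset experiment.

#' Ground-truth network specification
#'
#' @param n_nodes node count.
#' @param edges data frame with columns \code{from}, \code{to} (integer node
#'   indices), \code{lag} (samples, >= 1), \code{strength} (coupling
#'   coefficient).
#' @param root designated source node index (or indices).
#' @param epochs optional data frame \code{name}, \code{start_s},
#'   \code{end_s}, \code{multiplier}: non-overlapping intervals scaling the
#'   root nodes' outgoing couplings.
#' @return a \code{ground_truth} object.
#' @export
ground_truth <- function(n_nodes, edges, root = integer(0), epochs = NULL) {
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (any(edges$lag < 1)) stop("edge lags must be >= 1 sample")
    if (any(edges$from > n_nodes | edges$to > n_nodes)) stop("edge endpoint out of range")
  }
  if (!is.null(epochs) && nrow(epochs) > 1L) {
    o <- order(epochs$start_s)
    if (any(epochs$start_s[o][-1L] < epochs$end_s[o][-nrow(epochs)]))
      stop("epochs must not overlap")
  }
  structure(list(n_nodes = n_nodes, edges = edges, root = root,
                 epochs = epochs),
            class = "ground_truth")
}

#' Export ground-truth edges as labeled truth set
#'
#' @param truth a \code{ground_truth}.
#' @param labels channel labels (default \code{ch<i>}).
#' @return data frame \code{from}, \code{to} with labels.
#' @export
truth_edge_labels <- function(truth, labels = paste0("ch", seq_len(truth$n_nodes))) {
  data.frame(from = labels[truth$edges$from], to = labels[truth$edges$to],
             stringsAsFactors = FALSE)
}

# Assemble A_l coefficient arrays from an edge list plus diagonal AR terms,
# then rescale toward stability: scaling A_l by s^l scales every companion
# eigenvalue by s, so one deterministic rescaling reaches the target radius.
build_var_coefs <- function(spec, self_coef = 0.3, target_radius = 0.95) {
  p <- max(1L, if (nrow(spec$edges)) max(spec$edges$lag) else 1L)
  n <- spec$n_nodes
  A <- array(0, dim = c(n, n, p))
  for (i in seq_len(n)) A[i, i, 1L] <- self_coef
  for (r in seq_len(nrow(spec$edges)))
    A[spec$edges$to[r], spec$edges$from[r], spec$edges$lag[r]] <-
      A[spec$edges$to[r], spec$edges$from[r], spec$edges$lag[r]] +
      spec$edges$strength[r]
  m <- list(A = A, n = n, p = p)
  sr <- var_spectral_radius(m)
  if (sr >= target_radius) {
    s <- target_radius / sr
    for (l in seq_len(p)) A[, , l] <- A[, , l] * s^l
  }
  A
}

simulate_var <- function(A, T, noise, burn = 200L) {
  n <- dim(A)[1L]; p <- dim(A)[3L]
  total <- T + burn
  x <- matrix(0, n, total)
  for (t in (p + 1L):total) {
    acc <- noise[, t]
    for (l in seq_len(p)) acc <- acc + A[, , l] %*% x[, t - l]
    x[, t] <- acc
  }
  x[, (burn + 1L):total, drop = FALSE]
}

#' Generate a linear VAR network with known directed couplings
#'
#' @param spec a \code{\link{ground_truth}}; an empty edge set yields
#'   independent AR(1) channels.
#' @param T samples to generate.
#' @param noise_sd innovation standard deviation.
#' @param seed RNG seed.
#' @param fs nominal sampling rate attached to the output.
#' @return list \code{series} (an \code{\link{mv_series}}) and \code{truth}.
#' @export
gen_var_network <- function(spec, T, noise_sd = 1, seed = 1L, fs = 1) {
  set.seed(seed)
  A <- build_var_coefs(spec)
  p <- dim(A)[3L]
  noise <- matrix(stats::rnorm(spec$n_nodes * (T + 200L), sd = noise_sd),
                  spec$n_nodes)
  x <- simulate_var(A, T, noise)
  list(series = mv_series(x, fs = fs), truth = spec)
}

#' Generate a plant-wide oscillation network
#'
#' The root node carries a stiction-like limit cycle — a sinusoid at the
#' common frequency, amplitude-clipped into a harmonic-rich near-square wave
#' as produced by a sticking valve — plus noise. Each true edge applies its
#' lag and a first-order low-pass smoothing to the source signal, so every
#' driven channel shares the common spectral peak with its own delay and
#' attenuation.
#'
#' @param spec a \code{\link{ground_truth}} whose edges form a DAG rooted at
#'   \code{spec$root}.
#' @param fs sampling rate in Hz (industrial default 0.05 Hz = 20 s interval).
#' @param T samples per channel (default 8640, i.e. 48 h at 20 s).
#' @param osc_period_s oscillation period in seconds.
#' @param clip clipping level as a fraction of the sine amplitude.
#' @param noise_sd additive noise standard deviation.
#' @param smooth first-order low-pass coefficient in (0, 1] applied per edge.
#' @param seed RNG seed.
#' @return list \code{series}, \code{truth}.
#' @export
gen_oscillatory_network <- function(spec, fs = 0.05, T = 8640L,
                                    osc_period_s = 6250, clip = 0.6,
                                    noise_sd = 0.1, smooth = 0.3, seed = 1L) {
  if (osc_period_s <= 2 / fs) stop("oscillation period must be >> 1/fs")
  set.seed(seed)
  n <- spec$n_nodes
  tt <- seq_len(T) / fs
  x <- matrix(stats::rnorm(n * T, sd = noise_sd), n, T)
  base <- sin(2 * pi * tt / osc_period_s)
  for (r in spec$root)
    x[r, ] <- x[r, ] + pmin(pmax(base, -clip), clip) / clip
  # verify the edge set is acyclic (Kahn) before propagating
  deg <- tabulate(spec$edges$to, nbins = n)
  alive <- rep(TRUE, nrow(spec$edges))
  queue <- setdiff(seq_len(n), spec$edges$to[alive])
  while (length(queue)) {
    v0 <- queue[1L]; queue <- queue[-1L]
    out <- which(alive & spec$edges$from == v0)
    alive[out] <- FALSE
    for (w in spec$edges$to[out])
      if (!any(alive & spec$edges$to == w)) queue <- c(queue, w)
  }
  if (any(alive)) stop("edge set is not a DAG reachable from the root")
  # propagate in topological order
  remaining <- spec$edges
  done <- spec$root
  guard <- 0L
  while (nrow(remaining) && guard < n + 2L) {
    ready <- remaining$from %in% done
    for (r in which(ready)) {
      e <- remaining[r, ]
      src <- x[e$from, ]
      lagged <- c(rep(src[1L], e$lag), src[seq_len(T - e$lag)])
      sm <- as.numeric(stats::filter(lagged * smooth, 1 - smooth,
                                     method = "recursive"))
      x[e$to, ] <- x[e$to, ] + e$strength * sm
    }
    done <- unique(c(done, remaining$to[ready]))
    remaining <- remaining[!ready, , drop = FALSE]
    guard <- guard + 1L
  }
  if (nrow(remaining)) stop("edge set is not a DAG reachable from the root")
  list(series = mv_series(x, fs = fs), truth = spec)
}

#' Generate unidirectionally or bidirectionally coupled logistic maps
#'
#' \code{x(t+1) = x(t) (r - r x(t) - beta_yx y(t))},
#' \code{y(t+1) = y(t) (r - r y(t) - beta_xy x(t))}: the canonical chaotic
#' benchmark for cross-map causality, with \code{beta_xy} the strength of
#' the x-to-y coupling.
#'
#' @param beta_xy,beta_yx coupling strengths in [0, 1).
#' @param r logistic parameter in the chaotic range (about 3.6-4.0).
#' @param T samples after burn-in.
#' @param seed RNG seed (random initial conditions).
#' @param burn burn-in samples discarded.
#' @return list \code{x}, \code{y} (numeric vectors) and \code{truth}.
#' @export
gen_coupled_logistic <- function(beta_xy = 0.4, beta_yx = 0, r = 3.8,
                                 T = 3000L, seed = 1L, burn = 300L) {
  if (beta_xy < 0 || beta_xy >= 1 || beta_yx < 0 || beta_yx >= 1)
    stop("couplings must lie in [0, 1)")
  set.seed(seed)
  total <- T + burn
  x <- numeric(total); y <- numeric(total)
  x[1L] <- stats::runif(1, 0.2, 0.8); y[1L] <- stats::runif(1, 0.2, 0.8)
  for (t in seq_len(total - 1L)) {
    x[t + 1L] <- x[t] * (r - r * x[t] - beta_yx * y[t])
    y[t + 1L] <- y[t] * (r - r * y[t] - beta_xy * x[t])
    if (!is.finite(x[t + 1L]) || !is.finite(y[t + 1L]) ||
        x[t + 1L] <= 0 || y[t + 1L] <= 0 ||
        x[t + 1L] >= 1 || y[t + 1L] >= 1)
      stop("divergent parameters for the coupled logistic maps")
  }
  edges <- data.frame(from = integer(0), to = integer(0), lag = integer(0),
                      strength = numeric(0))
  if (beta_xy > 0) edges <- rbind(edges, data.frame(from = 1L, to = 2L,
                                                    lag = 1L, strength = beta_xy))
  if (beta_yx > 0) edges <- rbind(edges, data.frame(from = 2L, to = 1L,
                                                    lag = 1L, strength = beta_yx))
  list(x = x[(burn + 1L):total], y = y[(burn + 1L):total],
       truth = ground_truth(2L, edges))
}

#' Generate an epoch-switching oscillatory network
#'
#' A VAR-type network whose designated source nodes' outgoing coefficients
#' are multiplied per epoch — weak before, strong during the "ictal" epoch,
#' relaxed after — driven by narrowband innovations band-limited to the
#' analysis band, emulating abnormal discharges spreading from onset nodes
#' through oscillatory synchrony. Stationarity holds within epochs but not
#' globally.
#'
#' @param spec a \code{\link{ground_truth}} with \code{root} (source nodes)
#'   and \code{epochs} (\code{name}, \code{start_s}, \code{end_s},
#'   \code{multiplier}) tiling \code{[0, T/fs]}.
#' @param fs sampling rate in Hz.
#' @param T total samples.
#' @param innovation_band a \code{\link{band_spec}} for the innovations
#'   (default 1-30 Hz).
#' @param noise_sd innovation standard deviation before filtering.
#' @param seed RNG seed.
#' @return list \code{series}, \code{truth}.
#' @export
gen_switching_network <- function(spec, fs = 250, T, innovation_band = NULL,
                                  noise_sd = 1, seed = 1L) {
  if (is.null(spec$epochs) || !nrow(spec$epochs)) stop("spec must define epochs")
  ep <- spec$epochs[order(spec$epochs$start_s), , drop = FALSE]
  if (abs(ep$start_s[1L]) > 1e-9 || abs(ep$end_s[nrow(ep)] - T / fs) > 1e-6 ||
      (nrow(ep) > 1L && any(abs(ep$start_s[-1L] - ep$end_s[-nrow(ep)]) > 1e-9)))
    stop("epochs must tile [0, T/fs]")
  set.seed(seed)
  n <- spec$n_nodes
  A0 <- build_var_coefs(spec)
  p <- dim(A0)[3L]
  innovation_band <- innovation_band %||% band_spec(1, 30)
  flt <- signal::butter(2, c(max(innovation_band$f_lo, 1e-3), innovation_band$f_hi) /
                          (fs / 2), type = "pass")
  burn <- 4L * p + 100L
  total <- T + burn
  noise <- t(apply(matrix(stats::rnorm(n * total, sd = noise_sd), n, total), 1L,
                   function(ch) as.numeric(signal::filter(flt, ch))))
  noise <- noise / stats::sd(noise) * noise_sd
  src_mask <- matrix(FALSE, n, n)
  src_mask[, spec$root] <- TRUE          # columns = source channels
  diag(src_mask) <- FALSE
  # per-epoch coefficient sets, each checked for stability
  A_by_epoch <- lapply(seq_len(nrow(ep)), function(r) {
    A <- A0
    for (l in seq_len(p)) A[, , l][src_mask] <- A[, , l][src_mask] * ep$multiplier[r]
    if (var_spectral_radius(list(A = A, n = n, p = p)) >= 1)
      stop("unstable epoch configuration: ", ep$name[r])
    A
  })
  x <- matrix(0, n, total)
  epoch_of <- function(t) {
    s <- (t - burn) / fs
    i <- findInterval(max(s, 0), ep$start_s, rightmost.closed = TRUE)
    min(max(i, 1L), nrow(ep))
  }
  for (t in (p + 1L):total) {
    A <- A_by_epoch[[epoch_of(t)]]
    acc <- noise[, t]
    for (l in seq_len(p)) acc <- acc + A[, , l] %*% x[, t - l]
    x[, t] <- acc
  }
  list(series = mv_series(x[, (burn + 1L):total, drop = FALSE], fs = fs),
       truth = spec)
}
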