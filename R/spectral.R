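# Frequency-domain causality from a fitted MVAR.
#
# The coefficient transform A(f) = -(sum_{l=0}^p A_l e^{-2 pi i f l / fs})
# with A_0 = -I, and the transfer function H(f) = A(f)^{-1}, give the two
# classic measures: DTF normalizes |H_ij(f)| by its row (inflow to target i),
# PDC normalizes |A_ij(f)| by its column (outflow from source j). In both,
# entry (i, j) quantifies the influence of channel j on channel i.

#' Frequency-domain representation of a fitted MVAR
#'
#' @param model a \code{\link{fit_var}} result; must be stable (companion
#'   spectral radius < 1).
#' @param fs sampling rate in Hz; defaults to the rate recorded in the model.
#' @param freqs frequency grid in Hz; default 129 evenly spaced points from 0
#'   to \code{fs/2}.
#' @return a \code{spectral_model}: complex arrays \code{Af} and \code{Hf}
#'   (\code{n x n x F}), the grid, \code{fs}, residual covariance and labels.
#' @export
var_to_spectral <- function(model, fs = NULL, freqs = NULL) {
  fs <- fs %||% model$fs
  if (is.null(fs) || is.na(fs)) stop("sampling rate unknown; supply fs")
  sr <- var_spectral_radius(model)
  if (sr >= 1) stop(sprintf("unstable VAR (spectral radius %.3f)", sr))
  if (is.null(freqs)) freqs <- seq(0, fs / 2, length.out = 129L)
  n <- model$n; p <- model$p; F <- length(freqs)
  Af <- array(0i, dim = c(n, n, F))
  Hf <- array(0i, dim = c(n, n, F))
  I_n <- diag(n)
  for (k in seq_len(F)) {
    z <- exp(-2i * pi * freqs[k] / fs * seq_len(p))
    A <- I_n + 0i
    for (l in seq_len(p)) A <- A - model$A[, , l] * z[l]
    Af[, , k] <- A
    sv <- svd(A, nu = 0, nv = 0)$d
    kap <- if (min(sv) > 0) max(sv) / min(sv) else Inf
    if (!is.finite(kap) || kap > 1e12)
      stop(sprintf("A(f) numerically singular at f = %g Hz", freqs[k]))
    Hf[, , k] <- solve(A)
  }
  structure(list(freqs = freqs, Af = Af, Hf = Hf, fs = fs,
                 resid_cov = model$resid_cov, labels = model$labels, n = n),
            class = "spectral_model")
}

spectral_causality <- function(values, freqs, method, fs, labels, band = NULL) {
  dimnames(values) <- list(target = labels, source = labels, NULL)
  structure(list(method = method, values = values, freqs = freqs, fs = fs,
                 labels = labels, band = band),
            class = "spectral_causality")
}

#' @export
print.spectral_causality <- function(x, ...) {
  cat(sprintf("<spectral_causality:%s> %d channels x %d frequencies [%g, %g] Hz\n",
              x$method, length(x$labels), length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Directed transfer function
#'
#' \code{gamma_ij(f) = |H_ij(f)| / sqrt(sum_k |H_ik(f)|^2)}: the influence of
#' channel j on channel i at frequency f relative to the total inflow to i,
#' so each row of squared values sums to one at every frequency.
#'
#' @param spec a \code{\link{var_to_spectral}} result.
#' @return a \code{spectral_causality} with \code{values[i, j, f]} in [0, 1].
#' @export
dtf <- function(spec) {
  H <- Mod(spec$Hf)
  F <- length(spec$freqs)
  vals <- array(0, dim = dim(H))
  for (k in seq_len(F)) {
    Hk <- H[, , k, drop = FALSE][, , 1L, drop = FALSE]
    dim(Hk) <- dim(H)[1:2]
    vals[, , k] <- Hk / sqrt(rowSums(Hk^2))
  }
  spectral_causality(vals, spec$freqs, "DTF", spec$fs, spec$labels)
}

#' Partial directed coherence
#'
#' \code{pi_ij(f) = |A_ij(f)| / sqrt(sum_k |A_kj(f)|^2)}: the direct influence
#' of source j on target i relative to j's total outflow, so each column of
#' squared values sums to one at every frequency. Unlike DTF, PDC vanishes on
#' indirect (mediated) routes.
#'
#' @param spec a \code{\link{var_to_spectral}} result.
#' @return a \code{spectral_causality} with \code{values[i, j, f]} in [0, 1].
#' @export
pdc <- function(spec) {
  A <- Mod(spec$Af)
  F <- length(spec$freqs)
  vals <- array(0, dim = dim(A))
  for (k in seq_len(F)) {
    Ak <- A[, , k, drop = FALSE][, , 1L, drop = FALSE]
    dim(Ak) <- dim(A)[1:2]
    vals[, , k] <- sweep(Ak, 2L, sqrt(colSums(Ak^2)), "/")
  }
  spectral_causality(vals, spec$freqs, "PDC", spec$fs, spec$labels)
}

band_index <- function(freqs, band) {
  idx <- which(freqs >= band$f_lo - 1e-12 & freqs <= band$f_hi + 1e-12)
  if (!length(idx)) stop("no grid frequencies inside the band")
  idx
}

#' Full-frequency directed transfer function
#'
#' DTF with the row denominator pooled over the whole analysis band:
#' \code{eta_ij(f) = |H_ij(f)| / sqrt(sum_{f' in band} sum_k |H_ik(f')|^2)}.
#' Values on the band then form a distribution per row (squared values sum
#' to one over targets and frequencies jointly), which makes magnitudes
#' comparable across frequencies rather than renormalized at each one.
#'
#' @param spec a \code{\link{var_to_spectral}} result.
#' @param band a \code{\link{band_spec}} inside the grid.
#' @return a \code{spectral_causality} restricted to the band.
#' @export
ffdtf <- function(spec, band) {
  idx <- band_index(spec$freqs, band)
  H <- Mod(spec$Hf[, , idx, drop = FALSE])
  # pooled row denominator: sum over sources and band frequencies per target
  pooled <- sqrt(apply(H^2, 1L, sum))
  vals <- H / pooled   # recycles over first dimension (targets)
  spectral_causality(vals, spec$freqs[idx], "ffDTF", spec$fs, spec$labels, band)
}

#' Parametric power spectral density of each channel
#'
#' \code{S_jj(f) = [H(f) Sigma H(f)*]_jj} from the fitted MVAR, with Sigma the
#' residual covariance.
#'
#' @param spec a \code{\link{var_to_spectral}} result.
#' @return matrix \code{n x F} of nonnegative spectral densities.
#' @export
parametric_psd <- function(spec) {
  F <- length(spec$freqs); n <- spec$n
  out <- matrix(0, n, F, dimnames = list(spec$labels, NULL))
  for (k in seq_len(F)) {
    Hk <- spec$Hf[, , k]
    out[, k] <- Re(diag(Hk %*% spec$resid_cov %*% Conj(t(Hk))))
  }
  out
}

#' Spectrum-weighted causality (swDTF / swPDC)
#'
#' Reweights a DTF or PDC curve by the source channel's parametric power
#' spectral density, normalized to sum to one over the band, so frequency
#' components carrying more spectral energy count more.
#'
#' @param base a \code{spectral_causality} of method DTF or PDC.
#' @param spec the \code{\link{var_to_spectral}} model the base was computed
#'   from (same grid).
#' @param band a \code{\link{band_spec}}.
#' @return a \code{spectral_causality} restricted to the band, method
#'   \code{swDTF} or \code{swPDC}.
#' @export
spectrum_weighted <- function(base, spec, band) {
  if (!base$method %in% c("DTF", "PDC"))
    stop("spectrum weighting applies to DTF or PDC")
  if (length(base$freqs) != length(spec$freqs) ||
      max(abs(base$freqs - spec$freqs)) > 1e-9)
    stop("frequency grid mismatch between base measure and spectral model")
  idx <- band_index(spec$freqs, band)
  psd <- parametric_psd(spec)[, idx, drop = FALSE]
  w <- psd / rowSums(psd)                      # per-source weights, sum 1 on band
  vals <- base$values[, , idx, drop = FALSE]
  for (k in seq_along(idx))
    vals[, , k] <- sweep(vals[, , k, drop = FALSE][, , 1], 2L, w[, k], "*")
  spectral_causality(vals, spec$freqs[idx],
                     paste0("sw", base$method), spec$fs, spec$labels, band)
}

#' Aggregate a spectral causality measure over a band
#'
#' Sums the per-frequency causalities over all grid frequencies inside
#' \code{[f_lo, f_hi]} (inclusive) to a single scalar per ordered pair,
#' representing the overall causal effect in that band.
#'
#' @param mat a \code{spectral_causality}.
#' @param band a \code{\link{band_spec}}; defaults to the measure's own band
#'   or the full grid.
#' @return a \code{\link{causal_matrix}} (orientation from -> to).
#' @export
band_aggregate <- function(mat, band = NULL) {
  band <- band %||% mat$band %||% band_spec(min(mat$freqs), max(mat$freqs))
  idx <- band_index(mat$freqs, band)
  agg <- apply(mat$values[, , idx, drop = FALSE], c(1L, 2L), sum)
  # agg[i, j] = influence j -> i; causal_matrix stores from -> to
  causal_matrix(t(agg), labels = mat$labels, method = mat$method)
}
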