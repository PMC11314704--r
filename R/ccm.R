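# Convergent cross mapping.
#
# If X drives Y, the attractor reconstructed from Y's delay embedding
# contains a (distorted) copy of X's dynamics, so X can be recovered from
# Y's shadow manifold: cross-map skill rho(L) rises and converges as the
# library of manifold points grows. The causal effect X -> Y is therefore
# quantified by cross-mapping X from the manifold of Y.

#' Delay-embedding configuration
#'
#' @param dim embedding dimension (>= 2).
#' @param tau embedding delay in samples.
#' @param K number of nearest neighbors used for cross-map estimation.
#' @param theiler temporal exclusion radius in samples; neighbors closer in
#'   time than this to the target point are never used (guards against
#'   trivially autocorrelated neighbors on oscillatory data). Default
#'   \code{dim * tau}.
#' @return an \code{embedding_config}.
#' @export
embedding_config <- function(dim = 18L, tau = 1L, K = 8L, theiler = NULL) {
  if (dim < 2L) stop("embedding dimension must be >= 2")
  if (tau < 1L || K < 1L) stop("tau and K must be >= 1")
  structure(list(dim = as.integer(dim), tau = as.integer(tau),
                 K = as.integer(K),
                 theiler = as.integer(theiler %||% (dim * tau))),
            class = "embedding_config")
}

#' Delay-embed a series into its shadow manifold
#'
#' Vector at time t is \code{(x(t), x(t - tau), ..., x(t - (dim-1) tau))};
#' there are \code{T - (dim - 1) tau} such vectors, the first at
#' \code{t = (dim - 1) tau + 1} (1-based).
#'
#' @param x numeric vector.
#' @param config an \code{\link{embedding_config}}.
#' @return matrix with one delay vector per row; attribute \code{times} gives
#'   the (1-based) sample index of each vector's leading element.
#' @export
embed_series <- function(x, config) {
  x <- as.numeric(x)
  T <- length(x)
  span <- (config$dim - 1L) * config$tau
  if (T < span + 1L) stop("series too short for the requested embedding")
  tt <- (span + 1L):T
  M <- sapply(0:(config$dim - 1L), function(j) x[tt - j * config$tau])
  M <- matrix(M, ncol = config$dim)
  attr(M, "times") <- tt
  M
}

#' Cross-map estimate of x from the shadow manifold of y
#'
#' For each target time t, the K nearest neighbors (Euclidean) of m_Y(t)
#' within the library of the first \code{L} manifold points are weighted by
#' \code{u_i = exp(-d_i / d_1)} (normalized), and x(t) is estimated as the
#' weighted sum of the neighbors' co-temporal x values. An exact match
#' (d_1 = 0) receives all the weight of the zero-distance neighbors.
#' Returns the Pearson correlation between estimate and truth over target
#' times; under the package's convention this skill quantifies the causal
#' effect of x on y.
#'
#' @param x putative cause (to be recovered).
#' @param y putative effect (supplies the manifold).
#' @param config an \code{\link{embedding_config}}.
#' @param L library length (number of manifold points); \code{> K}.
#' @return correlation coefficient rho in [-1, 1].
#' @export
cross_map <- function(x, y, config, L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  My <- embed_series(y, config)
  times <- attr(My, "times")
  N <- nrow(My)
  if (L > N) stop("library longer than available manifold points")
  if (L < config$K + 1L) stop("library must exceed K")
  lib <- seq_len(L)
  # distances from every target point to every library point
  xt <- x[times]
  preds <- rep(NA_real_, N)
  lib_M <- My[lib, , drop = FALSE]
  sq_lib <- rowSums(lib_M^2)
  for (t in seq_len(N)) {
    d2 <- sq_lib - 2 * drop(lib_M %*% My[t, ]) + sum(My[t, ]^2)
    d <- sqrt(pmax(d2, 0))
    d[abs(times[lib] - times[t]) <= config$theiler] <- Inf
    if (sum(is.finite(d)) < config$K) next
    nn <- order(d)[seq_len(config$K)]
    dn <- d[nn]
    if (dn[1] == 0) {
      w <- as.numeric(dn == 0)
    } else {
      w <- exp(-dn / dn[1])
    }
    w <- w / sum(w)
    preds[t] <- sum(w * xt[times[lib][nn] - times[1] + 1L])
  }
  ok <- is.finite(preds)
  if (sum(ok) < 3L) stop("too few predictable target points")
  stats::cor(preds[ok], xt[ok])
}

#' Library-length sweep with convergence verdict
#'
#' Computes cross-map skill at each library length (libraries are the first
#' L manifold points, i.e. increasing prefixes of the recording). The curve
#' is judged converged when it has flattened: the least-squares slope over
#' the last half of the sweep changes rho by at most \code{tol} across that
#' half, and \code{|rho(L_max) - rho(L_max/2)| < tol}. The causal relation
#' is significant when the curve converges with \code{|rho| > 0.75}
#' (strictly).
#'
#' @param x,y cause and effect series (see \code{\link{cross_map}}).
#' @param config an \code{\link{embedding_config}}.
#' @param lengths strictly increasing library lengths, at least 4 of them.
#' @param tol convergence tolerance on rho.
#' @param threshold significance threshold on |rho|.
#' @return a \code{ccm_curve}: \code{lengths}, \code{rho}, \code{converged},
#'   \code{rho_conv} (terminal skill), \code{significant}.
#' @export
ccm_sweep <- function(x, y, config, lengths, tol = 0.05, threshold = 0.75) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 4L) stop("need at least 4 library lengths")
  if (any(diff(lengths) <= 0L)) stop("lengths must be strictly increasing")
  rho <- vapply(lengths, function(L) cross_map(x, y, config, L), 0)
  half <- lengths >= lengths[length(lengths)] / 2
  fit <- stats::lm.fit(cbind(1, lengths[half]), rho[half])
  drift <- fit$coefficients[2] * diff(range(lengths[half]))
  mid_idx <- which.min(abs(lengths - lengths[length(lengths)] / 2))
  jump <- abs(rho[length(rho)] - rho[mid_idx])
  converged <- is.finite(drift) && abs(drift) <= tol && jump < tol
  rho_conv <- rho[length(rho)]
  structure(list(lengths = lengths, rho = rho, converged = converged,
                 rho_conv = rho_conv,
                 significant = converged && abs(rho_conv) > threshold,
                 tol = tol, threshold = threshold),
            class = "ccm_curve")
}

#' @export
print.ccm_curve <- function(x, ...) {
  cat(sprintf("<ccm_curve> L in [%d, %d], rho_conv=%.3f, converged=%s, significant=%s\n",
              min(x$lengths), max(x$lengths), x$rho_conv,
              x$converged, x$significant))
  invisible(x)
}

#' Pairwise CCM over all channels
#'
#' @param series an \code{\link{mv_series}}.
#' @param config an \code{\link{embedding_config}}.
#' @param lengths library lengths for \code{\link{ccm_sweep}}.
#' @return list with \code{rho} matrix (from -> to: entry (i, j) is the skill
#'   of cross-mapping channel i from channel j's manifold, i.e. the effect of
#'   i on j), boolean \code{adjacency} of significant relations, and the
#'   per-pair \code{ccm_curve}s.
#' @export
ccm_matrix <- function(series, config = embedding_config(), lengths) {
  v <- series$values
  n <- nrow(v)
  rho <- matrix(NA_real_, n, n, dimnames = list(from = series$labels,
                                                to = series$labels))
  adj <- matrix(FALSE, n, n, dimnames = dimnames(rho))
  curves <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cur <- ccm_sweep(v[i, ], v[j, ], config, lengths)
    rho[i, j] <- cur$rho_conv
    adj[i, j] <- cur$significant
    curves[[(i - 1L) * n + j]] <- cur
  }
  list(rho = rho, adjacency = adj, curves = curves, labels = series$labels)
}
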