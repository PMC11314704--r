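# Transfer entropy and its conditional (direct) extension.
#
# T_{X->Y} = H(Y_{t+h} | Y_t^-) - H(Y_{t+h} | X_t^-, Y_t^-): the reduction in
# uncertainty about the target's future when the source's past is added to
# the target's own past. Model-free, so nonlinear couplings invisible to
# linear Granger measures can still be detected. Reported in bits.

#' Transfer entropy parameters
#'
#' @param h prediction horizon in samples.
#' @param l1,l2 source and target history lengths (number of embedded lags).
#' @param tau embedding delay in samples.
#' @param estimator \code{"binned"} (equiprobable rank binning, plug-in
#'   entropies) or \code{"knn"} (Kraskov-style nearest-neighbor conditional
#'   mutual information for continuous data).
#' @param bins bins per embedded dimension for the binned estimator.
#' @param k neighbor count for the knn estimator.
#' @return a \code{te_params} list.
#' @export
te_params <- function(h = 1L, l1 = 1L, l2 = 1L, tau = 1L,
                      estimator = c("binned", "knn"), bins = 4L, k = 4L) {
  estimator <- match.arg(estimator)
  if (h < 1L || l1 < 1L || l2 < 1L || tau < 1L)
    stop("h, l1, l2 and tau must all be >= 1")
  structure(list(h = as.integer(h), l1 = as.integer(l1), l2 = as.integer(l2),
                 tau = as.integer(tau), estimator = estimator,
                 bins = as.integer(bins), k = as.integer(k)),
            class = "te_params")
}

# Equiprobable discretization via ranks; invariant under strictly monotone
# transforms. Collapses naturally when the series takes < bins distinct values.
discretize_ranks <- function(x, bins) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(r * bins / length(x))
  pmin(pmax(b, 1L), bins)
}

joint_entropy_bits <- function(cols) {
  cols <- as.matrix(cols)
  # pack the small integer columns into one key; radix = per-column maximum
  key <- cols[, 1L]
  if (ncol(cols) > 1L) for (c in 2:ncol(cols))
    key <- key * (max(cols[, c]) + 1L) + cols[, c]
  p <- tabulate(match(key, unique(key)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Build the embedded blocks shared by TE and DTE. Returns a list of matrices:
# yf (future), yp (target past), xp (source past), zp (conditioning past).
te_embed <- function(x, y, params, cond = list()) {
  T <- length(y)
  lmax <- max(params$l1, params$l2,
              if (length(cond)) params$l2 else 1L)
  t0 <- params$tau * (lmax - 1L) + 1L
  tt <- t0:(T - params$h)
  if (length(tt) < 10L) stop("insufficient samples for the requested embedding")
  lagmat <- function(v, l) {
    out <- sapply(0:(l - 1L), function(j) v[tt - j * params$tau])
    matrix(out, ncol = l)
  }
  list(yf = matrix(y[tt + params$h], ncol = 1L),
       yp = lagmat(y, params$l2),
       xp = if (is.null(x)) NULL else lagmat(x, params$l1),
       zp = if (length(cond)) do.call(cbind, lapply(cond, lagmat, l = params$l2))
            else NULL)
}

te_binned <- function(emb, bins) {
  dis <- function(m) if (is.null(m)) NULL else apply(m, 2L, discretize_ranks, bins = bins)
  yf <- dis(emb$yf); yp <- dis(emb$yp); xp <- dis(emb$xp); zp <- dis(emb$zp)
  base <- cbind(yp, zp)
  joint_entropy_bits(cbind(yf, base)) - joint_entropy_bits(base) -
    joint_entropy_bits(cbind(yf, xp, base)) + joint_entropy_bits(cbind(xp, base))
}

# Kraskov-style conditional mutual information I(yf ; xp | yp, zp) with
# max-norm distances; O(N^2), so large inputs are subsampled.
te_knn <- function(emb, k, max_points = 2000L) {
  A <- emb$yf; B <- emb$xp; C <- cbind(emb$yp, emb$zp)
  N <- nrow(A)
  if (N > max_points) {
    keep <- round(seq(1L, N, length.out = max_points))
    A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
    C <- C[keep, , drop = FALSE]; N <- max_points
  }
  maxdist <- function(M) {
    d <- matrix(0, N, N)
    for (c in seq_len(ncol(M))) d <- pmax(d, abs(outer(M[, c], M[, c], "-")))
    d
  }
  dA <- maxdist(A); dB <- maxdist(B); dC <- maxdist(C)
  dJ <- pmax(dA, dB, dC)
  diag(dJ) <- Inf
  eps <- apply(dJ, 1L, function(r) sort(r, partial = k)[k])
  count_lt <- function(d) rowSums(sweep(d, 1L, eps, "<")) - 1L
  n_bc <- count_lt(pmax(dB, dC)); n_ac <- count_lt(pmax(dA, dC)); n_c <- count_lt(dC)
  cmi_nats <- digamma(k) + mean(digamma(n_c + 1) - digamma(n_bc + 1) -
                                  digamma(n_ac + 1))
  cmi_nats / log(2)
}

#' Transfer entropy between two series
#'
#' @param x source series (numeric vector).
#' @param y target series, same length.
#' @param params a \code{\link{te_params}}.
#' @return estimated transfer entropy from x to y in bits. Small negative
#'   estimator noise is possible; matrix-level reporting clamps at zero.
#' @export
transfer_entropy <- function(x, y, params = te_params()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant channel")
  emb <- te_embed(x, y, params)
  if (params$estimator == "binned") te_binned(emb, params$bins)
  else te_knn(emb, params$k)
}

#' Direct (conditional) transfer entropy
#'
#' Transfer entropy from x to y conditioned on the embedded pasts of a set of
#' other channels: \code{H(Y+|Y-,Z-) - H(Y+|X-,Y-,Z-)}. With an empty
#' conditioning set this equals \code{\link{transfer_entropy}} exactly.
#' Conditioning removes the part of the apparent X to Y information flow that
#' is routed through (or driven by) the Z channels.
#'
#' @param x,y source and target series.
#' @param cond list of conditioning series (possibly empty).
#' @param params a \code{\link{te_params}}.
#' @return direct transfer entropy in bits.
#' @export
direct_transfer_entropy <- function(x, y, cond = list(), params = te_params()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  cond <- lapply(cond, as.numeric)
  if (params$estimator == "binned") {
    dim_total <- 1L + params$l1 + params$l2 + length(cond) * params$l2
    if (dim_total > 12L)
      stop("embedded dimension ", dim_total,
           " too high for the binned estimator; use estimator = 'knn'")
  }
  emb <- te_embed(x, y, params, cond = cond)
  if (params$estimator == "binned") te_binned(emb, params$bins)
  else te_knn(emb, params$k)
}

#' Pairwise transfer-entropy matrix with surrogate significance
#'
#' @param series an \code{\link{mv_series}}.
#' @param params a \code{\link{te_params}}.
#' @param surrogate a \code{\link{surrogate_config}}; \code{NULL} skips
#'   thresholding (adjacency all FALSE, thresholds NA).
#' @return a \code{te_matrix}: \code{values[i, j]} = TE from channel i to
#'   channel j (from -> to, clamped at 0), raw values, per-pair thresholds
#'   and boolean adjacency.
#' @export
te_matrix <- function(series, params = te_params(), surrogate = NULL) {
  v <- series$values
  n <- nrow(v)
  vals <- matrix(0, n, n, dimnames = list(from = series$labels, to = series$labels))
  raw <- vals
  thr <- matrix(NA_real_, n, n, dimnames = dimnames(vals))
  adj <- matrix(FALSE, n, n, dimnames = dimnames(vals))
  # one surrogate bank per channel, shared across ordered pairs: the couple
  # members stay independent, which is what the null requires
  banks <- NULL
  if (!is.null(surrogate)) {
    if (!is.null(surrogate$seed)) set.seed(surrogate$seed)
    cfg <- surrogate; cfg$seed <- NULL
    banks <- lapply(seq_len(n), function(i)
      make_surrogates(v[i, ], cfg, surrogate$n_pairs))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    te <- transfer_entropy(v[i, ], v[j, ], params)
    raw[i, j] <- te
    vals[i, j] <- max(te, 0)
    if (!is.null(surrogate)) {
      null_vals <- vapply(seq_len(surrogate$n_pairs), function(r)
        transfer_entropy(banks[[i]][[r]], banks[[j]][[r]], params), 0)
      thr[i, j] <- mean(null_vals) + surrogate$multiplier * stats::sd(null_vals)
      adj[i, j] <- te > thr[i, j]
    }
  }
  structure(list(values = vals, raw = raw, threshold = thr, adjacency = adj,
                 params = params, labels = series$labels, banks = banks),
            class = "te_matrix")
}

#' Prune indirect edges from a TE graph with direct transfer entropy
#'
#' For every TE-significant edge X to Y, the conditioning set is every third
#' channel Z that is itself TE-linked as a common cause (Z to X and Z to Y)
#' or as a mediator (X to Z and Z to Y). The edge is kept only if the DTE
#' given that set exceeds its own surrogate threshold. Edges with an empty
#' conditioning set are kept as is.
#'
#' @param te_mat a \code{\link{te_matrix}} computed with surrogates.
#' @param series the same \code{\link{mv_series}} the TE matrix came from.
#' @param params a \code{\link{te_params}}.
#' @param surrogate a \code{\link{surrogate_config}} for the DTE thresholds.
#' @return the \code{te_matrix} with pruned \code{adjacency} (and a
#'   \code{dte} matrix of conditional values where evaluated).
#' @export
dte_prune <- function(te_mat, series, params = te_params(), surrogate) {
  adj <- te_mat$adjacency
  n <- nrow(adj)
  v <- series$values
  dte_vals <- matrix(NA_real_, n, n, dimnames = dimnames(adj))
  pruned <- adj
  banks <- te_mat$banks   # reuse the TE null ensembles where available
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!adj[i, j]) next
    zs <- setdiff(which((adj[, i] & adj[, j]) | (adj[i, ] & adj[, j])), c(i, j))
    if (!length(zs)) next
    cond <- lapply(zs, function(z) v[z, ])
    d <- direct_transfer_entropy(v[i, ], v[j, ], cond, params)
    dte_vals[i, j] <- d
    if (!is.null(banks)) {
      null_vals <- vapply(seq_len(surrogate$n_pairs), function(r)
        direct_transfer_entropy(banks[[i]][[r]], banks[[j]][[r]], cond, params), 0)
      thr <- mean(null_vals) + surrogate$multiplier * stats::sd(null_vals)
    } else {
      thr <- surrogate_threshold(
        function(a, b) direct_transfer_entropy(a, b, cond, params),
        v[i, ], v[j, ], surrogate)
    }
    pruned[i, j] <- d > thr
  }
  te_mat$adjacency <- pruned
  te_mat$dte <- dte_vals
  te_mat
}
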