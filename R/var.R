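# Multivariate autoregression and Granger causality.
#
# Each channel X_i(t) is regressed on the lagged values of all channels,
# X(t) = sum_l A_l X(t-l) + e(t). Granger causality from X_j to X_i is the
# log ratio of the residual variance of the restricted model (X_j excluded
# from the regressors) over that of the full model: F_{j->i} =
# ln(var(e_i^(j)) / var(e_i)); near zero means no predictive improvement.

lagged_design <- function(v, p) {
  # v: n x T matrix -> response (T-p) x n and regressors (T-p) x (n*p + 1)
  n <- nrow(v); T <- ncol(v)
  Y <- t(v[, (p + 1L):T, drop = FALSE])
  X <- matrix(1, nrow = T - p, ncol = n * p + 1L)
  for (l in seq_len(p))
    X[, ((l - 1L) * n + 2L):(l * n + 1L)] <- t(v[, (p + 1L - l):(T - l), drop = FALSE])
  list(Y = Y, X = X)
}

ols_fit <- function(Y, X) {
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    stop("rank-deficient design matrix (collinear or duplicated channels)")
  coef <- qr.coef(qr_X, Y)
  resid <- Y - X %*% coef
  list(coef = coef, resid = resid)
}

#' Fit a multivariate autoregression by least squares
#'
#' Per-channel ordinary least squares with an intercept on the lagged values
#' of every channel. The residual covariance uses denominator \code{T - p}.
#'
#' @param series an \code{\link{mv_series}} (or plain matrix, channels in rows).
#' @param p lag order, at least 1.
#' @return a \code{var_model}: coefficient array \code{A} (\code{n x n x p},
#'   \code{A[i, j, l]} = influence of channel j at lag l on channel i),
#'   intercept \code{c}, residuals (\code{n x (T - p)}), residual covariance,
#'   \code{bic}, and the data dimensions.
#' @export
fit_var <- function(series, p) {
  v <- if (inherits(series, "mv_series")) series$values else as.matrix(series)
  n <- nrow(v); T <- ncol(v)
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  if (T <= n * p + 1L) stop("insufficient samples for order ", p)
  d <- lagged_design(v, p)
  fit <- ols_fit(d$Y, d$X)
  Teff <- T - p
  A <- array(0, dim = c(n, n, p))
  for (l in seq_len(p))
    A[, , l] <- t(fit$coef[((l - 1L) * n + 2L):(l * n + 1L), , drop = FALSE])
  resid <- t(fit$resid)
  resid_cov <- tcrossprod(resid) / Teff
  sigma_ml <- tcrossprod(resid) / Teff
  k <- n * (n * p + 1L)
  bic <- Teff * determinant(sigma_ml, logarithm = TRUE)$modulus[1] + k * log(Teff)
  labels <- if (inherits(series, "mv_series")) series$labels else rownames(v)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  structure(list(p = p, A = A, intercept = fit$coef[1L, ], resid = resid,
                 resid_cov = resid_cov, bic = as.numeric(bic), n = n, T = T,
                 labels = labels,
                 fs = if (inherits(series, "mv_series")) series$fs else NA_real_),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> n=%d, p=%d, T=%d, BIC=%.2f\n", x$n, x$p, x$T, x$bic))
  invisible(x)
}

#' Select the MVAR lag order by BIC
#'
#' Scans orders 1..\code{p_max}, refitting the full model each time, and
#' returns the argmin of the Bayesian information criterion; ties break
#' toward the smaller (more parsimonious) order.
#'
#' @param series an \code{\link{mv_series}} or matrix.
#' @param p_max largest order to consider.
#' @return the selected integer order.
#' @export
select_order <- function(series, p_max) {
  v <- if (inherits(series, "mv_series")) series$values else as.matrix(series)
  p_max <- as.integer(p_max)
  if (p_max < 1L) stop("p_max must be >= 1")
  if (ncol(v) <= nrow(v) * p_max + 1L)
    stop("insufficient samples for p_max = ", p_max)
  bics <- vapply(seq_len(p_max), function(p) fit_var(v, p)$bic, 0)
  which.min(bics)  # first minimum = smallest order on ties
}

#' Spectral radius of the VAR companion matrix
#'
#' @param model a \code{var_model}.
#' @return largest eigenvalue modulus; < 1 means the process is stable.
#' @export
var_spectral_radius <- function(model) {
  n <- model$n; p <- model$p
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[1:n, ((l - 1) * n + 1):(l * n)] <- model$A[, , l]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Bivariate Granger causality
#'
#' Compares the univariate autoregression of each series with the bivariate
#' model including the other series' past. The causality value is the log
#' ratio of restricted over full residual variances; significance is the
#' classical F test on the residual sums of squares with
#' \code{(p, T - 2p - 1)} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @param p lag order.
#' @param alpha significance level (per-pair, no correction).
#' @return data frame with one row per direction (\code{x->y}, \code{y->x}):
#'   \code{F} (log variance ratio), \code{pvalue}, \code{significant}.
#' @export
granger_pairwise <- function(x, y, p, alpha = 0.001) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must have equal length")
  T <- length(x)
  if (T <= 2L * p + 1L) stop("series too short for order ", p)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant channel")
  both <- rbind(x = x, y = y)
  full <- fit_var(both, p)
  dir_stats <- function(target_idx, source_idx) {
    tv <- both[target_idx, , drop = FALSE]
    restr <- fit_var(tv, p)
    # align samples: both models conditioned on the first p values
    rss_r <- sum(restr$resid[1L, ]^2)
    rss_f <- sum(full$resid[target_idx, ]^2)
    Teff <- T - p
    Fgc <- log(rss_r / rss_f)
    df2 <- T - 2L * p - 1L
    f_stat <- ((rss_r - rss_f) / p) / (rss_f / df2)
    pval <- stats::pf(f_stat, p, df2, lower.tail = FALSE)
    c(F = Fgc, pvalue = pval)
  }
  xy <- dir_stats(2L, 1L)  # x -> y: does x improve prediction of y
  yx <- dir_stats(1L, 2L)
  out <- data.frame(direction = c("x->y", "y->x"),
                    F = c(xy["F"], yx["F"]),
                    pvalue = c(xy["pvalue"], yx["pvalue"]))
  out$significant <- out$pvalue < alpha
  rownames(out) <- NULL
  out
}

#' Multivariate Granger causality
#'
#' For every ordered pair (j to i) the full n-channel model is compared with
#' the restricted model that excludes channel j from the regressor set.
#' \code{F[i, j]} = ln(var(e_i^(j)) / var(e_i)); the likelihood-ratio
#' statistic \code{(T - p) * F} is referred to a chi-squared distribution
#' with \code{p} degrees of freedom.
#'
#' @param series an \code{\link{mv_series}} or matrix (channels in rows).
#' @param p lag order; if \code{NULL}, chosen by \code{\link{select_order}}
#'   with \code{p_max}.
#' @param alpha per-pair significance level.
#' @param p_max order scan bound when \code{p} is \code{NULL}.
#' @param correction \code{"none"} (default) or \code{"bonferroni"} across the
#'   \code{n(n-1)} ordered pairs.
#' @return a \code{gc_matrix}: \code{F} and \code{pvalue} matrices in the
#'   target-by-source layout (\code{F[i, j]} = causality j to i, diagonal 0),
#'   boolean \code{adjacency}, \code{alpha}, \code{p}, labels.
#' @export
granger_multivariate <- function(series, p = NULL, alpha = 0.001, p_max = 10L,
                                 correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  v <- if (inherits(series, "mv_series")) series$values else as.matrix(series)
  n <- nrow(v); T <- ncol(v)
  if (is.null(p)) p <- select_order(v, p_max)
  if (T <= n * (p + 1L)) stop("insufficient samples")
  full <- fit_var(v, p)
  var_full <- apply(full$resid, 1L, function(e) sum(e^2)) / (T - p)
  Fm <- matrix(0, n, n); pv <- matrix(1, n, n)
  labels <- if (inherits(series, "mv_series")) series$labels else
    rownames(v) %||% paste0("ch", seq_len(n))
  dimnames(Fm) <- dimnames(pv) <- list(target = labels, source = labels)
  for (j in seq_len(n)) {
    restr <- fit_var(v[-j, , drop = FALSE], p)
    var_restr <- apply(restr$resid, 1L, function(e) sum(e^2)) / (T - p)
    others <- setdiff(seq_len(n), j)
    for (k in seq_along(others)) {
      i <- others[k]
      Fm[i, j] <- log(var_restr[k] / var_full[i])
      stat <- (T - p) * max(Fm[i, j], 0)
      pv[i, j] <- stats::pchisq(stat, df = p, lower.tail = FALSE)
    }
  }
  alpha_eff <- if (correction == "bonferroni") alpha / (n * (n - 1L)) else alpha
  adj <- pv < alpha_eff
  diag(adj) <- FALSE
  structure(list(F = Fm, pvalue = pv, adjacency = adj, alpha = alpha,
                 correction = correction, p = p, labels = labels,
                 model = full),
            class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf("<gc_matrix> %d channels, order p=%d, alpha=%g, %d significant edges\n",
              length(x$labels), x$p, x$alpha, sum(x$adjacency)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
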