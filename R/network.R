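# Causal graphs, information outflow and root-cause / SOZ ranking.
#
# The node statistic driving root-cause analysis is the causal information
# outflow: outflow(X_i) = sum_{j != i} Causality(X_i -> X_j). On a causal
# graph the designated root should dominate the outflow ranking; on sliding
# windows the per-window outflow traces the driving force of each channel
# over time.

#' Scalar causal-strength matrix
#'
#' The common container for aggregated causality between every ordered pair,
#' always oriented from -> to: \code{values[i, j]} is the strength of
#' channel i driving channel j.
#'
#' @param values square numeric matrix (from in rows, to in columns).
#' @param labels channel labels.
#' @param method provenance tag (e.g. "MVGC", "ffDTF").
#' @param adjacency optional boolean significance matrix, same shape.
#' @param pvalue optional p-value matrix, same shape.
#' @return a \code{causal_matrix}.
#' @export
causal_matrix <- function(values, labels = NULL, method = "unknown",
                          adjacency = NULL, pvalue = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("causal matrix must be square")
  n <- nrow(values)
  labels <- labels %||% rownames(values) %||% paste0("ch", seq_len(n))
  if (length(labels) != n) stop("labels do not match matrix size")
  dimnames(values) <- list(from = labels, to = labels)
  diag(values) <- 0
  if (!is.null(adjacency)) {
    if (!all(dim(adjacency) == n)) stop("adjacency shape mismatch")
    dimnames(adjacency) <- dimnames(values)
    diag(adjacency) <- FALSE
  }
  structure(list(values = values, labels = labels, method = method,
                 adjacency = adjacency, pvalue = pvalue),
            class = "causal_matrix")
}

#' @export
print.causal_matrix <- function(x, ...) {
  cat(sprintf("<causal_matrix:%s> %d channels%s\n", x$method, length(x$labels),
              if (!is.null(x$adjacency))
                sprintf(", %d significant edges", sum(x$adjacency)) else ""))
  invisible(x)
}

#' Convert method results to a causal matrix
#'
#' Transposes target-by-source layouts (Granger, DTF/PDC aggregates) into
#' the uniform from -> to orientation.
#'
#' @param x a \code{gc_matrix}, \code{te_matrix} or \code{causal_matrix}.
#' @param ... unused.
#' @return a \code{\link{causal_matrix}}.
#' @export
as_causal_matrix <- function(x, ...) UseMethod("as_causal_matrix")

#' @export
as_causal_matrix.causal_matrix <- function(x, ...) x

#' @export
as_causal_matrix.gc_matrix <- function(x, ...) {
  causal_matrix(t(pmax(x$F, 0)), labels = x$labels, method = "MVGC",
                adjacency = t(x$adjacency), pvalue = t(x$pvalue))
}

#' @export
as_causal_matrix.te_matrix <- function(x, ...) {
  causal_matrix(x$values, labels = x$labels, method = "TE",
                adjacency = if (any(is.finite(x$threshold))) x$adjacency else NULL)
}

#' Build a causal graph from a causal matrix
#'
#' One directed edge per significant ordered pair, weighted by the measure
#' value; the diagonal is ignored (no self-loops).
#'
#' @param cm a \code{\link{causal_matrix}} (or coercible object).
#' @param adjacency optional boolean matrix overriding \code{cm$adjacency};
#'   when neither exists, every positive off-diagonal weight becomes an edge.
#' @return a \code{causal_graph}: \code{nodes}, \code{edges} data frame
#'   (from, to, weight, significant), \code{method}.
#' @export
build_graph <- function(cm, adjacency = NULL) {
  cm <- as_causal_matrix(cm)
  n <- length(cm$labels)
  adj <- adjacency %||% cm$adjacency %||% (cm$values > 0)
  if (!all(dim(adj) == n)) stop("adjacency shape mismatch")
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = cm$labels[idx[, 1L]], to = cm$labels[idx[, 2L]],
                      weight = cm$values[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = cm$labels, edges = edges, method = cm$method),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph:%s> %d nodes, %d edges\n", x$method,
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Causal information outflow per node
#'
#' \code{outflow_i = sum_{j != i} causality(i -> j)}, optionally restricted
#' to significant edges (graph mode) or using the raw continuous measure
#' (heatmap mode).
#'
#' @param cm a \code{\link{causal_matrix}} (or coercible).
#' @param exclude_nonsignificant if TRUE and an adjacency is present,
#'   non-significant entries contribute zero.
#' @return named numeric vector of per-node outflow.
#' @export
information_outflow <- function(cm, exclude_nonsignificant = FALSE) {
  cm <- as_causal_matrix(cm)
  v <- cm$values
  if (exclude_nonsignificant && !is.null(cm$adjacency)) v <- v * cm$adjacency
  diag(v) <- 0
  rowSums(v)
}

#' Per-node outflow curves over frequency
#'
#' For a spectral causality measure (values\[target, source, f\]), the
#' outflow of source j at frequency f is the sum over targets i != j.
#'
#' @param spec_mat a \code{spectral_causality}.
#' @return matrix node x frequency; attribute \code{"freqs"}.
#' @export
outflow_spectrum <- function(spec_mat) {
  vals <- spec_mat$values
  n <- dim(vals)[1L]; F <- dim(vals)[3L]
  out <- matrix(0, n, F, dimnames = list(spec_mat$labels, NULL))
  for (k in seq_len(F)) {
    m <- vals[, , k, drop = FALSE][, , 1L, drop = FALSE]
    dim(m) <- c(n, n)
    diag(m) <- 0
    out[, k] <- colSums(m)     # column j = source j's outflow to all targets
  }
  attr(out, "freqs") <- spec_mat$freqs
  out
}

# One-window causal matrix for a named method (continuous, unthresholded).
window_causal_matrix <- function(win, method, method_params = list(), band = NULL) {
  mp <- method_params
  if (method %in% c("mvgc", "gc")) {
    p <- mp$p %||% select_order(win, mp$p_max %||% 8L)
    return(as_causal_matrix(granger_multivariate(win, p = p,
                                                 alpha = mp$alpha %||% 0.001)))
  }
  if (method == "te") {
    return(as_causal_matrix(te_matrix(win, params = mp$te %||% te_params())))
  }
  if (method %in% c("dtf", "pdc", "ffdtf", "swdtf", "swpdc")) {
    p <- mp$p %||% select_order(win, mp$p_max %||% 8L)
    sm <- var_to_spectral(fit_var(win, p), fs = win$fs, freqs = mp$freqs)
    band <- band %||% band_spec(min(sm$freqs), max(sm$freqs))
    base <- switch(method,
                   dtf = dtf(sm),
                   pdc = pdc(sm),
                   ffdtf = ffdtf(sm, band),
                   swdtf = spectrum_weighted(dtf(sm), sm, band),
                   swpdc = spectrum_weighted(pdc(sm), sm, band))
    return(band_aggregate(base, band))
  }
  stop("unknown method: ", method)
}

#' Sliding-window dynamic outflow
#'
#' Estimates the chosen causality measure independently in every window,
#' aggregates spectral measures over the band, and records each channel's
#' information outflow, producing the node x window map that traces the
#' driving force of each channel over time. A window where estimation fails
#' is flagged and reported as NA rather than aborting the sweep.
#'
#' @param series an \code{\link{mv_series}}.
#' @param win_spec a \code{\link{window_spec}}.
#' @param method one of \code{"mvgc"}, \code{"te"}, \code{"dtf"},
#'   \code{"pdc"}, \code{"ffdtf"}, \code{"swdtf"}, \code{"swpdc"}.
#' @param method_params list of method parameters (\code{p} or \code{p_max},
#'   \code{alpha}, \code{te}, \code{freqs}).
#' @param band a \code{\link{band_spec}} for spectral aggregation.
#' @return an \code{outflow_map}: \code{outflow} (node x window matrix),
#'   \code{starts_s}, \code{width_s}, \code{failed} (logical per window).
#' @export
dynamic_outflow <- function(series, win_spec, method, method_params = list(),
                            band = NULL) {
  wins <- sliding_windows(series, win_spec)
  n <- n_channels(series)
  out <- matrix(NA_real_, n, length(wins),
                dimnames = list(series$labels, NULL))
  failed <- logical(length(wins))
  for (k in seq_along(wins)) {
    res <- tryCatch(
      information_outflow(window_causal_matrix(wins[[k]], method,
                                               method_params, band)),
      error = function(e) e)
    if (inherits(res, "error")) failed[k] <- TRUE else out[, k] <- res
  }
  structure(list(outflow = out,
                 starts_s = vapply(wins, `[[`, 0, "t0"),
                 width_s = win_spec$width_s, method = method,
                 failed = failed, labels = series$labels),
            class = "outflow_map")
}

#' @export
print.outflow_map <- function(x, ...) {
  cat(sprintf("<outflow_map:%s> %d nodes x %d windows (%d failed)\n",
              x$method, nrow(x$outflow), ncol(x$outflow), sum(x$failed)))
  invisible(x)
}

#' Rank candidate source nodes from a dynamic outflow map
#'
#' Windows are assigned to epochs by their midpoints; nodes are ranked by
#' their median outflow within the ranking epoch (by default the epoch named
#' \code{"ictal"} when present, otherwise all windows pooled). Per-node,
#' per-epoch quartile summaries support boxplot-style reporting.
#'
#' @param om an \code{outflow_map} from \code{\link{dynamic_outflow}}.
#' @param epochs data frame with columns \code{name}, \code{start_s},
#'   \code{end_s}; \code{NULL} pools everything into one epoch.
#' @param rank_epoch epoch name used for the ranking.
#' @return a \code{source_ranking}: \code{ranking} (node names, strongest
#'   first), \code{median_outflow}, \code{summaries} data frame (node,
#'   epoch, n, q1, median, q3).
#' @export
rank_sources <- function(om, epochs = NULL, rank_epoch = NULL) {
  mids <- om$starts_s + om$width_s / 2
  if (is.null(epochs))
    epochs <- data.frame(name = "all", start_s = -Inf, end_s = Inf)
  assign_epoch <- rep(NA_character_, length(mids))
  for (r in seq_len(nrow(epochs))) {
    inside <- mids >= epochs$start_s[r] & mids < epochs$end_s[r]
    assign_epoch[inside] <- epochs$name[r]
  }
  for (nm in epochs$name)
    if (!any(assign_epoch == nm, na.rm = TRUE))
      stop("epoch '", nm, "' contains no windows")
  rank_epoch <- rank_epoch %||%
    (if ("ictal" %in% epochs$name) "ictal" else epochs$name[1L])
  rows <- list()
  for (nm in unique(stats::na.omit(assign_epoch))) {
    cols <- which(assign_epoch == nm & !om$failed)
    q <- apply(om$outflow[, cols, drop = FALSE], 1L,
               stats::quantile, probs = c(.25, .5, .75), na.rm = TRUE)
    rows[[nm]] <- data.frame(node = om$labels, epoch = nm, n = length(cols),
                             q1 = q[1L, ], median = q[2L, ], q3 = q[3L, ],
                             row.names = NULL)
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  med <- summaries$median[summaries$epoch == rank_epoch]
  names(med) <- summaries$node[summaries$epoch == rank_epoch]
  ranking <- names(sort(med, decreasing = TRUE))
  structure(list(ranking = ranking, median_outflow = sort(med, decreasing = TRUE),
                 rank_epoch = rank_epoch, summaries = summaries),
            class = "source_ranking")
}

#' @export
print.source_ranking <- function(x, ...) {
  cat(sprintf("<source_ranking> epoch '%s': %s\n", x$rank_epoch,
              paste(utils::head(x$ranking, 6), collapse = " > ")))
  invisible(x)
}

# Chu-Liu/Edmonds maximum-weight spanning arborescence, rooted at `root`.
# Edges are parallel vectors (from, to, weight) over integer node ids; every
# non-root node is assumed reachable from the root (the caller restricts to
# the reachable subgraph). Returns indices into the original edge vectors.
# On contraction, each edge carries (a) its original id and (b) for edges
# entering the cycle, the cycle node it actually enters, so the expansion
# step knows which within-cycle best edge to drop.
edmonds_max_arborescence <- function(n, from, to, weight, root) {
  E <- data.frame(from = from, to = to, w = weight, id = seq_along(from),
                  enters = to)   # `enters`: true target node at this level
  E <- E[E$to != root & E$from != E$to, , drop = FALSE]
  recurse <- function(n, E, root) {
    if (!nrow(E)) return(integer(0))
    parent <- rep(NA_integer_, n)
    best <- rep(NA_integer_, n)        # row index into E of best incoming edge
    for (v in setdiff(sort(unique(E$to)), root)) {
      cand <- which(E$to == v)
      b <- cand[which.max(E$w[cand])]
      parent[v] <- E$from[b]; best[v] <- b
    }
    cycle <- NULL
    for (v in which(!is.na(parent))) {
      path <- integer(0); u <- v
      while (!is.na(u) && !(u %in% path)) { path <- c(path, u); u <- parent[u] }
      if (!is.na(u) && u != root && u %in% path) {
        cycle <- path[which(path == u):length(path)]; break
      }
    }
    if (is.null(cycle)) return(E$id[stats::na.omit(best)])
    super <- n + 1L
    in_cycle <- function(v) v %in% cycle
    E2 <- E
    entering <- vapply(seq_len(nrow(E)), function(r)
      in_cycle(E$to[r]) && !in_cycle(E$from[r]), TRUE)
    # reduced weight for edges entering the cycle
    E2$w[entering] <- E$w[entering] -
      vapply(which(entering), function(r) E$w[best[E$to[r]]], 0)
    E2$enters[entering] <- E$to[entering]    # remember true entry node
    E2$to[vapply(E$to, in_cycle, TRUE)] <- super
    E2$from[vapply(E$from, in_cycle, TRUE)] <- super
    E2 <- E2[E2$from != E2$to, , drop = FALSE]
    sel_ids <- recurse(super, E2, root)
    # which selected edge enters the supernode? find its true entry point
    sel_rows <- match(sel_ids, E$id)
    enter_row <- sel_rows[vapply(sel_rows, function(r)
      in_cycle(E$to[r]) && !in_cycle(E$from[r]), TRUE)]
    drop_node <- if (length(enter_row)) E$to[enter_row[1L]] else cycle[1L]
    cyc_edge_ids <- E$id[best[setdiff(cycle, drop_node)]]
    c(sel_ids, cyc_edge_ids)
  }
  recurse(n, E, root)
}

#' Propagation path from a root node
#'
#' Extracts the maximum-weight spanning arborescence rooted at the given
#' node over the graph's significant edges: the highest-total-strength
#' directed tree along which the fault or seizure most plausibly spread.
#' Nodes unreachable from the root are reported separately.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param root node label.
#' @return a \code{propagation_path}: \code{edges} (tree rows of the graph's
#'   edge frame), \code{order} (nodes in breadth-first spread order),
#'   \code{unreachable}.
#' @export
propagation_path <- function(graph, root) {
  if (!root %in% graph$nodes) stop("root not in graph: ", root)
  nodes <- graph$nodes
  e <- graph$edges
  fi <- match(e$from, nodes); ti <- match(e$to, nodes)
  # reachable subgraph first
  reach <- match(root, nodes)
  repeat {
    nxt <- unique(c(reach, ti[fi %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  unreachable <- nodes[-reach]
  sub <- which(fi %in% reach & ti %in% reach)
  if (length(sub)) {
    remap <- match(seq_along(nodes), reach)
    sel <- edmonds_max_arborescence(length(reach), remap[fi[sub]],
                                    remap[ti[sub]], e$weight[sub],
                                    remap[match(root, nodes)])
    tree <- e[sub[sel], , drop = FALSE]
  } else tree <- e[0, , drop = FALSE]
  # breadth-first spread order
  ord <- root; frontier <- root
  while (length(frontier)) {
    frontier <- tree$to[tree$from %in% frontier]
    ord <- c(ord, frontier)
  }
  structure(list(edges = tree, order = unique(ord), root = root,
                 unreachable = unreachable),
            class = "propagation_path")
}

#' Compare a detected graph with ground truth
#'
#' Directed-edge set arithmetic: true/false positives, false negatives,
#' precision and recall.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param truth_edges data frame with columns \code{from}, \code{to}.
#' @return an \code{eval_report} with counts, rates, and matched/unmatched
#'   edge lists.
#' @export
evaluate_edges <- function(graph, truth_edges) {
  unknown <- setdiff(unique(c(truth_edges$from, truth_edges$to)), graph$nodes)
  if (length(unknown)) stop("unknown node(s) in truth set: ",
                            paste(unknown, collapse = ", "))
  key <- function(d) paste(d$from, d$to, sep = "->")
  det <- unique(key(graph$edges)); tru <- unique(key(truth_edges))
  tp <- intersect(det, tru)
  structure(list(tp = length(tp), fp = length(setdiff(det, tru)),
                 fn = length(setdiff(tru, det)),
                 precision = if (length(det)) length(tp) / length(det) else NA_real_,
                 recall = if (length(tru)) length(tp) / length(tru) else NA_real_,
                 matched = tp, false_positives = setdiff(det, tru),
                 missed = setdiff(tru, det)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> tp=%d fp=%d fn=%d precision=%.3f recall=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}
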