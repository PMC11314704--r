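test_that("graphs carry one edge per significant pair and round-trip", {
  vals <- matrix(c(0, 2, 3, 0, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  adj <- vals > 0
  cm <- causal_matrix(vals, labels = c("a", "b", "c"), method = "x",
                      adjacency = adj)
  g <- build_graph(cm)
  expect_equal(nrow(g$edges), 3)
  # empty adjacency -> empty edge set
  g0 <- build_graph(cm, adjacency = matrix(FALSE, 3, 3))
  expect_equal(nrow(g0$edges), 0)
  # round-trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(g$edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$from, g$edges$from)
  expect_equal(back$to, g$edges$to)
  expect_equal(back$weight, g$edges$weight, tolerance = 1e-12)
})

test_that("information outflow sums outgoing strengths", {
  # star: hub drives 4 leaves with equal weight
  vals <- matrix(0, 5, 5); vals[1, 2:5] <- 2.5
  cm <- causal_matrix(vals, labels = letters[1:5], method = "star")
  out <- information_outflow(cm)
  expect_equal(unname(out), c(10, 0, 0, 0, 0))
  # permutation invariance
  perm <- c(3, 1, 5, 4, 2)
  cmp <- causal_matrix(vals[perm, perm], labels = letters[1:5][perm])
  expect_equal(information_outflow(cmp), out[perm], ignore_attr = TRUE)
  # significance-masked mode
  adj <- vals > 0; adj[1, 2] <- FALSE
  cm2 <- causal_matrix(vals, labels = letters[1:5], adjacency = adj)
  expect_equal(unname(information_outflow(cm2, exclude_nonsignificant = TRUE))[1],
               7.5)
  # outflow conservation: total outflow equals total edge weight
  g <- build_graph(cm)
  expect_equal(sum(information_outflow(cm)), sum(g$edges$weight))
})

test_that("spectral outflow sums to the band-aggregated outflow", {
  m <- random_var_model(4, 2, seed = 31)
  sm <- var_to_spectral(m, fs = 1, freqs = seq(0, 0.5, length.out = 65))
  d <- dtf(sm)
  os <- outflow_spectrum(d)
  agg <- band_aggregate(d)
  expect_equal(rowSums(os), information_outflow(agg), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("propagation path equals exhaustive arborescence enumeration", {
  enum_best_weight <- function(nodes, edges, root) {
    nonroot <- setdiff(nodes, root)
    if (!length(nonroot)) return(0)
    cands <- lapply(nonroot, function(v) which(edges$to == v))
    if (any(lengths(cands) == 0)) return(NA_real_)
    grid <- do.call(expand.grid, cands)
    bw <- -Inf
    for (r in seq_len(nrow(grid))) {
      sel <- unlist(grid[r, ])
      reach <- root
      repeat {
        nx <- unique(c(reach, edges$to[sel][edges$from[sel] %in% reach]))
        if (length(nx) == length(reach)) break
        reach <- nx
      }
      if (length(reach) == length(nodes)) bw <- max(bw, sum(edges$weight[sel]))
    }
    bw
  }
  set.seed(42)
  for (trial in 1:30) {
    n <- sample(3:5, 1)
    pairs <- expand.grid(from = 1:n, to = 1:n)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample(nrow(pairs), sample(4:nrow(pairs), 1)), ]
    edges <- data.frame(from = letters[pick$from], to = letters[pick$to],
                        weight = round(runif(nrow(pick), 0.1, 1), 3))
    g <- structure(list(nodes = letters[1:n], edges = edges, method = "t"),
                   class = "causal_graph")
    pp <- propagation_path(g, "a")
    reach <- setdiff(letters[1:n], pp$unreachable)
    sub <- edges[edges$from %in% reach & edges$to %in% reach, ]
    ref <- enum_best_weight(reach, sub, "a")
    expect_equal(sum(pp$edges$weight), ref, tolerance = 1e-9)
    # result is a tree over reachable nodes: one incoming edge per non-root
    expect_equal(sort(pp$edges$to), sort(setdiff(reach, "a")))
  }
})

test_that("chain and star graphs give their own propagation paths", {
  chain <- structure(list(nodes = c("a", "b", "c"),
                          edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                             weight = c(1, 1)),
                          method = "t"), class = "causal_graph")
  pp <- propagation_path(chain, "a")
  expect_equal(pp$order, c("a", "b", "c"))
  star <- structure(list(nodes = letters[1:4],
                         edges = data.frame(from = "a", to = c("b", "c", "d"),
                                            weight = 1:3),
                         method = "t"), class = "causal_graph")
  pp2 <- propagation_path(star, "a")
  expect_equal(nrow(pp2$edges), 3)
  expect_true(all(pp2$edges$from == "a"))
  expect_error(propagation_path(star, "z"), "root")
})

test_that("edge evaluation matches brute-force set arithmetic", {
  set.seed(8)
  for (trial in 1:10) {
    nodes <- letters[1:6]
    all_pairs <- expand.grid(from = nodes, to = nodes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
    det <- all_pairs[sample(nrow(all_pairs), 8), ]
    tru <- all_pairs[sample(nrow(all_pairs), 6), ]
    g <- structure(list(nodes = nodes,
                        edges = cbind(det, weight = 1), method = "t"),
                   class = "causal_graph")
    rep <- evaluate_edges(g, tru)
    key <- function(d) paste(d$from, d$to)
    expect_equal(rep$tp, length(intersect(key(det), key(tru))))
    expect_equal(rep$fp, length(setdiff(key(det), key(tru))))
    expect_equal(rep$fn, length(setdiff(key(tru), key(det))))
    expect_equal(rep$precision, rep$tp / (rep$tp + rep$fp))
    expect_equal(rep$recall, rep$tp / (rep$tp + rep$fn))
  }
  g1 <- structure(list(nodes = c("a", "b"),
                       edges = data.frame(from = "a", to = "b", weight = 1),
                       method = "t"), class = "causal_graph")
  expect_error(evaluate_edges(g1, data.frame(from = "a", to = "zz")), "unknown")
})

test_that("dynamic outflow with a single window equals the static pipeline", {
  sim <- gen_var_network(recovery_spec(), T = 1000, seed = 2, fs = 1)
  s <- sim$series
  om <- dynamic_outflow(s, window_spec(1000, 1000), "dtf",
                        method_params = list(p = 2))
  static <- information_outflow(band_aggregate(
    dtf(var_to_spectral(fit_var(s, 2), fs = 1))))
  expect_equal(ncol(om$outflow), 1)
  expect_equal(om$outflow[, 1], static, tolerance = 1e-10)
})

test_that("stationary networks give flat outflow profiles", {
  sim <- gen_var_network(recovery_spec(), T = 6000, seed = 3, fs = 100)
  om <- dynamic_outflow(sim$series, window_spec(10, 10), "dtf",
                        method_params = list(p = 2))
  expect_equal(ncol(om$outflow), 6)
  expect_false(any(om$failed))
  # per-node relative spread across windows stays modest
  rel_spread <- apply(om$outflow, 1, function(r) sd(r) / max(mean(r), 1e-9))
  expect_lt(max(rel_spread), 0.5)
})

test_that("switching sources dominate the ictal epoch and relax after", {
  spec <- switching_demo_spec()
  sim <- gen_switching_network(spec, fs = 250, T = 15000, seed = 4)
  om <- dynamic_outflow(sim$series, window_spec(5, 1), "ffdtf",
                        method_params = list(p = 3), band = band_spec(1, 30))
  expect_false(any(om$failed))
  rk <- rank_sources(om, spec$epochs)
  expect_setequal(head(rk$ranking, 2), c("ch1", "ch2"))
  gap <- function(ep) {
    m <- rk$summaries[rk$summaries$epoch == ep, ]
    mean(m$median[m$node %in% c("ch1", "ch2")]) -
      mean(m$median[!m$node %in% c("ch1", "ch2")])
  }
  expect_gt(gap("ictal"), gap("postictal"))   # driving force declines postictally
  expect_gt(gap("ictal"), gap("preictal"))
  expect_error(rank_sources(om, data.frame(name = "late", start_s = 100,
                                           end_s = 200)), "no windows")
})
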