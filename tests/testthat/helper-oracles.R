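# Independent oracles and small fixture builders used across tests.
# These deliberately use naive formulations (double loops, exhaustive
# enumeration, direct pair counting) so they share no code path with the
# package implementations they check.

# raster with given values (vector filled column-major) and geometry
rg <- function(values, nr, nc, ...) {
  raster_grid(matrix(values, nr, nc), ...)
}

# exhaustive simple-path minimum cost between two nodes of a
# conductance_graph, by depth-first enumeration over the edge list
brute_force_lcp_cost <- function(g, src_node, dst_node) {
  e <- g$edges
  n <- length(g$cells)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- rbind(adj[[e$from[k]]], c(e$to[k], e$cost[k]))
    adj[[e$to[k]]] <- rbind(adj[[e$to[k]]], c(e$from[k], e$cost[k]))
  }
  best <- Inf
  visited <- rep(FALSE, n)
  dfs <- function(node, cost) {
    if (cost >= best) return()
    if (node == dst_node) { best <<- cost; return() }
    visited[node] <<- TRUE
    nb <- adj[[node]]
    if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
      nxt <- nb[k, 1]
      if (!visited[nxt]) dfs(nxt, cost + nb[k, 2])
    }
    visited[node] <<- FALSE
  }
  dfs(src_node, 0)
  best
}

# naive double-loop Moran's I over a dense weight matrix
loop_morans_i <- function(x, wm) {
  n <- length(x); z <- x - mean(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + wm[i, j] * z[i] * z[j]
  (n / sum(wm)) * s / sum(z^2)
}

# naive double-loop Geary's C
loop_gearys_c <- function(x, wm) {
  n <- length(x); z <- x - mean(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + wm[i, j] * (x[i] - x[j])^2
  ((n - 1) / (2 * sum(wm))) * s / sum(z^2)
}

# AUC by direct concordant-pair counting
pair_count_auc <- function(sp, sb) {
  conc <- 0
  for (p in sp) for (b in sb)
    conc <- conc + if (p > b) 1 else if (p == b) 0.5 else 0
  conc / (length(sp) * length(sb))
}

# small presence/background design around a single informative predictor
toy_design <- function(n = 200, informative = TRUE, seed = 1, p_extra = 2) {
  set.seed(seed)
  label <- rep(c(1L, 0L), each = n / 2)
  x1 <- if (informative) rnorm(n, mean = 2 * label) else rnorm(n)
  x <- data.frame(x1 = x1)
  for (k in seq_len(p_extra)) x[[paste0("noise", k)]] <- rnorm(n)
  structure(list(x = x, label = label, month = 6L, predictors = names(x),
                 n_dropped = 0L),
            class = "sdm_design")
}

# manually assembled two-branch parallel circuit:
# node 1 = source, node 4 = ground; branch A via node 2 (two edges of
# conductance 2 => series conductance 1), branch B via node 3 (two edges of
# conductance 6 => series conductance 3)
parallel_branch_graph <- function() {
  edges <- data.frame(from = c(1L, 2L, 1L, 3L), to = c(2L, 4L, 3L, 4L),
                      length = 1, cost = c(0.5, 0.5, 1/6, 1/6),
                      conductance = c(2, 2, 6, 6))
  g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to),
                                   directed = FALSE)
  igraph::E(g)$cost <- edges$cost
  structure(list(graph = g, edges = edges, cells = 1:4,
                 node_of_cell = 1:4, n_rows = 1L, n_cols = 4L,
                 origin_lon = 0, origin_lat = 0, cell_size_deg = 1),
            class = "conductance_graph")
}
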