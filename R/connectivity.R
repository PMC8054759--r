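#' Seasonal conductance surface from monthly suitability rasters
#'
#' Cell-wise mean of the season's monthly suitability rasters (March--May
#' for spring, August--October for fall), floored at a small positive value
#' so every unmasked cell is traversable.
#'
#' @param monthly_sdms list of aligned monthly `raster_grid`s, named or
#'   indexed by month; for a named list the season's months are selected by
#'   name `"1"`..`"12"`.
#' @param season `"spring"` or `"fall"`.
#' @param floor_eps positivity floor applied to unmasked cells.
#' @return A `raster_grid` conductance surface.
#' @export
seasonal_conductance <- function(monthly_sdms, season = c("spring", "fall"),
                                 floor_eps = 1e-6) {
  season <- match.arg(season)
  months <- season_months(season)
  keys <- if (!is.null(names(monthly_sdms))) as.character(months) else months
  present <- if (!is.null(names(monthly_sdms)))
    keys %in% names(monthly_sdms) else months <= length(monthly_sdms)
  if (!all(present))
    stop("missing month(s) for ", season, " conductance: ",
         paste(months[!present], collapse = ", "), call. = FALSE)
  rs <- lapply(keys, function(k) monthly_sdms[[k]])
  for (r in rs[-1]) check_aligned(rs[[1L]], r)
  acc <- Reduce(`+`, lapply(rs, `[[`, "values")) / length(rs)
  ok <- is.finite(acc)
  acc[ok] <- pmax(acc[ok], floor_eps)
  set_values(rs[[1L]], acc)
}

#' Monotone transforms of a conductance surface
#'
#' Optional square-root, base-10 log, natural-log or cube-root transform,
#' rescaled back onto (0, 1] so the result remains a valid conductance.
#'
#' @param r positive `raster_grid`.
#' @param transform transform name.
#' @param floor_eps positivity floor after rescaling.
#' @return A `raster_grid`.
#' @export
transform_conductance <- function(r, transform = c("none", "sqrt", "log",
                                                   "ln", "cbrt"),
                                  floor_eps = 1e-6) {
  transform <- match.arg(transform)
  if (transform == "none") return(r)
  v <- r$values
  ok <- is.finite(v)
  if (any(v[ok] <= 0)) stop("conductance must be positive", call. = FALSE)
  t <- switch(transform, sqrt = sqrt(v), log = log10(v), ln = log(v),
              cbrt = v^(1 / 3))
  lo <- min(t[ok]); hi <- max(t[ok])
  v[ok] <- if (hi > lo) (t[ok] - lo) / (hi - lo) * (1 - floor_eps) + floor_eps
           else 1
  set_values(r, v)
}

#' Build the 8-connected conductance graph of a raster
#'
#' One node per unmasked cell; edges join 8-neighbouring unmasked cells.
#' Edge length is 1 cell for rook moves and sqrt(2) for diagonal moves;
#' edge cost = length x mean of the endpoint resistances (1/conductance);
#' edge conductance = mean of the endpoint conductances / length. LCP and
#' circuit analyses share this one graph.
#'
#' @param conductance `raster_grid`, positive on unmasked cells.
#' @return An object of class `conductance_graph`: list with the `igraph`
#'   graph (edge attribute `cost`), `edges` data.frame (`from`, `to`,
#'   `length`, `cost`, `conductance` over node ids), `cells` (linear
#'   column-major cell index per node), `node_of_cell` (reverse lookup),
#'   and the raster geometry.
#' @export
build_graph <- function(conductance) {
  stopifnot(inherits(conductance, "raster_grid"))
  v <- conductance$values
  nr <- nrow(v); nc <- ncol(v)
  valid <- is.finite(v)
  if (!any(valid)) stop("empty graph: all cells masked", call. = FALSE)
  if (any(v[valid] <= 0))
    stop("conductance must be > 0 on unmasked cells", call. = FALSE)
  node_of_cell <- rep(NA_integer_, nr * nc)
  cells <- which(valid)
  node_of_cell[cells] <- seq_along(cells)

  # neighbour offsets: E, S, SE, SW (each undirected pair counted once)
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))
  from <- to <- integer(0); len <- numeric(0)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  for (o in offs) {
    r2 <- row + o[1L]; c2 <- col + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    cell2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- !is.na(node_of_cell[cell2])
    from <- c(from, node_of_cell[cells[ok]][ok2])
    to <- c(to, node_of_cell[cell2][ok2])
    len <- c(len, rep(o[3L], sum(ok2)))
  }
  cv <- v[cells]
  resist <- 1 / cv
  cost <- len * (resist[from] + resist[to]) / 2
  cond <- ((cv[from] + cv[to]) / 2) / len
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(cells) - igraph::vcount(g)))
  igraph::E(g)$cost <- cost
  structure(list(graph = g,
                 edges = data.frame(from = from, to = to, length = len,
                                    cost = cost, conductance = cond),
                 cells = cells, node_of_cell = node_of_cell,
                 n_rows = nr, n_cols = nc,
                 origin_lon = conductance$origin_lon,
                 origin_lat = conductance$origin_lat,
                 cell_size_deg = conductance$cell_size_deg),
            class = "conductance_graph")
}

# coerce a cell specification to node ids on a conductance_graph:
# accepts a data.frame with row/col columns, with lon/lat columns, or a
# vector of linear cell indices.
as_nodes <- function(g, x) {
  nr <- g$n_rows
  if (is.data.frame(x) && all(c("row", "col") %in% names(x))) {
    cell <- (x$col - 1L) * nr + x$row
  } else if (is.data.frame(x) && all(c("lon", "lat") %in% names(x))) {
    col <- floor((x$lon - g$origin_lon) / g$cell_size_deg) + 1L
    row <- floor((g$origin_lat - x$lat) / g$cell_size_deg) + 1L
    out <- row < 1L | row > nr | col < 1L | col > g$n_cols
    cell <- ifelse(out, NA_integer_, (col - 1L) * nr + row)
  } else {
    cell <- as.integer(x)
  }
  g$node_of_cell[cell]
}

node_centers <- function(g, nodes) {
  cell <- g$cells[nodes]
  row <- (cell - 1L) %% g$n_rows + 1L
  col <- (cell - 1L) %/% g$n_rows + 1L
  data.frame(row = row, col = col,
             lon = g$origin_lon + (col - 0.5) * g$cell_size_deg,
             lat = g$origin_lat - (row - 0.5) * g$cell_size_deg)
}

graph_template <- function(g, fill = 0) {
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[g$cells] <- fill
  raster_grid(m, g$origin_lon, g$origin_lat, g$cell_size_deg)
}

#' Least-cost path between two cells
#'
#' Dijkstra shortest path on the conductance graph's accumulated-cost edge
#' weights.
#'
#' @param g a [build_graph()] result.
#' @param src,dst single-cell specifications (data.frame with `row`/`col` or
#'   `lon`/`lat`, or a linear cell index).
#' @return List with `nodes` (node id sequence, empty when `src == dst`),
#'   `cells` (linear cell indices) and `cost`.
#' @export
least_cost_path <- function(g, src, dst) {
  stopifnot(inherits(g, "conductance_graph"))
  s <- as_nodes(g, src); d <- as_nodes(g, dst)
  if (length(s) != 1L || length(d) != 1L || is.na(s) || is.na(d))
    stop("src and dst must each be one unmasked cell", call. = FALSE)
  if (s == d) return(list(nodes = integer(0), cells = integer(0), cost = 0))
  sp <- suppressWarnings(igraph::shortest_paths(
    g$graph, from = s, to = d, weights = igraph::E(g$graph)$cost,
    output = "both"))
  nodes <- as.integer(sp$vpath[[1L]])
  if (length(nodes) == 0L)
    stop("no path: destination unreachable from source", call. = FALSE)
  list(nodes = nodes, cells = g$cells[nodes],
       cost = sum(igraph::E(g$graph)$cost[as.integer(sp$epath[[1L]])]))
}

#' All-pairs least-cost paths and their density surface
#'
#' Computes one least-cost path per (winter point, summer point) pair and
#' aggregates them into a path-density raster: `density(cell)` = number of
#' paths traversing the cell. High-density cells trace the most likely
#' migratory pathway; cells with density >= 1 form the all-paths mask.
#'
#' @param g a [build_graph()] result.
#' @param winter,summer occurrence data.frames (`lon`/`lat`) or cell
#'   specifications; points on masked cells are skipped with a message.
#' @return List of class `path_set`: `pairs` data.frame (src/dst lon-lat,
#'   `cost`, `path_km`, `straight_km`), `density` `raster_grid`, and
#'   `all_paths_mask` (binary `raster_grid` of density >= 1).
#' @export
lcp_density <- function(g, winter, summer) {
  stopifnot(inherits(g, "conductance_graph"))
  wn <- as_nodes(g, winter); sn <- as_nodes(g, summer)
  if (anyNA(wn) || anyNA(sn)) {
    message(sum(is.na(wn)) + sum(is.na(sn)),
            " endpoint(s) on masked cells skipped")
    wn <- wn[!is.na(wn)]; sn <- sn[!is.na(sn)]
  }
  if (length(wn) == 0L || length(sn) == 0L)
    stop("no paths: no usable winter/summer endpoints", call. = FALSE)
  wu <- sort(unique(wn)); su <- sort(unique(sn))
  costs <- igraph::distances(g$graph, v = wu, to = su,
                             weights = igraph::E(g$graph)$cost)
  dens <- numeric(length(g$cells))
  pairs <- vector("list", length(wu))
  for (i in seq_along(wu)) {
    sp <- suppressWarnings(igraph::shortest_paths(
      g$graph, from = wu[i], to = su, weights = igraph::E(g$graph)$cost,
      output = "vpath"))
    mult_w <- sum(wn == wu[i]) # point multiplicity in this source cell
    path_km <- numeric(length(su))
    for (j in seq_along(su)) {
      nodes <- as.integer(sp$vpath[[j]])
      if (length(nodes) == 0L && wu[i] != su[j]) { path_km[j] <- NA; next }
      mult <- mult_w * sum(sn == su[j])
      dens[unique(nodes)] <- dens[unique(nodes)] + mult
      ctr <- node_centers(g, nodes)
      path_km[j] <- if (length(nodes) >= 2L)
        sum(geodesic_km(ctr$lon[-nrow(ctr)], ctr$lat[-nrow(ctr)],
                        ctr$lon[-1L], ctr$lat[-1L])) else 0
    }
    wc <- node_centers(g, wu[i]); sc <- node_centers(g, su)
    pairs[[i]] <- data.frame(
      src_lon = wc$lon, src_lat = wc$lat, dst_lon = sc$lon, dst_lat = sc$lat,
      cost = as.numeric(costs[i, ]), path_km = path_km,
      straight_km = geodesic_km(wc$lon, wc$lat, sc$lon, sc$lat),
      n_point_pairs = mult_w * vapply(su, function(s) sum(sn == s), 0L))
  }
  pairs <- do.call(rbind, pairs)
  failed <- !is.finite(pairs$cost)
  if (all(failed)) stop("no paths: all endpoint pairs unreachable", call. = FALSE)
  if (any(failed)) {
    message(sum(failed), " unreachable endpoint pair(s) skipped")
    pairs <- pairs[!failed, , drop = FALSE]
  }
  density <- graph_template(g)
  density$values[g$cells] <- dens
  mask <- set_values(density, (density$values >= 1) * 1)
  mask$values[!is.finite(density$values)] <- NA_real_
  structure(list(pairs = pairs, density = density, all_paths_mask = mask),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set: %d endpoint cell pairs (%d point pairs), mean cost %.3g\n",
              nrow(x$pairs), sum(x$pairs$n_point_pairs), mean(x$pairs$cost)))
  cat(sprintf("  mean path %.1f km vs straight %.1f km\n",
              mean(x$pairs$path_km), mean(x$pairs$straight_km)))
  invisible(x)
}

#' Circuit-theory current map
#'
#' Solves the Kirchhoff system on the conductance graph: ground cells fixed
#' at potential zero, total current `injection` split equally across source
#' cells. The per-cell current (half the sum of absolute incident edge
#' currents) measures movement likelihood through the cell.
#'
#' @param conductance `raster_grid` (a [build_graph()] result is also
#'   accepted).
#' @param sources,grounds non-empty, disjoint cell specifications.
#' @param injection total injected current (amperes).
#' @return List: `current` (`raster_grid` of node currents), `potential`
#'   (`raster_grid`), `effective_resistance` (mean source potential /
#'   injection).
#' @export
solve_current <- function(conductance, sources, grounds, injection = 1) {
  g <- if (inherits(conductance, "conductance_graph")) conductance
       else build_graph(conductance)
  src <- unique(as_nodes(g, sources)); gnd <- unique(as_nodes(g, grounds))
  src <- src[!is.na(src)]; gnd <- gnd[!is.na(gnd)]
  if (length(src) == 0L || length(gnd) == 0L)
    stop("sources and grounds must be non-empty", call. = FALSE)
  if (length(intersect(src, gnd)))
    stop("sources and grounds must be disjoint", call. = FALSE)
  n <- length(g$cells)
  e <- g$edges
  L <- Matrix::sparseMatrix(
    i = c(e$from, e$to, e$from, e$to),
    j = c(e$to, e$from, e$from, e$to),
    x = c(-e$conductance, -e$conductance, e$conductance, e$conductance),
    dims = c(n, n))
  keep <- setdiff(seq_len(n), gnd)
  rhs <- numeric(n)
  rhs[src] <- injection / length(src)
  comp <- igraph::components(g$graph)$membership
  if (!any(comp[gnd] %in% comp[src]))
    stop("singular system: sources disconnected from grounds", call. = FALSE)
  v <- numeric(n)
  sol <- try(Matrix::solve(L[keep, keep, drop = FALSE], rhs[keep]), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("singular system: sources disconnected from grounds", call. = FALSE)
  v[keep] <- as.numeric(sol)
  edge_abs <- abs(e$conductance * (v[e$from] - v[e$to]))
  node_cur <- numeric(n)
  acc <- tapply(c(edge_abs, edge_abs), c(e$from, e$to), sum)
  node_cur[as.integer(names(acc))] <- acc / 2
  current <- graph_template(g); current$values[g$cells] <- node_cur
  potential <- graph_template(g); potential$values[g$cells] <- v
  list(current = current, potential = potential,
       effective_resistance = mean(v[src]) / injection)
}

#' Binary mask of cells at or above a percentile
#'
#' @param suitability `raster_grid` with >= 2 distinct valid values.
#' @param q percentile in [0, 100] (default 95, the conventional
#'   high-suitability cutoff for corridor delineation).
#' @return Binary `raster_grid` (1 = at or above the q-th percentile).
#' @export
percentile_mask <- function(suitability, q = 95) {
  stopifnot(inherits(suitability, "raster_grid"))
  v <- suitability$values
  ok <- is.finite(v)
  if (length(unique(v[ok])) < 2L)
    stop("degenerate range: raster is constant", call. = FALSE)
  thr <- pctl(v, q)
  out <- ifelse(ok, (v >= thr) * 1, NA_real_)
  set_values(suitability, out)
}

#' Consensus of the three corridor methods
#'
#' Binarizes the LCP-density and current surfaces at their own percentile
#' thresholds and counts, per cell, how many of the three corridor methods
#' (LCP density, circuit current, percentile suitability mask) flag the
#' cell. Cells flagged by all three are the candidate corridors.
#'
#' @param density LCP-density `raster_grid`.
#' @param current circuit-current `raster_grid`.
#' @param mask binary percentile-suitability `raster_grid`.
#' @param density_q,current_q binarization percentiles (default 95).
#' @return An object of class `corridor_result`: list with `consensus`
#'   (`raster_grid` of counts 0--3), the three binary layers, and
#'   `corridor_cells` (linear indices of consensus-3 cells).
#' @export
consensus_overlap <- function(density, current, mask,
                              density_q = 95, current_q = 95) {
  check_aligned(density, current); check_aligned(density, mask)
  bd <- percentile_mask(density, density_q)
  bc <- percentile_mask(current, current_q)
  cons <- bd$values + bc$values + mask$values
  res <- set_values(density, cons)
  structure(list(consensus = res, density_mask = bd, current_mask = bc,
                 suitability_mask = mask,
                 corridor_cells = which(cons == 3)),
            class = "corridor_result")
}

#' @export
print.corridor_result <- function(x, ...) {
  tab <- table(factor(x$consensus$values[is.finite(x$consensus$values)],
                      levels = 0:3))
  cat("corridor_result: consensus cell counts\n")
  print(tab)
  invisible(x)
}
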