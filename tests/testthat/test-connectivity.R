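test_that("seasonal conductance is the floored mean of the season's months", {
  mk <- function(x) raster_grid(matrix(x, 2, 2))
  months <- stats::setNames(lapply(1:12, function(m) mk(0.5)), 1:12)
  months[["3"]] <- mk(0.1); months[["4"]] <- mk(0.2); months[["5"]] <- mk(0.6)
  out <- seasonal_conductance(months, "spring")
  expect_equal(out$values, matrix(0.3, 2, 2))
  # identical rasters: unchanged
  expect_equal(seasonal_conductance(months, "fall")$values, matrix(0.5, 2, 2))
  # zero cells get the positivity floor
  for (m in c("8", "9", "10")) months[[m]] <- mk(0)
  expect_equal(min(seasonal_conductance(months, "fall")$values), 1e-6)
  expect_error(seasonal_conductance(months[c("3", "4")], "spring"),
               "missing month")
})

test_that("graph edges use length times mean endpoint resistance", {
  # 2 x 1 grid, unit conductances: one edge, cost 1, conductance 1
  g <- build_graph(raster_grid(matrix(1, 2, 1)))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$cost, 1)
  expect_equal(g$edges$conductance, 1)
  # rook-adjacent cells {1, 0.1}: cost (1 + 10) / 2 = 5.5
  g2 <- build_graph(raster_grid(matrix(c(1, 0.1), 2, 1)))
  expect_equal(g2$edges$cost, 5.5)
  # diagonal edge between unit-conductance cells: cost sqrt(2)
  v <- matrix(NA_real_, 2, 2); v[1, 1] <- 1; v[2, 2] <- 1
  g3 <- build_graph(raster_grid(v))
  expect_equal(g3$edges$cost, sqrt(2))
  expect_equal(g3$edges$conductance, 1 / sqrt(2))
  expect_error(build_graph(raster_grid(matrix(NA_real_, 2, 2))), "empty graph")
  expect_error(build_graph(raster_grid(matrix(0, 2, 2))), "> 0")
})

test_that("least-cost paths match series intuition and avoid low-conductance cells", {
  # uniform 1 x 3 grid end to end: cost 2 through the middle cell
  g <- build_graph(raster_grid(matrix(1, 1, 3)))
  p <- least_cost_path(g, 1, 3)
  expect_equal(p$cost, 2)
  expect_equal(p$cells, c(1L, 2L, 3L))
  # src = dst: empty path, cost 0
  p0 <- least_cost_path(g, 2, 2)
  expect_equal(p0$cost, 0)
  expect_length(p0$nodes, 0)
  # 3 x 3 grid, center conductance 0.1: corner-to-corner path routes around
  v <- matrix(1, 3, 3); v[2, 2] <- 0.1
  g2 <- build_graph(raster_grid(v))
  src <- 1L; dst <- 9L # corners (linear cell indices)
  p2 <- least_cost_path(g2, src, dst)
  expect_false(5L %in% p2$cells) # center avoided
  expect_equal(p2$cost, 2 + sqrt(2), tolerance = 1e-12)
  # unreachable destination
  v3 <- matrix(c(1, NA, 1), 1, 3)
  g3 <- build_graph(raster_grid(v3))
  expect_error(least_cost_path(g3, 1, 3), "no path")
})

test_that("Dijkstra cost equals exhaustive simple-path enumeration on small grids", {
  set.seed(99)
  for (rep in 1:20) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    g <- build_graph(raster_grid(matrix(runif(nr * nc, 0.05, 1), nr, nc)))
    n <- length(g$cells)
    ends <- sample(n, 2)
    expect_equal(least_cost_path(g, g$cells[ends[1]], g$cells[ends[2]])$cost,
                 brute_force_lcp_cost(g, ends[1], ends[2]),
                 tolerance = 1e-12)
  }
})

test_that("raising a cell's conductance never increases any LCP cost", {
  set.seed(7)
  v <- matrix(runif(25, 0.1, 1), 5, 5)
  g <- build_graph(raster_grid(v))
  pairs <- cbind(sample(25, 6), sample(25, 6))
  base <- apply(pairs, 1, function(pr)
    least_cost_path(g, pr[1], pr[2])$cost)
  for (i in 1:3) {
    v2 <- v; cell <- sample(25, 1); v2[cell] <- min(1, v2[cell] * 3)
    g2 <- build_graph(raster_grid(v2))
    after <- apply(pairs, 1, function(pr)
      least_cost_path(g2, pr[1], pr[2])$cost)
    expect_true(all(after <= base + 1e-12))
  }
})

test_that("path density counts traversals and totals the path lengths", {
  g <- build_graph(raster_grid(matrix(1, 1, 5), origin_lat = 1,
                               cell_size_deg = 1))
  winter <- data.frame(row = 1L, col = 1L)
  summer <- data.frame(row = c(1L, 1L), col = c(4L, 5L))
  ps <- lcp_density(g, winter, summer)
  expect_equal(nrow(ps$pairs), 2L)
  # density: cells 1..4 hit twice(1..4 shared), cell 5 once
  expect_equal(as.vector(ps$density$values), c(2, 2, 2, 2, 1))
  # total density = sum over paths of path length in cells
  expect_equal(sum(ps$density$values), 4 + 5)
  # all-paths mask flags density >= 1
  expect_equal(as.vector(ps$all_paths_mask$values), rep(1, 5))
  # single pair: density is the indicator of one path
  ps1 <- lcp_density(g, winter, data.frame(row = 1L, col = 3L))
  expect_equal(as.vector(ps1$density$values), c(1, 1, 1, 0, 0))
  # n x m pairs -> n * m entries
  ps2 <- lcp_density(g, data.frame(row = c(1L, 1L), col = c(1L, 2L)), summer)
  expect_equal(nrow(ps2$pairs), 4L)
  expect_error(lcp_density(g, winter[0, ], summer), "no paths|no usable")
})

test_that("uniform-conductance density concentrates on the straight line", {
  g <- build_graph(raster_grid(matrix(1, 7, 7), origin_lat = 7,
                               cell_size_deg = 1))
  ps <- lcp_density(g, data.frame(row = 4L, col = 1L),
                    data.frame(row = 4L, col = 7L))
  on_line <- which(ps$density$values >= 1, arr.ind = TRUE)
  expect_true(all(on_line[, "row"] == 4))
})

test_that("circuit solver reproduces series and parallel closed forms", {
  # chain of 5 unit-conductance cells: effective resistance 4, potentials 4..0
  chain <- raster_grid(matrix(1, 1, 5))
  out <- solve_current(chain, 1, 5, injection = 1)
  expect_equal(out$effective_resistance, 4, tolerance = 1e-10)
  expect_equal(as.vector(out$potential$values), c(4, 3, 2, 1, 0),
               tolerance = 1e-10)
  # interior node currents equal the through-current
  expect_equal(as.vector(out$current$values)[2:4], rep(1, 3),
               tolerance = 1e-10)
  # parallel branches of conductance 1 and 3: currents split 0.25 / 0.75
  g <- parallel_branch_graph()
  out2 <- solve_current(g, 1, 4, injection = 1)
  cur <- out2$current$values[g$cells]
  expect_equal(cur[2], 0.25, tolerance = 1e-10)
  expect_equal(cur[3], 0.75, tolerance = 1e-10)
  expect_equal(out2$effective_resistance, 1 / (1 + 3), tolerance = 1e-10)
  # scale equivariance: doubling injection doubles every node current
  out3 <- solve_current(g, 1, 4, injection = 2)
  expect_equal(out3$current$values, 2 * out2$current$values,
               tolerance = 1e-10)
  expect_error(solve_current(chain, 1, 1), "disjoint")
  split <- raster_grid(matrix(c(1, NA, 1), 1, 3))
  expect_error(solve_current(split, 1, 3), "singular")
})

test_that("Kirchhoff current is conserved at interior nodes", {
  set.seed(12)
  cond <- raster_grid(matrix(runif(64, 0.05, 1), 8, 8))
  g <- build_graph(cond)
  out <- solve_current(g, sources = 1, grounds = 64)
  v <- out$potential$values[g$cells]
  e <- g$edges
  net <- numeric(length(g$cells))
  flow <- e$conductance * (v[e$from] - v[e$to])
  for (k in seq_len(nrow(e))) {
    net[e$from[k]] <- net[e$from[k]] - flow[k]
    net[e$to[k]] <- net[e$to[k]] + flow[k]
  }
  interior <- setdiff(seq_along(net), c(1, 64))
  expect_true(all(abs(net[interior]) < 1e-8))
  # ladder cross-check: effective resistance from an independent dense solve
  L <- matrix(0, 64, 64)
  for (k in seq_len(nrow(e))) {
    L[e$from[k], e$to[k]] <- L[e$from[k], e$to[k]] - e$conductance[k]
    L[e$to[k], e$from[k]] <- L[e$to[k], e$from[k]] - e$conductance[k]
  }
  diag(L) <- -rowSums(L)
  keep <- 1:63
  vref <- solve(L[keep, keep], c(1, rep(0, 62)))
  expect_equal(out$effective_resistance, vref[1], tolerance = 1e-8)
})

test_that("percentile masks set exactly the top tail", {
  r <- raster_grid(matrix(1:100, 10, 10))
  m <- percentile_mask(r, 95)
  expect_equal(sum(m$values), 5)              # values 96..100
  expect_true(all(which(m$values == 1) %in% 96:100))
  expect_equal(sum(percentile_mask(r, 0)$values), 100)
  # mask pattern preserved
  r$values[3, 3] <- NA
  m2 <- percentile_mask(r, 50)
  expect_true(is.na(m2$values[3, 3]))
  expect_error(percentile_mask(raster_grid(matrix(1, 2, 2)), 95), "degenerate")
})

test_that("consensus counts agreeing methods per cell", {
  mk <- function(x) raster_grid(matrix(x, 1, 4))
  dens <- mk(c(5, 1, 0, 0)); cur <- mk(c(0.9, 0.8, 0.1, 0.05))
  mask <- mk(c(1, 0, 1, 0))
  out <- consensus_overlap(dens, cur, mask, density_q = 50, current_q = 50)
  expect_true(all(out$consensus$values %in% 0:3))
  expect_equal(out$consensus$values[1, 1], 3)
  expect_equal(out$corridor_cells, 1L)
  # disjoint layers: max consensus 1
  out2 <- consensus_overlap(mk(c(9, 1, 1, 1)), mk(c(0.1, 0.9, 0.1, 0.1)),
                            mk(c(0, 0, 1, 0)), 75, 75)
  expect_equal(max(out2$consensus$values), 1)
  expect_error(consensus_overlap(dens, cur, raster_grid(matrix(1, 2, 2))),
               "not aligned")
})

test_that("conductance transforms are monotone and land in (0, 1]", {
  r <- raster_grid(matrix(c(0.01, 0.1, 0.5, 1), 2, 2))
  for (tr in c("sqrt", "log", "ln", "cbrt")) {
    out <- transform_conductance(r, tr)
    v <- as.vector(out$values)
    expect_true(all(v > 0 & v <= 1), info = tr)
    expect_equal(order(v), order(as.vector(r$values)), info = tr)
  }
  expect_identical(transform_conductance(r, "none"), r)
})
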