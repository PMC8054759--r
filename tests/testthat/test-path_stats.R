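test_that("spatial weights are symmetric binary contiguity with zero diagonal", {
  r <- raster_grid(matrix(1:12, 3, 4))
  wq <- spatial_weights(r, "queen"); wr <- spatial_weights(r, "rook")
  expect_true(Matrix::isSymmetric(wq$w))
  expect_equal(Matrix::diag(wq$w), rep(0, 12))
  # rook 3x4: 2*(3*3) + 2*(2*4) horizontal+vertical ordered pairs
  expect_equal(wr$W, 2 * (3 * 3 + 2 * 4))
  expect_gt(wq$W, wr$W)
  # masked cells are excluded entirely
  r$values[2, 2] <- NA
  w2 <- spatial_weights(r, "rook")
  expect_equal(w2$n, 11L)
})

test_that("Moran's I and Geary's C reproduce the closed forms", {
  # even-dimension checkerboard, rook weights: I = -1, C = 2(N-1)/N
  cb <- raster_grid(outer(1:4, 1:4, function(i, j) (-1)^(i + j)))
  w <- spatial_weights(cb, "rook")
  expect_equal(morans_i(cb, w), -1, tolerance = 1e-12)
  expect_equal(gearys_c(cb, w), 2 * 15 / 16, tolerance = 1e-12)
  # 1-D chain (1,1,0,0): I = 1/3, C = 0.5
  ch <- raster_grid(matrix(c(1, 1, 0, 0), 1, 4))
  wc <- spatial_weights(ch, "rook")
  expect_equal(morans_i(ch, wc), 1 / 3, tolerance = 1e-12)
  expect_equal(gearys_c(ch, wc), 0.5, tolerance = 1e-12)
  # constant raster: undefined
  expect_error(morans_i(raster_grid(matrix(1, 2, 3)), w2 <- spatial_weights(
    raster_grid(matrix(1, 2, 3)), "rook")), "zero variance")
  # two homogeneous blocks: strong positive clustering, C < 1
  blocks <- raster_grid(cbind(matrix(1, 4, 2), matrix(0, 4, 2)))
  wb <- spatial_weights(blocks, "rook")
  expect_lt(gearys_c(blocks, wb), 1)
  expect_gt(morans_i(blocks, wb), 0)
})

test_that("sparse statistics agree with naive double-loop computation", {
  set.seed(31)
  for (i in 1:8) {
    r <- raster_grid(matrix(rnorm(30), 5, 6))
    if (i > 4) r$values[sample(30, 5)] <- NA
    w <- spatial_weights(r, sample(c("rook", "queen"), 1))
    x <- r$values[w$cells]
    wm <- as.matrix(w$w)
    expect_equal(morans_i(r, w), loop_morans_i(x, wm), tolerance = 1e-12)
    expect_equal(gearys_c(r, w), loop_gearys_c(x, wm), tolerance = 1e-12)
  }
})

test_that("expected values under randomness: E[I] ~ -1/(N-1), E[C] ~ 1", {
  set.seed(5)
  n_rep <- 200
  I <- C <- numeric(n_rep)
  r0 <- raster_grid(matrix(0, 6, 6))
  w <- spatial_weights(r0, "queen")
  for (i in seq_len(n_rep)) {
    r <- set_values(r0, matrix(rnorm(36), 6, 6))
    I[i] <- morans_i(r, w); C[i] <- gearys_c(r, w)
  }
  expect_lt(abs(mean(I) - (-1 / 35)), 3 * sd(I) / sqrt(n_rep))
  expect_lt(abs(mean(C) - 1), 3 * sd(C) / sqrt(n_rep))
})

test_that("permutation p-values have the +1 granularity and detect clustering", {
  blocks <- raster_grid(cbind(matrix(1, 5, 5) + matrix(rnorm(25, 0, 0.1), 5),
                              matrix(rnorm(25, 0, 0.1), 5, 5)))
  w <- spatial_weights(blocks, "queen")
  out <- permutation_test(blocks, w, "moran", n_perm = 99, seed = 8)
  expect_equal(out$p_value, 0.01) # more extreme than all 99 permutations
  outg <- permutation_test(blocks, w, "geary", n_perm = 99, seed = 8)
  expect_equal(outg$p_value, 0.01)
  expect_identical(permutation_test(blocks, w, "moran", 99, seed = 2),
                   permutation_test(blocks, w, "moran", 99, seed = 2))
  expect_error(permutation_test(blocks, w, "moran", n_perm = 5), ">= 19")
})

test_that("paired distance-increase test matches the textbook t formula", {
  out <- paired_increase_test(c(11, 12, 13), c(10, 10, 10))
  expect_equal(out$mean_increase, 2)
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, stats::pt(out$t, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # path equal to straight everywhere: boundary case flagged
  out2 <- paired_increase_test(c(5, 6), c(5, 6))
  expect_equal(out2$mean_increase, 0)
  expect_equal(out2$p_value, 0.5)
  expect_true(out2$degenerate)
  # constant positive difference: infinite t, p -> 0
  out3 <- paired_increase_test(c(6, 7), c(5, 6))
  expect_equal(out3$t, Inf)
  expect_equal(out3$p_value, 0)
  expect_error(paired_increase_test(1, numeric(0)), "equal length")
  expect_error(paired_increase_test(1, 1), "at least 2")
})

test_that("great-circle distances match spherical geometry and geosphere", {
  expect_equal(geodesic_km(5, 5, 5, 5), 0)
  expect_equal(geodesic_km(0, 0, 0, 90), pi / 2 * 6371, tolerance = 1e-6)
  expect_equal(geodesic_km(0, 0, 1, 0), 2 * pi * 6371 / 360, tolerance = 1e-6)
  skip_if_not_installed("geosphere")
  set.seed(17)
  lon1 <- runif(20, -180, 180); lat1 <- runif(20, -89, 89)
  lon2 <- runif(20, -180, 180); lat2 <- runif(20, -89, 89)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371) # km radius
  expect_equal(geodesic_km(lon1, lat1, lon2, lat2), ref, tolerance = 1e-9)
})

test_that("seasonal similarity is Pearson r over shared valid cells", {
  set.seed(23)
  a <- raster_grid(matrix(runif(40), 5, 8))
  expect_equal(seasonal_similarity(a, a), 1)
  expect_equal(seasonal_similarity(a, set_values(a, 1 - a$values)), -1)
  b <- set_values(a, matrix(runif(40), 5, 8))
  b$values[1:3] <- NA
  ok <- 4:40
  expect_equal(seasonal_similarity(a, b),
               cor(a$values[ok], b$values[ok]))
  expect_error(seasonal_similarity(a, set_values(a, matrix(1, 5, 8))),
               "zero variance")
})

test_that("a stationary niche shows higher winter-summer similarity than a migrant", {
  spec <- env_stack_spec(30, 12, noise_sd = 0, seed = 6)
  jan <- generate_env_stack(spec, 1); jul <- generate_env_stack(spec, 7)
  migrant <- niche_spec(optimum_by_month = 8, tolerance = 3)
  mig_sim <- seasonal_similarity(true_suitability(jan, migrant, 1),
                                 true_suitability(jul, migrant, 7))
  # resident: optimum tracks the seasonal cycle, so the spatial pattern stays
  resident <- niche_spec(
    optimum_by_month = 8 + 10 * cos(2 * pi * ((1:12) - 7) / 12), tolerance = 3)
  res_sim <- seasonal_similarity(true_suitability(jan, resident, 1),
                                 true_suitability(jul, resident, 7))
  expect_gt(res_sim, mig_sim)
  expect_equal(res_sim, 1, tolerance = 1e-9)
})
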