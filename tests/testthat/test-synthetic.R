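noise_free_spec <- function(...) {
  env_stack_spec(n_rows = 12, n_cols = 10, noise_sd = 0, seed = 5, ...)
}

test_that("environmental layers follow the stated linear construction", {
  spec <- noise_free_spec(seasonal_amplitude = 0,
                          spatial_gradient = c(0.3, 40, 0.7, 0.01, -0.01,
                                               0.2, 0, -0.002, -0.3))
  # no seasonal term: identical across all 12 months
  stacks <- lapply(1:12, function(m) generate_env_stack(spec, m))
  for (m in 2:12)
    expect_identical(stacks[[m]]$tavg$values, stacks[[1]]$tavg$values)
  # adjacent-row difference equals the gradient exactly
  tavg <- stacks[[1]]$tavg$values
  expect_equal(as.vector(diff(tavg)), rep(0.7, length(diff(tavg))),
               tolerance = 1e-12)
  # same seed twice: bit-identical
  again <- generate_env_stack(noise_free_spec(seasonal_amplitude = 0,
    spatial_gradient = c(0.3, 40, 0.7, 0.01, -0.01, 0.2, 0, -0.002, -0.3)), 1)
  expect_identical(again$tavg$values, tavg)
})

test_that("seasonal sinusoid peaks in July and noise fields are reproducible", {
  spec <- noise_free_spec()
  july <- generate_env_stack(spec, 7)$tavg$values
  for (m in c(1, 4, 10))
    expect_true(all(generate_env_stack(spec, m)$tavg$values < july))
  # with noise: deterministic given seed, different across seeds
  s1 <- env_stack_spec(8, 8, seed = 11)
  s2 <- env_stack_spec(8, 8, seed = 12)
  expect_identical(generate_env_stack(s1, 3)$precip$values,
                   generate_env_stack(s1, 3)$precip$values)
  expect_false(identical(generate_env_stack(s1, 3)$precip$values,
                         generate_env_stack(s2, 3)$precip$values))
  expect_error(env_stack_spec(2, 10), "n_rows")
})

test_that("true suitability is the Gaussian kernel of temperature", {
  spec <- noise_free_spec()
  stack <- generate_env_stack(spec, 6)
  tol <- 3
  # pick the optimum equal to an actual cell temperature: kernel max = 1
  t0 <- stack$tavg$values[5, 2]
  niche <- niche_spec(optimum_by_month = t0, tolerance = tol)
  suit <- true_suitability(stack, niche, 6)
  expect_equal(suit$values[5, 2], 1.0)
  expect_true(all(suit$values >= 0 & suit$values <= 1))
  # one tolerance away from the optimum: exp(-0.5)
  niche2 <- niche_spec(optimum_by_month = t0 + tol, tolerance = tol)
  suit2 <- true_suitability(stack, niche2, 6)
  expect_equal(suit2$values[5, 2], exp(-0.5), tolerance = 1e-12)
  expect_error(true_suitability(stack[c("precip", "elev")], niche, 6),
               "missing layer")
})

test_that("corridor boost raises corridor cells and zero boost ignores the polyline", {
  spec <- noise_free_spec()
  stack <- generate_env_stack(spec, 6)
  line <- cbind(lon = c(-99, -99), lat = c(45, 42.2))
  base <- niche_spec(optimum_by_month = 10, tolerance = 5)
  boosted <- niche_spec(optimum_by_month = 10, tolerance = 5,
                        corridor_polyline = line, corridor_width_cells = 2,
                        corridor_boost = 0.3, max_suitability = 1)
  s0 <- true_suitability(stack, base, 6)
  s1 <- true_suitability(stack, boosted, 6)
  inside <- corridor_mask(s0, boosted)
  expect_true(any(inside))
  # at equal temperature, corridor cells strictly exceed non-corridor cells
  expect_true(all(s1$values[inside] >= s0$values[inside]))
  expect_gt(mean(s1$values[inside] - s0$values[inside]), 0)
  expect_true(all(s1$values[!inside] == s0$values[!inside]))
  expect_true(all(s1$values <= 1))
  # corridor_boost = 0: polyline is irrelevant
  nob <- niche_spec(optimum_by_month = 10, tolerance = 5,
                    corridor_polyline = line, corridor_boost = 0)
  expect_equal(true_suitability(stack, nob, 6)$values, s0$values)
})

test_that("a niche optimum moving north shifts the suitability argmax accordingly", {
  # gradient 1 per row, no noise: optimum decreasing by k per month moves the
  # argmax row north (down in temperature) by k rows per month
  spec <- env_stack_spec(n_rows = 30, n_cols = 6, noise_sd = 0,
                         seasonal_amplitude = 0,
                         base_level = c(60, 15000, 0, 1, 3.5, 20, 300, 0.5, 40),
                         spatial_gradient = c(0.3, 40, 1, 0.01, -0.01, 0.2,
                                              0, -0.002, -0.3),
                         seed = 3)
  k <- 2
  niche <- niche_spec(optimum_by_month = 20 - k * (1:12), tolerance = 2)
  argmax_row <- vapply(1:6, function(m) {
    s <- true_suitability(generate_env_stack(spec, m), niche, m)
    which.max(apply(s$values, 1, max))
  }, 0L)
  expect_equal(diff(argmax_row), rep(-k, 5))
})

test_that("occurrence sampling respects weights, bias and the seed", {
  v <- matrix(0, 6, 6); v[3, 4] <- 1
  suit <- raster_grid(v, cell_size_deg = 1)
  occ <- sample_occurrences(suit, 25, seed = 9, month = 2)
  rc <- cell_from_lonlat(suit, occ$lon, occ$lat)
  expect_true(all(rc$row == 3 & rc$col == 4))
  expect_equal(occ$month, rep(2L, 25))
  # same seed: identical tables; degenerate weights error
  expect_identical(sample_occurrences(suit, 25, seed = 9, month = 2), occ)
  expect_error(sample_occurrences(set_values(suit, matrix(0, 6, 6)), 5),
               "degenerate")
  # bias multiplies the sampling weights
  uni <- set_values(suit, matrix(1, 6, 6))
  bias <- set_values(suit, matrix(rep(c(0, 1), each = 18), 6, 6))
  occb <- sample_occurrences(uni, 200, bias = bias, seed = 4)
  expect_true(all(cell_from_lonlat(uni, occb$lon, occb$lat)$col >= 4))
})

test_that("uniform suitability sampling is consistent with a uniform multinomial", {
  suit <- raster_grid(matrix(1, 5, 5), cell_size_deg = 1)
  occ <- sample_occurrences(suit, 10000, seed = 21)
  rc <- cell_from_lonlat(suit, occ$lon, occ$lat)
  counts <- table(factor(paste(rc$row, rc$col), levels = outer(
    1:5, 1:5, paste)[TRUE]))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})
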