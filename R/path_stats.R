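#' Binary contiguity spatial weights for a raster
#'
#' Symmetric binary adjacency over the valid cells of a raster, rook
#' (4-neighbour) or queen (8-neighbour) contiguity, zero diagonal, not
#' row-standardized.
#'
#' @param r a `raster_grid` (the mask defines the valid cells).
#' @param style `"queen"` (default) or `"rook"`.
#' @return An object of class `spatial_weights`: list with sparse symmetric
#'   `w` over valid cells, `cells` (linear indices), `W` (total weight, sum
#'   over ordered pairs).
#' @export
spatial_weights <- function(r, style = c("queen", "rook")) {
  stopifnot(inherits(r, "raster_grid"))
  style <- match.arg(style)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  cells <- which(is.finite(v))
  if (length(cells) < 2L) stop("need >= 2 valid cells", call. = FALSE)
  id <- rep(NA_integer_, nr * nc); id[cells] <- seq_along(cells)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (style == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  from <- to <- integer(0)
  for (o in offs) {
    r2 <- row + o[1L]; c2 <- col + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    cell2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- !is.na(id[cell2])
    from <- c(from, id[cells[ok]][ok2])
    to <- c(to, id[cell2][ok2])
  }
  n <- length(cells)
  w <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = 1, dims = c(n, n))
  structure(list(w = w, cells = cells, W = sum(w), n = n, style = style),
            class = "spatial_weights")
}

stat_values <- function(values, weights) {
  x <- if (inherits(values, "raster_grid")) values$values[weights$cells]
       else as.numeric(values)
  if (length(x) != weights$n)
    stop("values do not match the weights' valid cells", call. = FALSE)
  if (stats::var(x) == 0)
    stop("undefined statistic: values have zero variance", call. = FALSE)
  x
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N/W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the deviations
#' from the mean over valid cells. Values near `-1/(N-1)` indicate no
#' autocorrelation; larger values indicate positive clustering.
#'
#' @param values `raster_grid` (or numeric vector over the weights' cells).
#' @param weights a [spatial_weights()] object.
#' @return The statistic.
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  x <- stat_values(values, weights)
  z <- x - mean(x)
  (weights$n / weights$W) *
    as.numeric(t(z) %*% (weights$w %*% z)) / sum(z^2)
}

#' Geary's C spatial autocorrelation
#'
#' `C = ((N-1)/(2W)) * sum_ij w_ij (x_i - x_j)^2 / sum_i z_i^2`. C ranges
#' over [0, 2]; values below 1 indicate positive clustering.
#'
#' @inheritParams morans_i
#' @return The statistic.
#' @export
gearys_c <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  x <- stat_values(values, weights)
  z <- x - mean(x)
  # sum_ij w_ij (x_i - x_j)^2 = 2 * (x' D x - x' W x) with D = row sums
  d <- Matrix::rowSums(weights$w)
  num <- 2 * (sum(d * x^2) - as.numeric(t(x) %*% (weights$w %*% x)))
  ((weights$n - 1) / (2 * weights$W)) * num / sum(z^2)
}

#' Permutation test for spatial clustering
#'
#' Random-labelling permutation test: values are shuffled over the valid
#' cells and the statistic recomputed. One-sided p =
#' `(1 + #{permutations at least as clustered}) / (n_perm + 1)`, where
#' "more clustered" means higher Moran's I or lower Geary's C. With the
#' default 99 permutations the smallest attainable p is 0.01.
#'
#' @param values `raster_grid` or numeric vector.
#' @param weights a [spatial_weights()] object.
#' @param statistic `"moran"` or `"geary"`.
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed.
#' @return List with `observed`, `p_value`, `n_perm`, `statistic`.
#' @export
permutation_test <- function(values, weights, statistic = c("moran", "geary"),
                             n_perm = 99L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (n_perm < 19L) stop("n_perm must be >= 19", call. = FALSE)
  fn <- if (statistic == "moran") morans_i else gearys_c
  x <- stat_values(values, weights)
  obs <- fn(x, weights)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) fn(sample(x), weights), 0)
  extreme <- if (statistic == "moran") sum(perm >= obs) else sum(perm <= obs)
  list(observed = obs, p_value = (1 + extreme) / (n_perm + 1),
       n_perm = as.integer(n_perm), statistic = statistic)
}

#' Paired one-sided test for distance increase
#'
#' Tests whether least-cost ground distances exceed the straight-line
#' distances of the same endpoint pairs: paired one-sided t-test of
#' `mean(path - straight) > 0`.
#'
#' @param path_km,straight_km equal-length distance vectors (km), n >= 2.
#' @return List with `mean_increase`, `t`, `df`, `p_value`, and `degenerate`
#'   (TRUE when the differences have zero variance).
#' @export
paired_increase_test <- function(path_km, straight_km) {
  if (length(path_km) != length(straight_km))
    stop("vectors must have equal length", call. = FALSE)
  n <- length(path_km)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- path_km - straight_km
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(mean_increase = m,
                t = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1L,
                p_value = if (m > 0) 0 else if (m == 0) 0.5 else 1,
                degenerate = TRUE))
  }
  ht <- stats::t.test(path_km, straight_km, paired = TRUE,
                      alternative = "greater")
  list(mean_increase = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value, degenerate = FALSE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
geodesic_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Correlation between two seasonal suitability surfaces
#'
#' Pearson correlation over the cells valid in both rasters. A high
#' winter-vs-summer similarity indicates a resident (non-migratory)
#' distribution; migrants show low or negative similarity.
#'
#' @param a,b aligned `raster_grid`s.
#' @return Pearson r.
#' @export
seasonal_similarity <- function(a, b) {
  check_aligned(a, b)
  x <- as.vector(a$values); y <- as.vector(b$values)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("fewer than 3 shared valid cells", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x[ok], y[ok])
}

#' Clustering and distance statistics for one corridor run
#'
#' Convenience wrapper producing one row of the corridor statistics table:
#' Moran's I and Geary's C of the LCP-density surface with permutation
#' p-values, and the paired distance-increase test.
#'
#' @param path_set an [lcp_density()] result.
#' @param weights optional [spatial_weights()]; queen contiguity on the
#'   density raster by default.
#' @param n_perm permutations for the clustering tests.
#' @param seed integer seed.
#' @return One-row data.frame: `morans_i`, `morans_p`, `gearys_c`,
#'   `gearys_p`, `mean_increase_km`, `t`, `df`, `t_p`.
#' @export
corridor_stats <- function(path_set, weights = NULL, n_perm = 99L, seed = 1L) {
  stopifnot(inherits(path_set, "path_set"))
  if (is.null(weights)) weights <- spatial_weights(path_set$density, "queen")
  mi <- permutation_test(path_set$density, weights, "moran", n_perm, seed)
  gc <- permutation_test(path_set$density, weights, "geary", n_perm,
                         derive_seed(seed, 3L))
  tt <- paired_increase_test(path_set$pairs$path_km, path_set$pairs$straight_km)
  data.frame(morans_i = mi$observed, morans_p = mi$p_value,
             gearys_c = gc$observed, gearys_p = gc$p_value,
             mean_increase_km = tt$mean_increase, t = tt$t, df = tt$df,
             t_p = tt$p_value)
}
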