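#' Specification for a synthetic monthly environmental raster stack
#'
#' Describes a stack of monthly predictor layers emulating the structure of
#' gridded climate products: each layer is a north--south linear gradient plus
#' a seasonal sinusoid (peaking in July) plus a spatially smoothed Gaussian
#' random field. The default roster mirrors the nine predictors commonly used
#' for continental bat distribution modelling: precipitation, solar radiation,
#' average temperature, vapor pressure, wind speed, human influence,
#' elevation, NDVI and forest cover.
#'
#' The random field of each layer is drawn once per (seed, layer) and held
#' fixed across months, so a layer with zero seasonal amplitude is identical
#' in every month (as elevation or human influence should be) and all monthly
#' variation comes from the seasonal term.
#'
#' @param n_rows,n_cols grid dimensions (>= 4).
#' @param cell_size_deg cell size in decimal degrees.
#' @param origin_lon,origin_lat north-west corner, decimal degrees.
#' @param layer_names character vector of predictor names.
#' @param base_level per-layer mean level at the northern edge (recycled).
#' @param seasonal_amplitude per-layer sinusoid amplitude (recycled).
#' @param spatial_gradient per-layer increment per row moving south (recycled).
#' @param noise_sd per-layer Gaussian field standard deviation (recycled).
#' @param corridor_polyline optional 2-column lon/lat matrix: a linear
#'   landscape feature (e.g. a river valley) imprinted on the predictor
#'   layers named in `corridor_effect`, so a planted corridor is
#'   identifiable from the environment, not only from occurrence density.
#' @param corridor_width_cells buffer width of the imprinted feature, cells.
#' @param corridor_effect named additive offsets applied inside the feature
#'   buffer (default: an elevation depression and an NDVI boost).
#' @param seed integer seed controlling all random fields.
#' @return An object of class `env_stack_spec`.
#' @export
env_stack_spec <- function(n_rows, n_cols, cell_size_deg = 0.25,
                           origin_lon = -100, origin_lat = 45,
                           layer_names = c("precip", "solar", "tavg", "vapor",
                                           "wind", "human", "elev", "ndvi",
                                           "forest"),
                           base_level = c(60, 15000, 0, 1.0, 3.5, 20, 400, 0.5, 40),
                           seasonal_amplitude = c(30, 6000, 10, 0.5, 0.8, 0, 0, 0.25, 0),
                           spatial_gradient = c(0.3, 40, 0.5, 0.01, -0.01, 0.2, 0, -0.002, -0.3),
                           noise_sd = c(8, 300, 0.6, 0.04, 0.3, 5, 150, 0.03, 10),
                           corridor_polyline = NULL,
                           corridor_width_cells = 3L,
                           corridor_effect = c(elev = -250, ndvi = 0.15),
                           seed = 1L) {
  if (n_rows < 4 || n_cols < 4)
    stop("invalid spec: n_rows and n_cols must be >= 4", call. = FALSE)
  if (cell_size_deg <= 0)
    stop("invalid spec: cell_size_deg must be > 0", call. = FALSE)
  k <- length(layer_names)
  spec <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               cell_size_deg = cell_size_deg,
               origin_lon = origin_lon, origin_lat = origin_lat,
               layer_names = layer_names,
               base_level = rep_len(base_level, k),
               seasonal_amplitude = rep_len(seasonal_amplitude, k),
               spatial_gradient = rep_len(spatial_gradient, k),
               noise_sd = rep_len(noise_sd, k),
               corridor_polyline = corridor_polyline,
               corridor_width_cells = as.integer(corridor_width_cells),
               corridor_effect = corridor_effect,
               seed = as.integer(seed))
  names(spec$base_level) <- names(spec$seasonal_amplitude) <-
    names(spec$spatial_gradient) <- names(spec$noise_sd) <- layer_names
  structure(spec, class = "env_stack_spec")
}

# Smoothed Gaussian random field: white noise blurred with a 3x3 Gaussian
# kernel (blur radius = 1 cell), renormalized at the edges.
smoothed_noise_field <- function(n_rows, n_cols, sd, seed) {
  if (sd == 0) return(matrix(0, n_rows, n_cols))
  set.seed(seed)
  w <- matrix(stats::rnorm(n_rows * n_cols, sd = sd), n_rows, n_cols)
  k <- outer(exp(-(-1:1)^2 / 2), exp(-(-1:1)^2 / 2))
  out <- matrix(0, n_rows, n_cols)
  wt <- matrix(0, n_rows, n_cols)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(n_rows, n_rows + di)
    rj <- max(1, 1 + dj):min(n_cols, n_cols + dj)
    si <- ri - di; sj <- rj - dj
    kv <- k[di + 2, dj + 2]
    out[ri, rj] <- out[ri, rj] + kv * w[si, sj]
    wt[ri, rj] <- wt[ri, rj] + kv
  }
  out / wt * sum(k) / sqrt(sum(k^2)) # unit-variance-preserving rescale
}

#' Generate the monthly environmental stack for one month
#'
#' Each layer is `base + gradient * (row - 1) + amplitude * cos(2*pi*(month - 7)/12)`
#' plus its fixed smoothed noise field; the cosine peaks at month 7 (July).
#' Rows count from the northern edge, so a positive gradient means values
#' increase southwards. Deterministic given the spec's seed.
#'
#' @param spec an [env_stack_spec()].
#' @param month month index in 1..12.
#' @return Named list of [raster_grid()] layers.
#' @export
generate_env_stack <- function(spec, month) {
  stopifnot(inherits(spec, "env_stack_spec"))
  if (!month %in% 1:12) stop("month must be in 1..12", call. = FALSE)
  season <- cos(2 * pi * (month - 7) / 12)
  rows <- matrix(seq_len(spec$n_rows) - 1, spec$n_rows, spec$n_cols)
  template <- raster_grid(rows, spec$origin_lon, spec$origin_lat,
                          spec$cell_size_deg)
  feature <- if (!is.null(spec$corridor_polyline)) {
    corridor_mask(template,
                  niche_spec(corridor_polyline = spec$corridor_polyline,
                             corridor_width_cells = spec$corridor_width_cells,
                             corridor_boost = 1))
  }
  stack <- vector("list", length(spec$layer_names))
  names(stack) <- spec$layer_names
  for (i in seq_along(spec$layer_names)) {
    nm <- spec$layer_names[i]
    noise <- smoothed_noise_field(spec$n_rows, spec$n_cols, spec$noise_sd[i],
                                  derive_seed(spec$seed, i))
    v <- spec$base_level[i] + spec$spatial_gradient[i] * rows +
      spec$seasonal_amplitude[i] * season + noise
    if (!is.null(feature) && nm %in% names(spec$corridor_effect))
      v[feature] <- v[feature] + spec$corridor_effect[[nm]]
    stack[[i]] <- raster_grid(v, spec$origin_lon, spec$origin_lat,
                              spec$cell_size_deg)
  }
  stack
}

#' Specification of a known seasonal niche with a planted corridor
#'
#' Ground truth for recovery tests: habitat suitability is a Gaussian kernel
#' around a (possibly month-varying) optimal temperature, with an additive
#' suitability boost inside a buffered polyline corridor, capped at
#' `max_suitability`. With a fixed optimum and a seasonally varying
#' temperature field, the suitable band tracks the optimal isotherm and so
#' shifts south in winter and north in summer.
#'
#' @param optimum_by_month numeric length 12 (or 1, recycled): optimal
#'   temperature per month, same units as the temperature layer.
#' @param tolerance niche breadth (Gaussian kernel sd), > 0.
#' @param corridor_polyline 2-column matrix of lon/lat vertices, or NULL.
#' @param corridor_width_cells corridor buffer width in cells.
#' @param corridor_boost additive suitability inside the corridor, in [0, 1].
#' @param max_suitability cap applied after the boost, in [0, 1].
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(optimum_by_month = 15, tolerance = 2,
                       corridor_polyline = NULL, corridor_width_cells = 3L,
                       corridor_boost = 0, max_suitability = 1) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (corridor_boost < 0 || corridor_boost > 1 ||
      max_suitability < 0 || max_suitability > 1)
    stop("corridor_boost and max_suitability must lie in [0, 1]", call. = FALSE)
  structure(list(optimum_by_month = rep_len(optimum_by_month, 12),
                 tolerance = tolerance,
                 corridor_polyline = corridor_polyline,
                 corridor_width_cells = as.integer(corridor_width_cells),
                 corridor_boost = corridor_boost,
                 max_suitability = max_suitability),
            class = "niche_spec")
}

# Minimum planar distance (degrees) from points to a polyline.
dist_to_polyline <- function(lon, lat, polyline) {
  d2 <- rep(Inf, length(lon))
  for (s in seq_len(nrow(polyline) - 1L)) {
    ax <- polyline[s, 1]; ay <- polyline[s, 2]
    bx <- polyline[s + 1L, 1]; by <- polyline[s + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(lon)) else
      pmin(1, pmax(0, ((lon - ax) * vx + (lat - ay) * vy) / len2))
    d2 <- pmin(d2, (lon - (ax + t * vx))^2 + (lat - (ay + t * vy))^2)
  }
  sqrt(d2)
}

#' Rasterize the corridor buffer of a niche onto a grid
#'
#' @param template a `raster_grid` supplying the geometry.
#' @param niche a [niche_spec()].
#' @return Logical matrix: TRUE inside the corridor buffer.
#' @export
corridor_mask <- function(template, niche) {
  stopifnot(inherits(template, "raster_grid"), inherits(niche, "niche_spec"))
  nr <- nrow(template$values); nc <- ncol(template$values)
  if (is.null(niche$corridor_polyline) || niche$corridor_boost == 0)
    return(matrix(FALSE, nr, nc))
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- cell_center(template, idx$row, idx$col)
  d <- dist_to_polyline(ctr$lon, ctr$lat, niche$corridor_polyline)
  half_width <- niche$corridor_width_cells * template$cell_size_deg / 2
  matrix(d <= half_width, nr, nc)
}

#' True habitat suitability for a synthetic niche
#'
#' `exp(-(T - optimum_m)^2 / (2 * tolerance^2))` on the temperature layer,
#' plus `corridor_boost` inside the corridor buffer, capped at
#' `max_suitability`. Values lie in [0, 1].
#'
#' @param stack named list of `raster_grid` layers containing `temp_layer`.
#' @param niche a [niche_spec()].
#' @param month month index in 1..12.
#' @param temp_layer name of the temperature layer in `stack`.
#' @return A `raster_grid` of suitabilities in [0, 1].
#' @export
true_suitability <- function(stack, niche, month, temp_layer = "tavg") {
  stopifnot(inherits(niche, "niche_spec"))
  if (!temp_layer %in% names(stack))
    stop("missing layer: stack has no '", temp_layer, "' layer", call. = FALSE)
  r <- stack[[temp_layer]]
  opt <- niche$optimum_by_month[month]
  s <- exp(-(r$values - opt)^2 / (2 * niche$tolerance^2))
  if (!is.null(niche$corridor_polyline) && niche$corridor_boost > 0) {
    inside <- corridor_mask(r, niche)
    s[inside] <- s[inside] + niche$corridor_boost
  }
  s <- pmin(s, niche$max_suitability)
  set_values(r, s)
}

#' Default spatial sampling-bias layer
#'
#' A logistic gradient increasing toward one map edge, emulating the
#' institutional east/west imbalance of public occurrence archives. Values in
#' (0, 1].
#'
#' @param template a `raster_grid` supplying the geometry.
#' @param direction edge toward which sampling effort increases.
#' @param steepness logistic slope on the 0..1 across-map coordinate.
#' @return A `raster_grid` of relative sampling effort.
#' @export
default_bias <- function(template, direction = c("east", "west", "north", "south"),
                         steepness = 6) {
  direction <- match.arg(direction)
  nr <- nrow(template$values); nc <- ncol(template$values)
  frac <- switch(direction,
    east  = matrix((seq_len(nc) - 0.5) / nc, nr, nc, byrow = TRUE),
    west  = matrix(1 - (seq_len(nc) - 0.5) / nc, nr, nc, byrow = TRUE),
    north = matrix(1 - (seq_len(nr) - 0.5) / nr, nr, nc),
    south = matrix((seq_len(nr) - 0.5) / nr, nr, nc))
  set_values(template, stats::plogis(steepness * (frac - 0.5)))
}

#' Sample presence-only occurrence records from a suitability surface
#'
#' Draws `n` presence points with per-cell probability proportional to
#' suitability times sampling bias (bias = 1 everywhere when omitted), then
#' jitters each point uniformly within its cell. Deterministic given `seed`.
#'
#' @param suit `raster_grid` of suitabilities in [0, 1].
#' @param n number of points (>= 1).
#' @param bias optional aligned `raster_grid` of relative sampling effort.
#' @param seed integer seed.
#' @param month month label attached to the records (1..12).
#' @param species species name column value.
#' @param year,basis_of_record record metadata columns.
#' @return An occurrence data.frame with columns `species`, `lon`, `lat`,
#'   `year`, `month`, `day`, `basis_of_record`.
#' @export
sample_occurrences <- function(suit, n, bias = NULL, seed = 1L, month = 6L,
                               species = "synthetic_migrant", year = 2015L,
                               basis_of_record = "HUMAN_OBSERVATION") {
  stopifnot(inherits(suit, "raster_grid"), n >= 1)
  w <- suit$values
  if (!is.null(bias)) {
    check_aligned(suit, bias)
    w <- w * bias$values
  }
  w[!is.finite(w)] <- 0
  if (all(w <= 0))
    stop("degenerate weights: all sampling weights are zero", call. = FALSE)
  set.seed(seed)
  cells <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  nr <- nrow(w)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cs <- suit$cell_size_deg
  lon <- suit$origin_lon + (col - 1L) * cs + stats::runif(n) * cs
  lat <- suit$origin_lat - (row - 1L) * cs - stats::runif(n) * cs
  data.frame(species = species, lon = lon, lat = lat,
             year = year, month = as.integer(month),
             day = sample.int(28L, n, replace = TRUE),
             basis_of_record = basis_of_record,
             stringsAsFactors = FALSE)
}
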