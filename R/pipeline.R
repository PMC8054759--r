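#' Configuration for a full synthetic corridor-inference run
#'
#' Bundles every tunable of the end-to-end workflow: synthetic landscape and
#' niche, occurrence preparation, predictor screening, per-month model
#' fitting and evaluation, seasonal conductance, the three corridor methods
#' and the clustering statistics. Defaults are the package's reference study
#' conditions: a 60 x 60 quarter-degree landscape, a temperature niche
#' shifting ~40 rows between winter and summer, a planted 3-cell-wide
#' corridor with suitability boost 0.3 following a low-elevation valley, 300
#' presence records per month with an eastward sampling bias, 1,000
#' pseudo-absences per month, 5-fold cross-validation and a TSS-weighted
#' ensemble.
#'
#' @param out_dir output directory for artifacts (NULL = no files written).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_rows,n_cols,cell_size_deg,origin_lon,origin_lat landscape grid.
#' @param noise_sd_scale multiplier applied to the per-layer noise defaults
#'   (0 gives the noise-free scenario).
#' @param corridor_polyline lon/lat matrix of the planted corridor (NULL =
#'   no corridor); the default runs roughly north--south through the domain.
#' @param corridor_boost,corridor_width_cells corridor suitability boost and
#'   width.
#' @param niche_optimum,niche_tolerance temperature niche optimum (deg C)
#'   and breadth.
#' @param n_presence_per_month presence points drawn per month.
#' @param bias_direction edge of increasing sampling effort (NULL = no bias).
#' @param thin_cell_deg spatial thinning cell size, degrees.
#' @param ref_year,window_years occurrence recency filter.
#' @param cor_threshold predictor screening |r| threshold.
#' @param algorithms SDM algorithms to fit.
#' @param weight_metric ensemble weighting metric, `"tss"` or `"auc"`.
#' @param k cross-validation folds.
#' @param n_pseudo pseudo-absences per month.
#' @param percentile_q corridor binarization percentile.
#' @param n_perm permutations for the clustering tests.
#' @param min_occ_warn,min_occ_refuse monthly sample-size guards: warn below
#'   the first, stop below the second unless `allow_small`.
#' @param allow_small proceed below `min_occ_refuse` anyway.
#' @param importance_month month whose fitted models get permutation
#'   variable importance (NULL = skip).
#' @param importance_reps permutations per variable for importance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L,
                            n_rows = 60L, n_cols = 60L, cell_size_deg = 0.25,
                            origin_lon = -100, origin_lat = 50,
                            noise_sd_scale = 1,
                            corridor_polyline = cbind(
                              lon = c(-93, -92, -93),
                              lat = c(50, 43, 35)),
                            corridor_boost = 0.3, corridor_width_cells = 3L,
                            niche_optimum = 15, niche_tolerance = 2,
                            n_presence_per_month = 300L,
                            bias_direction = "east",
                            thin_cell_deg = 1, ref_year = 2019L,
                            window_years = 50L, cor_threshold = 0.8,
                            algorithms = c("bioclim", "glm", "maxent", "rf"),
                            weight_metric = "tss", k = 5L, n_pseudo = 1000L,
                            percentile_q = 95, n_perm = 99L,
                            min_occ_warn = 25L, min_occ_refuse = 13L,
                            allow_small = FALSE,
                            importance_month = 6L, importance_reps = 5L) {
  known <- c("bioclim", "glm", "maxent", "rf")
  bad <- setdiff(algorithms, known)
  if (length(bad))
    stop("unknown algorithm(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (cor_threshold <= 0 || cor_threshold > 1)
    stop("cor_threshold must be in (0, 1]", call. = FALSE)
  if (percentile_q < 0 || percentile_q > 100)
    stop("percentile_q must be in [0, 100]", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

config_specs <- function(config) {
  noise <- c(8, 300, 0.6, 0.04, 0.3, 5, 150, 0.03, 10) * config$noise_sd_scale
  env <- env_stack_spec(
    n_rows = config$n_rows, n_cols = config$n_cols,
    cell_size_deg = config$cell_size_deg,
    origin_lon = config$origin_lon, origin_lat = config$origin_lat,
    noise_sd = noise,
    corridor_polyline = config$corridor_polyline,
    corridor_width_cells = config$corridor_width_cells,
    seed = derive_seed(config$seed, 1L))
  niche <- niche_spec(
    optimum_by_month = config$niche_optimum,
    tolerance = config$niche_tolerance,
    corridor_polyline = config$corridor_polyline,
    corridor_width_cells = config$corridor_width_cells,
    corridor_boost = config$corridor_boost)
  list(env = env, niche = niche)
}

#' Run the full corridor-inference workflow
#'
#' Executes the whole pipeline on a synthetic landscape with known ground
#' truth: generate monthly predictor stacks and biased presence samples;
#' filter, thin and season-label the occurrences; screen correlated
#' predictors; per month, draw pseudo-absences, cross-validate the four SDM
#' algorithms, build the TSS-weighted ensemble and predict the monthly
#' suitability raster; average spring and fall months into seasonal
#' conductance surfaces; infer corridors by least-cost-path density,
#' circuit-theory current and the 95th-percentile mask; form their
#' consensus; and compute clustering and distance statistics. Fully
#' deterministic given the config's seed.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `config`,
#'   `specs`, `occurrences` (raw and prepped), `screen`, `evaluation`
#'   (per-month tables), `weights`, `ensembles` (monthly normalized
#'   rasters), `truth` (monthly true-suitability rasters), `importance`,
#'   `corridors` (per season: path_set, current, masks, consensus, stats),
#'   and `manifest` (when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  specs <- config_specs(config)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  ## stage 1: synthetic landscape, truth and occurrence sampling
  stacks <- lapply(1:12, function(m) generate_env_stack(specs$env, m))
  truth <- lapply(1:12, function(m)
    true_suitability(stacks[[m]], specs$niche, m))
  bias <- if (!is.null(config$bias_direction))
    default_bias(truth[[1L]], config$bias_direction)
  raw <- do.call(rbind, lapply(1:12, function(m)
    sample_occurrences(truth[[m]], config$n_presence_per_month, bias = bias,
                       seed = derive_seed(config$seed, 200L + m), month = m,
                       year = config$ref_year - 4L)))

  ## stage 2: occurrence preparation (filter, thin per month, seasons)
  filtered <- filter_records(raw, ref_year = config$ref_year,
                             window_years = config$window_years)
  prepped <- do.call(rbind, lapply(1:12, function(m)
    grid_thin(filtered[filtered$month == m, , drop = FALSE],
              config$thin_cell_deg)))
  prepped <- assign_season(prepped)
  counts <- table(factor(prepped$month, levels = 1:12))
  low <- which(counts < config$min_occ_refuse)
  if (length(low) && !config$allow_small)
    stop("months with fewer than ", config$min_occ_refuse,
         " occurrences: ", paste(low, collapse = ", "),
         " (set allow_small = TRUE to proceed)", call. = FALSE)
  warn <- which(counts < config$min_occ_warn)
  if (length(warn))
    warning("months below ", config$min_occ_warn, " occurrences: ",
            paste(warn, collapse = ", "), call. = FALSE)

  ## stage 3: predictor screening (on the mid-year stack)
  report <- pairwise_correlation(stacks[[6L]])
  drops <- drop_correlated(report, threshold = config$cor_threshold)
  predictors <- drops$retained

  ## stage 4: monthly fits, evaluation, ensemble
  eval_tables <- vector("list", 12L)
  ensembles <- vector("list", 12L); names(ensembles) <- as.character(1:12)
  weights_by_month <- vector("list", 12L)
  importance <- NULL
  for (m in 1:12) {
    pres_m <- prepped[prepped$month == m, , drop = FALSE]
    abs_m <- sample_pseudo_absences(
      truth[[m]], n = config$n_pseudo, exclude = pres_m,
      seed = derive_seed(config$seed, 300L + m), month = m)
    design <- extract_design(pres_m, abs_m, stacks[[m]][predictors], month = m)
    ev <- evaluate_models(design, algorithms = config$algorithms,
                          k = config$k,
                          seed = derive_seed(config$seed, 400L + m),
                          weight_metric = config$weight_metric)
    ev$table$month <- m
    eval_tables[[m]] <- ev$table
    weights_by_month[[m]] <- ev$weights
    fits <- lapply(config$algorithms, function(alg)
      fit_sdm(design, alg, seed = derive_seed(config$seed, 500L + m)))
    names(fits) <- config$algorithms
    rasters <- lapply(fits, predict_raster, stack = stacks[[m]][predictors])
    ens <- ensemble_weighted(rasters, ev$weights)
    ensembles[[m]] <- normalize_raster(ens, winsor_q = 99)
    if (!is.null(config$importance_month) && m == config$importance_month) {
      importance <- do.call(rbind, lapply(config$algorithms, function(alg) {
        imp <- permutation_importance(fits[[alg]], design,
                                      n_reps = config$importance_reps,
                                      seed = derive_seed(config$seed, 700L))
        imp$algorithm <- alg
        imp
      }))
    }
  }
  evaluation <- do.call(rbind, eval_tables)

  ## stage 5: seasonal endpoints and conductance
  winter_pts <- grid_thin(prepped[prepped$season == "winter", , drop = FALSE],
                          config$thin_cell_deg)
  summer_pts <- grid_thin(prepped[prepped$season == "summer", , drop = FALSE],
                          config$thin_cell_deg)
  corridors <- list()
  for (season in c("spring", "fall")) {
    cond <- seasonal_conductance(ensembles, season)
    graph <- build_graph(cond)
    # migration direction: spring = winter -> summer, fall = summer -> winter
    src <- if (season == "spring") winter_pts else summer_pts
    dst <- if (season == "spring") summer_pts else winter_pts
    paths <- lcp_density(graph, src, dst)
    # a cell holding both seasons' points cannot be source and ground at
    # once; such cells stay grounds and are removed from the sources
    src_cells <- cell_from_lonlat(cond, src$lon, src$lat)
    dst_cells <- cell_from_lonlat(cond, dst$lon, dst$lat)
    shared <- paste(src_cells$row, src_cells$col) %in%
      paste(dst_cells$row, dst_cells$col)
    if (any(shared))
      message(sum(shared), " ", season,
              " source point(s) share a cell with grounds; dropped")
    circuit <- solve_current(graph, src[!shared, , drop = FALSE], dst)
    suit_mask <- percentile_mask(cond, config$percentile_q)
    cons <- consensus_overlap(paths$density, circuit$current, suit_mask,
                              density_q = config$percentile_q,
                              current_q = config$percentile_q)
    stats <- corridor_stats(paths, n_perm = config$n_perm,
                            seed = derive_seed(config$seed,
                                               600L + (season == "fall")))
    stats$season <- season
    corridors[[season]] <- list(conductance = cond, paths = paths,
                                current = circuit$current,
                                suitability_mask = suit_mask,
                                consensus = cons, stats = stats)
  }
  stats_table <- do.call(rbind, lapply(corridors, `[[`, "stats"))

  result <- structure(
    list(config = config, specs = specs,
         occurrences = list(raw = raw, prepped = prepped,
                            winter = winter_pts, summer = summer_pts),
         screen = list(report = report, drops = drops,
                       predictors = predictors),
         evaluation = evaluation, weights = weights_by_month,
         ensembles = ensembles, truth = truth, importance = importance,
         corridors = corridors, stats = stats_table),
    class = "pipeline_result")

  if (!is.null(out)) {
    result$manifest <- write_pipeline_artifacts(result, out, t0)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  occurrences: %d raw -> %d prepped\n",
              nrow(x$occurrences$raw), nrow(x$occurrences$prepped)))
  cat("  predictors retained:", paste(x$screen$predictors, collapse = ", "),
      "\n")
  ens <- x$evaluation[x$evaluation$algorithm == "ensemble", ]
  cat(sprintf("  ensemble test AUC: %.3f (mean over months), TSS: %.3f\n",
              mean(ens$auc), mean(ens$tss)))
  print(x$stats[, c("season", "morans_i", "morans_p", "gearys_c", "gearys_p",
                    "mean_increase_km", "t_p")], row.names = FALSE)
  invisible(x)
}

# Write all artifacts and return the manifest (also written as JSON).
write_pipeline_artifacts <- function(result, out, t0) {
  dir.create(file.path(out, "sdm"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "corridors"), showWarnings = FALSE)
  dir.create(file.path(out, "stats"), showWarnings = FALSE)
  num_csv <- function(df, path) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) signif(col, 15) else col)
    utils::write.csv(df, path, row.names = FALSE)
  }
  num_csv(result$occurrences$raw, file.path(out, "occurrences_raw.csv"))
  num_csv(result$occurrences$prepped, file.path(out, "occurrences_prepped.csv"))
  write_correlation_report(result$screen$report, result$screen$drops,
                           file.path(out, "screen"))
  num_csv(result$evaluation, file.path(out, "sdm", "evaluation.csv"))
  if (!is.null(result$importance))
    num_csv(result$importance, file.path(out, "sdm", "importance.csv"))
  for (m in 1:12)
    write_raster(result$ensembles[[m]],
                 file.path(out, "sdm", sprintf("ensemble_m%02d.asc", m)))
  for (season in names(result$corridors)) {
    cr <- result$corridors[[season]]
    write_raster(cr$paths$density,
                 file.path(out, "corridors", paste0(season, "_density.asc")))
    write_raster(cr$current,
                 file.path(out, "corridors", paste0(season, "_current.asc")))
    write_raster(cr$suitability_mask,
                 file.path(out, "corridors", paste0(season, "_mask.asc")))
    write_raster(cr$consensus$consensus,
                 file.path(out, "corridors", paste0(season, "_consensus.asc")))
    num_csv(cr$paths$pairs,
            file.path(out, "corridors", paste0(season, "_pairs.csv")))
  }
  num_csv(result$stats, file.path(out, "stats", "corridor_stats.csv"))

  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  cfg <- result$config
  cfg <- cfg[!vapply(cfg, is.matrix, TRUE)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("migrascape")),
    config = cfg,
    corridor_polyline = result$config$corridor_polyline,
    seed = result$config$seed,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = hashes)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
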