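#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann--Whitney statistic: the
#' probability that a random presence scores above a random background
#' point, with ties counted 0.5.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0L || nb == 0L) stop("both score sets must be non-empty", call. = FALSE)
  r <- rank(c(scores_presence, scores_background), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximum True Skill Statistic over thresholds
#'
#' TSS = sensitivity + specificity - 1, with `score >= threshold` predicting
#' presence. Candidate thresholds are the midpoints of the sorted unique
#' scores plus one threshold below the minimum; ties on TSS break toward the
#' lower threshold.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return List with `tss` (the maximum) and `threshold`.
#' @export
tss_max <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0L || nb == 0L) stop("both score sets must be non-empty", call. = FALSE)
  u <- sort(unique(c(scores_presence, scores_background)))
  cand <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else numeric(0)
  cand <- c(u[1L] - 1, cand)
  best_tss <- -Inf; best_thr <- cand[1L]
  for (thr in cand) {
    sens <- mean(scores_presence >= thr)
    spec <- mean(scores_background < thr)
    tss <- sens + spec - 1
    if (tss > best_tss + 1e-12) { best_tss <- tss; best_thr <- thr }
  }
  list(tss = best_tss, threshold = best_thr)
}

#' Permutation variable importance
#'
#' Importance of a predictor = baseline AUC on the design minus the mean AUC
#' over `n_reps` random permutations of that predictor's column (model is
#' not refit). Rank 1 = most important.
#'
#' @param model a fitted `sdm`.
#' @param design the `sdm_design` to score on.
#' @param n_reps permutations per predictor.
#' @param seed integer seed.
#' @return data.frame with `predictor`, `importance`, `rank`, sorted by rank.
#' @export
permutation_importance <- function(model, design, n_reps = 10L, seed = 1L) {
  stopifnot(inherits(model, "sdm"), inherits(design, "sdm_design"))
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  pres <- design$label == 1L
  base_scores <- predict(model, design$x)
  base_auc <- auc(base_scores[pres], base_scores[!pres])
  set.seed(seed)
  imp <- vapply(design$predictors, function(v) {
    drop_auc <- vapply(seq_len(n_reps), function(r) {
      xp <- design$x
      xp[[v]] <- sample(xp[[v]])
      s <- predict(model, xp)
      auc(s[pres], s[!pres])
    }, 0)
    base_auc - mean(drop_auc)
  }, 0)
  out <- data.frame(predictor = design$predictors, importance = unname(imp))
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}

#' Performance-weighted ensemble of suitability rasters
#'
#' Cell-wise weighted mean of aligned per-algorithm rasters. Raw weights are
#' floored at zero (a worse-than-chance model contributes nothing) and
#' normalized to sum to one; cells masked in any input are masked in the
#' output.
#'
#' @param rasters named list of aligned `raster_grid`s, one per algorithm.
#' @param weights numeric vector of raw weights (e.g. per-model TSS), named
#'   or in the order of `rasters`.
#' @return A `raster_grid`.
#' @export
ensemble_weighted <- function(rasters, weights) {
  stopifnot(is.list(rasters), length(rasters) >= 1L)
  if (!is.null(names(weights)) && !is.null(names(rasters))) {
    missing <- setdiff(names(rasters), names(weights))
    if (length(missing))
      stop("weights missing for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    weights <- weights[names(rasters)]
  }
  if (length(weights) != length(rasters))
    stop("one weight per raster required", call. = FALSE)
  for (r in rasters[-1]) check_aligned(rasters[[1L]], r)
  w <- pmax(as.numeric(weights), 0)
  if (sum(w) <= 0)
    stop("degenerate weights: all weights are <= 0", call. = FALSE)
  w <- w / sum(w)
  acc <- 0
  for (i in seq_along(rasters)) acc <- acc + w[i] * rasters[[i]]$values
  set_values(rasters[[1L]], acc)
}

#' Winsorize and rescale a raster to [0, 1]
#'
#' Caps values at the `winsor_q`-th percentile of valid cells (removing the
#' influence of outlier cells), then min--max rescales to [0, 1].
#'
#' @param r a `raster_grid` with at least 2 distinct valid values.
#' @param winsor_q cap percentile (default 99; 100 = no capping).
#' @return A `raster_grid` with valid values in [0, 1].
#' @export
normalize_raster <- function(r, winsor_q = 99) {
  stopifnot(inherits(r, "raster_grid"))
  v <- r$values
  ok <- is.finite(v)
  if (length(unique(v[ok])) < 2L)
    stop("degenerate range: raster is constant", call. = FALSE)
  cap <- pctl(v, winsor_q)
  v[ok & v > cap] <- cap
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi == lo) stop("degenerate range after capping", call. = FALSE)
  set_values(r, (v - lo) / (hi - lo))
}

#' Cross-validated evaluation of the four algorithms plus the ensemble
#'
#' Splits the design into `k` folds; for each fold, fits every algorithm on
#' the other k-1 folds and scores the held-out fold. Pooled out-of-fold
#' scores give each algorithm's test AUC, maximum TSS and TSS threshold.
#' The ensemble column is the TSS-weighted (or AUC-weighted) combination of
#' the per-algorithm out-of-fold scores, evaluated on the same folds.
#'
#' @param design an `sdm_design` with both classes.
#' @param algorithms algorithms to fit.
#' @param k number of folds.
#' @param seed integer seed.
#' @param weight_metric `"tss"` or `"auc"`: the ensemble weighting metric.
#' @return List with `table` (data.frame: algorithm, auc, tss, threshold),
#'   `weights` (raw ensemble weights), and `oof_scores` (matrix of pooled
#'   out-of-fold scores, one column per algorithm plus `ensemble`), `label`.
#' @export
evaluate_models <- function(design, algorithms = c("bioclim", "glm", "maxent", "rf"),
                            k = 5L, seed = 1L, weight_metric = c("tss", "auc")) {
  weight_metric <- match.arg(weight_metric)
  n <- length(design$label)
  folds <- make_folds(n, k = k, seed = derive_seed(seed, 17L))
  oof <- matrix(NA_real_, n, length(algorithms),
                dimnames = list(NULL, algorithms))
  for (f in seq_len(k)) {
    train <- design_subset(design, folds != f)
    test_x <- design$x[folds == f, , drop = FALSE]
    for (alg in algorithms) {
      fit <- fit_sdm(train, alg, seed = derive_seed(seed, 100L + f))
      oof[folds == f, alg] <- predict(fit, test_x)
    }
  }
  pres <- design$label == 1L
  tab <- do.call(rbind, lapply(algorithms, function(alg) {
    ts <- tss_max(oof[pres, alg], oof[!pres, alg])
    data.frame(algorithm = alg, auc = auc(oof[pres, alg], oof[!pres, alg]),
               tss = ts$tss, threshold = ts$threshold)
  }))
  w <- pmax(if (weight_metric == "tss") tab$tss else tab$auc, 0)
  names(w) <- algorithms
  if (sum(w) <= 0) w[] <- 1 # all models at or below chance: fall back to mean
  ens <- drop(oof %*% (w / sum(w)))
  ts <- tss_max(ens[pres], ens[!pres])
  tab <- rbind(tab, data.frame(algorithm = "ensemble",
                               auc = auc(ens[pres], ens[!pres]),
                               tss = ts$tss, threshold = ts$threshold))
  list(table = tab, weights = w, oof_scores = cbind(oof, ensemble = ens),
       label = design$label)
}
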