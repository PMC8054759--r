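#' Build a presence-background training design from rasters
#'
#' Samples predictor values at each presence and background point's cell
#' (nearest-cell extraction). Rows falling on a masked cell in any predictor,
#' or outside the grid, are dropped and counted.
#'
#' @param presences,absences occurrence data.frames with `lon`, `lat`.
#' @param stack named list of aligned predictor `raster_grid`s.
#' @param month month index attached to the design, or NA.
#' @return An object of class `sdm_design`: list with `x` (predictor
#'   data.frame), `label` (1 presence / 0 background), `month`,
#'   `predictors`, `n_dropped`.
#' @export
extract_design <- function(presences, absences, stack, month = NA_integer_) {
  template <- stack[[1L]]
  pts <- rbind(presences[, c("lon", "lat")], absences[, c("lon", "lat")])
  label <- c(rep(1L, nrow(presences)), rep(0L, nrow(absences)))
  rc <- cell_from_lonlat(template, pts$lon, pts$lat)
  x <- as.data.frame(lapply(stack, function(r)
    r$values[cbind(rc$row, rc$col)]))
  ok <- stats::complete.cases(x) & !is.na(rc$row)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(n_dropped, " point(s) on masked or out-of-extent cells dropped")
  x <- x[ok, , drop = FALSE]; label <- label[ok]
  if (sum(label == 1L) < 1L)
    stop("empty design: no usable presence rows", call. = FALSE)
  structure(list(x = x, label = label, month = month,
                 predictors = names(stack), n_dropped = n_dropped),
            class = "sdm_design")
}

# subset a design by row index (used for cross-validation)
design_subset <- function(design, idx) {
  structure(list(x = design$x[idx, , drop = FALSE], label = design$label[idx],
                 month = design$month, predictors = design$predictors,
                 n_dropped = 0L),
            class = "sdm_design")
}

#' Fit a species distribution model
#'
#' Fits one of the four presence-background suitability algorithms:
#' \describe{
#'   \item{`bioclim`}{classic climate envelope: scores a point by how central
#'     its predictor values sit within the training presences' empirical
#'     distribution (uses presences only).}
#'   \item{`glm`}{logistic regression of presence vs background on
#'     standardized predictors with quadratic terms, allowing unimodal
#'     responses.}
#'   \item{`maxent`}{MaxEnt-style presence-background model fit as an
#'     L1-regularized logistic regression on linear + quadratic +
#'     pairwise-product features of the standardized predictors.}
#'   \item{`rf`}{random forest classifier (500 trees, square-root feature
#'     sampling); the score is the presence-vote fraction.}
#' }
#' All scores lie in [0, 1] and fits are deterministic given `seed`.
#'
#' @param design an [extract_design()] result with both classes (bioclim
#'   uses only the presence rows).
#' @param algorithm one of `"bioclim"`, `"glm"`, `"maxent"`, `"rf"`.
#' @param seed integer seed (used by the stochastic fits).
#' @param reg_weight L1 regularization multiplier for `maxent`.
#' @return An object of class `c("sdm_<algorithm>", "sdm")`.
#' @export
fit_sdm <- function(design, algorithm = c("bioclim", "glm", "maxent", "rf"),
                    seed = 1L, reg_weight = 1.0) {
  stopifnot(inherits(design, "sdm_design"))
  algorithm <- match.arg(algorithm)
  fitter <- switch(algorithm, bioclim = fit_bioclim_impl,
                   glm = fit_glm_impl, maxent = fit_maxent_impl,
                   rf = fit_rf_impl)
  fit <- fitter(design, seed = seed, reg_weight = reg_weight)
  structure(c(fit, list(algorithm = algorithm, month = design$month,
                        predictors = design$predictors, seed = seed)),
            class = c(paste0("sdm_", algorithm), "sdm"))
}

#' @export
print.sdm <- function(x, ...) {
  cat(sprintf("sdm fit: algorithm = %s, predictors = %s%s\n",
              x$algorithm, paste(x$predictors, collapse = ", "),
              if (is.na(x$month %||% NA)) "" else paste0(", month = ", x$month)))
  invisible(x)
}

## ---- BIOCLIM envelope ----

fit_bioclim_impl <- function(design, ...) {
  pres <- design$x[design$label == 1L, , drop = FALSE]
  if (nrow(pres) < 2L) stop("bioclim needs >= 2 presence rows", call. = FALSE)
  list(train = lapply(pres, sort))
}

# Envelope tail score for one predictor: p = fraction of training values <=
# x; s = 2 * min(p, 1 - p). A constant predictor scores 1 at its constant
# value and 0 elsewhere.
bioclim_tail_score <- function(train, x) {
  n <- length(train)
  if (train[1L] == train[n])
    return(ifelse(x == train[1L], 1, 0))
  p <- findInterval(x, train) / n # sorted train: count of values <= x
  pmin(1, pmax(0, 2 * pmin(p, 1 - p)))
}

#' Predict suitability scores from a fitted model
#'
#' @param object a fitted `sdm`.
#' @param newdata data.frame with the model's predictor columns.
#' @param ... unused.
#' @return Numeric vector of scores in [0, 1].
#' @export
predict.sdm_bioclim <- function(object, newdata, ...) {
  s <- rep(1, nrow(newdata))
  for (v in object$predictors)
    s <- pmin(s, bioclim_tail_score(object$train[[v]], newdata[[v]]))
  s
}

## ---- logistic GLM with quadratic terms ----

standardize_fit <- function(x) {
  center <- vapply(x, mean, 0)
  scale <- vapply(x, stats::sd, 0)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  as.data.frame(Map(function(col, c, s) (col - c) / s, x,
                    std$center[names(x)], std$scale[names(x)]))
}

fit_glm_impl <- function(design, ...) {
  std <- standardize_fit(design$x)
  z <- standardize_apply(design$x, std)
  z2 <- as.data.frame(lapply(z, function(v) v^2))
  names(z2) <- paste0(names(z), "_sq")
  dat <- cbind(y = design$label, z, z2)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial()))
  list(coef = stats::coef(fit), std = std)
}

glm_linpred <- function(object, newdata) {
  z <- standardize_apply(newdata[object$predictors], object$std)
  z2 <- as.data.frame(lapply(z, function(v) v^2))
  names(z2) <- paste0(names(z), "_sq")
  mm <- cbind(1, as.matrix(cbind(z, z2)))
  b <- object$coef
  b[!is.finite(b)] <- 0
  drop(mm %*% b)
}

#' @rdname predict.sdm_bioclim
#' @export
predict.sdm_glm <- function(object, newdata, ...) {
  stats::plogis(glm_linpred(object, newdata))
}

## ---- MaxEnt-style penalized exponential model ----

maxent_features <- function(z) {
  p <- ncol(z)
  feats <- cbind(as.matrix(z), as.matrix(z)^2)
  colnames(feats) <- c(names(z), paste0(names(z), "_sq"))
  if (p >= 2L) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      feats <- cbind(feats, z[[i]] * z[[j]])
      colnames(feats)[ncol(feats)] <- paste0(names(z)[i], "_x_", names(z)[j])
    }
  }
  feats
}

fit_maxent_impl <- function(design, seed = 1L, reg_weight = 1.0) {
  std <- standardize_fit(design$x)
  z <- standardize_apply(design$x, std)
  feats <- maxent_features(z)
  n <- nrow(feats)
  # fixed, sample-size-scaled penalty in the spirit of MaxEnt's default
  # regularization (shrinks like 1/sqrt(n))
  lambda <- reg_weight * sqrt(log(ncol(feats)) / n)
  set.seed(seed)
  fit <- glmnet::glmnet(feats, design$label, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  list(beta = as.numeric(fit$beta), intercept = as.numeric(fit$a0),
       feature_names = colnames(feats), std = std, lambda = lambda)
}

#' @rdname predict.sdm_bioclim
#' @export
predict.sdm_maxent <- function(object, newdata, ...) {
  z <- standardize_apply(newdata[object$predictors], object$std)
  feats <- maxent_features(z)
  stats::plogis(object$intercept + drop(feats %*% object$beta))
}

## ---- random forest ----

fit_rf_impl <- function(design, seed = 1L, ...) {
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = design$x, y = factor(design$label, levels = c(0L, 1L)),
    ntree = 500, mtry = max(1L, floor(sqrt(ncol(design$x)))))
  list(forest = fit)
}

#' @rdname predict.sdm_bioclim
#' @export
predict.sdm_rf <- function(object, newdata, ...) {
  unname(stats::predict(object$forest, newdata = newdata,
                        type = "prob")[, "1"])
}

## ---- raster prediction ----

#' Predict a suitability raster from a fitted model
#'
#' Scores every valid cell of the predictor stack; cells masked in any
#' predictor stay masked in the output.
#'
#' @param model a fitted `sdm`.
#' @param stack named list of aligned predictor `raster_grid`s containing
#'   all the model's predictors.
#' @return A `raster_grid` of suitabilities in [0, 1].
#' @export
predict_raster <- function(model, stack) {
  stopifnot(inherits(model, "sdm"))
  missing <- setdiff(model$predictors, names(stack))
  if (length(missing))
    stop("missing layer(s): ", paste(missing, collapse = ", "), call. = FALSE)
  template <- stack[[model$predictors[1L]]]
  x <- as.data.frame(lapply(stack[model$predictors], function(r)
    as.vector(r$values)))
  ok <- stats::complete.cases(x)
  out <- rep(NA_real_, nrow(x))
  if (any(ok)) out[ok] <- predict(model, x[ok, , drop = FALSE])
  set_values(template, matrix(out, nrow(template$values)))
}
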