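#' Pairwise Pearson correlations between predictor layers
#'
#' Computes Pearson r for every pair of layers over the cells valid in both.
#' A layer with zero variance over the shared cells yields NA for its pairs
#' and a note in the report.
#'
#' @param stack named list of aligned `raster_grid` layers (>= 2).
#' @return An object of class `correlation_report`: list with `variables`,
#'   the symmetric correlation `matrix`, and `degenerate` (zero-variance
#'   layer names).
#' @export
pairwise_correlation <- function(stack) {
  if (length(stack) < 2L) stop("need at least 2 layers", call. = FALSE)
  vars <- names(stack)
  for (nm in vars[-1]) check_aligned(stack[[1L]], stack[[nm]])
  n <- length(vars)
  m <- diag(1, n); dimnames(m) <- list(vars, vars)
  degenerate <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    x <- as.vector(stack[[i]]$values); y <- as.vector(stack[[j]]$values)
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop("fewer than 3 shared valid cells", call. = FALSE)
    sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
    if (sx == 0 || sy == 0) {
      m[i, j] <- m[j, i] <- NA_real_
      if (sx == 0) degenerate <- union(degenerate, vars[i])
      if (sy == 0) degenerate <- union(degenerate, vars[j])
    } else {
      m[i, j] <- m[j, i] <- stats::cor(x[ok], y[ok])
    }
  }
  structure(list(variables = vars, matrix = m, degenerate = degenerate),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("correlation_report over", length(x$variables), "layers\n")
  print(round(x$matrix, 3))
  if (length(x$degenerate))
    cat("zero-variance layers:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Drop one member of each highly correlated predictor pair
#'
#' Pairs with |r| strictly above `threshold` are processed greedily in
#' descending |r|; within a pair, the variable ranked lower in `preference`
#' is dropped and takes no further part. The default threshold of 0.8 is the
#' conventional collinearity cutoff for distribution-model predictors; the
#' default preference order puts average temperature and the radiation /
#' moisture variables first, reflecting their typical biological relevance
#' for insectivorous bats.
#'
#' @param report a [pairwise_correlation()] result.
#' @param threshold |r| above which a pair is considered redundant.
#' @param preference character vector ranking all variables, most-preferred
#'   first.
#' @return List with `retained` (names), `dropped` (data.frame of dropped
#'   variable, retained partner and r).
#' @export
drop_correlated <- function(report, threshold = 0.8,
                            preference = c("tavg", "solar", "vapor", "precip",
                                           "elev", "human", "wind", "ndvi",
                                           "forest")) {
  stopifnot(inherits(report, "correlation_report"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  vars <- report$variables
  missing <- setdiff(vars, preference)
  if (length(missing))
    stop("variables missing from preference order: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rank <- match(vars, preference); names(rank) <- vars
  m <- abs(report$matrix); diag(m) <- 0
  pairs <- which(upper.tri(m) & m > threshold & is.finite(m), arr.ind = TRUE)
  if (nrow(pairs)) pairs <- pairs[order(-m[pairs]), , drop = FALSE]
  dropped <- data.frame(dropped = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  out <- character(0)
  for (p in seq_len(nrow(pairs))) {
    a <- vars[pairs[p, 1]]; b <- vars[pairs[p, 2]]
    if (a %in% out || b %in% out) next
    loser <- if (rank[a] <= rank[b]) b else a
    winner <- setdiff(c(a, b), loser)
    out <- c(out, loser)
    dropped <- rbind(dropped, data.frame(
      dropped = loser, partner = winner,
      r = report$matrix[a, b], stringsAsFactors = FALSE))
  }
  list(retained = setdiff(vars, out), dropped = dropped)
}

#' Write a correlation report and drop log to disk
#'
#' @param report a `correlation_report`.
#' @param drops result of [drop_correlated()], or NULL.
#' @param dir output directory.
#' @export
write_correlation_report <- function(report, drops = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$matrix, file.path(dir, "predictor_correlations.csv"))
  if (!is.null(drops))
    jsonlite::write_json(drops, file.path(dir, "predictor_drops.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
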