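#' Remove extreme-value outliers from a sample table
#'
#' Drops measurements strictly greater than the threshold (default 250
#' ug/m3, above which daily PM2.5 values are either recording errors or
#' short extreme events); values exactly at the threshold are kept.
#'
#' @param samples An [st_samples()] table.
#' @param threshold Positive cutoff in ug/m3.
#' @return List with the kept `samples` and the `removed` count.
#' @export
remove_outliers <- function(samples, threshold = 250) {
  samples <- st_samples(samples)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  keep <- samples$w <= threshold
  list(samples = samples[keep, , drop = FALSE],
       removed = sum(!keep))
}

#' Random k-fold assignment
#'
#' Splits n samples into k near-equal folds uniformly at random (fold
#' sizes differ by at most one); reproducible under a fixed seed.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed.
#' @return Object of class `fold_assignment` with `fold_of` (integer in
#'   1..k per sample), `k` and `seed`.
#' @export
kfold_split <- function(n, k = 10L, seed = 20090101L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (is.na(n) || is.na(k) || k < 2L)
    stop("`n` and `k` must be integers, k >= 2", call. = FALSE)
  if (n < k)
    stop(sprintf("cannot split n=%d samples into k=%d folds", n, k),
         call. = FALSE)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  perm <- withr::with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), times = sizes)
  structure(list(fold_of = fold_of, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Interpolation error statistics
#'
#' Computes, for paired interpolated (I) and observed (O) values:
#' MAE = mean |I - O|; MSE = mean (I - O)^2; RMSE = sqrt(MSE);
#' MARE = mean |I - O| / O; and a cross-validated R-squared against the
#' 1-1 line, R2 = max(0, 1 - RMSE^2 / MSE_obs) with
#' MSE_obs = mean (O - mean(O))^2. MARE requires strictly positive
#' observations. A constant observed set makes MSE_obs zero and the
#' R-squared undefined; it is reported as 0 with a warning.
#'
#' @param interpolated,observed Equal-length numeric vectors.
#' @return Named numeric vector `mae`, `mse`, `rmse`, `mare`, `r2cv`.
#' @examples
#' error_stats(c(2, 2, 2), c(1, 2, 3))
#' @export
error_stats <- function(interpolated, observed) {
  I <- as.numeric(interpolated)
  O <- as.numeric(observed)
  if (length(I) != length(O))
    stop("interpolated and observed must have equal length", call. = FALSE)
  if (length(I) == 0L)
    stop("empty input: no pairs to score", call. = FALSE)
  if (anyNA(I) || anyNA(O))
    stop("NA values in error_stats input", call. = FALSE)
  if (any(O <= 0))
    stop("observed values must be > 0 (MARE divides by them)",
         call. = FALSE)
  e <- I - O
  mae <- mean(abs(e))
  mse <- mean(e * e)
  rmse <- sqrt(mse)
  mare <- mean(abs(e) / O)
  mse_obs <- mean((O - mean(O))^2)
  if (mse_obs == 0) {
    if (mse > 0)
      warning("constant observed set: R2_cv undefined, reported as 0",
              call. = FALSE)
    r2cv <- if (mse == 0) 1 else 0
  } else {
    r2cv <- max(0, 1 - mse / mse_obs)
  }
  c(mae = mae, mse = mse, rmse = rmse, mare = mare, r2cv = r2cv)
}

#' k-fold cross-validation of a spatiotemporal interpolator
#'
#' Holds out each fold in turn, fits the interpolator on the remaining
#' folds (a fresh mesh for the shape-function method; the training sample
#' set for IDW), interpolates the held-out space-time points and scores
#' them. Per-fold statistics are averaged arithmetically, statistic by
#' statistic (so the averaged RMSE is the mean of per-fold RMSEs, not the
#' root of the averaged MSE).
#'
#' Held-out points falling outside the convex hull of a training mesh
#' cannot be interpolated by shape functions; they are excluded from that
#' fold's statistics and counted in `n_outside`.
#'
#' @param samples An [st_samples()] table.
#' @param method `"sf"` (shape function) or `"idw"`.
#' @param scale A [time_scale()] or bare c.
#' @param k Number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param n_neighbors,exponent IDW configuration (required for
#'   `method = "idw"`).
#' @param folds Optional pre-computed [kfold_split()] (lets several
#'   configurations share one assignment for paired comparison).
#' @return Object of class `cv_report`: `per_fold` data frame (one row per
#'   fold), `averaged` named statistics, configuration fields, and
#'   exclusion counts.
#' @export
cross_validate <- function(samples, method = c("sf", "idw"), scale,
                           k = 10L, seed = 20090101L,
                           n_neighbors = NULL, exponent = NULL,
                           folds = NULL) {
  samples <- st_samples(samples)
  method <- match.arg(method)
  scale <- as_time_scale(scale)
  if (is.null(folds)) folds <- kfold_split(nrow(samples), k, seed)
  stopifnot(inherits(folds, "fold_assignment"))
  if (length(folds$fold_of) != nrow(samples))
    stop("fold assignment does not match the sample count", call. = FALSE)
  k <- folds$k
  if (method == "idw") {
    if (is.null(n_neighbors) || is.null(exponent))
      stop("IDW cross-validation needs `n_neighbors` and `exponent`",
           call. = FALSE)
    cfg <- idw_config(n_neighbors, exponent, scale)
  }
  per <- vector("list", k)
  n_outside <- integer(k)
  n_test <- integer(k)
  for (i in seq_len(k)) {
    hold <- folds$fold_of == i
    train <- samples[!hold, , drop = FALSE]
    test <- samples[hold, , drop = FALSE]
    n_test[i] <- nrow(test)
    if (method == "sf") {
      mesh <- build_mesh(train, scale)
      pred <- sf_interpolate(mesh, test, outside = "missing")
      drop <- is.na(pred)
      n_outside[i] <- sum(drop)
      if (all(drop))
        stop(sprintf(
          "fold %d: every held-out point lies outside the training hull",
          i), call. = FALSE)
      st <- error_stats(pred[!drop], test$w[!drop])
    } else {
      pred <- idw_interpolate(train, test, cfg)
      st <- error_stats(pred, test$w)
    }
    per[[i]] <- c(fold = i, st)
  }
  per_fold <- as.data.frame(do.call(rbind, per))
  averaged <- colMeans(per_fold[, c("mae", "mse", "rmse", "mare", "r2cv")])
  structure(list(
    method = method,
    scale = scale,
    n_neighbors = if (method == "idw") cfg$n_neighbors else NA_integer_,
    exponent = if (method == "idw") cfg$exponent else NA_real_,
    k = k, seed = folds$seed,
    per_fold = per_fold,
    averaged = averaged,
    n_outside = n_outside,
    n_test = n_test
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  desc <- if (x$method == "sf") sprintf("SF, %s", x$scale$label) else
    sprintf("IDW (N=%d, p=%g), %s", x$n_neighbors, x$exponent,
            x$scale$label)
  cat(sprintf("<cv_report> %s; %d-fold (seed %d)\n", desc, x$k, x$seed))
  if (sum(x$n_outside) > 0)
    cat(sprintf("  %d of %d held-out points outside training hull\n",
                sum(x$n_outside), sum(x$n_test)))
  cat("  averaged: ",
      paste(sprintf("%s=%.*f", names(x$averaged), digits, x$averaged),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Grid search over time scales and IDW configurations
#'
#' Cross-validates every candidate configuration -- each time scale for
#' the shape-function method, or each (scale, N, p) triple for IDW -- with
#' a single shared fold assignment so rankings reflect configuration
#' differences only, then ranks by the chosen averaged error statistic
#' (ascending for errors, descending for the cross-validated R-squared).
#' The default IDW grid is N in 3..7 and p in 1.0, 1.5, ..., 5.0 (45
#' configurations per time scale).
#'
#' @param samples An [st_samples()] table.
#' @param method `"sf"` or `"idw"`.
#' @param scales List of [time_scale()]s (default: the four presets).
#' @param n_neighbors,exponents IDW grid (ignored for `"sf"`).
#' @param criterion Ranking statistic: one of `"mare"`, `"mae"`, `"mse"`,
#'   `"rmse"`, `"r2cv"`.
#' @param k,seed Cross-validation folds and seed.
#' @return Object of class `grid_search`: ranked `table` (one row per
#'   configuration with its averaged statistics) and the underlying list
#'   of `reports`.
#' @export
grid_search <- function(samples, method = c("sf", "idw"),
                        scales = time_scale_presets(),
                        n_neighbors = 3:7,
                        exponents = seq(1, 5, by = 0.5),
                        criterion = c("mare", "mae", "mse", "rmse", "r2cv"),
                        k = 10L, seed = 20090101L) {
  samples <- st_samples(samples)
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (inherits(scales, "time_scale")) scales <- list(scales)
  if (length(scales) == 0L) stop("empty time-scale grid", call. = FALSE)
  scales <- lapply(scales, as_time_scale)
  folds <- kfold_split(nrow(samples), k, seed)
  reports <- list()
  if (method == "sf") {
    for (sc in scales)
      reports[[length(reports) + 1L]] <-
        cross_validate(samples, "sf", sc, folds = folds)
  } else {
    n_neighbors <- as.integer(n_neighbors)
    if (length(n_neighbors) == 0L || length(exponents) == 0L)
      stop("empty IDW grid", call. = FALSE)
    kmax <- max(n_neighbors)
    if (kmax > min(table(folds$fold_of)) * (folds$k - 1L))
      stop("n_neighbors too large for the training folds", call. = FALSE)
    for (sc in scales) {
      nn_by_fold <- precompute_fold_nn(samples, sc, folds, kmax)
      for (N in n_neighbors) for (p in exponents)
        reports[[length(reports) + 1L]] <-
          cv_idw_from_nn(samples, sc, folds, nn_by_fold, N, p)
    }
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(scale_label = r$scale$label, c = r$scale$c,
               n_neighbors = r$n_neighbors, exponent = r$exponent,
               t(r$averaged))
  }))
  ord <- if (criterion == "r2cv") order(-tab[[criterion]]) else
    order(tab[[criterion]])
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, reports = reports[ord],
                 criterion = criterion, method = method,
                 k = folds$k, seed = folds$seed),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, n = 10, ...) {
  cat(sprintf("<grid_search> %s, %d configurations ranked by %s\n",
              toupper(x$method), nrow(x$table), x$criterion))
  print(utils::head(x$table, n), digits = 4)
  invisible(x)
}

# one kNN query per fold (held-out points against the other folds) at the
# largest requested neighbourhood; every (N, p) then reuses the sorted
# neighbour lists, which keeps the paired comparison exact and cheap
precompute_fold_nn <- function(samples, scale, folds, kmax) {
  S <- st_coords(samples, scale)
  lapply(seq_len(folds$k), function(i) {
    hold <- folds$fold_of == i
    nn <- knn_cpp(S[!hold, , drop = FALSE], S[hold, , drop = FALSE], kmax)
    nn$train_w <- samples$w[!hold]
    nn$test_w <- samples$w[hold]
    nn
  })
}

cv_idw_from_nn <- function(samples, scale, folds, nn_by_fold, N, p) {
  per <- lapply(seq_len(folds$k), function(i) {
    nn <- nn_by_fold[[i]]
    pred <- idw_from_nn(list(idx = nn$idx[, seq_len(N), drop = FALSE],
                             dist = nn$dist[, seq_len(N), drop = FALSE]),
                        nn$train_w, p)
    c(fold = i, error_stats(pred, nn$test_w))
  })
  per_fold <- as.data.frame(do.call(rbind, per))
  averaged <- colMeans(per_fold[, c("mae", "mse", "rmse", "mare", "r2cv")])
  structure(list(
    method = "idw", scale = scale,
    n_neighbors = as.integer(N), exponent = as.numeric(p),
    k = folds$k, seed = folds$seed,
    per_fold = per_fold, averaged = averaged,
    n_outside = integer(folds$k),
    n_test = as.integer(table(folds$fold_of))
  ), class = "cv_report")
}
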