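#' Inverse-distance-weighting configuration
#'
#' @param n_neighbors Number N of nearest known points used per query.
#' @param exponent Distance-decay exponent p > 0.
#' @param scale A [time_scale()] (or bare c) giving the space-time metric.
#' @return An object of class `idw_config`.
#' @export
idw_config <- function(n_neighbors, exponent, scale) {
  n_neighbors <- as.integer(n_neighbors)
  if (length(n_neighbors) != 1L || is.na(n_neighbors) || n_neighbors < 1L)
    stop("`n_neighbors` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(exponent) || length(exponent) != 1L ||
      !is.finite(exponent) || exponent <= 0)
    stop("`exponent` must be a single positive number", call. = FALSE)
  structure(list(n_neighbors = n_neighbors, exponent = as.numeric(exponent),
                 scale = as_time_scale(scale)),
            class = "idw_config")
}

#' @export
print.idw_config <- function(x, ...) {
  cat(sprintf("<idw_config> N = %d, p = %g, %s\n",
              x$n_neighbors, x$exponent, x$scale$label))
  invisible(x)
}

#' Space-time distance under the extension approach
#'
#' The 3D Euclidean distance between space-time points after mapping the
#' day index through the time scale:
#' sqrt((x1-x2)^2 + (y1-y2)^2 + c^2 (t1-t2)^2).
#'
#' @param a,b Numeric length-3 vectors (x, y, t), or matrices with three
#'   columns (rowwise distances; rows are recycled to the longer of the
#'   two).
#' @param scale A [time_scale()] or bare c.
#' @return Numeric distance(s) in the spatial distance unit.
#' @examples
#' st_distance(c(0, 0, 0), c(0, 0, 10), time_scale(1 / 10)) # 1
#' @export
st_distance <- function(a, b, scale) {
  scale <- as_time_scale(scale)
  a <- if (is.matrix(a)) a else matrix(a, ncol = 3L, byrow = TRUE)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 3L, byrow = TRUE)
  dx <- a[, 1] - b[, 1]
  dy <- a[, 2] - b[, 2]
  dt <- scale$c * (a[, 3] - b[, 3])
  sqrt(dx * dx + dy * dy + dt * dt)
}

# weighted value from a sorted k-nearest-neighbour result; exact at zero
# distance (mean of all co-located selected samples, the p -> continuity
# limit of the IDW formula). Overflow-safe for large p: weights are
# computed as (dmin/d)^p <= 1.
idw_from_nn <- function(nn, values, p) {
  d <- nn$dist
  if (!is.matrix(d)) d <- matrix(d, ncol = 1L)
  idx <- nn$idx
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 1L)
  vals <- matrix(values[idx], ncol = ncol(idx))
  zero <- d == 0
  has_zero <- rowSums(zero) > 0L
  dmin <- d[, 1]
  dmin[has_zero] <- 1  # placeholder, rows overwritten below
  ratio <- dmin / d
  wts <- ratio^p
  res <- rowSums(wts * vals) / rowSums(wts)
  if (any(has_zero))
    res[has_zero] <- rowSums((zero * vals)[has_zero, , drop = FALSE]) /
      rowSums(zero[has_zero, , drop = FALSE])
  res
}

#' Inverse-distance-weighting spatiotemporal interpolation
#'
#' For each query, selects its N nearest samples under the scaled
#' space-time distance (ties broken deterministically by sample order) and
#' returns the weighted mean with weights proportional to 1/d^p. A query
#' coinciding with a sample gets the measured value (the mean, if several
#' samples share the location) -- the continuity limit of the weights.
#'
#' @param samples An [st_samples()] table.
#' @param queries Data frame with `x`, `y`, `t` columns.
#' @param config An [idw_config()].
#' @return Numeric vector of interpolated concentrations.
#' @examples
#' s <- data.frame(site_id = c("a", "b", "c"), x = c(1, 2, 4),
#'                 y = 0, t = 1L, w = c(1, 2, 3))
#' cfg <- idw_config(3, 1, time_scale(1))
#' idw_interpolate(st_samples(s), data.frame(x = 0, y = 0, t = 1L), cfg)
#' # (1/1*1 + 1/2*2 + 1/4*3) / (1 + 1/2 + 1/4) = 1.5714...
#' @export
idw_interpolate <- function(samples, queries, config) {
  samples <- st_samples(samples)
  stopifnot(inherits(config, "idw_config"))
  n <- nrow(samples)
  if (config$n_neighbors > n)
    stop(sprintf(
      "n_neighbors (%d) exceeds the number of samples (%d)",
      config$n_neighbors, n), call. = FALSE)
  S <- st_coords(samples, config$scale)
  Q <- query_coords_idw(queries, config$scale)
  nn <- knn_cpp(S, Q, config$n_neighbors)
  idw_from_nn(nn, samples$w, config$exponent)
}

query_coords_idw <- function(queries, scale) {
  if (is.matrix(queries)) {
    stopifnot(ncol(queries) == 3L)
    return(queries)
  }
  if (!all(c("x", "y", "t") %in% names(queries)))
    stop("queries need columns x, y, t", call. = FALSE)
  st_coords(queries, scale)
}
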