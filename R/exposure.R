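#' Validate a centroid table
#'
#' @param centroids Data frame with `unit_id`, `x`, `y` (degrees);
#'   optionally `population`.
#' @return The validated data frame.
#' @export
st_centroids <- function(centroids) {
  if (!is.data.frame(centroids))
    stop("`centroids` must be a data frame", call. = FALSE)
  miss <- setdiff(c("unit_id", "x", "y"), names(centroids))
  if (length(miss))
    stop("missing centroid columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(centroids) == 0L)
    stop("`centroids` has no rows", call. = FALSE)
  if (anyDuplicated(centroids$unit_id))
    stop("duplicate unit_id in centroid table", call. = FALSE)
  centroids
}

#' Interpolate daily concentrations at census-unit centroids
#'
#' Evaluates the chosen interpolator at every (centroid, day) pair,
#' producing the long table that exposure summaries aggregate. Work is
#' chunked over centroids so memory stays bounded in the number of units;
#' the mesh (for the shape-function method) is built once.
#'
#' @param samples An [st_samples()] table (monitoring data).
#' @param centroids An [st_centroids()] table.
#' @param method `"sf"` or `"idw"`.
#' @param scale A [time_scale()] or bare c.
#' @param days Integer vector of day indices to interpolate (e.g.
#'   `1:365`).
#' @param n_neighbors,exponent IDW configuration (`method = "idw"`).
#' @param outside Out-of-hull policy for the shape-function method (see
#'   [sf_interpolate()]).
#' @param chunk_size Number of centroids interpolated per chunk.
#' @return Data frame `unit_id`, `t`, `w` (NA where a centroid-day is
#'   outside the mesh hull under the `"missing"` policy).
#' @export
interpolate_daily_grid <- function(samples, centroids,
                                   method = c("sf", "idw"), scale,
                                   days,
                                   n_neighbors = 3L, exponent = 5,
                                   outside = "missing",
                                   chunk_size = 200L) {
  samples <- st_samples(samples)
  centroids <- st_centroids(centroids)
  method <- match.arg(method)
  scale <- as_time_scale(scale)
  days <- as.integer(days)
  if (length(days) == 0L)
    stop("`days` must be a nonempty vector of day indices", call. = FALSE)
  if (anyNA(days) || any(days < 1L))
    stop("`days` must be positive day indices", call. = FALSE)
  if (method == "sf") mesh <- build_mesh(samples, scale)
  else cfg <- idw_config(n_neighbors, exponent, scale)
  nu <- nrow(centroids)
  chunks <- split(seq_len(nu),
                  ceiling(seq_len(nu) / max(1L, as.integer(chunk_size))))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    # unit-major ordering: consecutive days of one centroid are adjacent,
    # which keeps the mesh walk local
    q <- data.frame(
      unit_id = rep(centroids$unit_id[idx], each = length(days)),
      x = rep(centroids$x[idx], each = length(days)),
      y = rep(centroids$y[idx], each = length(days)),
      t = rep(days, times = length(idx)))
    q$w <- if (method == "sf")
      sf_interpolate(mesh, q, outside = outside)
    else
      idw_interpolate(samples, q, cfg)
    out[[ci]] <- q[, c("unit_id", "t", "w")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_missing <- sum(is.na(res$w))
  if (n_missing > 0)
    message(sprintf(
      "%d of %d centroid-days outside the mesh hull left missing",
      n_missing, nrow(res)))
  res
}

#' Annual mean concentration per census unit
#'
#' Unweighted mean of the available (non-missing) daily values.
#'
#' @param daily Long table `unit_id`, `t`, `w` as produced by
#'   [interpolate_daily_grid()].
#' @return Data frame `unit_id`, `annual_mean`, `days_available`.
#' @export
annual_means <- function(daily) {
  check_daily(daily)
  ids <- unique(daily$unit_id)
  ok <- !is.na(daily$w)
  avail <- tapply(ok, daily$unit_id, sum)
  mn <- tapply(daily$w, daily$unit_id, mean, na.rm = TRUE)
  mn[avail[names(mn)] == 0] <- NA_real_
  data.frame(unit_id = ids,
             annual_mean = as.numeric(mn[as.character(ids)]),
             days_available = as.integer(avail[as.character(ids)]))
}

#' Seasonal mean concentrations per census unit
#'
#' Seasons follow the single-calendar-year convention: winter combines
#' January, February and December of the same year; spring is
#' March-May, summer June-August, fall September-November. Missing days
#' are excluded from the denominators; a unit with no available day in a
#' season gets NA for it.
#'
#' @param daily Long table `unit_id`, `t`, `w`.
#' @param year Study year (maps day indices to months).
#' @return Data frame `unit_id`, `winter`, `spring`, `summer`, `fall`.
#' @export
seasonal_means <- function(daily, year = 2009L) {
  check_daily(daily)
  mon <- month_of_day(daily$t, year)
  season <- c("winter", "winter", "spring", "spring", "spring",
              "summer", "summer", "summer", "fall", "fall", "fall",
              "winter")[mon]
  ids <- unique(daily$unit_id)
  res <- data.frame(unit_id = ids)
  for (s in c("winter", "spring", "summer", "fall")) {
    sel <- season == s
    avail <- tapply(!is.na(daily$w[sel]), daily$unit_id[sel], sum)
    mn <- tapply(daily$w[sel], daily$unit_id[sel], mean, na.rm = TRUE)
    mn[avail[names(mn)] == 0] <- NA_real_
    res[[s]] <- as.numeric(mn[as.character(ids)])
  }
  res
}

month_of_day <- function(t, year) {
  t <- as.integer(t)
  ndays <- if (is_leap(year)) 366L else 365L
  if (any(t < 1L) || any(t > ndays))
    stop(sprintf("day index out of range 1..%d for year %d", ndays, year),
         call. = FALSE)
  origin <- as.Date(sprintf("%d-01-01", year))
  as.POSIXlt(origin + (t - 1L))$mon + 1L
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Air-quality-standard exceedance flags
#'
#' Flags, per census unit, whether any interpolated day exceeds the daily
#' standard (strictly greater than 35 ug/m3 by default) and whether the
#' annual mean exceeds the annual standard (strictly greater than 15
#' ug/m3). Missing days cannot trigger the daily flag; a unit with no
#' available data is never flagged.
#'
#' @param daily Long table `unit_id`, `t`, `w`.
#' @param annual Output of [annual_means()] (computed if omitted).
#' @param daily_threshold,annual_threshold Standards in ug/m3.
#' @return Data frame `unit_id`, `exceeds_daily`, `exceeds_annual`.
#' @export
naaqs_flags <- function(daily, annual = NULL,
                        daily_threshold = 35, annual_threshold = 15) {
  check_daily(daily)
  if (is.null(annual)) annual <- annual_means(daily)
  if (!all(c("unit_id", "annual_mean") %in% names(annual)))
    stop("`annual` needs columns unit_id and annual_mean", call. = FALSE)
  ids <- unique(daily$unit_id)
  if (!setequal(ids, annual$unit_id))
    stop("daily and annual tables cover different unit_id sets",
         call. = FALSE)
  mx <- tapply(daily$w, daily$unit_id, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  ex_d <- !is.na(mx[as.character(ids)]) &
    mx[as.character(ids)] > daily_threshold
  am <- annual$annual_mean[match(ids, annual$unit_id)]
  ex_a <- !is.na(am) & am > annual_threshold
  data.frame(unit_id = ids,
             exceeds_daily = as.logical(ex_d),
             exceeds_annual = as.logical(ex_a))
}

#' Exposed population under each air-quality rule
#'
#' Counts flagged census units and sums their population, separately for
#' the daily and the annual rule.
#'
#' @param flags Output of [naaqs_flags()].
#' @param populations Data frame `unit_id`, `population`.
#' @return List `units_daily`, `pop_daily`, `units_annual`, `pop_annual`.
#' @export
population_exposed <- function(flags, populations) {
  if (!all(c("unit_id", "exceeds_daily", "exceeds_annual") %in%
           names(flags)))
    stop("`flags` needs unit_id, exceeds_daily, exceeds_annual",
         call. = FALSE)
  if (!all(c("unit_id", "population") %in% names(populations)))
    stop("`populations` needs unit_id and population", call. = FALSE)
  flagged <- flags$unit_id[flags$exceeds_daily | flags$exceeds_annual]
  pop <- populations$population[match(flags$unit_id,
                                      populations$unit_id)]
  no_pop <- flagged[is.na(pop[match(flagged, flags$unit_id)])]
  if (length(no_pop))
    stop("flagged units with no population record: ",
         paste(utils::head(no_pop, 10), collapse = ", "),
         if (length(no_pop) > 10) " ..." else "", call. = FALSE)
  list(units_daily = sum(flags$exceeds_daily),
       pop_daily = sum(pop[flags$exceeds_daily], na.rm = FALSE),
       units_annual = sum(flags$exceeds_annual),
       pop_annual = sum(pop[flags$exceeds_annual], na.rm = FALSE))
}

#' Full per-unit exposure summary
#'
#' Combines annual and seasonal means, availability and exceedance flags
#' (and population if supplied) into one row per census unit.
#'
#' @param daily Long table `unit_id`, `t`, `w`.
#' @param year Study year.
#' @param populations Optional data frame `unit_id`, `population`.
#' @param daily_threshold,annual_threshold Standards in ug/m3.
#' @return Data frame with one row per unit.
#' @export
exposure_summary <- function(daily, year = 2009L, populations = NULL,
                             daily_threshold = 35, annual_threshold = 15) {
  ann <- annual_means(daily)
  sea <- seasonal_means(daily, year)
  fl <- naaqs_flags(daily, ann, daily_threshold, annual_threshold)
  res <- merge(ann, sea, by = "unit_id", sort = FALSE)
  res <- merge(res, fl, by = "unit_id", sort = FALSE)
  if (!is.null(populations)) {
    if (!all(c("unit_id", "population") %in% names(populations)))
      stop("`populations` needs unit_id and population", call. = FALSE)
    res$population <- populations$population[
      match(res$unit_id, populations$unit_id)]
  }
  res[match(unique(daily$unit_id), res$unit_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

check_daily <- function(daily) {
  if (!is.data.frame(daily) ||
      !all(c("unit_id", "t", "w") %in% names(daily)))
    stop("daily table needs columns unit_id, t, w", call. = FALSE)
  if (nrow(daily) == 0L) stop("daily table has no rows", call. = FALSE)
  invisible(daily)
}
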