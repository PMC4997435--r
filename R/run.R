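# Orchestration layer behind the command-line interface: each run_* reads
# the declared inputs, executes one pipeline stage, logs counts, and writes
# its outputs atomically. Errors propagate (the CLI converts them to a
# nonzero exit status).

#' Simulate a monitoring network and census tables to disk
#'
#' Writes `monitoring.csv`, `centroids.csv`, `population.csv` and
#' `truth.csv` (the noiseless per-unit exposure summary) under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_sites,days,missing_rate Passed to [generate_network()].
#' @param n_units Passed to [generate_units()].
#' @param seed Seed stored into the [field_spec()].
#' @param year Study year used for dates in the monitoring CSV.
#' @param spec Optional ready-made [field_spec()] (overrides `seed`).
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(out_dir, n_sites = 100L, days = 365L,
                         missing_rate = 0.2, n_units = 200L,
                         seed = 20090101L, year = 2009L, spec = NULL) {
  if (is.null(spec)) spec <- field_spec(seed = seed)
  net <- generate_network(spec, n_sites = n_sites, days = days,
                          missing_rate = missing_rate)
  units <- generate_units(spec, n_units = n_units)
  truth <- true_exposure(spec, units, days = seq_len(days), year = year)
  paths <- c(monitoring = file.path(out_dir, "monitoring.csv"),
             centroids = file.path(out_dir, "centroids.csv"),
             population = file.path(out_dir, "population.csv"),
             truth = file.path(out_dir, "truth.csv"))
  write_monitoring(net$samples, paths["monitoring"], year = year)
  write_csv_atomic(data.frame(id = units$unit_id, x = units$x,
                              y = units$y), paths["centroids"])
  write_csv_atomic(data.frame(id = units$unit_id,
                              population = units$population),
                   paths["population"])
  write_csv_atomic(format_numeric(truth), paths["truth"])
  message(sprintf(
    "simulated %d samples at %d sites (%d outliers, %d site-days missing), %d units",
    nrow(net$samples), n_sites, net$n_outliers, net$n_missing, n_units))
  invisible(paths)
}

#' Cross-validate interpolation configurations from a monitoring CSV
#'
#' Reads the monitoring data, removes outliers, grid-searches the
#' requested configurations with a shared fold assignment, and writes a
#' tidy CSV: one row per (configuration, fold) plus averaged rows flagged
#' `fold = "avg"`.
#'
#' @param monitoring Path to the monitoring CSV.
#' @param out Output CSV path.
#' @param method `"sf"` or `"idw"`.
#' @param c_values Numeric vector of time-scale factors to test.
#' @param n_neighbors,exponents IDW grid.
#' @param k,seed Cross-validation setup.
#' @param outlier_threshold Outlier cutoff in ug/m3 (NULL to skip).
#' @param criterion Ranking statistic.
#' @return Invisibly, the [grid_search()] object.
#' @export
run_cv <- function(monitoring, out, method = c("sf", "idw"),
                   c_values = c(1, 1 / 10, 1 / 5, 1 / 15),
                   n_neighbors = 3:7, exponents = seq(1, 5, by = 0.5),
                   k = 10L, seed = 20090101L, outlier_threshold = 250,
                   criterion = "mare") {
  method <- match.arg(method)
  samples <- read_monitoring(monitoring)
  if (!is.null(outlier_threshold)) {
    filt <- remove_outliers(samples, outlier_threshold)
    message(sprintf("removed %d outliers above %g ug/m3",
                    filt$removed, outlier_threshold))
    samples <- filt$samples
  }
  gs <- grid_search(samples, method = method,
                    scales = lapply(c_values, time_scale),
                    n_neighbors = n_neighbors, exponents = exponents,
                    criterion = criterion, k = k, seed = seed)
  rows <- lapply(gs$reports, function(r) {
    pf <- r$per_fold
    pf$fold <- as.character(pf$fold)
    avg <- data.frame(fold = "avg", t(r$averaged))
    block <- rbind(pf, avg)
    data.frame(method = r$method, c = r$scale$c,
               n_neighbors = r$n_neighbors, exponent = r$exponent,
               block)
  })
  write_csv_atomic(format_numeric(do.call(rbind, rows)), out)
  message(sprintf("wrote %s (%d configurations, ranked by %s)",
                  out, nrow(gs$table), criterion))
  invisible(gs)
}

#' Interpolate daily surfaces at centroids from CSV inputs
#'
#' @param monitoring,centroids Input CSV paths.
#' @param out Output CSV path (`unit_id,t,w` long table).
#' @param method,c,days,n_neighbors,exponent,outside Passed to
#'   [interpolate_daily_grid()].
#' @param outlier_threshold Outlier cutoff (NULL to skip).
#' @return Invisibly, the daily table.
#' @export
run_interpolate <- function(monitoring, centroids, out,
                            method = c("sf", "idw"), c = 1 / 5,
                            days = NULL, n_neighbors = 3L, exponent = 5,
                            outside = "missing",
                            outlier_threshold = 250) {
  method <- match.arg(method)
  samples <- read_monitoring(monitoring)
  if (!is.null(outlier_threshold))
    samples <- remove_outliers(samples, outlier_threshold)$samples
  cents <- read_centroids(centroids)
  if (is.null(days)) days <- seq_len(max(samples$t))
  daily <- interpolate_daily_grid(samples, cents, method = method,
                                  scale = time_scale(c), days = days,
                                  n_neighbors = n_neighbors,
                                  exponent = exponent, outside = outside)
  write_csv_atomic(format_numeric(daily), out)
  message(sprintf("wrote %s (%d centroid-days)", out, nrow(daily)))
  invisible(daily)
}

#' Population-exposure analysis from CSV inputs
#'
#' Runs the full chain monitoring -> outlier filter -> daily interpolation
#' at centroids -> annual/seasonal means -> exceedance flags -> population
#' counts, and writes `exposure_summary.csv` (one row per unit).
#'
#' @param monitoring,centroids,population Input CSV paths.
#' @param out Output CSV path.
#' @param method,c,n_neighbors,exponent,outside Interpolator settings.
#' @param year Study year.
#' @param days Day indices (defaults to the full year).
#' @param outlier_threshold Outlier cutoff (NULL to skip).
#' @return Invisibly, a list with the summary table and the
#'   [population_exposed()] totals.
#' @export
run_exposure <- function(monitoring, centroids, population, out,
                         method = c("sf", "idw"), c = 1 / 5,
                         year = 2009L, days = NULL,
                         n_neighbors = 3L, exponent = 5,
                         outside = "missing", outlier_threshold = 250) {
  method <- match.arg(method)
  samples <- read_monitoring(monitoring)
  if (!is.null(outlier_threshold)) {
    filt <- remove_outliers(samples, outlier_threshold)
    message(sprintf("removed %d outliers above %g ug/m3",
                    filt$removed, outlier_threshold))
    samples <- filt$samples
  }
  cents <- read_centroids(centroids)
  pops <- read_population(population)
  ndays <- if (is_leap(year)) 366L else 365L
  if (is.null(days)) days <- seq_len(min(max(samples$t), ndays))
  daily <- interpolate_daily_grid(samples, cents, method = method,
                                  scale = time_scale(c), days = days,
                                  n_neighbors = n_neighbors,
                                  exponent = exponent, outside = outside)
  summ <- exposure_summary(daily, year = year, populations = pops)
  totals <- population_exposed(
    summ[, c("unit_id", "exceeds_daily", "exceeds_annual")], pops)
  write_csv_atomic(format_numeric(summ), out)
  message(sprintf(
    "wrote %s; daily rule: %d units / %g people; annual rule: %d units / %g people",
    out, totals$units_daily, totals$pop_daily,
    totals$units_annual, totals$pop_annual))
  invisible(list(summary = summ, totals = totals))
}

# print numeric columns with 6 significant digits for stable CSV output
format_numeric <- function(df) {
  for (col in names(df))
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- signif(df[[col]], 6)
  df
}
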