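#' Specification of a synthetic concentration field
#'
#' Defines a smooth ground-truth field w*(x, y, t) = baseline + sum of
#' Gaussian spatial bumps + a seasonal sinusoid, from which synthetic
#' monitoring networks and centroid truths are generated. The defaults
#' emulate a contiguous-US daily PM2.5 year: a background near 10 ug/m3,
#' a few regional hotspots strong enough to push nearby annual means over
#' the 15 ug/m3 standard, a winter-peaking seasonal cycle, measurement
#' noise of a few ug/m3, and rare gross outliers far above 250 ug/m3.
#'
#' @param baseline Background concentration, ug/m3.
#' @param bumps List of spatial hotspots, each
#'   `list(x=, y=, amplitude=, length_scale=)` (degrees; ug/m3 at the
#'   centre; Gaussian length scale in degrees).
#' @param seasonal_amplitude Amplitude A of the sinusoid
#'   `A * sin(2*pi*(t - phase)/365)`, ug/m3.
#' @param seasonal_phase Phase in days; the default peaks in mid-January.
#' @param noise_sd Gaussian measurement noise standard deviation, ug/m3.
#' @param outlier_rate Per-observation probability of a gross outlier.
#' @param outlier_floor Amount (> 250 ug/m3) added to an observation to
#'   make it an outlier.
#' @param bbox Named vector `xmin`, `xmax`, `ymin`, `ymax` in degrees.
#' @param seed Integer seed making every generated artifact reproducible.
#' @return Object of class `field_spec`.
#' @export
field_spec <- function(baseline = 10,
                       bumps = list(
                         list(x = -119, y = 36, amplitude = 10,
                              length_scale = 2.5),
                         list(x = -114, y = 46.5, amplitude = 8,
                              length_scale = 2),
                         list(x = -78, y = 41, amplitude = 6,
                              length_scale = 3)),
                       seasonal_amplitude = 3,
                       seasonal_phase = -76.25,
                       noise_sd = 3,
                       outlier_rate = 1e-4,
                       outlier_floor = 300,
                       bbox = c(xmin = -124.7, xmax = -67,
                                ymin = 25.1, ymax = 49.4),
                       seed = 20090101L) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L)
  if (!is.list(bumps))
    stop("`bumps` must be a list of hotspot descriptions", call. = FALSE)
  for (b in bumps)
    if (!all(c("x", "y", "amplitude", "length_scale") %in% names(b)))
      stop("each bump needs x, y, amplitude, length_scale", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("`outlier_rate` must lie in [0, 1)", call. = FALSE)
  if (outlier_floor <= 250)
    stop("`outlier_floor` must exceed 250 ug/m3 so injected outliers are ",
         "recognizable", call. = FALSE)
  bbox <- bbox[c("xmin", "xmax", "ymin", "ymax")]
  if (anyNA(bbox) || bbox["xmax"] <= bbox["xmin"] ||
      bbox["ymax"] <= bbox["ymin"])
    stop("`bbox` must be named xmin/xmax/ymin/ymax with positive extent",
         call. = FALSE)
  structure(list(baseline = baseline, bumps = bumps,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_phase = seasonal_phase,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 outlier_floor = outlier_floor, bbox = bbox,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' Evaluate the noiseless ground-truth field
#'
#' @param spec A [field_spec()].
#' @param x,y,t Coordinates (vectors of equal length, or scalars recycled).
#' @return w*(x, y, t) in ug/m3, floored at 0.1 so relative errors stay
#'   defined.
#' @export
true_field <- function(spec, x, y, t) {
  stopifnot(inherits(spec, "field_spec"))
  w <- rep(spec$baseline, length.out = max(length(x), length(y), length(t)))
  for (b in spec$bumps) {
    d2 <- (x - b$x)^2 + (y - b$y)^2
    w <- w + b$amplitude * exp(-d2 / (2 * b$length_scale^2))
  }
  w <- w + spec$seasonal_amplitude *
    sin(2 * pi * (t - spec$seasonal_phase) / 365)
  pmax(w, 0.1)
}

#' Generate a synthetic monitoring network
#'
#' Scatters sites uniformly in the bounding box and simulates one noisy
#' observation per site-day, dropping a `missing_rate` fraction of
#' site-days (monitoring networks rarely report every day) and promoting
#' a small random subset to gross outliers by adding `outlier_floor`.
#' Everything is reproducible from the spec's seed.
#'
#' @param spec A [field_spec()].
#' @param n_sites Number of monitoring sites (>= 4).
#' @param days Number of days simulated (series run over t = 1..days).
#' @param missing_rate Fraction of site-days without a measurement,
#'   in [0, 1).
#' @return List: `samples` (an [st_samples()] table), `sites` (site
#'   coordinates), `n_outliers` (count injected), `n_missing` (site-days
#'   dropped), and the `spec`.
#' @export
generate_network <- function(spec, n_sites = 955L, days = 365L,
                             missing_rate = 0.58) {
  stopifnot(inherits(spec, "field_spec"))
  n_sites <- as.integer(n_sites)
  days <- as.integer(days)
  if (is.na(n_sites) || n_sites < 4L)
    stop("`n_sites` must be at least 4", call. = FALSE)
  if (is.na(days) || days < 1L)
    stop("`days` must be at least 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  bb <- spec$bbox
  withr::with_seed(spec$seed, {
    sites <- data.frame(
      site_id = sprintf("s%04d", seq_len(n_sites)),
      x = runif(n_sites, bb["xmin"], bb["xmax"]),
      y = runif(n_sites, bb["ymin"], bb["ymax"]))
    g <- data.frame(site = rep(seq_len(n_sites), times = days),
                    t = rep(seq_len(days), each = n_sites))
    w_true <- true_field(spec, sites$x[g$site], sites$y[g$site], g$t)
    w <- pmax(w_true + rnorm(nrow(g), 0, spec$noise_sd), 0.1)
    is_out <- runif(nrow(g)) < spec$outlier_rate
    w[is_out] <- w[is_out] + spec$outlier_floor
    keep <- runif(nrow(g)) >= missing_rate
  })
  samples <- data.frame(site_id = sites$site_id[g$site[keep]],
                        x = sites$x[g$site[keep]],
                        y = sites$y[g$site[keep]],
                        t = g$t[keep],
                        w = w[keep])
  list(samples = st_samples(samples),
       sites = sites,
       n_outliers = sum(is_out & keep),
       n_missing = sum(!keep),
       spec = spec)
}

#' Generate synthetic census units
#'
#' Centroids are placed uniformly inside an interior margin of the
#' bounding box (limiting out-of-hull queries at the edges of the
#' monitoring network) with populations drawn uniformly from
#' `pop_range` -- by default 600..3000, the size band census block
#' groups are defined to contain.
#'
#' @param spec A [field_spec()].
#' @param n_units Number of units (>= 1).
#' @param pop_range Length-2 integer range of unit populations.
#' @param margin Fraction of each bbox dimension kept clear at the edges.
#' @return Data frame `unit_id`, `x`, `y`, `population`.
#' @export
generate_units <- function(spec, n_units = 500L,
                           pop_range = c(600L, 3000L), margin = 0.1) {
  stopifnot(inherits(spec, "field_spec"))
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L)
    stop("`n_units` must be at least 1", call. = FALSE)
  bb <- spec$bbox
  mx <- margin * (bb["xmax"] - bb["xmin"])
  my <- margin * (bb["ymax"] - bb["ymin"])
  withr::with_seed(spec$seed + 1L, {
    data.frame(
      unit_id = sprintf("u%05d", seq_len(n_units)),
      x = runif(n_units, bb["xmin"] + mx, bb["xmax"] - mx),
      y = runif(n_units, bb["ymin"] + my, bb["ymax"] - my),
      population = sample(seq(pop_range[1], pop_range[2]), n_units,
                          replace = TRUE))
  })
}

#' Ground-truth exposure summary
#'
#' Evaluates the noiseless field at the unit centroids for every day and
#' aggregates exactly as the estimation pipeline does -- the recovery
#' oracle for end-to-end tests.
#'
#' @param spec A [field_spec()].
#' @param units Output of [generate_units()] (or any centroid table).
#' @param days Day indices covered (default a full year).
#' @param year Study year for the season calendar.
#' @return [exposure_summary()] table computed from the true field.
#' @export
true_exposure <- function(spec, units, days = 1:365, year = 2009L) {
  stopifnot(inherits(spec, "field_spec"))
  units <- st_centroids(units)
  daily <- data.frame(
    unit_id = rep(units$unit_id, each = length(days)),
    t = rep(as.integer(days), times = nrow(units)))
  daily$w <- true_field(spec,
                        rep(units$x, each = length(days)),
                        rep(units$y, each = length(days)),
                        daily$t)
  pops <- if ("population" %in% names(units))
    units[, c("unit_id", "population")] else NULL
  exposure_summary(daily, year = year, populations = pops)
}
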