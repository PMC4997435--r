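make_daily <- function(units, days, w) {
  data.frame(unit_id = rep(units, each = length(days)),
             t = rep(days, times = length(units)),
             w = w)
}

test_that("the daily grid has one row per centroid-day and honours
           constant and co-located fields", {
  s <- st_samples(make_cloud(40, seed = 51, days = 10,
                             value_fn = function(x, y, t) rep(12, length(x))))
  cents <- withr::with_seed(515, data.frame(
    unit_id = sprintf("u%02d", 1:10),
    x = runif(10, 0.3, 0.7), y = runif(10, 0.3, 0.7)))
  daily <- interpolate_daily_grid(s, cents, "sf", time_scale(0.1),
                                  days = 1:10)
  expect_equal(nrow(daily), 100L)
  expect_equal(daily$unit_id, rep(cents$unit_id, each = 10))
  inside <- !is.na(daily$w)
  expect_true(all(abs(daily$w[inside] - 12) < 1e-9))
  # IDW path: convexity forces the constant too
  d2 <- interpolate_daily_grid(s, cents, "idw", time_scale(0.1),
                               days = 1:10, n_neighbors = 4, exponent = 2)
  expect_true(all(abs(d2$w - 12) < 1e-9))
  # a centroid on a station reproduces the measured series where measured
  cents2 <- data.frame(unit_id = "at_site", x = s$x[1], y = s$y[1])
  d3 <- interpolate_daily_grid(s, cents2, "sf", time_scale(0.1),
                               days = s$t[1])
  expect_equal(d3$w, s$w[1], tolerance = 1e-6)
  expect_error(interpolate_daily_grid(s, cents, "sf", time_scale(0.1),
                                      days = integer(0)), "nonempty")
})

test_that("seasonal means follow the same-year season calendar", {
  days <- 1:365
  mon <- as.POSIXlt(as.Date("2009-01-01") + days - 1)$mon + 1
  # constant series
  d1 <- make_daily("u1", days, 10)
  s1 <- seasonal_means(d1, 2009)
  expect_equal(unlist(s1[1, c("winter", "spring", "summer", "fall")]),
               c(winter = 10, spring = 10, summer = 10, fall = 10))
  # series equal to the month number: spring mean is the day-weighted 4.0
  d2 <- make_daily("u1", days, mon)
  s2 <- seasonal_means(d2, 2009)
  expect_equal(s2$spring, 4)                   # (31*3+30*4+31*5)/92
  expect_equal(s2$winter, (31 * 1 + 28 * 2 + 31 * 12) / 90)
  # missing summer leaves the season NA
  d3 <- d1
  d3$w[mon %in% 6:8] <- NA
  s3 <- seasonal_means(d3, 2009)
  expect_true(is.na(s3$summer))
  expect_equal(s3$winter, 10)
})

test_that("annual means conserve the sum of daily values across seasons", {
  withr::with_seed(52, {
    d <- make_daily(c("u1", "u2"), 1:365, runif(730, 2, 30))
    d$w[sample.int(730, 60)] <- NA
  })
  ann <- annual_means(d)
  sea <- seasonal_means(d, 2009)
  mon <- as.POSIXlt(as.Date("2009-01-01") + d$t - 1)$mon + 1
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "fall", "fall", "fall", "winter")[mon]
  for (u in c("u1", "u2")) {
    avail <- vapply(c("winter", "spring", "summer", "fall"), function(sn)
      sum(!is.na(d$w) & d$unit_id == u & season == sn), numeric(1))
    wsum <- sum(unlist(sea[sea$unit_id == u,
                           c("winter", "spring", "summer", "fall")]) * avail)
    expect_equal(wsum / sum(avail),
                 ann$annual_mean[ann$unit_id == u], tolerance = 1e-12)
  }
})

test_that("exceedance flags use strict thresholds", {
  days <- 1:365
  d <- rbind(make_daily("at35", days, 35),    # never above 35
             make_daily("just", days, c(35.00001, rep(10, 364))),
             make_daily("ann", days, 15.01),  # annual 15.01
             make_daily("low", days, 14.999))
  fl <- naaqs_flags(d)
  expect_equal(fl$exceeds_daily[fl$unit_id == "at35"], FALSE)
  expect_equal(fl$exceeds_daily[fl$unit_id == "just"], TRUE)
  expect_equal(fl$exceeds_annual[fl$unit_id == "at35"], TRUE) # 35 > 15
  expect_equal(fl$exceeds_annual[fl$unit_id == "ann"], TRUE)
  expect_equal(fl$exceeds_annual[fl$unit_id == "low"], FALSE)
  # raising one daily value never clears the annual flag (monotone)
  d2 <- d
  i <- which(d2$unit_id == "ann")[100]
  d2$w[i] <- d2$w[i] + 50
  fl2 <- naaqs_flags(d2)
  expect_true(fl2$exceeds_annual[fl2$unit_id == "ann"])
})

test_that("planted exceedances are counted and populations summed", {
  units <- sprintf("u%02d", 1:20)
  withr::with_seed(53, {
    w <- runif(20 * 30, 5, 12)
  })
  d <- make_daily(units, 1:30, w)
  hot <- c("u03", "u07", "u18")
  for (u in hot) d$w[d$unit_id == u][5] <- 40
  fl <- naaqs_flags(d)
  expect_setequal(fl$unit_id[fl$exceeds_daily], hot)
  pops <- data.frame(unit_id = units, population = seq(100, 2000, 100))
  tot <- population_exposed(fl, pops)
  expect_equal(tot$units_daily, 3L)
  expect_equal(tot$pop_daily,
               sum(pops$population[pops$unit_id %in% hot]))
  expect_equal(tot$units_annual, 0L)
  expect_equal(tot$pop_annual, 0)
  # brute-force loop oracle and permutation invariance
  loop_pop <- 0
  for (i in seq_len(nrow(fl)))
    if (fl$exceeds_daily[i])
      loop_pop <- loop_pop +
        pops$population[pops$unit_id == fl$unit_id[i]]
  expect_equal(tot$pop_daily, loop_pop)
  perm <- withr::with_seed(54, sample(nrow(pops)))
  flperm <- withr::with_seed(55, fl[sample(nrow(fl)), ])
  expect_equal(population_exposed(flperm, pops[perm, ]), tot)
  # no flags at all
  none <- naaqs_flags(make_daily(units, 1:30, w * 0 + 5))
  tot0 <- population_exposed(none, pops)
  expect_equal(unlist(tot0),
               c(units_daily = 0, pop_daily = 0,
                 units_annual = 0, pop_annual = 0))
  # flagged unit without population record
  expect_error(population_exposed(fl, pops[pops$unit_id != "u03", ]),
               "u03")
})
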