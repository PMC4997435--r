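#' Validate a table of space-time measurements
#'
#' A sample set is a data frame with one row per measurement: `site_id`,
#' longitude `x` and latitude `y` in decimal degrees, day index `t`
#' (1 = January 1 of the study year), and concentration `w` in ug/m3.
#' Concentrations must be finite and strictly positive: zero entries in
#' monitoring feeds mean "no measurement" and are dropped at ingest.
#'
#' @param samples Data frame with columns `site_id`, `x`, `y`, `t`, `w`.
#' @param max_t Largest admissible day index (366 covers leap years).
#' @return The validated data frame, classed `st_samples`.
#' @export
st_samples <- function(samples, max_t = 366L) {
  if (!is.data.frame(samples))
    stop("`samples` must be a data frame", call. = FALSE)
  need <- c("site_id", "x", "y", "t", "w")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("missing sample columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) == 0L)
    stop("`samples` has no rows", call. = FALSE)
  for (col in c("x", "y", "t", "w"))
    if (!is.numeric(samples[[col]]) || anyNA(samples[[col]]) ||
        any(!is.finite(samples[[col]])))
      stop("column `", col, "` must be finite numeric without NAs",
           call. = FALSE)
  if (any(samples$t < 1) || any(samples$t != round(samples$t)) ||
      any(samples$t > max_t))
    stop("`t` must be whole-numbered day indices in 1..", max_t,
         call. = FALSE)
  if (any(samples$w <= 0))
    stop("`w` must be strictly positive (zero entries mean 'no ",
         "measurement' and are dropped at ingest)", call. = FALSE)
  samples <- as.data.frame(samples)
  class(samples) <- unique(c("st_samples", class(samples)))
  samples
}

# scaled (x, y, c*t) coordinate matrix for a sample table or any data
# frame carrying x, y, t
st_coords <- function(df, scale) {
  scale <- as_time_scale(scale)
  cbind(x = as.numeric(df$x), y = as.numeric(df$y),
        ct = scale$c * as.numeric(df$t))
}
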