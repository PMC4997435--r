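#' Time scale for the space-time extension approach
#'
#' A time scale carries the factor `c` (in spatial-distance units per day)
#' that maps a day index `t` to the third interpolation coordinate `c * t`.
#' Interpolating in (x, y, c*t) treats time as another spatial dimension;
#' `c` controls how strongly observations on nearby days influence each
#' other relative to observations at nearby sites.
#'
#' @param c Positive scale factor, spatial-distance units (here decimal
#'   degrees) per day.
#' @param label Optional human-readable label.
#' @return An object of class `time_scale`.
#' @examples
#' sc <- time_scale(1 / 5, "Scale C")
#' scale_time(365, sc)
#' @export
time_scale <- function(c, label = NULL) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("`c` must be a single positive finite number", call. = FALSE)
  if (is.null(label)) label <- sprintf("c=%g", c)
  structure(list(c = as.numeric(c), label = as.character(label)),
            class = "time_scale")
}

#' @export
print.time_scale <- function(x, ...) {
  cat(sprintf("<time_scale> %s (c = %g degrees/day)\n", x$label, x$c))
  invisible(x)
}

#' The four canonical daily time scales
#'
#' Presets A-D with c = 1, 1/10, 1/5 and 1/15 degrees per day, the four
#' candidate scales commonly examined for daily PM2.5 interpolation.
#'
#' @return Named list of [time_scale()] objects `A`, `B`, `C`, `D`.
#' @export
time_scale_presets <- function() {
  list(A = time_scale(1,      "Scale A"),
       B = time_scale(1 / 10, "Scale B"),
       C = time_scale(1 / 5,  "Scale C"),
       D = time_scale(1 / 15, "Scale D"))
}

#' Map a day index to its scaled time coordinate
#'
#' @param t Day index (1 = January 1 of the study year); positive whole
#'   number(s).
#' @param scale A [time_scale()].
#' @return `scale$c * t`, the third coordinate of the space-time point.
#' @examples
#' scale_time(365, time_scale(1 / 10)) # 36.5
#' @export
scale_time <- function(t, scale) {
  stopifnot(inherits(scale, "time_scale"))
  if (!is.numeric(t) || length(t) == 0L || anyNA(t) ||
      any(t < 1) || any(t != round(t)))
    stop("`t` must be positive whole-numbered day indices (t >= 1)",
         call. = FALSE)
  scale$c * as.numeric(t)
}

as_time_scale <- function(scale) {
  if (inherits(scale, "time_scale")) return(scale)
  if (is.numeric(scale) && length(scale) == 1L) return(time_scale(scale))
  stop("`scale` must be a time_scale object or a single positive number",
       call. = FALSE)
}
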