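#' Read a monitoring CSV
#'
#' Expects a headered CSV with columns `id,x,y,year,month,day,w` (decimal
#' point, UTF-8). Dates are converted to the day index t within the study
#' year. Rows with non-positive `w` (zero means "no measurement") are
#' dropped and counted; malformed rows are an error that names the first
#' offending line numbers.
#'
#' @param path Path to the CSV file.
#' @return An [st_samples()] table; attributes `dropped_nonpositive` and
#'   `year` record the ingest bookkeeping.
#' @export
read_monitoring <- function(path) {
  if (!file.exists(path))
    stop("monitoring file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "year", "month", "day", "w")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("monitoring file missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("monitoring file has no data rows: ", path, call. = FALSE)
  for (col in c("x", "y", "year", "month", "day", "w")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("unparseable `%s` at line(s) %s of %s", col,
                   paste(utils::head(bad + 1L, 5), collapse = ", "),
                   path), call. = FALSE)
    df[[col]] <- v
  }
  years <- unique(df$year)
  if (length(years) != 1L)
    stop("monitoring file spans multiple years (",
         paste(years, collapse = ", "),
         "); one study year expected", call. = FALSE)
  dt <- as.Date(sprintf("%04d-%02d-%02d", df$year, df$month, df$day),
                format = "%Y-%m-%d")
  bad <- which(is.na(dt))
  if (length(bad))
    stop("invalid calendar date at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  t <- as.integer(dt - as.Date(sprintf("%04d-01-01", years))) + 1L
  keep <- df$w > 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("dropped %d rows with non-positive w (no measurement)",
                    dropped))
  if (!any(keep))
    stop("no rows with positive w in ", path, call. = FALSE)
  out <- st_samples(data.frame(site_id = as.character(df$id[keep]),
                               x = df$x[keep], y = df$y[keep],
                               t = t[keep], w = df$w[keep]),
                    max_t = if (is_leap(years)) 366L else 365L)
  attr(out, "dropped_nonpositive") <- dropped
  attr(out, "year") <- as.integer(years)
  out
}

#' Write a sample table as a monitoring CSV
#'
#' Inverse of [read_monitoring()]: day indices become (year, month, day).
#'
#' @param samples An [st_samples()] table.
#' @param path Output path (written atomically).
#' @param year Study year.
#' @export
write_monitoring <- function(samples, path, year = 2009L) {
  samples <- st_samples(samples)
  dt <- as.Date(sprintf("%d-01-01", year)) + (samples$t - 1L)
  df <- data.frame(id = samples$site_id,
                   x = samples$x, y = samples$y,
                   year = as.integer(format(dt, "%Y")),
                   month = as.integer(format(dt, "%m")),
                   day = as.integer(format(dt, "%d")),
                   w = samples$w)
  write_csv_atomic(df, path)
}

#' Read a centroid CSV (`id,x,y`)
#' @param path Path to the CSV file.
#' @return An [st_centroids()] table.
#' @export
read_centroids <- function(path) {
  if (!file.exists(path))
    stop("centroid file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "x", "y"), names(df))
  if (length(miss))
    stop("centroid file missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  st_centroids(data.frame(unit_id = as.character(df$id),
                          x = as.numeric(df$x), y = as.numeric(df$y)))
}

#' Read a population CSV (`id,population`)
#' @param path Path to the CSV file.
#' @return Data frame `unit_id`, `population`.
#' @export
read_population <- function(path) {
  if (!file.exists(path))
    stop("population file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "population"), names(df))
  if (length(miss))
    stop("population file missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(unit_id = as.character(df$id),
             population = as.numeric(df$population))
}

# atomic CSV write: temp file in the target directory, then rename
write_csv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = paste0(basename(path), ".tmp"),
                  tmpdir = dirname(path))
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}
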