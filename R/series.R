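#' Daily series of blood units issued
#'
#' Constructs a validated daily series: one non-negative count of red blood
#' cell (RBC) units issued per consecutive calendar day, starting at
#' `start_date`. This is the raw input to the forecasting pipeline.
#'
#' @param values Numeric vector of non-negative daily issue counts, one per
#'   consecutive calendar day (no gaps).
#' @param start_date A `Date` (or string coercible to one): the calendar date
#'   of the first value.
#' @return An object of class `daily_series`: the numeric vector with
#'   attributes `start_date`.
#' @seealso [aggregate_weekly()], [read_daily_csv()], [simulate_demand()]
#' @export
#' @examples
#' d <- daily_series(rep(100, 14), "2020-01-01")
#' aggregate_weekly(d)
daily_series <- function(values, start_date) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("daily series must contain at least one value", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("daily series contains missing values", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("daily issue counts must be non-negative", call. = FALSE)
  }
  start_date <- as.Date(start_date)
  if (is.na(start_date)) stop("invalid start_date", call. = FALSE)
  structure(values, start_date = start_date, class = "daily_series")
}

#' Aggregated period series (weekly or multi-week)
#'
#' Holds the smoothed series x(n), n = 1..N, produced by the aggregation
#' stage: nonoverlapping weekly sums, nonoverlapping 4-week weekly averages,
#' or overlapping annual (52-week) weekly averages.
#'
#' @param values Numeric vector x(1)..x(N).
#' @param period_weeks Positive integer: weeks per period (1 for weekly, 4
#'   for the 4-week series, 52 for the annual smoothing).
#' @param origin_date `Date` of the first period's first day.
#' @param overlapping Logical: do consecutive periods overlap (shift of one
#'   week) rather than tile the calendar?
#' @return An object of class `period_series`.
#' @export
period_series <- function(values, period_weeks, origin_date,
                          overlapping = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("period series must contain at least one value", call. = FALSE)
  }
  period_weeks <- as.integer(period_weeks)
  if (period_weeks < 1L) stop("period_weeks must be >= 1", call. = FALSE)
  structure(values,
    period_weeks = period_weeks,
    origin_date = as.Date(origin_date),
    overlapping = isTRUE(overlapping),
    class = "period_series"
  )
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf(
    "<daily_series> %d days from %s (total %s units)\n",
    length(x), format(attr(x, "start_date")),
    format(sum(x), big.mark = ",")
  ))
  invisible(x)
}

#' @export
print.period_series <- function(x, ...) {
  cat(sprintf(
    "<period_series> %d points, %d-week periods%s, origin %s\n",
    length(x), attr(x, "period_weeks"),
    if (attr(x, "overlapping")) " (overlapping)" else "",
    format(attr(x, "origin_date"))
  ))
  invisible(x)
}

# strip class/attributes to a bare numeric vector
series_values <- function(x) as.numeric(unclass(x))

#' Aggregate daily issues into nonoverlapping weekly sums
#'
#' First smoothing transform: weeks are fixed 7-day blocks anchored at the
#' series' first day, so week k is the sum of days 7(k-1)+1 .. 7k. Summing
#' over whole weeks removes both day-to-day and weekday/weekend variability.
#' A trailing block of fewer than 7 days is discarded.
#'
#' @param daily A [daily_series()].
#' @return A [period_series()] of weekly sums (`period_weeks = 1`), with
#'   `N = floor(length(daily) / 7)` points.
#' @export
#' @examples
#' aggregate_weekly(daily_series(1:10, "2020-01-01")) # one week: sum(1:7)
aggregate_weekly <- function(daily) {
  stopifnot(inherits(daily, "daily_series"))
  v <- series_values(daily)
  n_weeks <- length(v) %/% 7L
  if (n_weeks < 1L) {
    stop("series too short to aggregate: need at least 7 days", call. = FALSE)
  }
  kept <- v[seq_len(7L * n_weeks)]
  weekly <- colSums(matrix(kept, nrow = 7L))
  period_series(weekly,
    period_weeks = 1L,
    origin_date = attr(daily, "start_date")
  )
}

#' Aggregate weekly sums into nonoverlapping 4-week averages
#'
#' Second smoothing transform: each point is the average weekly usage over a
#' block of 4 consecutive weeks (sum of the 4 weekly sums divided by 4).
#' This is the series all prediction methods operate on. A trailing block of
#' fewer than 4 weeks is discarded.
#'
#' @param weekly A nonoverlapping weekly [period_series()].
#' @return A [period_series()] with `period_weeks = 4` and
#'   `N = floor(N_weekly / 4)` points.
#' @export
aggregate_fourweek <- function(weekly) {
  stopifnot(inherits(weekly, "period_series"))
  if (attr(weekly, "period_weeks") != 1L || attr(weekly, "overlapping")) {
    stop("input must be a nonoverlapping weekly series", call. = FALSE)
  }
  v <- series_values(weekly)
  n_blocks <- length(v) %/% 4L
  if (n_blocks < 1L) {
    stop("series too short to aggregate: need at least 4 weeks", call. = FALSE)
  }
  kept <- v[seq_len(4L * n_blocks)]
  fourweek <- colSums(matrix(kept, nrow = 4L)) / 4
  period_series(fourweek,
    period_weeks = 4L,
    origin_date = attr(weekly, "origin_date")
  )
}

#' Overlapping annual smoothing of a weekly series
#'
#' Average weekly usage over overlapping `span_weeks`-week periods, shifting
#' by one week each time: point k is the mean of weeks k .. k+span-1. With
#' the default 52-week span this exposes the slow annual structure of the
#' demand. It is a smoothing view only; no predictor in this package is
#' built on it.
#'
#' @param weekly A nonoverlapping weekly [period_series()].
#' @param span_weeks Integer window length in weeks (default 52).
#' @return An overlapping [period_series()] with
#'   `N = N_weekly - span_weeks + 1` points.
#' @export
aggregate_overlapping_annual <- function(weekly, span_weeks = 52L) {
  stopifnot(inherits(weekly, "period_series"))
  if (attr(weekly, "period_weeks") != 1L || attr(weekly, "overlapping")) {
    stop("input must be a nonoverlapping weekly series", call. = FALSE)
  }
  span_weeks <- as.integer(span_weeks)
  if (span_weeks < 1L) stop("span_weeks must be >= 1", call. = FALSE)
  v <- series_values(weekly)
  n <- length(v) - span_weeks + 1L
  if (n < 1L) {
    stop(sprintf(
      "series shorter than span: %d weeks < %d", length(v), span_weeks
    ), call. = FALSE)
  }
  cs <- c(0, cumsum(v))
  out <- (cs[(span_weeks + 1L):(length(v) + 1L)] - cs[seq_len(n)]) / span_weeks
  period_series(out,
    period_weeks = span_weeks,
    origin_date = attr(weekly, "origin_date"),
    overlapping = TRUE
  )
}
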