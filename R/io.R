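#' Read a daily issues CSV
#'
#' Reads a two-column CSV (`date` in ISO-8601, `issues` >= 0; rows in any
#' order), sorts by date and checks the days are consecutive. Under the
#' `"zero_fill"` policy, absent days become 0 with a warning listing them;
#' under `"error"` (the default) a gap is an error naming the first missing
#' date.
#'
#' @param path Path to the CSV file.
#' @param missing_policy `"error"` or `"zero_fill"`.
#' @return A [daily_series()].
#' @export
read_daily_csv <- function(path, missing_policy = c("error", "zero_fill")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "issues") %in% names(df))) {
    stop("expected columns 'date' and 'issues'", call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1L]
    stop(sprintf("row %d: invalid ISO-8601 date '%s'", bad, df$date[bad]),
         call. = FALSE)
  }
  issues <- suppressWarnings(as.numeric(df$issues))
  if (anyNA(issues)) {
    bad <- which(is.na(issues))[1L]
    stop(sprintf("row %d: non-numeric issue count '%s'", bad, df$issues[bad]),
         call. = FALSE)
  }
  if (any(issues < 0)) {
    bad <- which(issues < 0)[1L]
    stop(sprintf("row %d: negative issue count %s", bad, issues[bad]),
         call. = FALSE)
  }
  if (anyDuplicated(dates)) {
    dup <- dates[duplicated(dates)][1L]
    stop(sprintf("duplicate date: %s", format(dup)), call. = FALSE)
  }
  ord <- order(dates)
  dates <- dates[ord]
  issues <- issues[ord]
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  if (length(full) != length(dates)) {
    missing_days <- full[!full %in% dates]
    if (missing_policy == "error") {
      stop(sprintf("gap in daily series: first missing date is %s",
                   format(missing_days[1L])), call. = FALSE)
    }
    warning(sprintf("zero-filling %d missing day(s): %s",
                    length(missing_days),
                    paste(format(missing_days), collapse = ", ")),
            call. = FALSE)
    filled <- numeric(length(full))
    filled[full %in% dates] <- issues
    issues <- filled
    dates <- full
  }
  daily_series(issues, dates[1L])
}

#' Write a daily series to CSV
#'
#' Writes the standard two-column daily CSV (`date,issues`) read back by
#' [read_daily_csv()], so simulated data can feed the command-line pipeline.
#'
#' @param daily A [daily_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  stopifnot(inherits(daily, "daily_series"))
  dates <- seq(attr(daily, "start_date"), by = "day", length.out = length(daily))
  df <- data.frame(date = format(dates, "%Y-%m-%d"),
                   issues = signif(series_values(daily), 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write forecast records or grid results to CSV
#'
#' Serializes [rolling_forecast()] records (columns `target_index`,
#' `target_start_date`, `true_value`, `predicted`, `pct_error`; the true
#' value is empty for pure future forecasts) or a [grid_search()] table
#' (columns `w,m,d,alpha,method,mean_pct_err,sd_pct_err,pct_within_5,n`).
#' Floats are written at 6 significant digits; row order is deterministic.
#'
#' @param x A `forecast_records` or `grid_result` data frame.
#' @param path Output path.
#' @param origin_date Optional `Date` of the series' first period, used to
#'   derive `target_start_date` for forecast records.
#' @param period_weeks Weeks per period for date derivation (default 4).
#' @return The path, invisibly.
#' @export
write_forecasts <- function(x, path, origin_date = NULL, period_weeks = 4L) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("nothing to write: results are empty", call. = FALSE)
  }
  if (inherits(x, "grid_result")) {
    df <- data.frame(
      w = x$w, m = x$m, d = x$d, alpha = x$alpha, method = x$method,
      mean_pct_err = signif(x$mean_pct_err, 6),
      sd_pct_err = signif(x$sd_pct_err, 6),
      pct_within_5 = signif(x$pct_within_5, 6),
      n = x$n
    )
  } else {
    stopifnot(all(c("target_index", "predicted") %in% names(x)))
    target_start <- if (!is.null(origin_date)) {
      format(as.Date(origin_date) + (x$target_index - 1L) * 7L * period_weeks,
             "%Y-%m-%d")
    } else {
      NA_character_
    }
    df <- data.frame(
      target_index = x$target_index,
      target_start_date = target_start,
      true_value = if ("true_value" %in% names(x)) signif(x$true_value, 6) else NA_real_,
      predicted = signif(x$predicted, 6),
      pct_error = if ("pct_error" %in% names(x)) signif(x$pct_error, 6) else NA_real_
    )
    df <- df[order(df$target_index), , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
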