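#' Simulate a noisy straight line at a given signal-to-noise ratio
#'
#' Generates y(t) = intercept + slope * t + eps(t) for t = 0..n-1, with
#' Gaussian noise whose variance is set by the SNR in decibels: the variance
#' of the noiseless signal about its own mean, divided by the noise
#' variance, equals 10^(snr_db / 10). An infinite `snr_db` gives the exact
#' line. Used by the detrending benefit experiment.
#'
#' @param n Number of points (>= 2, so the signal variance is defined).
#' @param slope,intercept Line parameters (defaults: unit gradient, zero
#'   intercept).
#' @param snr_db Signal-to-noise ratio in dB (default 10).
#' @param seed Integer seed; the series is reproducible for a fixed seed.
#' @return Numeric vector of length n.
#' @export
simulate_line_noise <- function(n, slope = 1, intercept = 0, snr_db = 10,
                                seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2: signal variance undefined", call. = FALSE)
  t <- seq_len(n) - 1
  signal <- intercept + slope * t
  if (is.infinite(snr_db)) return(signal)
  noise_var <- stats::var(signal) / 10^(snr_db / 10)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  signal + stats::rnorm(n, sd = sqrt(noise_var))
}

# Set the RNG seed, returning the previous .Random.seed for restoration so
# generators never leak global state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Does detrending improve linear prediction? (line-plus-noise experiment)
#'
#' For each of `n_seeds` replicates of a noisy line
#' ([simulate_line_noise()]), makes one-step MMSE predictions at every
#' feasible origin twice: (i) fitting the MMSE coefficients directly to the
#' raw w-point window, with no modification of the data, and (ii) fitting an
#' order-d polynomial to the whole simulated series, subtracting it, running
#' windowed MMSE on the zero-mean residuals and adding the trend back. As in
#' the preliminary study this replicates, the polynomial is fitted to the
#' full series rather than per window (this is an in-sample diagnostic of
#' detrending, not a production forecast). Reports the standard deviation of
#' the fractional errors (xhat - x) / x for both routes.
#'
#' @param n Series length per replicate (default 100).
#' @param snr_db Noise level in dB (default 10).
#' @param w,m,d Window size, prediction order and polynomial order
#'   (defaults 26, 5, 2).
#' @param n_seeds Number of replicates (default 25).
#' @param seed Base seed; replicate k uses `seed + k - 1`.
#' @return A data frame with one row per replicate: `seed`, `sd_raw`,
#'   `sd_detrended`.
#' @export
detrending_benefit_experiment <- function(n = 100, snr_db = 10, w = 26,
                                          m = 5, d = 2, n_seeds = 25,
                                          seed = 1L) {
  predictor_spec(1L, w = w, m = m, d = d, alpha = 0L)  # validate parameters
  if (n < w + 1) stop("series too short for the window", call. = FALSE)
  rows <- lapply(seq_len(n_seeds), function(k) {
    y <- simulate_line_noise(n, snr_db = snr_db, seed = seed + k - 1L)
    origins <- w:(n - 1L)
    frac_err <- function(pred, truth) (pred - truth) / truth
    one_step <- function(series, o) {
      window <- series[(o - w + 1L):o]
      a <- fit_mmse(window, m, 0L)
      predict_linear(a, window[(w - m + 1L):w])
    }
    raw_err <- vapply(origins, function(o) {
      frac_err(one_step(y, o), y[o + 1L])
    }, numeric(1))
    fit <- fit_trend(y, d)  # whole-series trend, as in the preliminary study
    z <- detrended_window(fit)
    det_err <- vapply(origins, function(o) {
      pred <- one_step(z, o) + poly_eval(fit$coefficients, o) + fit$residual_mean
      frac_err(pred, y[o + 1L])
    }, numeric(1))
    data.frame(seed = seed + k - 1L,
               sd_raw = stats::sd(raw_err),
               sd_detrended = stats::sd(det_err))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic daily demand model
#'
#' Parameters of the daily RBC-issue generator used to exercise the whole
#' pipeline in place of confidential service data. Daily issues are modelled
#' as a base level modulated multiplicatively by a weekday profile (elective
#' surgery and routine transfusion drop at weekends) and an annual sinusoid,
#' plus a slow linear trend and additive Gaussian noise truncated at zero.
#'
#' Defaults emulate a national service: 3800 units/day base (about 27,000
#' weekly issues), weekday multipliers 1.12 Monday-Friday and 0.70 at
#' weekends (profile mean 1), 5% annual amplitude, a slow decline of 40
#' units/day per year, and 300 units/day of noise (about 3% coefficient of
#' variation at weekly aggregation).
#'
#' @param base_level Mean daily issues, units/day (> 0).
#' @param weekday_effects Seven positive multipliers, Monday..Sunday.
#' @param annual_amplitude Relative amplitude of the annual sinusoid.
#' @param annual_phase Phase offset of the sinusoid, radians.
#' @param linear_trend Trend in units/day per elapsed year.
#' @param noise_sd Standard deviation of the additive daily noise,
#'   units/day.
#' @param seed Integer seed.
#' @return An object of class `demand_model`.
#' @seealso [simulate_demand()]
#' @export
demand_model <- function(base_level = 3800,
                         weekday_effects = c(rep(1.12, 5), 0.70, 0.70),
                         annual_amplitude = 0.05,
                         annual_phase = 0,
                         linear_trend = -40,
                         noise_sd = 300,
                         seed = 1L) {
  if (base_level <= 0) stop("base_level must be > 0", call. = FALSE)
  if (length(weekday_effects) != 7L || any(weekday_effects <= 0)) {
    stop("weekday_effects must be 7 positive multipliers (Mon..Sun)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(base_level = base_level, weekday_effects = weekday_effects,
         annual_amplitude = annual_amplitude, annual_phase = annual_phase,
         linear_trend = linear_trend, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "demand_model"
  )
}

#' Simulate daily blood issues
#'
#' One value per calendar day from `start_date` to `end_date`:
#' `base_level * weekday_effect(day) * (1 + annual_amplitude *
#' sin(2 pi doy / 365.25 + phase)) + linear_trend * years_elapsed + noise`,
#' truncated at zero (issues cannot be negative). Reproducible for a fixed
#' model seed.
#'
#' @param model A [demand_model()].
#' @param start_date,end_date Calendar dates spanning at least 7 days.
#' @return A [daily_series()].
#' @export
#' @examples
#' d <- simulate_demand(demand_model(noise_sd = 0), "2020-01-06", "2020-01-19")
#' aggregate_weekly(d)
simulate_demand <- function(model, start_date, end_date) {
  stopifnot(inherits(model, "demand_model"))
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stop("invalid dates", call. = FALSE)
  }
  if (end_date < start_date + 6) {
    stop("end_date must be at least 6 days after start_date", call. = FALSE)
  }
  dates <- seq(start_date, end_date, by = "day")
  n <- length(dates)
  wday <- as.POSIXlt(dates)$wday          # 0 = Sunday
  wd_idx <- ifelse(wday == 0L, 7L, wday)  # 1 = Monday .. 7 = Sunday
  doy <- as.numeric(dates - as.Date(format(dates, "%Y-01-01"))) + 1
  years_elapsed <- as.numeric(dates - start_date) / 365.25
  seasonal <- 1 + model$annual_amplitude *
    sin(2 * pi * doy / 365.25 + model$annual_phase)
  mean_level <- model$base_level * model$weekday_effects[wd_idx] * seasonal +
    model$linear_trend * years_elapsed
  if (model$noise_sd > 0) {
    old <- local_seed(model$seed)
    on.exit(restore_seed(old))
    values <- mean_level + stats::rnorm(n, sd = model$noise_sd)
  } else {
    values <- mean_level
  }
  daily_series(pmax(values, 0), start_date)
}
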