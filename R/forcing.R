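# Daily forcing containers and the synthetic reference ("truth") weather
# generator standing in for a reanalysis product.

#' Daily temperature/precipitation series for one sub-catchment
#'
#' @param temperature numeric vector of daily mean air temperature (degC).
#' @param precipitation numeric vector of daily precipitation totals
#'   (mm d^-1, non-negative), same length as `temperature`.
#' @param start `c(year, month, day)` of the first value.
#' @param calendar `"noleap365"` (default) or `"gregorian"`.
#' @param subcatchment_id `"C1"` (upstream, colder, snow-affected) or `"C2"`
#'   (downstream, urbanized).
#' @return object of class `forcing_series`.
#' @export
forcing_series <- function(temperature, precipitation, start,
                           calendar = c("noleap365", "gregorian"),
                           subcatchment_id = c("C1", "C2")) {
  calendar <- match.arg(calendar)
  subcatchment_id <- match.arg(subcatchment_id)
  temperature <- as.numeric(temperature)
  precipitation <- as.numeric(precipitation)
  if (length(temperature) != length(precipitation))
    stop("temperature and precipitation must have equal length")
  if (any(!is.finite(temperature)) || any(!is.finite(precipitation)))
    stop("non-finite forcing values")
  if (any(precipitation < 0)) stop("precipitation must be >= 0")
  structure(list(temperature = temperature, precipitation = precipitation,
                 start = as.integer(start), calendar = calendar,
                 subcatchment_id = subcatchment_id),
            class = "forcing_series")
}

#' Date table of a forcing series
#' @param fs a `forcing_series`.
#' @return `data.frame(year, month, day)`, one row per day.
#' @export
forcing_dates <- function(fs) {
  make_dates(fs$start, length(fs$temperature), fs$calendar)
}

#' @export
print.forcing_series <- function(x, ...) {
  d <- forcing_dates(x)
  if (nrow(d) == 0L) {
    cat(sprintf("<forcing_series %s, %s, empty>\n", x$subcatchment_id,
                x$calendar))
    return(invisible(x))
  }
  cat(sprintf("<forcing_series %s, %s, %d days from %04d-%02d-%02d>\n",
              x$subcatchment_id, x$calendar, nrow(d),
              d$year[1], d$month[1], d$day[1]))
  invisible(x)
}

#' @export
as.data.frame.forcing_series <- function(x, ...) {
  cbind(forcing_dates(x),
        data.frame(temperature = x$temperature,
                   precipitation = x$precipitation))
}

#' Write/read a forcing series as CSV
#'
#' Plain-text interchange format: columns `year, month, day, temperature,
#' precipitation`.
#' @param fs a `forcing_series`.
#' @param path file path.
#' @export
write_forcing_csv <- function(fs, path) {
  write.csv(as.data.frame(fs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @param calendar,subcatchment_id metadata not stored in the CSV body.
#' @export
read_forcing_csv <- function(path, calendar = "noleap365",
                             subcatchment_id = "C1") {
  d <- read.csv(path)
  forcing_series(d$temperature, d$precipitation,
                 start = c(d$year[1], d$month[1], d$day[1]),
                 calendar = calendar, subcatchment_id = subcatchment_id)
}

#' Synthetic climate parameters
#'
#' Parameters of the synthetic weather generator emulating a Mediterranean
#' two-sub-catchment climate: a sinusoidal annual temperature cycle with AR(1)
#' daily anomalies, seasonally varying wet-day occurrence with gamma
#' intensities (bimodal, autumn/spring maxima), and an elevation offset making
#' the upstream sub-catchment C1 colder (snow-affected) and slightly wetter.
#'
#' @param t_mean annual mean temperature at C2 (degC).
#' @param t_amp amplitude of the annual cycle (degC).
#' @param t_peak_doy day of year of the temperature maximum.
#' @param ar1_rho AR(1) persistence of daily temperature anomalies, in \[0,1).
#' @param ar1_sd innovation standard deviation of the anomalies (degC).
#' @param p_wet length-12 wet-day probability per calendar month.
#' @param wet_mean length-12 mean precipitation on wet days (mm d^-1).
#' @param wet_shape gamma shape of wet-day amounts.
#' @param c1_temp_offset additive temperature offset of C1 relative to C2
#'   (degC, negative: colder).
#' @param c1_precip_factor multiplicative precipitation factor of C1.
#' @return list of class `climate_config`.
#' @export
climate_config <- function(t_mean = 13, t_amp = 8.5, t_peak_doy = 200,
                           ar1_rho = 0.75, ar1_sd = 1.6,
                           p_wet = c(0.22, 0.20, 0.28, 0.32, 0.30, 0.22,
                                     0.12, 0.16, 0.30, 0.34, 0.28, 0.24),
                           wet_mean = c(5, 5, 6, 8, 8, 7,
                                        5, 7, 10, 12, 8, 6),
                           wet_shape = 0.9,
                           c1_temp_offset = -4.5, c1_precip_factor = 1.15) {
  stopifnot(length(p_wet) == 12L, length(wet_mean) == 12L,
            all(p_wet >= 0 & p_wet <= 1), all(wet_mean > 0), wet_shape > 0,
            ar1_rho >= 0, ar1_rho < 1, ar1_sd >= 0, c1_precip_factor > 0)
  structure(list(t_mean = t_mean, t_amp = t_amp, t_peak_doy = t_peak_doy,
                 ar1_rho = ar1_rho, ar1_sd = ar1_sd, p_wet = p_wet,
                 wet_mean = wet_mean, wet_shape = wet_shape,
                 c1_temp_offset = c1_temp_offset,
                 c1_precip_factor = c1_precip_factor),
            class = "climate_config")
}

#' Generate synthetic reference ("truth") weather for both sub-catchments
#'
#' Produces the pseudo-reanalysis daily series the rest of the chain treats
#' as truth. The two sub-catchments share the same random draws (anomalies,
#' wet days, intensities) so their weather is fully correlated, with C1
#' shifted colder and scaled wetter.
#'
#' @param config a [climate_config()].
#' @param n_years number of years (>= 1).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param start_year first calendar year.
#' @param calendar `"noleap365"` (default) or `"gregorian"`.
#' @return named list of two [forcing_series()]: `C1`, `C2`.
#' @export
generate_truth_weather <- function(config, n_years, seed,
                                   start_year = 1993L,
                                   calendar = c("noleap365", "gregorian")) {
  calendar <- match.arg(calendar)
  if (!inherits(config, "climate_config")) stop("config must be climate_config")
  if (n_years < 1L) stop("n_years must be >= 1")
  n <- if (calendar == "noleap365") n_years * 365L else {
    as.integer(as.Date(sprintf("%04d-01-01", start_year + n_years)) -
                 as.Date(sprintf("%04d-01-01", start_year)))
  }
  dates <- make_dates(c(start_year, 1L, 1L), n, calendar)
  doy <- seq_len(n)
  if (calendar == "noleap365") {
    doy <- (doy - 1L) %% 365L + 1L
  } else {
    doy <- as.POSIXlt(seq(as.Date(sprintf("%04d-01-01", start_year)),
                          by = "day", length.out = n))$yday + 1L
  }
  set.seed(as.integer(seed))
  cyc <- config$t_mean +
    config$t_amp * cos(2 * pi * (doy - config$t_peak_doy) / 365)
  # AR(1) anomaly process
  anom <- numeric(n)
  if (config$ar1_sd > 0) {
    innov <- rnorm(n, 0, config$ar1_sd)
    sd_stat <- config$ar1_sd / sqrt(1 - config$ar1_rho^2)
    anom[1] <- rnorm(1, 0, sd_stat)
    for (t in 2:n) anom[t] <- config$ar1_rho * anom[t - 1] + innov[t]
  }
  temp2 <- cyc + anom
  m <- dates$month
  wet <- runif(n) < config$p_wet[m]
  amt <- rgamma(n, shape = config$wet_shape, rate = config$wet_shape) *
    config$wet_mean[m]
  prec2 <- ifelse(wet, amt, 0)
  list(C1 = forcing_series(temp2 + config$c1_temp_offset,
                           prec2 * config$c1_precip_factor,
                           start = c(start_year, 1L, 1L), calendar = calendar,
                           subcatchment_id = "C1"),
       C2 = forcing_series(temp2, prec2, start = c(start_year, 1L, 1L),
                           calendar = calendar, subcatchment_id = "C2"))
}

#' Monthly climatology of a truth series
#'
#' Per-calendar-month statistics over the full series: temperature mean and
#' standard deviation, dry-day frequency (below `dry_threshold`), and a
#' method-of-moments gamma fit to wet-day precipitation. Used to define
#' anomalies and the transformed-Gaussian precipitation construction of the
#' forecast-ensemble generator.
#'
#' @param fs a [forcing_series()].
#' @param dry_threshold dry-day threshold (mm d^-1).
#' @return `data.frame` with 12 rows: `month, t_mean, t_sd, p_dry, g_shape,
#'   g_rate, n_wet`.
#' @export
truth_climatology <- function(fs, dry_threshold = 0.1) {
  d <- forcing_dates(fs)
  out <- data.frame(month = 1:12, t_mean = NA_real_, t_sd = NA_real_,
                    p_dry = NA_real_, g_shape = NA_real_, g_rate = NA_real_,
                    n_wet = NA_integer_)
  for (m in 1:12) {
    i <- d$month == m
    tt <- fs$temperature[i]
    pp <- fs$precipitation[i]
    out$t_mean[m] <- mean(tt)
    out$t_sd[m] <- if (sum(i) > 1) sd(tt) else 0
    wetv <- pp[pp >= dry_threshold]
    out$p_dry[m] <- 1 - length(wetv) / max(1L, sum(i))
    out$n_wet[m] <- length(wetv)
    if (length(wetv) >= 2 && var(wetv) > 0) {
      mu <- mean(wetv); v <- var(wetv)
      out$g_shape[m] <- mu^2 / v
      out$g_rate[m] <- mu / v
    } else {
      # degenerate/dry month: nominal unit gamma, effectively unused
      out$g_shape[m] <- 1
      out$g_rate[m] <- 1 / max(mean(wetv), 1)
    }
  }
  attr(out, "dry_threshold") <- dry_threshold
  out
}

# Mixed Bernoulli-gamma probability-integral transform: daily precipitation
# to standard-normal space and back, per calendar month. Dry days map to the
# midpoint of the dry probability mass so the transform is invertible.
precip_to_z <- function(x, clim_row, dry_threshold = 0.1) {
  p_dry <- clim_row$p_dry
  u <- ifelse(x < dry_threshold,
              pmax(p_dry / 2, 1e-9),
              p_dry + (1 - p_dry) *
                pgamma(x, shape = clim_row$g_shape, rate = clim_row$g_rate))
  qnorm(pmin(pmax(u, 1e-9), 1 - 1e-9))
}

z_to_precip <- function(z, clim_row) {
  p_dry <- clim_row$p_dry
  u <- pmin(pnorm(z), 1 - 1e-9)
  out <- numeric(length(z))
  wet <- u > p_dry
  if (any(wet))
    out[wet] <- qgamma((u[wet] - p_dry) / (1 - p_dry),
                       shape = clim_row$g_shape, rate = clim_row$g_rate)
  out
}

#' Sparse observation series (grab samples or gauge record)
#'
#' @param timestamps `data.frame(year, month, day)` with strictly increasing
#'   dates, or an integer day index.
#' @param values measured values (non-negative or `NA`).
#' @param variable free-text tag, e.g. `"doc"` (mg L^-1) or `"q"` (m^3 s^-1).
#' @return object of class `observation_series`.
#' @export
observation_series <- function(timestamps, values, variable = "doc") {
  values <- as.numeric(values)
  if (is.data.frame(timestamps)) {
    key <- timestamps$year * 10000L + timestamps$month * 100L + timestamps$day
    if (any(diff(key) <= 0)) stop("timestamps must be strictly increasing")
    if (nrow(timestamps) != length(values)) stop("length mismatch")
  } else {
    timestamps <- as.integer(timestamps)
    if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
    if (length(timestamps) != length(values)) stop("length mismatch")
  }
  if (any(values < 0, na.rm = TRUE)) stop("values must be >= 0 or NA")
  structure(list(timestamps = timestamps, values = values,
                 variable = variable),
            class = "observation_series")
}

#' Sample sparse, noisy grab-sample observations from a simulated series
#'
#' Emulates a monthly grab-sampling programme: the simulated daily series is
#' sampled every `cadence` days starting at day 1 (so a 365-day series at
#' cadence 30 yields `ceiling(365/30) = 13` samples), with multiplicative
#' lognormal measurement noise of coefficient of variation `noise_cv`
#' (unit mean).
#'
#' @param sim daily simulated values (e.g. DOC, mg L^-1).
#' @param dates optional `data.frame(year, month, day)` aligned with `sim`.
#' @param cadence sampling interval in days (>= 1).
#' @param noise_cv coefficient of variation of the noise (>= 0; 0 = exact).
#' @param seed integer RNG seed.
#' @return an [observation_series()].
#' @export
sample_doc_observations <- function(sim, dates = NULL, cadence = 30L,
                                    noise_cv = 0.1, seed = 1L) {
  sim <- as.numeric(sim)
  if (length(sim) < 1L) stop("empty simulation series")
  if (cadence < 1L) stop("cadence must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  idx <- seq(1L, length(sim), by = as.integer(cadence))
  vals <- sim[idx]
  set.seed(as.integer(seed))
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    vals <- vals * rlnorm(length(vals), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  ts <- if (is.null(dates)) idx else dates[idx, , drop = FALSE]
  observation_series(ts, vals, variable = "doc")
}
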