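# Probabilistic verification: ensemble CRPS, leave-one-year-out climatology
# reference, CRPSS grids over initialization months x leads, and the
# traffic-light skill classification.

#' Ensemble CRPS (empirical-CDF estimator)
#'
#' `CRPS = mean(|x_i - y|) - sum(|x_i - x_j|)/(2 m^2)`, the standard (NRG)
#' estimator, equal to the integral of `(F(x) - 1{x >= y})^2` over the
#' empirical ensemble CDF `F`. The "fair" (unbiased) variant divides the
#' pair term by `2 m (m-1)` instead.
#'
#' @param members finite ensemble member values (m >= 1).
#' @param obs verifying observation.
#' @param fair use the fair variant (default `FALSE`).
#' @return CRPS >= 0 (fair variant only for m >= 2).
#' @export
crps_ensemble <- function(members, obs, fair = FALSE) {
  m <- length(members)
  if (m < 1L) stop("empty ensemble")
  if (any(!is.finite(members)) || !is.finite(obs))
    stop("non-finite values")
  t1 <- mean(abs(members - obs))
  if (m == 1L) return(t1)
  pair <- sum(abs(outer(members, members, "-")))
  denom <- if (fair) 2 * m * (m - 1) else 2 * m^2
  t1 - pair / denom
}

#' Exact integral CRPS oracle
#'
#' Piecewise integration of the squared difference between the empirical
#' ensemble CDF and the observation step function, used as an independent
#' check of [crps_ensemble()].
#'
#' @inheritParams crps_ensemble
#' @return CRPS >= 0.
#' @export
crps_integral_oracle <- function(members, obs) {
  m <- length(members)
  if (m < 1L) stop("empty ensemble")
  pts <- sort(unique(c(members, obs)))
  if (length(pts) == 1L) return(0)
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    a <- pts[i]; b <- pts[i + 1L]
    Fm <- mean(members <= a)
    H <- as.numeric(obs <= a)
    total <- total + (Fm - H)^2 * (b - a)
  }
  total
}

#' Leave-one-year-out climatological reference ensemble
#'
#' The climatology "forecast" for one calendar month: the observed monthly
#' values of that month across the reference years, excluding the verifying
#' year (so the reference never contains the value it is verified against).
#'
#' @param obs_monthly `data.frame(year, month, value)` of monthly means.
#' @param calendar_month month 1-12.
#' @param ref_years reference years (span >= 3 recommended).
#' @param exclude_year year to exclude (LOO); `NULL` keeps all.
#' @return numeric vector of climatology members.
#' @export
climatology_ensemble <- function(obs_monthly, calendar_month, ref_years,
                                 exclude_year = NULL) {
  yrs <- ref_years
  if (!is.null(exclude_year)) yrs <- setdiff(yrs, exclude_year)
  v <- obs_monthly$value[obs_monthly$month == calendar_month &
                           obs_monthly$year %in% yrs]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty climatology ensemble")
  v
}

#' CRPSS skill grid over initialization months and leads
#'
#' For each (initialization month, lead): every hindcast year's ensemble of
#' monthly means is verified against the pseudo-observed monthly mean of the
#' target calendar month, and compared to the leave-one-year-out climatology
#' reference built from `ref_years`. The cell value is
#' `CRPSS = 1 - mean_y(CRPS_forecast) / mean_y(CRPS_climatology)` (ratio of
#' mean scores, i.e. the skill of the system, not the mean of per-year
#' ratios). `CRPSS = 1` is a perfect forecast, `0` no improvement over
#' climatology, negative worse than climatology. Cells with fewer than 2
#' verification years or a degenerate (zero-CRPS) climatology are flagged
#' missing.
#'
#' @param fc long `data.frame(init_month, year, member, lead, value)` of
#'   forecast monthly means for one variable (see
#'   [ensemble_monthly_means()] and [run_hindcasts()]).
#' @param obs_monthly `data.frame(year, month, value)` pseudo-observed
#'   monthly means.
#' @param ref_years climatology reference years.
#' @param loo exclude the verifying year from its climatology (default TRUE).
#' @param fair use the fair CRPS estimator.
#' @return `data.frame(init_month, lead, crpss, n, class)` of class
#'   `skill_grid`; `crpss <= 1` wherever defined.
#' @export
crpss_grid <- function(fc, obs_monthly, ref_years, loo = TRUE, fair = FALSE) {
  cells <- unique(fc[, c("init_month", "lead")])
  cells <- cells[order(cells$init_month, cells$lead), ]
  out <- data.frame(init_month = cells$init_month, lead = cells$lead,
                    crpss = NA_real_, n = 0L, class = NA_character_)
  obs_key <- paste(obs_monthly$year, obs_monthly$month)
  for (i in seq_len(nrow(out))) {
    im <- out$init_month[i]; l <- out$lead[i]
    sub <- fc[fc$init_month == im & fc$lead == l, ]
    years <- sort(unique(sub$year))
    crps_f <- c(); crps_c <- c()
    for (y in years) {
      cm <- target_month(im, l)
      ty <- y + target_year_offset(im, l)
      oi <- match(paste(ty, cm), obs_key)
      if (is.na(oi) || !is.finite(obs_monthly$value[oi])) next
      o <- obs_monthly$value[oi]
      mem <- sub$value[sub$year == y]
      mem <- mem[is.finite(mem)]
      if (length(mem) == 0L) next
      clim <- tryCatch(
        climatology_ensemble(obs_monthly, cm, ref_years,
                             exclude_year = if (loo) ty else NULL),
        error = function(e) NULL)
      if (is.null(clim)) next
      crps_f <- c(crps_f, crps_ensemble(mem, o, fair = fair))
      crps_c <- c(crps_c, crps_ensemble(clim, o, fair = fair))
    }
    out$n[i] <- length(crps_f)
    if (length(crps_f) >= 2L && mean(crps_c) > 0) {
      out$crpss[i] <- 1 - mean(crps_f) / mean(crps_c)
      out$class[i] <- as.character(classify_skill(out$crpss[i]))
    }
  }
  class(out) <- c("skill_grid", class(out))
  out
}

#' Traffic-light skill classification
#'
#' `CRPSS > 0.6` is high skill, `0.2 <= CRPSS <= 0.6` acceptable skill and
#' `CRPSS < 0.2` no skill (boundaries inclusive on the acceptable side,
#' exactly as printed).
#'
#' @param crpss finite CRPSS value(s).
#' @return ordered factor with levels `none < acceptable < high`.
#' @export
classify_skill <- function(crpss) {
  if (any(!is.finite(crpss))) stop("non-finite CRPSS")
  out <- ifelse(crpss > 0.6, "high",
                ifelse(crpss >= 0.2, "acceptable", "none"))
  factor(out, levels = c("none", "acceptable", "high"), ordered = TRUE)
}

#' Write a skill grid to CSV
#' @param grid a `skill_grid`.
#' @param path file path.
#' @export
write_skill_grid_csv <- function(grid, path) {
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' Monthly means of a truth-forced series (pseudo-observations)
#'
#' Convenience wrapper producing the `data.frame(year, month, value)` layout
#' consumed by [crpss_grid()] and the tercile products.
#'
#' @param values daily values.
#' @param dates date table aligned with `values`.
#' @param calendar calendar name.
#' @return `data.frame(year, month, value)` (complete months only).
#' @export
pseudo_obs_monthly <- function(values, dates, calendar = "noleap365") {
  a <- aggregate_monthly(values, dates, calendar)
  a[a$complete, c("year", "month", "value")]
}
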