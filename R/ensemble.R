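# Synthetic seasonal forecast ensembles standing in for an operational
# coupled forecast system: member anomalies are a lead-dependent blend of the
# truth anomaly and independent noise, with controllable marginal bias.

#' Skill structure of a synthetic forecast system
#'
#' Controls how forecast skill decays with lead time and how biased the
#' marginals are. At lead l each member's anomaly is
#' `lambda[l] * truth_anomaly + sqrt(1 - lambda[l]^2) * noise`, so
#' `lambda = 1` reproduces truth exactly and `lambda = 0` is pure noise.
#' Bias is additive for temperature (degC) and multiplicative for
#' precipitation (must be > 0).
#'
#' @param lambda_by_lead signal weights in \[0,1\], one per lead month.
#' @param bias_by_lead per-lead biases; default 0 (interpreted additively for
#'   temperature, and `bias + 1` would not apply - pass multiplicative values
#'   explicitly for precipitation, default 1 is used when `NULL`).
#' @param noise_sd temperature noise standard deviation (degC); precipitation
#'   noise lives in the transformed standard-normal space.
#' @return list of class `skill_structure`.
#' @export
skill_structure <- function(lambda_by_lead, bias_by_lead = NULL,
                            noise_sd = 3) {
  lambda_by_lead <- as.numeric(lambda_by_lead)
  if (any(lambda_by_lead < 0 | lambda_by_lead > 1))
    stop("lambda values must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(lambda_by_lead = lambda_by_lead,
                 bias_by_lead = bias_by_lead, noise_sd = noise_sd),
            class = "skill_structure")
}

.skill_bias <- function(skill, variable, n_leads) {
  b <- skill$bias_by_lead
  if (is.null(b)) b <- if (variable == "precipitation") rep(1, n_leads)
                       else rep(0, n_leads)
  b <- rep_len(as.numeric(b), n_leads)
  if (variable == "precipitation" && any(b <= 0))
    stop("multiplicative precipitation biases must be > 0")
  b
}

#' Generate one synthetic forecast ensemble
#'
#' Builds an ensemble of `n_members` daily series over the fixed 215-day
#' prediction horizon starting on day 1 of the initialization month.
#' Temperature members blend the truth anomaly (about the truth monthly
#' climatology) with independent Gaussian noise. Precipitation is blended in
#' a transformed standard-normal space and mapped back through climatological
#' mixed Bernoulli-gamma quantiles, which preserves zeros, skewness and
#' non-negativity.
#'
#' @param truth a [forcing_series()] covering the 215-day window.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param init_year,init_month initialization date (day 1 of `init_month`).
#' @param n_members ensemble size (>= 1).
#' @param skill a [skill_structure()].
#' @param seed integer RNG seed.
#' @param horizon prediction horizon in days (default 215 = 7 lead months).
#' @return object of class `ensemble_forecast` with a
#'   `members` matrix (n_members x horizon).
#' @export
generate_ensemble <- function(truth, variable = c("temperature", "precipitation"),
                              init_year, init_month, n_members, skill, seed,
                              horizon = 215L) {
  variable <- match.arg(variable)
  if (n_members < 1L) stop("n_members must be >= 1")
  if (!inherits(skill, "skill_structure")) stop("skill must be skill_structure")
  d <- forcing_dates(truth)
  i0 <- which(d$year == init_year & d$month == init_month & d$day == 1L)
  if (length(i0) != 1L || i0 + horizon - 1L > nrow(d))
    stop("truth window too short for the requested initialization")
  win <- i0:(i0 + horizon - 1L)
  dw <- d[win, , drop = FALSE]
  lead <- lead_of_dates(dw, init_year, init_month)
  n_leads <- max(lead)
  lam <- rep_len(skill$lambda_by_lead, n_leads)[lead]
  bias <- .skill_bias(skill, variable, n_leads)[lead]
  clim <- truth_climatology(truth)
  set.seed(as.integer(seed))
  members <- matrix(NA_real_, nrow = n_members, ncol = horizon)
  if (variable == "temperature") {
    mu <- clim$t_mean[dw$month]
    anom <- truth$temperature[win] - mu
    for (k in seq_len(n_members)) {
      eps <- rnorm(horizon, 0, skill$noise_sd)
      members[k, ] <- mu + lam * anom + sqrt(1 - lam^2) * eps + bias
    }
  } else {
    thr <- attr(clim, "dry_threshold")
    z_truth <- numeric(horizon)
    for (m in unique(dw$month)) {
      i <- dw$month == m
      z_truth[i] <- precip_to_z(truth$precipitation[win][i], clim[m, ], thr)
    }
    for (k in seq_len(n_members)) {
      eps <- rnorm(horizon)
      z <- lam * z_truth + sqrt(1 - lam^2) * eps
      p <- numeric(horizon)
      for (m in unique(dw$month)) {
        i <- dw$month == m
        p[i] <- z_to_precip(z[i], clim[m, ])
      }
      members[k, ] <- pmax(p * bias, 0)
    }
  }
  structure(list(variable = variable, init_year = as.integer(init_year),
                 init_month = as.integer(init_month), members = members,
                 subcatchment_id = truth$subcatchment_id,
                 calendar = truth$calendar, dates = dw),
            class = "ensemble_forecast")
}

#' @export
print.ensemble_forecast <- function(x, ...) {
  cat(sprintf("<ensemble_forecast %s %s init %04d-%02d, %d members x %d days>\n",
              x$subcatchment_id, x$variable, x$init_year, x$init_month,
              nrow(x$members), ncol(x$members)))
  invisible(x)
}

.archive_key <- function(variable, year, month) {
  sprintf("%s_%04d_%02d", variable, year, month)
}

#' Build a synthetic hindcast archive
#'
#' One [generate_ensemble()] per (year x initialization month x variable) for
#' one sub-catchment, mirroring an operational hindcast stream (e.g. 25
#' members over 1993-2016, all 12 initialization months). Deterministic under
#' `seed`: sub-seeds are derived per ensemble.
#'
#' @param truth a [forcing_series()] covering every initialization plus the
#'   215-day horizon.
#' @param years integer vector of initialization years (non-empty).
#' @param init_months initialization months, subset of 1:12 (non-empty).
#' @param n_members members per ensemble.
#' @param skill a [skill_structure()] applied to both variables, or a named
#'   list `list(temperature = , precipitation = )`.
#' @param seed integer RNG seed.
#' @param variables variables to generate.
#' @return object of class `hindcast_archive`: a keyed list of
#'   [generate_ensemble()] outputs plus metadata.
#' @export
build_hindcast_archive <- function(truth, years, init_months, n_members, skill,
                                   seed,
                                   variables = c("temperature", "precipitation")) {
  if (length(years) < 1L) stop("years must be non-empty")
  if (length(init_months) < 1L) stop("init_months must be non-empty")
  if (inherits(skill, "skill_structure"))
    skill <- stats::setNames(rep(list(skill), length(variables)), variables)
  fcs <- list()
  k <- 0L
  base <- as.integer(seed) %% 100000L
  for (v in variables) for (y in sort(as.integer(years)))
    for (m in sort(as.integer(init_months))) {
      k <- k + 1L
      sub_seed <- (base * 20011L + k * 977L) %% 2147483647L
      fcs[[.archive_key(v, y, m)]] <-
        generate_ensemble(truth, v, y, m, n_members, skill[[v]], sub_seed)
    }
  structure(list(forecasts = fcs, years = sort(as.integer(years)),
                 init_months = sort(as.integer(init_months)),
                 n_members = as.integer(n_members), variables = variables,
                 subcatchment_id = truth$subcatchment_id),
            class = "hindcast_archive")
}

#' Member-series count of an archive, per variable
#'
#' @param archive a [build_hindcast_archive()] result.
#' @return named integer vector: total member-series per variable (e.g.
#'   25 members x 24 years x 12 months = 7200).
#' @export
archive_cardinality <- function(archive) {
  out <- stats::setNames(integer(length(archive$variables)), archive$variables)
  for (ef in archive$forecasts) out[ef$variable] <- out[ef$variable] +
      nrow(ef$members)
  out
}

#' Fetch one ensemble from an archive
#' @param archive a `hindcast_archive`.
#' @param variable,year,month ensemble key.
#' @export
archive_get <- function(archive, variable, year, month) {
  ef <- archive$forecasts[[.archive_key(variable, year, month)]]
  if (is.null(ef)) stop("no such ensemble in archive")
  ef
}

#' Monthly ensemble means per lead
#'
#' Aggregates the daily member values of each ensemble in an archive to
#' monthly means per lead month (lead 1 = initialization month). In the
#' noleap365 calendar all 7 lead months fit inside the 215-day horizon, so
#' every lead is complete; incomplete trailing months (gregorian) are
#' dropped.
#'
#' @param archive a `hindcast_archive`, or a single `ensemble_forecast`.
#' @param variable variable to extract when `archive` is an archive.
#' @return long `data.frame(init_month, year, member, lead, value)`.
#' @export
ensemble_monthly_means <- function(archive, variable = "temperature") {
  efs <- if (inherits(archive, "ensemble_forecast")) list(archive)
         else Filter(function(e) e$variable == variable, archive$forecasts)
  out <- vector("list", length(efs))
  j <- 0L
  for (ef in efs) {
    lead <- lead_of_dates(ef$dates, ef$init_year, ef$init_month)
    rows <- list()
    for (l in sort(unique(lead))) {
      i <- lead == l
      cm <- target_month(ef$init_month, l)
      cy <- ef$init_year + target_year_offset(ef$init_month, l)
      if (sum(i) < days_in_month(cy, cm, ef$calendar)) next  # incomplete
      mv <- rowMeans(ef$members[, i, drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(init_month = ef$init_month, year = ef$init_year,
                   member = seq_along(mv), lead = l, value = mv)
    }
    j <- j + 1L
    out[[j]] <- do.call(rbind, rows)
  }
  do.call(rbind, out[seq_len(j)])
}
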