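# Empirical quantile mapping (EQM) bias correction of forecast ensembles
# against pseudo-observations, leave-one-year-out cross-validated, fitted per
# (initialization month, lead calendar month) and applied at daily scale.

#' Fit an empirical quantile map
#'
#' Matches forecast and observed empirical quantiles at `n_q` equally spaced
#' probabilities (default 99: 1%..99%, type-7 quantiles). Corrections are
#' applied by linear interpolation between matched quantiles with
#' constant-shift tails. For precipitation, a frequency-adaptation rule
#' preserves the observed dry-day frequency: forecast values below the
#' forecast quantile at the observed dry fraction map to zero
#' (`dry_threshold` defines a dry day). Degenerate (constant) samples fall
#' back to a constant shift; an all-dry observed sample maps everything
#' to zero.
#'
#' @param fc_sample pooled daily forecast values (training).
#' @param obs_sample pooled daily observed values (training).
#' @param n_q number of matched probabilities (>= 2).
#' @param variable `"temperature"` or `"precipitation"`.
#' @param dry_threshold dry-day threshold for precipitation (mm d^-1).
#' @return object of class `quantile_map`.
#' @export
fit_eqm <- function(fc_sample, obs_sample, n_q = 99L,
                    variable = c("temperature", "precipitation"),
                    dry_threshold = 0.1) {
  variable <- match.arg(variable)
  fc_sample <- fc_sample[is.finite(fc_sample)]
  obs_sample <- obs_sample[is.finite(obs_sample)]
  if (length(fc_sample) == 0L || length(obs_sample) == 0L)
    stop("training samples must be non-empty")
  if (n_q < 2L) stop("n_q must be >= 2")
  map <- list(variable = variable, dry_threshold = dry_threshold)
  if (variable == "precipitation") {
    obs_sample[obs_sample < dry_threshold] <- 0
    map$f_dry_obs <- mean(obs_sample < dry_threshold)
    if (map$f_dry_obs >= 1) {
      map$type <- "alldry"
      class(map) <- "quantile_map"
      return(map)
    }
    map$dry_cut <- if (map$f_dry_obs > 0)
      as.numeric(quantile(fc_sample, map$f_dry_obs, type = 7)) else -Inf
  }
  if (stats::sd(fc_sample) == 0 || stats::sd(obs_sample) == 0) {
    map$type <- "shift"
    map$shift <- mean(obs_sample) - mean(fc_sample)
    class(map) <- "quantile_map"
    return(map)
  }
  probs <- seq_len(n_q) / (n_q + 1)
  fq <- as.numeric(quantile(fc_sample, probs, type = 7))
  oq <- as.numeric(quantile(obs_sample, probs, type = 7))
  # collapse tied forecast quantiles (keeps the map single-valued, monotone)
  if (anyDuplicated(fq)) {
    oq <- as.numeric(tapply(oq, match(fq, unique(fq)), mean))
    probs <- as.numeric(tapply(probs, match(fq, unique(fq)), mean))
    fq <- unique(fq)
  }
  map$type <- if (length(fq) < 2L) "shift" else "eqm"
  if (map$type == "shift") map$shift <- oq[1] - fq[1]
  map$probs <- probs
  map$fq <- fq
  map$oq <- oq
  class(map) <- "quantile_map"
  map
}

#' Apply a fitted quantile map
#'
#' Linear interpolation between matched quantiles; outside the fitted range a
#' constant shift equal to the boundary correction is applied (so the map is
#' continuous and monotone everywhere). Precipitation output is clamped at
#' zero and forecast values at or below the fitted dry cut map to zero.
#'
#' @param map a [fit_eqm()] result.
#' @param values forecast values to correct.
#' @return corrected values, same length.
#' @export
apply_eqm <- function(map, values) {
  if (!inherits(map, "quantile_map")) stop("map must be a quantile_map")
  if (map$type == "alldry") return(rep(0, length(values)))
  out <- if (map$type == "shift") {
    values + map$shift
  } else {
    y <- approx(map$fq, map$oq, xout = values, ties = "ordered")$y
    lo <- values < map$fq[1]
    hi <- values > map$fq[length(map$fq)]
    y[lo] <- values[lo] + (map$oq[1] - map$fq[1])
    y[hi] <- values[hi] + (map$oq[length(map$oq)] - map$fq[length(map$fq)])
    y
  }
  if (map$variable == "precipitation") {
    if (!is.null(map$dry_cut)) out[values <= map$dry_cut] <- 0
    out <- pmax(out, 0)
  }
  out
}

# Training samples for one LOO cell: all members and all days of the lead
# calendar month pooled across training years; observed days of the same
# calendar month excluding the calendar year being verified.
.eqm_training <- function(archive, truth, variable, init_month, target_year,
                          lead) {
  cm <- target_month(init_month, lead)
  verif_year <- target_year + target_year_offset(init_month, lead)
  fc <- c()
  for (y in setdiff(archive$years, target_year)) {
    ef <- archive$forecasts[[.archive_key(variable, y, init_month)]]
    if (is.null(ef)) next
    sel <- lead_of_dates(ef$dates, ef$init_year, ef$init_month) == lead
    fc <- c(fc, as.vector(ef$members[, sel, drop = FALSE]))
  }
  d <- forcing_dates(truth)
  vals <- if (variable == "temperature") truth$temperature else
    truth$precipitation
  obs <- vals[d$month == cm & d$year != verif_year]
  list(fc = fc, obs = obs, calendar_month = cm, verif_year = verif_year)
}

#' Leave-one-year-out EQM correction of a hindcast archive
#'
#' For each (initialization month, lead calendar month, target year): the
#' training forecast sample pools all members and all days of that lead
#' month from every other year's ensemble; the training observed sample
#' pools the pseudo-observation days of the same calendar month excluding
#' the calendar year being verified (which, for leads crossing the year
#' boundary, is the year after the initialization year). The fitted map is
#' applied to the target year's member days of that month. Output has the
#' same shape as the input.
#'
#' @param archive a [build_hindcast_archive()] result spanning >= 2 years.
#' @param pseudo_obs the truth [forcing_series()] for the same sub-catchment.
#' @param n_q number of quantile-map probabilities.
#' @return a `hindcast_archive` of identical shape with
#'   `attr(, "provenance") == "eqm-loo"` (input archives carry `"raw"`).
#' @export
correct_archive_loo <- function(archive, pseudo_obs, n_q = 99L) {
  if (length(archive$years) < 2L)
    stop("LOO correction needs an archive spanning >= 2 years")
  corrected <- archive
  for (key in names(archive$forecasts)) {
    ef <- archive$forecasts[[key]]
    lead <- lead_of_dates(ef$dates, ef$init_year, ef$init_month)
    mem <- ef$members
    for (l in sort(unique(lead))) {
      tr <- .eqm_training(archive, pseudo_obs, ef$variable, ef$init_month,
                          ef$init_year, l)
      if (length(tr$fc) == 0L || length(tr$obs) == 0L) next
      map <- fit_eqm(tr$fc, tr$obs, n_q = n_q, variable = ef$variable)
      sel <- lead == l
      mem[, sel] <- matrix(apply_eqm(map, as.vector(mem[, sel, drop = FALSE])),
                           nrow = nrow(mem))
    }
    corrected$forecasts[[key]]$members <- mem
  }
  attr(corrected, "provenance") <- "eqm-loo"
  corrected
}
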