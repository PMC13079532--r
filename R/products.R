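# Tercile forecast products: per-calendar-month tercile climatologies,
# probabilistic tercile forecasts from ensemble monthly means, management
# action levels from the above-normal probability, and the monthly report.

#' Tercile bounds of a reference climatology
#'
#' Empirical 33.33% and 66.67% percentiles (type-7: linear interpolation
#' between order statistics) of the monthly values of one calendar month
#' across the reference years.
#'
#' @param values monthly values of one calendar month over the reference
#'   years (>= 3).
#' @return `list(t1, t2, degenerate)`; `degenerate` flags an all-equal
#'   sample (t1 == t2 carries no information).
#' @export
tercile_bounds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need >= 3 values for tercile bounds")
  q <- as.numeric(quantile(values, c(1 / 3, 2 / 3), type = 7))
  list(t1 = q[1], t2 = q[2], degenerate = q[1] == q[2])
}

#' Tercile climatology for all 12 calendar months
#'
#' @param obs_monthly `data.frame(year, month, value)`.
#' @param ref_years reference period (e.g. 1993:2016 for climate variables,
#'   2000:2016 for streamflow/DOC where a management regime shift makes the
#'   earlier record unrepresentative).
#' @param variable label stored with the climatology.
#' @return `data.frame(month, t1, t2, degenerate)` of class
#'   `tercile_climatology` with a `ref_years` attribute.
#' @export
tercile_climatology <- function(obs_monthly, ref_years, variable = "doc") {
  out <- data.frame(month = 1:12, t1 = NA_real_, t2 = NA_real_,
                    degenerate = NA)
  for (m in 1:12) {
    v <- obs_monthly$value[obs_monthly$month == m &
                             obs_monthly$year %in% ref_years]
    b <- tercile_bounds(v)
    out$t1[m] <- b$t1; out$t2[m] <- b$t2; out$degenerate[m] <- b$degenerate
  }
  attr(out, "ref_years") <- ref_years
  attr(out, "variable") <- variable
  class(out) <- c("tercile_climatology", class(out))
  out
}

#' Tercile probabilities of an ensemble
#'
#' Fraction of members below `t1` (below-normal), above `t2` (above-normal)
#' and the remainder (normal). Members exactly equal to a bound count as
#' normal (documented tie rule). Probabilities are multiples of 1/members
#' and sum to 1.
#'
#' @param members ensemble monthly means (>= 1 member).
#' @param bounds a [tercile_bounds()] result (or list with `t1`, `t2`).
#' @return `list(pBN, pN, pAN, n_members, label)` where `label` is the most
#'   probable tercile.
#' @export
tercile_probabilities <- function(members, bounds) {
  members <- members[is.finite(members)]
  m <- length(members)
  if (m < 1L) stop("empty ensemble")
  pBN <- sum(members < bounds$t1) / m
  pAN <- sum(members > bounds$t2) / m
  pN <- 1 - pBN - pAN
  list(pBN = pBN, pN = pN, pAN = pAN, n_members = m,
       label = most_probable_tercile(c(pBN, pN, pAN)))
}

#' Management action level from the above-normal DOC probability
#'
#' `watch` (pAN < 0.60), `prepare` (0.60 <= pAN < 0.70), `act`
#' (0.70 <= pAN < 0.80), `escalate` (pAN >= 0.80) — boundary semantics
#' exactly as printed; monotone non-decreasing in pAN.
#'
#' @param pAN probability of the above-normal tercile, in \[0, 1\].
#' @return ordered factor `watch < prepare < act < escalate`.
#' @export
action_level <- function(pAN) {
  if (any(!is.finite(pAN)) || any(pAN < 0 | pAN > 1))
    stop("pAN must lie in [0, 1]")
  out <- ifelse(pAN >= 0.80, "escalate",
                ifelse(pAN >= 0.70, "act",
                       ifelse(pAN >= 0.60, "prepare", "watch")))
  factor(out, levels = c("watch", "prepare", "act", "escalate"),
         ordered = TRUE)
}

#' Most probable tercile label
#'
#' Argmax of (pBN, pN, pAN); ties are resolved toward `normal` if it is
#' among the maxima, otherwise toward the lower tercile.
#'
#' @param probabilities numeric `c(pBN, pN, pAN)` summing to 1.
#' @return one of `"below-normal"`, `"normal"`, `"above-normal"`.
#' @export
most_probable_tercile <- function(probabilities) {
  stopifnot(length(probabilities) == 3L,
            abs(sum(probabilities) - 1) < 1e-9)
  labs <- c("below-normal", "normal", "above-normal")
  mx <- max(probabilities)
  cand <- which(probabilities >= mx - 1e-12)
  if (2L %in% cand) return("normal")
  labs[min(cand)]
}

#' Assemble the monthly forecast report
#'
#' Machine-readable content of the monthly stakeholder report: for each of 4
#' lead months, the DOC tercile forecast with its action level and
#' historical-skill class, and the most probable tercile of temperature,
#' precipitation and streamflow. A lead whose skill-grid cell is missing
#' carries `"no skill information"` rather than a fabricated class.
#'
#' @param init_year,init_month initialization date (report issued at the
#'   beginning of `init_month`).
#' @param forecasts named list with elements `temperature`, `precipitation`,
#'   `streamflow`, `doc`; each a list of [tercile_probabilities()] entries
#'   indexed by lead (>= `n_leads` entries).
#' @param skill a [crpss_grid()] result for DOC covering `init_month`.
#' @param n_leads number of leads displayed (default 4).
#' @param provenance optional list (reference periods, member counts, ...).
#' @return nested list of class `monthly_report`.
#' @export
assemble_report <- function(init_year, init_month, forecasts, skill,
                            n_leads = 4L, provenance = list()) {
  need <- c("temperature", "precipitation", "streamflow", "doc")
  if (!all(need %in% names(forecasts))) stop("missing forecast variables")
  if (any(vapply(forecasts[need], length, 0L) < n_leads))
    stop("forecasts must cover at least ", n_leads, " leads")
  leads <- vector("list", n_leads)
  for (l in seq_len(n_leads)) {
    doc <- forecasts$doc[[l]]
    cell <- skill[skill$init_month == init_month & skill$lead == l, ]
    skill_class <- if (nrow(cell) == 1L && is.finite(cell$crpss))
      as.character(classify_skill(cell$crpss)) else "no skill information"
    leads[[l]] <- list(
      lead = l,
      month = target_month(init_month, l),
      year = init_year + target_year_offset(init_month, l),
      doc = c(doc[c("pBN", "pN", "pAN", "n_members", "label")],
              list(action_level = as.character(action_level(doc$pAN)),
                   skill = skill_class)),
      temperature = forecasts$temperature[[l]]$label,
      precipitation = forecasts$precipitation[[l]]$label,
      streamflow = forecasts$streamflow[[l]]$label)
  }
  structure(list(init_year = init_year, init_month = init_month,
                 n_leads = n_leads, leads = leads, provenance = provenance),
            class = "monthly_report")
}

#' Write a monthly report as JSON
#' @param report a `monthly_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Render a monthly report as Markdown
#'
#' Deterministic static rendering: identical reports give byte-identical
#' output.
#'
#' @param report a `monthly_report`.
#' @return character vector of Markdown lines.
#' @export
render_report_markdown <- function(report) {
  mn <- month.name
  lines <- c(
    sprintf("# Seasonal DOC forecast — issued %s %d",
            mn[report$init_month], report$init_year),
    "",
    sprintf("Lead months shown: %d (lead 1 = initialization month).",
            report$n_leads),
    "")
  for (ld in report$leads) {
    d <- ld$doc
    lines <- c(lines,
      sprintf("## Lead %d — %s %d", ld$lead, mn[ld$month], ld$year),
      "",
      sprintf("- DOC terciles: below-normal %.0f%%, normal %.0f%%, above-normal %.0f%% (%d members)",
              100 * d$pBN, 100 * d$pN, 100 * d$pAN, d$n_members),
      sprintf("- Most probable DOC tercile: %s", d$label),
      sprintf("- Action level (pAN): %s", d$action_level),
      sprintf("- Historical skill: %s", d$skill),
      sprintf("- Hydroclimatic context: temperature %s, precipitation %s, streamflow %s",
              ld$temperature, ld$precipitation, ld$streamflow),
      "")
  }
  lines
}
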