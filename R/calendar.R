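# Calendar arithmetic for the two supported calendars. The synthetic chain
# uses a fixed 365-day ("noleap365") year so that a 5-year warm-up plus the
# 215-day prediction horizon is exactly 5*365 + 215 = 2040 daily steps;
# gregorian is supported for user-supplied observational data.

#' Month lengths of the 365-day calendar
#' @keywords internal
.NOLEAP_MLEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.noleap_doy0 <- cumsum(c(0L, .NOLEAP_MLEN[-12]))  # day-of-year before month m

#' Build a daily date table
#'
#' Expands a start date into `n` consecutive daily dates under the requested
#' calendar. In the `noleap365` calendar every year has 365 days (no Feb 29).
#'
#' @param start integer vector `c(year, month, day)`.
#' @param n number of days (>= 1).
#' @param calendar `"noleap365"` or `"gregorian"`.
#' @return `data.frame` with integer columns `year`, `month`, `day`.
#' @examples
#' make_dates(c(2001, 1, 1), 3)
#' @export
make_dates <- function(start, n, calendar = c("noleap365", "gregorian")) {
  calendar <- match.arg(calendar)
  stopifnot(length(start) == 3L, n >= 0L)
  if (n == 0L)
    return(data.frame(year = integer(), month = integer(), day = integer()))
  y <- as.integer(start[1]); m <- as.integer(start[2]); d <- as.integer(start[3])
  if (m < 1L || m > 12L) stop("invalid start month")
  if (calendar == "noleap365") {
    if (d < 1L || d > .NOLEAP_MLEN[m]) stop("invalid start day for noleap365")
    abs0 <- y * 365L + .noleap_doy0[m] + (d - 1L)
    abs <- abs0 + seq_len(n) - 1L
    yr <- abs %/% 365L
    doy <- abs %% 365L + 1L
    mo <- findInterval(doy - 1L, .noleap_doy0)
    dy <- doy - .noleap_doy0[mo]
    data.frame(year = as.integer(yr), month = as.integer(mo),
               day = as.integer(dy))
  } else {
    d0 <- as.Date(sprintf("%04d-%02d-%02d", y, m, d))
    if (is.na(d0)) stop("invalid gregorian start date")
    dd <- seq(d0, by = "day", length.out = n)
    lt <- as.POSIXlt(dd)
    data.frame(year = lt$year + 1900L, month = lt$mon + 1L,
               day = lt$mday)
  }
}

#' Number of days in a calendar month
#' @param year,month integers.
#' @param calendar calendar name.
#' @return integer month length.
#' @export
days_in_month <- function(year, month, calendar = c("noleap365", "gregorian")) {
  calendar <- match.arg(calendar)
  if (calendar == "noleap365") return(.NOLEAP_MLEN[month])
  len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  ifelse(month == 2L & leap, 29L, len[month])
}

# Lead month of each day in a forecast window: lead 1 is the initialization
# calendar month itself, lead 2 the following month, and so on.
lead_of_dates <- function(dates, init_year, init_month) {
  (dates$year - init_year) * 12L + dates$month - init_month + 1L
}

# Calendar month and year reached at a given lead from an initialization.
target_month <- function(init_month, lead) (init_month + lead - 2L) %% 12L + 1L
target_year_offset <- function(init_month, lead) (init_month + lead - 2L) %/% 12L
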