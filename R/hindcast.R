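# Hindcast engine: warm-up + prediction forcing assembly, state resets from
# the reference run, ensemble execution through the catchment model, and
# monthly aggregation per initialization month and lead.

#' Enumerate hindcast jobs
#'
#' Cartesian product of initialization years, initialization months and
#' ensemble members in deterministic (year, month, member) order — e.g. 25
#' members x 24 years x 12 months = 7200 jobs per variable/sub-catchment.
#'
#' @param n_members number of members (or a vector of member ids).
#' @param years initialization years.
#' @param init_months initialization months.
#' @return `data.frame(init_year, init_month, member)`.
#' @export
enumerate_jobs <- function(n_members, years, init_months) {
  members <- if (length(n_members) == 1L) seq_len(n_members) else n_members
  if (length(members) < 1L || length(years) < 1L || length(init_months) < 1L)
    stop("empty job dimension")
  g <- expand.grid(member = as.integer(members),
                   init_month = sort(as.integer(init_months)),
                   init_year = sort(as.integer(years)))
  g <- g[, c("init_year", "init_month", "member")]
  rownames(g) <- NULL
  g
}

#' Assemble warm-up + prediction forcing for one member
#'
#' Concatenates the truth (pseudo-reanalysis) warm-up window ending the day
#' before initialization with the member's 215-day prediction series:
#' `warmup_years * 365 + 215` daily steps in the noleap365 calendar (2040
#' steps for the default 5-year warm-up). Warm-up is always taken from
#' truth, never from forecast members.
#'
#' @param member named list `list(temperature =, precipitation =)` of
#'   215-day member series (rows of the two ensembles' `members` matrices).
#' @param truth the truth [forcing_series()] covering the warm-up window.
#' @param init_year,init_month initialization date.
#' @param warmup_years warm-up length in years (>= 0; default 5).
#' @return a [forcing_series()] of length `warmup_years*365 + horizon`.
#' @export
build_forcing <- function(member, truth, init_year, init_month,
                          warmup_years = 5L) {
  if (warmup_years < 0L) stop("warmup_years must be >= 0")
  if (truth$calendar != "noleap365")
    stop("hindcast forcing assembly requires the noleap365 calendar")
  d <- forcing_dates(truth)
  i0 <- which(d$year == init_year & d$month == init_month & d$day == 1L)
  if (length(i0) != 1L) stop("initialization date not in truth")
  iw <- i0 - warmup_years * 365L
  if (iw < 1L) stop("truth coverage insufficient for warm-up")
  idx <- if (warmup_years > 0L) iw:(i0 - 1L) else integer(0)
  forcing_series(c(truth$temperature[idx], member$temperature),
                 c(truth$precipitation[idx], member$precipitation),
                 start = c(d$year[iw], d$month[iw], d$day[iw]),
                 calendar = truth$calendar,
                 subcatchment_id = truth$subcatchment_id)
}

#' Extract the stored model state at a date from a reference run
#'
#' The reference (truth-forced) simulation must have been run with
#' `save_trajectory = TRUE`; the returned state is the exact stored state at
#' the start of the requested day, so feeding it back with the same forcing
#' reproduces the reference outputs bitwise from that date.
#'
#' @param reference a `simulation_output` with a trajectory.
#' @param year,month,day date inside the reference run.
#' @return a `model_state` matrix.
#' @export
initial_state_from_reference <- function(reference, year, month, day = 1L) {
  if (is.null(reference$trajectory))
    stop("reference run has no stored trajectory")
  d <- reference$dates
  i <- which(d$year == year & d$month == month & d$day == day)
  if (length(i) != 1L) stop("date outside the reference trajectory")
  dn <- reference$state_dimnames
  st <- matrix(reference$trajectory[i, ], nrow = length(dn[[1]]),
               byrow = TRUE, dimnames = dn)
  class(st) <- c("model_state", class(st))
  st
}

#' Run a hindcast ensemble through the catchment model
#'
#' For each (initialization year, initialization month): resets the model
#' state from the truth-forced reference run at the warm-up start date, runs
#' the shared truth warm-up once (all members of one initialization share
#' identical warm-up forcing, hence identical warm-up states), then runs
#' each member's 215-day prediction window and aggregates daily streamflow
#' and DOC at the outlet reach to monthly means per lead (lead 1 = the
#' initialization calendar month).
#'
#' @param config a `catchment_config`.
#' @param archives named list of [build_hindcast_archive()] results, one per
#'   reach (same years/init months/member counts).
#' @param truth named list of truth [forcing_series()] per reach.
#' @param reference a truth-forced `simulation_output` with trajectory,
#'   covering every warm-up window.
#' @param warmup_years warm-up length (years, default 5).
#' @param outlet reach whose outputs are aggregated (default `"C2"`).
#' @return object of class `hindcast_output`: long data.frame
#'   `$monthly(init_month, year, member, lead, variable, value)` with
#'   `variable` in `q`, `doc`, plus job metadata. Failed jobs are reported
#'   and excluded.
#' @export
run_hindcasts <- function(config, archives, truth, reference,
                          warmup_years = 5L, outlet = "C2") {
  reaches <- names(config$reaches)
  if (!all(reaches %in% names(archives)) || !all(reaches %in% names(truth)))
    stop("archives and truth must cover every reach")
  a1 <- archives[[1]]
  rows <- list()
  failures <- character()
  for (y in a1$years) for (m in a1$init_months) {
    # warm-up shared across members of this initialization
    wstart <- make_dates(c(y, m, 1L), 1L)[1, ]  # init date
    state_w <- tryCatch({
      st <- initial_state_from_reference(
        reference, wstart$year - warmup_years, wstart$month, 1L)
      if (warmup_years > 0L) {
        wf <- lapply(reaches, function(r) {
          d <- forcing_dates(truth[[r]])
          i0 <- which(d$year == y & d$month == m & d$day == 1L)
          iw <- i0 - warmup_years * 365L
          forcing_series(truth[[r]]$temperature[iw:(i0 - 1L)],
                         truth[[r]]$precipitation[iw:(i0 - 1L)],
                         start = c(d$year[iw], d$month[iw], d$day[iw]),
                         calendar = truth[[r]]$calendar,
                         subcatchment_id = truth[[r]]$subcatchment_id)
        })
        names(wf) <- reaches
        run_simulation(config, wf, init_state = st)$final_state
      } else st
    }, error = function(e) e)
    if (inherits(state_w, "error")) {
      failures <- c(failures, sprintf("init %04d-%02d: %s", y, m,
                                      conditionMessage(state_w)))
      next
    }
    efs <- lapply(reaches, function(r) list(
      temperature = archive_get(archives[[r]], "temperature", y, m),
      precipitation = archive_get(archives[[r]], "precipitation", y, m)))
    names(efs) <- reaches
    n_mem <- nrow(efs[[1]]$temperature$members)
    horizon <- ncol(efs[[1]]$temperature$members)
    pdates <- efs[[1]]$temperature$dates
    lead <- lead_of_dates(pdates, y, m)
    for (k in seq_len(n_mem)) {
      res <- tryCatch({
        pf <- lapply(reaches, function(r)
          forcing_series(efs[[r]]$temperature$members[k, ],
                         efs[[r]]$precipitation$members[k, ],
                         start = c(y, m, 1L), calendar = "noleap365",
                         subcatchment_id = truth[[r]]$subcatchment_id))
        names(pf) <- reaches
        sim <- run_simulation(config, pf, init_state = state_w)
        out <- sim$reaches[[outlet]]
        lr <- list()
        for (l in sort(unique(lead))) {
          i <- lead == l
          cm <- target_month(m, l)
          cy <- y + target_year_offset(m, l)
          if (sum(i) < days_in_month(cy, cm, "noleap365")) next
          lr[[length(lr) + 1L]] <- data.frame(
            init_month = m, year = y, member = k, lead = l,
            variable = c("q", "doc"),
            value = c(mean(out$Q[i]), mean(out$doc[i])))
        }
        do.call(rbind, lr)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("job %04d-%02d member %d: %s", y, m,
                                        k, conditionMessage(res)))
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  structure(list(monthly = do.call(rbind, rows),
                 years = a1$years, init_months = a1$init_months,
                 warmup_years = warmup_years, outlet = outlet,
                 failures = failures),
            class = "hindcast_output")
}
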