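# Minimal daily rainfall-runoff and soil-carbon/DOC simulator with the same
# I/O contract as a coupled semi-distributed hydrology -> in-soil carbon
# chain: temperature and precipitation in; hydrologically effective rainfall
# (HER), soil moisture deficit (SMD), streamflow and DOC out. This is a
# deliberately small stand-in model, not a re-implementation of any published
# catchment model: it keeps the two properties the forecasting workflow
# exploits (HER/SMD mediation of runoff, slow carbon pools as system memory).
#
# Unit conventions: mm d^-1 over km^2 converts to m^3 s^-1 via *1000/86400;
# mg L^-1 is identical to g m^-3, so load (g s^-1) = conc (mg L^-1) * Q
# (m^3 s^-1).

#' One daily hydrology step for a single land-cover unit
#'
#' Degree-day snow store, single soil bucket with saturation-excess runoff,
#' and two linear reservoirs (quick/slow). Snow accumulates when
#' `T < T_snow`; melt is `min(snowpack, DDF * max(0, T - T_snow))`;
#' `PET = a_pet * max(0, T)`; `AET = min(PET * S/C_soil, S + W)` (capped at
#' available water so the balance closes exactly);
#' `HER = max(0, S + W - AET - C_soil)` (saturation excess);
#' the quick and slow stores receive `beta_q * HER` and `(1-beta_q) * HER`
#' and release `store/tau` after inflow.
#'
#' @param state list with `snow`, `S`, `Sq`, `Ss` (mm).
#' @param T_air daily mean air temperature (degC).
#' @param P daily precipitation (mm).
#' @param params one-row data.frame or list with the hydrological parameters
#'   (see [default_catchment_config()]).
#' @return `list(state = updated state, fluxes = list(rain, snowfall, melt,
#'   pet, aet, her, smd, q_quick, q_slow, S_end, C_soil))`, all fluxes in
#'   mm d^-1 and non-negative.
#' @export
step_hydrology <- function(state, T_air, P, params) {
  if (!is.finite(T_air) || !is.finite(P) || P < 0)
    stop("non-finite or negative forcing")
  if (params$C_soil <= 0 || params$tau_q < 1 || params$tau_s < 1 ||
      params$beta_q < 0 || params$beta_q > 1)
    stop("hydrological parameter out of admissible range")
  snowfall <- if (T_air < params$T_snow) P else 0
  rain <- P - snowfall
  snow <- state$snow + snowfall
  melt <- min(snow, params$DDF * max(0, T_air - params$T_snow))
  snow <- snow - melt
  W <- rain + melt
  pet <- params$a_pet * max(0, T_air)
  aet <- min(pet * state$S / params$C_soil, state$S + W)
  her <- max(0, state$S + W - aet - params$C_soil)
  S <- state$S + W - aet - her
  S <- min(max(S, 0), params$C_soil)
  Sq <- state$Sq + params$beta_q * her
  q_quick <- Sq / params$tau_q
  Sq <- Sq - q_quick
  Ss <- state$Ss + (1 - params$beta_q) * her
  q_slow <- Ss / params$tau_s
  Ss <- Ss - q_slow
  list(state = list(snow = snow, S = S, Sq = Sq, Ss = Ss),
       fluxes = list(rain = rain, snowfall = snowfall, melt = melt,
                     pet = pet, aet = aet, her = her,
                     smd = params$C_soil - S, q_quick = q_quick,
                     q_slow = q_slow, S_end = S, C_soil = params$C_soil))
}

#' One daily carbon step for a single land-cover unit
#'
#' Explicit-Euler update of three pools: labile organic-layer carbon
#' (`SOC_o`), mineral-layer carbon (`SOC_m`) and dissolved soil DOC (`D`),
#' all g C m^-2. DOC production
#' `k_p * SOC_o * Q10^((T - T_ref)/10) * (S/C_soil)` moves SOC_o -> D;
#' sorption `k_sorb * D` moves D -> SOC_m; mineralization `k_min * D` and a
#' slow mineral-layer mineralization `k_min_m * SOC_m` leave the system
#' (the latter gives the mineral pool a steady state); export
#' `D * min(1, HER/(S + 0.1))` leaves via quickflow. SOC_o gains the litter
#' input `I_litter`. Outgoing fluxes are proportionally capped so no pool
#' goes negative.
#'
#' @param state list with `SOC_o`, `SOC_m`, `D`.
#' @param hydro_fluxes the `fluxes` element of [step_hydrology()] (uses
#'   `her`, `S_end`, `C_soil`).
#' @param T_air daily mean air temperature (degC).
#' @param params one-row data.frame or list of carbon parameters.
#' @return `list(state, fluxes = list(production, sorption, mineralization,
#'   mineralization_dissolved, mineralization_mineral, export))`, fluxes in
#'   g C m^-2 d^-1.
#' @export
step_carbon <- function(state, hydro_fluxes, T_air, params) {
  if (!is.finite(T_air)) stop("non-finite forcing")
  S <- hydro_fluxes$S_end
  her <- hydro_fluxes$her
  production <- params$k_p * state$SOC_o *
    params$Q10^((T_air - params$T_ref) / 10) * (S / hydro_fluxes$C_soil)
  production <- min(production, state$SOC_o)
  sorption <- params$k_sorb * state$D
  miner_d <- params$k_min * state$D
  export <- state$D * min(1, her / (S + 0.1))
  tot <- sorption + miner_d + export
  if (tot > state$D && tot > 0) {
    sc <- state$D / tot
    sorption <- sorption * sc; miner_d <- miner_d * sc; export <- export * sc
  }
  miner_m <- min(params$k_min_m * state$SOC_m, state$SOC_m)
  list(state = list(SOC_o = state$SOC_o + params$I_litter - production,
                    SOC_m = state$SOC_m + sorption - miner_m,
                    D = state$D + production - sorption - miner_d - export),
       fluxes = list(production = production, sorption = sorption,
                     mineralization = miner_d + miner_m,
                     mineralization_dissolved = miner_d,
                     mineralization_mineral = miner_m, export = export))
}

#' Route local runoff and DOC loads through the reach network
#'
#' Reaches are processed in topological order (C1 discharges into C2).
#' Per reach: `Q = local runoff + upstream Q + point-source flows` with the
#' mm km^2 -> m^3 s^-1 conversion factor 1000/86400; `load = terrestrial
#' export + c_gw * q_slow + upstream load * (1 - instream_loss) +
#' sum(conc_ps * flow_ps)`; concentration = load / Q, flagged `NA` when
#' Q = 0.
#'
#' @param config a `catchment_config` (reach order = `names(config$reaches)`).
#' @param runoff named list per reach: `q_local_mm` (total local runoff depth,
#'   mm d^-1) and `q_slow_mm` (slow-flow depth, mm d^-1).
#' @param export_g_s named numeric: terrestrial DOC export per reach (g s^-1).
#' @return `data.frame(reach, Q, load, conc)`.
#' @export
route_network <- function(config, runoff, export_g_s) {
  reaches <- names(config$reaches)
  Q_up <- 0; load_up <- 0
  out <- data.frame(reach = reaches, Q = NA_real_, load = NA_real_,
                    conc = NA_real_)
  for (i in seq_along(reaches)) {
    r <- config$reaches[[reaches[i]]]
    f <- r$area_km2 * 1000 / 86400
    ps_flow <- sum(vapply(r$point_sources, function(p) p$flow_m3_s, 0))
    ps_load <- sum(vapply(r$point_sources,
                          function(p) p$conc_mg_l * p$flow_m3_s, 0))
    Q <- runoff[[reaches[i]]]$q_local_mm * f + Q_up + ps_flow
    load <- export_g_s[[reaches[i]]] +
      r$c_gw * runoff[[reaches[i]]]$q_slow_mm * f +
      load_up * (1 - r$instream_loss) + ps_load
    out$Q[i] <- Q
    out$load[i] <- load
    out$conc[i] <- if (Q > 0) load / Q else NA_real_
    Q_up <- Q; load_up <- load
  }
  out
}

# Flatten config to the matrices the C++ core expects.
.sim_inputs <- function(config, forcing, init_state) {
  reaches <- names(config$reaches)
  lc <- config$land_covers
  R <- length(reaches); U <- length(lc)
  Tm <- sapply(reaches, function(r) forcing[[r]]$temperature)
  Pm <- sapply(reaches, function(r) forcing[[r]]$precipitation)
  if (is.null(dim(Tm))) { Tm <- matrix(Tm, ncol = R); Pm <- matrix(Pm, ncol = R) }
  shares <- t(sapply(reaches, function(r) config$reaches[[r]]$shares[lc]))
  hp <- as.matrix(config$hydro[lc, .HYDRO_PARS])[rep(seq_len(U), R), ]
  cp <- as.matrix(config$carbon[lc, .CARBON_PARS])[rep(seq_len(U), R), ]
  area <- vapply(reaches, function(r) config$reaches[[r]]$area_km2, 0)
  ps_flow <- vapply(reaches, function(r)
    sum(vapply(config$reaches[[r]]$point_sources,
               function(p) p$flow_m3_s, 0)), 0)
  ps_load <- vapply(reaches, function(r)
    sum(vapply(config$reaches[[r]]$point_sources,
               function(p) p$conc_mg_l * p$flow_m3_s, 0)), 0)
  c_gw <- vapply(reaches, function(r) config$reaches[[r]]$c_gw, 0)
  loss <- vapply(reaches, function(r) config$reaches[[r]]$instream_loss, 0)
  list(Tm = Tm, Pm = Pm, area = area, shares = shares, hp = hp, cp = cp,
       ps_flow = ps_flow, ps_load = ps_load, c_gw = c_gw, loss = loss,
       state0 = unclass(init_state), reaches = reaches, R = R, U = U)
}

#' Run the coupled daily simulation
#'
#' Daily loop over all reach x land-cover units: hydrology step, carbon step,
#' area-share aggregation within each reach, then network routing. The heavy
#' loop runs in compiled code and reproduces the exported step functions
#' exactly.
#'
#' @param config a `catchment_config`.
#' @param forcing named list of [forcing_series()], one per reach, aligned in
#'   length, start and calendar.
#' @param init_state a `model_state` matrix (default: [default_model_state()]).
#' @param save_trajectory store the state at the start of every day (needed
#'   to reset hindcasts from a reference run).
#' @return object of class `simulation_output`: `dates`, per-reach
#'   data.frames (`Q` m^3 s^-1, `doc` mg L^-1 with `NA` when Q = 0, `load`
#'   g s^-1, `her`, `smd`, `aet`, `q_local`, `q_slow` mm, `mineralization`,
#'   `export_c` g C m^-2 d^-1), `final_state`, and optionally `trajectory`.
#' @export
run_simulation <- function(config, forcing, init_state = NULL,
                           save_trajectory = FALSE) {
  validate_catchment_config(config)
  reaches <- names(config$reaches)
  if (!all(reaches %in% names(forcing)))
    stop("forcing must contain one series per reach")
  n <- length(forcing[[reaches[1]]]$temperature)
  for (r in reaches) {
    fr <- forcing[[r]]
    if (length(fr$temperature) != n ||
        fr$calendar != forcing[[reaches[1]]]$calendar ||
        !all(fr$start == forcing[[reaches[1]]]$start))
      stop("forcing series misaligned across sub-catchments")
  }
  if (is.null(init_state)) init_state <- default_model_state(config)
  if (n == 0L) {
    return(structure(list(dates = NULL, reaches = NULL,
                          final_state = init_state, trajectory = NULL,
                          calendar = forcing[[reaches[1]]]$calendar),
                     class = "simulation_output"))
  }
  inp <- .sim_inputs(config, forcing, init_state)
  res <- sim_core_cpp(inp$Tm, inp$Pm, inp$area, inp$shares, inp$hp, inp$cp,
                      inp$ps_flow, inp$ps_load, inp$c_gw, inp$loss,
                      inp$state0, save_trajectory)
  dates <- forcing_dates(forcing[[reaches[1]]])
  per_reach <- stats::setNames(vector("list", inp$R), reaches)
  for (i in seq_len(inp$R)) {
    per_reach[[i]] <- data.frame(
      Q = res$Q[, i], doc = res$conc[, i], load = res$load[, i],
      her = res$her[, i], smd = res$smd[, i], aet = res$aet[, i],
      q_local = res$q_local[, i], q_slow = res$q_slow[, i],
      mineralization = res$miner[, i], export_c = res$export[, i])
  }
  fin <- res$state_final
  dimnames(fin) <- dimnames(unclass(init_state))
  class(fin) <- c("model_state", class(fin))
  traj <- NULL
  if (save_trajectory) {
    traj <- res$trajectory
    colnames(traj) <- as.vector(outer(colnames(init_state),
                                      rownames(init_state),
                                      function(v, r) paste(r, v, sep = "|")))
  }
  structure(list(dates = dates, reaches = per_reach, final_state = fin,
                 trajectory = traj, state_dimnames = dimnames(unclass(init_state)),
                 calendar = forcing[[reaches[1]]]$calendar),
            class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  n <- if (is.null(x$dates)) 0L else nrow(x$dates)
  cat(sprintf("<simulation_output: %d days, reaches %s>\n", n,
              paste(names(x$reaches), collapse = ", ")))
  invisible(x)
}

#' Write a simulation output to CSV (one file per reach)
#' @param sim a `simulation_output`.
#' @param dir output directory (created if missing).
#' @export
write_simulation_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in names(sim$reaches)) {
    write.csv(cbind(sim$dates, sim$reaches[[r]]),
              file.path(dir, paste0(r, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' Spin up the model on a repeated climatological year
#'
#' Repeats a single forcing year `n_years` times from the default initial
#' state and reports the final state together with a drift diagnostic: the
#' maximum relative change of any carbon pool over the final year. A
#' multi-year warm-up is needed because the carbon pools turn over slowly;
#' the drift diagnostic decreases towards zero as the pools converge to the
#' periodic cycle.
#'
#' @param config a `catchment_config`.
#' @param forcing_year named list of 365-day (one-year) [forcing_series()]
#'   per reach.
#' @param n_years number of repetitions (>= 1).
#' @param init_state optional starting state.
#' @return `list(state, drift, drift_by_pool)`; `drift` is the max over
#'   units and pools of |change over final year| / pool value.
#' @export
spin_up <- function(config, forcing_year, n_years, init_state = NULL) {
  if (n_years < 1L) stop("n_years must be >= 1")
  rep_fs <- function(fs) forcing_series(rep(fs$temperature, n_years),
                                        rep(fs$precipitation, n_years),
                                        start = fs$start, calendar = fs$calendar,
                                        subcatchment_id = fs$subcatchment_id)
  forcing <- lapply(forcing_year, rep_fs)
  ny <- length(forcing_year[[1]]$temperature)
  sim <- run_simulation(config, forcing, init_state = init_state,
                        save_trajectory = TRUE)
  n <- nrow(sim$trajectory)
  start_final <- sim$trajectory[n - ny + 1L, ]
  final <- as.vector(t(unclass(sim$final_state)))  # unit-major, like trajectory
  names(final) <- colnames(sim$trajectory)
  pools <- grep("\\|(SOC_o|SOC_m|D)$", colnames(sim$trajectory))
  rel <- abs(final[pools] - start_final[pools]) /
    pmax(abs(final[pools]), 1e-12)
  by_pool <- tapply(rel, sub("^.*\\|", "", names(rel)), max)
  list(state = sim$final_state, drift = max(rel), drift_by_pool = by_pool)
}
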