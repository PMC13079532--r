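# Shared fixtures, built in code and cached across test files within a run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 12-year synthetic truth weather (both sub-catchments), default climate
fix_truth12 <- function() {
  fixture("truth12", function()
    generate_truth_weather(climate_config(), 12, seed = 101,
                           start_year = 1995L))
}

# reference truth-forced run over the 12-year truth, with trajectory
fix_reference12 <- function() {
  fixture("reference12", function()
    run_simulation(default_catchment_config(), fix_truth12(),
                   save_trajectory = TRUE))
}

# pseudo-observed monthly means of Q and DOC at C2 from the reference run
fix_pseudo_obs12 <- function() {
  fixture("pseudo_obs12", function() {
    ref <- fix_reference12()
    list(q = pseudo_obs_monthly(ref$reaches$C2$Q, ref$dates),
         doc = pseudo_obs_monthly(ref$reaches$C2$doc, ref$dates))
  })
}

# one-year random forcing pair for short model tests
fix_forcing_pair <- function(n_days = 365L, seed = 7L, start_year = 2001L) {
  set.seed(seed)
  mk <- function(id) forcing_series(
    temperature = rnorm(n_days, 12, 6),
    precipitation = ifelse(runif(n_days) < 0.3, rgamma(n_days, 0.8, 0.1), 0),
    start = c(start_year, 1L, 1L), subcatchment_id = id)
  list(C1 = mk("C1"), C2 = mk("C2"))
}

# run the exported single-step R functions day by day, mirroring the
# compiled simulation loop; used as the dual-route check of run_simulation
run_simulation_reference_r <- function(config, forcing, init_state) {
  reaches <- names(config$reaches)
  lc <- config$land_covers
  n <- length(forcing[[1]]$temperature)
  st <- unclass(init_state)
  out <- lapply(reaches, function(r)
    data.frame(Q = numeric(n), doc = numeric(n), load = numeric(n),
               her = numeric(n)))
  names(out) <- reaches
  for (d in seq_len(n)) {
    runoff <- list(); export_gs <- c()
    for (r in reaches) {
      rc <- config$reaches[[r]]
      q_local <- 0; q_slow <- 0; her <- 0; exp_gs <- 0
      for (u in lc) {
        key <- paste(r, u, sep = ".")
        hs <- list(snow = st[key, "snow"], S = st[key, "S"],
                   Sq = st[key, "Sq"], Ss = st[key, "Ss"])
        h <- step_hydrology(hs, forcing[[r]]$temperature[d],
                            forcing[[r]]$precipitation[d],
                            config$hydro[u, ])
        cs <- list(SOC_o = st[key, "SOC_o"], SOC_m = st[key, "SOC_m"],
                   D = st[key, "D"])
        cb <- step_carbon(cs, h$fluxes, forcing[[r]]$temperature[d],
                          config$carbon[u, ])
        st[key, ] <- c(h$state$snow, h$state$S, h$state$Sq, h$state$Ss,
                       cb$state$SOC_o, cb$state$SOC_m, cb$state$D)
        w <- rc$shares[[u]]
        q_local <- q_local + w * (h$fluxes$q_quick + h$fluxes$q_slow)
        q_slow <- q_slow + w * h$fluxes$q_slow
        her <- her + w * h$fluxes$her
        exp_gs <- exp_gs + w * cb$fluxes$export * rc$area_km2 * 1e6 / 86400
      }
      runoff[[r]] <- list(q_local_mm = q_local, q_slow_mm = q_slow)
      export_gs[r] <- exp_gs
      out[[r]]$her[d] <- her
    }
    routed <- route_network(config, runoff, export_gs)
    for (i in seq_along(reaches)) {
      out[[reaches[i]]]$Q[d] <- routed$Q[i]
      out[[reaches[i]]]$doc[d] <- routed$conc[i]
      out[[reaches[i]]]$load[d] <- routed$load[i]
    }
  }
  list(reaches = out, final_state = st)
}
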