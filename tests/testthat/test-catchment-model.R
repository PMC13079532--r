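hp1 <- list(T_snow = 0, DDF = 3, a_pet = 0.15, C_soil = 150, beta_q = 0.5,
            tau_q = 2, tau_s = 40)
cp1 <- list(k_p = 0.004, Q10 = 2, T_ref = 12, k_sorb = 0.05, k_min = 0.03,
            k_min_m = 2e-4, I_litter = 0.02)

test_that("hydrology step: snow accumulation, saturation excess, empty system", {
  # sub-freezing day: everything accumulates as snow, nothing flows
  h <- step_hydrology(list(snow = 0, S = 0, Sq = 0, Ss = 0), -5, 10, hp1)
  expect_equal(h$state$snow, 10)
  expect_equal(h$fluxes$her, 0)
  expect_equal(h$fluxes$q_quick + h$fluxes$q_slow, 0)
  expect_equal(h$fluxes$melt, 0)

  # saturated soil, no evaporative demand: all rain becomes effective
  h2 <- step_hydrology(list(snow = 0, S = 150, Sq = 0, Ss = 0), 0, 10, hp1)
  expect_equal(h2$fluxes$pet, 0)
  expect_equal(h2$fluxes$her, 10)
  expect_equal(h2$state$S, 150)

  # empty system, no input: all fluxes zero
  h3 <- step_hydrology(list(snow = 0, S = 0, Sq = 0, Ss = 0), 10, 0, hp1)
  expect_true(all(unlist(h3$fluxes[c("rain", "melt", "aet", "her",
                                     "q_quick", "q_slow")]) == 0))

  # melt is degree-day limited and bounded by the snowpack
  h4 <- step_hydrology(list(snow = 2, S = 75, Sq = 0, Ss = 0), 4, 0, hp1)
  expect_equal(h4$fluxes$melt, 2)  # min(2, 3*4)
  h5 <- step_hydrology(list(snow = 50, S = 75, Sq = 0, Ss = 0), 1, 0, hp1)
  expect_equal(h5$fluxes$melt, 3)  # min(50, 3*1)

  expect_error(step_hydrology(list(snow = 0, S = 0, Sq = 0, Ss = 0), 5, 10,
                              modifyList(hp1, list(tau_q = 0.5))), "range")
})

test_that("bucket equations evaluate as stated", {
  # unsaturated: HER = max(0, S + W - AET - C_soil) by direct evaluation
  st <- list(snow = 0, S = 100, Sq = 5, Ss = 10)
  h <- step_hydrology(st, 10, 80, hp1)
  aet <- 0.15 * 10 * 100 / 150
  expect_equal(h$fluxes$aet, aet)
  expect_equal(h$fluxes$her, max(0, 100 + 80 - aet - 150))
  expect_equal(h$state$S, min(150, 100 + 80 - aet - h$fluxes$her))
  expect_equal(h$fluxes$smd, 150 - h$state$S)
  expect_equal(h$fluxes$q_quick, (5 + 0.5 * h$fluxes$her) / 2)
  expect_equal(h$fluxes$q_slow, (10 + 0.5 * h$fluxes$her) / 40)
})

test_that("carbon step: production formula, Q10 doubling, empty pool", {
  st <- list(SOC_o = 10, SOC_m = 50, D = 0.3)
  hf <- list(her = 0, S_end = 150, C_soil = 150)
  cb <- step_carbon(st, hf, 12, cp1)
  expect_equal(cb$fluxes$production, 0.004 * 10)  # T = T_ref, S = C_soil
  cb10 <- step_carbon(st, hf, 22, cp1)
  expect_equal(cb10$fluxes$production, 2 * cb$fluxes$production)

  empty <- step_carbon(list(SOC_o = 10, SOC_m = 50, D = 0),
                       list(her = 5, S_end = 100, C_soil = 150), 12, cp1)
  expect_equal(empty$fluxes$sorption, 0)
  expect_equal(empty$fluxes$mineralization_dissolved, 0)
  expect_equal(empty$fluxes$export, 0)

  # flux capping: demands exceeding D are scaled, pool stays non-negative
  greedy <- modifyList(cp1, list(k_sorb = 0.9, k_min = 0.8))
  cb2 <- step_carbon(list(SOC_o = 0, SOC_m = 0, D = 1),
                     list(her = 500, S_end = 10, C_soil = 150), 12, greedy)
  expect_gte(cb2$state$D, 0)
  expect_equal(cb2$fluxes$sorption + cb2$fluxes$mineralization_dissolved +
                 cb2$fluxes$export, 1)
})

test_that("routing: point-source mass balance, dry stream, dilution", {
  cfg <- default_catchment_config()
  # zero terrestrial load, 1 m3/s of local water in C2 before the source
  cfg2 <- cfg
  cfg2$reaches$C2$c_gw <- 0
  cfg2$reaches$C1$c_gw <- 0
  q2 <- 1 / (cfg$reaches$C2$area_km2 * 1000 / 86400)  # mm giving 1 m3/s
  r <- route_network(cfg2,
                     list(C1 = list(q_local_mm = 0, q_slow_mm = 0),
                          C2 = list(q_local_mm = q2, q_slow_mm = 0)),
                     c(C1 = 0, C2 = 0))
  expect_equal(r$Q[2], 1.13)
  expect_equal(r$conc[2], 12 * 0.13 / 1.13)

  # dry network: Q = 0, concentration flagged missing
  cfg3 <- cfg2
  cfg3$reaches$C2$point_sources <- list()
  r2 <- route_network(cfg3,
                      list(C1 = list(q_local_mm = 0, q_slow_mm = 0),
                           C2 = list(q_local_mm = 0, q_slow_mm = 0)),
                      c(C1 = 0, C2 = 0))
  expect_equal(r2$Q, c(0, 0))
  expect_true(all(is.na(r2$conc)))

  # dilution: doubling water with fixed load halves the concentration
  ld <- c(C1 = 5, C2 = 20)
  rn <- list(C1 = list(q_local_mm = 0.8, q_slow_mm = 0),
             C2 = list(q_local_mm = 1.6, q_slow_mm = 0))
  rn2 <- list(C1 = list(q_local_mm = 1.6, q_slow_mm = 0),
              C2 = list(q_local_mm = 3.2, q_slow_mm = 0))
  ra <- route_network(cfg3, rn, ld)
  rb <- route_network(cfg3, rn2, ld)
  expect_equal(rb$conc, ra$conc / 2)
})

test_that("compiled simulation reproduces the single-step R functions", {
  cfg <- default_catchment_config()
  forcing <- fix_forcing_pair(n_days = 60, seed = 21)
  st0 <- default_model_state(cfg)
  fast <- run_simulation(cfg, forcing, init_state = st0)
  slow <- run_simulation_reference_r(cfg, forcing, st0)
  for (r in c("C1", "C2")) {
    expect_equal(fast$reaches[[r]]$Q, slow$reaches[[r]]$Q, tolerance = 1e-12)
    expect_equal(fast$reaches[[r]]$load, slow$reaches[[r]]$load,
                 tolerance = 1e-12)
    expect_equal(fast$reaches[[r]]$doc, slow$reaches[[r]]$doc,
                 tolerance = 1e-12)
  }
  expect_equal(unclass(fast$final_state), slow$final_state,
               tolerance = 1e-12)
})

test_that("zero-length forcing returns empty output with unchanged state", {
  cfg <- default_catchment_config()
  st0 <- default_model_state(cfg)
  empty <- lapply(fix_forcing_pair(n_days = 5), function(fs)
    forcing_series(numeric(0), numeric(0), start = fs$start,
                   subcatchment_id = fs$subcatchment_id))
  out <- run_simulation(cfg, empty, init_state = st0)
  expect_null(out$reaches)
  expect_identical(unclass(out$final_state), unclass(st0))
})

test_that("water and carbon balances close and pools stay non-negative", {
  cfg <- default_catchment_config()
  for (seed in c(31, 32)) {
    forcing <- fix_forcing_pair(n_days = 730, seed = seed)
    st0 <- default_model_state(cfg)
    sim <- run_simulation(cfg, forcing, init_state = st0,
                          save_trajectory = TRUE)
    lc <- cfg$land_covers
    for (r in c("C1", "C2")) {
      shares <- cfg$reaches[[r]]$shares[lc]
      cols <- paste0(r, ".", lc)
      st_end <- unclass(sim$final_state)[cols, ]
      st_start <- unclass(st0)[cols, ]
      dW <- sum(shares * rowSums((st_end - st_start)[, c("snow", "S", "Sq",
                                                         "Ss")]))
      lhs <- sum(forcing[[r]]$precipitation) -
        sum(sim$reaches[[r]]$aet) - sum(sim$reaches[[r]]$q_local) - dW
      expect_lt(abs(lhs), 1e-6 * sum(forcing[[r]]$precipitation))
      # carbon: d(SOC_o + SOC_m + D) = I_litter - mineralization - export
      dC <- sum(shares * rowSums((st_end - st_start)[, c("SOC_o", "SOC_m",
                                                         "D")]))
      ilit <- 730 * sum(shares * cfg$carbon[lc, "I_litter"])
      rhs <- ilit - sum(sim$reaches[[r]]$mineralization) -
        sum(sim$reaches[[r]]$export_c)
      expect_lt(abs(dC - rhs), 1e-6 * ilit)
      expect_true(all(sim$trajectory >= 0))
      expect_true(all(st_end >= 0))
    }
  }
})

test_that("constant forcing drives every pool to a fixed point", {
  cfg <- default_catchment_config()
  # faster mineral-layer turnover on the fixture so the slowest pool
  # converges within a short run
  cfg$carbon$k_min_m <- rep(0.005, 5)
  n <- 20 * 365
  mk <- function(id) forcing_series(rep(10, n), rep(3, n),
                                    start = c(2000, 1, 1),
                                    subcatchment_id = id)
  sim <- run_simulation(cfg, list(C1 = mk("C1"), C2 = mk("C2")),
                        save_trajectory = TRUE)
  tr <- sim$trajectory
  last <- tr[nrow(tr), ]
  prev <- tr[nrow(tr) - 1L, ]
  active <- last > 1e-8
  expect_lt(max(abs(last - prev)[active] / last[active]), 1e-6)
})

test_that("soil carbon carries longer memory than effective rainfall", {
  ref <- fix_reference12()
  tr <- ref$trajectory
  soc <- tr[, "C2.coniferous_forest|SOC_o"]
  her <- ref$reaches$C2$her
  ac <- function(x) cor(x[-1], x[-length(x)])
  expect_gt(ac(soc), ac(her))
  expect_gt(ac(soc), 0.99)
})

test_that("spin-up converges and is deterministic", {
  cfg <- default_catchment_config()
  tw <- fix_truth12()
  yr <- lapply(tw, function(fs) forcing_series(
    fs$temperature[1:365], fs$precipitation[1:365], start = fs$start,
    subcatchment_id = fs$subcatchment_id))
  s1 <- spin_up(cfg, yr, 1)
  s5 <- spin_up(cfg, yr, 5)
  expect_lte(s5$drift, s1$drift)
  s5b <- spin_up(cfg, yr, 5)
  expect_identical(s5$state, s5b$state)
  s15 <- spin_up(cfg, yr, 15)
  expect_lt(s15$drift, 0.05)
})
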