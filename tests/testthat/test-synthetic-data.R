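test_that("truth weather is deterministic under seed and respects degenerate configs", {
  cc <- climate_config()
  a <- generate_truth_weather(cc, 3, seed = 11)
  b <- generate_truth_weather(cc, 3, seed = 11)
  expect_identical(a, b)
  d <- generate_truth_weather(cc, 3, seed = 12)
  expect_false(identical(a$C2$precipitation, d$C2$precipitation))

  # wet-day probability zero -> all-dry series
  dry <- climate_config(p_wet = rep(0, 12))
  g <- generate_truth_weather(dry, 2, seed = 5)
  expect_true(all(g$C1$precipitation == 0))
  expect_true(all(g$C2$precipitation == 0))

  # no persistence, no noise -> pure annual temperature cycle
  calm <- climate_config(ar1_rho = 0, ar1_sd = 0)
  g2 <- generate_truth_weather(calm, 2, seed = 5)
  doy <- rep(1:365, 2)
  cyc <- calm$t_mean + calm$t_amp * cos(2 * pi * (doy - calm$t_peak_doy) / 365)
  expect_equal(g2$C2$temperature, cyc)
  expect_equal(g2$C1$temperature, cyc + calm$c1_temp_offset)

  expect_error(generate_truth_weather(cc, 0, seed = 1), "n_years")
})

test_that("truth weather is seasonal and C1 is colder with snow-capable winters", {
  tw <- fix_truth12()
  d <- forcing_dates(tw$C2)
  expect_true(mean(tw$C1$temperature) < mean(tw$C2$temperature))
  jul <- d$month == 7; jan <- d$month == 1
  expect_gt(mean(tw$C2$temperature[jul]), mean(tw$C2$temperature[jan]) + 10)
  # C1 sees sub-freezing days in winter (snow accumulation possible)
  expect_gt(sum(tw$C1$temperature[jan] < 0), 0)
  expect_true(all(tw$C1$precipitation >= 0))
})

test_that("perfect-skill ensembles reproduce truth; member counts honoured", {
  tw <- fix_truth12()
  perfect <- skill_structure(rep(1, 7))
  efT <- generate_ensemble(tw$C2, "temperature", 2000, 3, 4, perfect, seed = 1)
  expect_equal(dim(efT$members), c(4, 215))
  for (k in 1:4)
    expect_equal(efT$members[k, ], tw$C2$temperature[
      which(forcing_dates(tw$C2)$year == 2000 &
              forcing_dates(tw$C2)$month == 3 &
              forcing_dates(tw$C2)$day == 1) + 0:214])
  efP <- generate_ensemble(tw$C2, "precipitation", 2000, 3, 3, perfect, seed = 1)
  truthP <- tw$C2$precipitation[
    which(forcing_dates(tw$C2)$year == 2000 &
            forcing_dates(tw$C2)$month == 3 &
            forcing_dates(tw$C2)$day == 1) + 0:214]
  # transformed-Gaussian round trip: equality within numerical tolerance,
  # sub-threshold drizzle maps to exact zero
  expect_lt(max(abs(efP$members[1, ] - ifelse(truthP < 0.1, 0, truthP))), 1e-6)
  expect_true(all(efP$members >= 0))

  ef51 <- generate_ensemble(tw$C2, "temperature", 2000, 1, 51, perfect, seed = 2)
  expect_equal(nrow(ef51$members), 51)
})

test_that("zero-skill member anomalies decorrelate from truth anomalies", {
  tw <- fix_truth12()
  none <- skill_structure(rep(0, 7), noise_sd = 2)
  d <- forcing_dates(tw$C2)
  clim <- truth_climatology(tw$C2)
  i0 <- which(d$year == 2001 & d$month == 1 & d$day == 1)
  win <- i0 + 0:214
  anom_truth <- tw$C2$temperature[win] - clim$t_mean[d$month[win]]
  cors <- vapply(1:60, function(s) {
    ef <- generate_ensemble(tw$C2, "temperature", 2001, 1, 1, none, seed = s)
    cor(ef$members[1, ] - clim$t_mean[d$month[win]], anom_truth)
  }, 0)
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("member-truth anomaly correlation is non-increasing in lead for decreasing lambda", {
  tw <- fix_truth12()
  lam <- c(0.95, 0.8, 0.6, 0.4, 0.25, 0.1, 0)
  sk <- skill_structure(lam, noise_sd = 2)
  d <- forcing_dates(tw$C2)
  clim <- truth_climatology(tw$C2)
  i0 <- which(d$year == 2001 & d$month == 1 & d$day == 1)
  win <- i0 + 0:214
  lead <- (d$year[win] - 2001) * 12 + d$month[win] - 1 + 1
  anom_truth <- tw$C2$temperature[win] - clim$t_mean[d$month[win]]
  cors <- matrix(NA_real_, 100, 7)
  for (s in 1:100) {
    ef <- generate_ensemble(tw$C2, "temperature", 2001, 1, 1, sk, seed = s)
    anom_mem <- ef$members[1, ] - clim$t_mean[d$month[win]]
    for (l in 1:7) cors[s, l] <- cor(anom_mem[lead == l], anom_truth[lead == l])
  }
  mc <- colMeans(cors)
  expect_true(all(diff(mc) <= 0.05))   # non-increasing up to Monte-Carlo noise
  expect_gt(mc[1], mc[7] + 0.5)        # and strongly decreasing overall
})

test_that("archives have the right cardinality and error on empty dimensions", {
  tw <- fix_truth12()
  sk <- skill_structure(rep(0.5, 7))
  arc <- build_hindcast_archive(tw$C2, years = 2000:2001,
                                init_months = c(1, 6), n_members = 2,
                                skill = sk, seed = 3)
  expect_equal(unname(archive_cardinality(arc)),
               c(8L, 8L))  # 2 years x 2 months x 2 members per variable
  expect_equal(length(arc$forecasts), 8)  # 2x2 ensembles x 2 variables
  arc2 <- build_hindcast_archive(tw$C2, 2000:2001, c(1, 6), 2, sk, seed = 3)
  expect_identical(arc, arc2)
  expect_error(build_hindcast_archive(tw$C2, integer(0), 1, 2, sk, 3),
               "years")
  expect_error(build_hindcast_archive(tw$C2, 2000, integer(0), 2, sk, 3),
               "init_months")
  # requested window beyond truth coverage
  expect_error(build_hindcast_archive(tw$C2, 2006:2007, 12, 1, sk, 3),
               "window")
})

test_that("DOC grab sampling: cadence, noise and determinism", {
  sim <- 2 + sin(seq_len(365) / 20)
  dates <- make_dates(c(2001, 1, 1), 365)
  exact <- sample_doc_observations(sim, dates, cadence = 30, noise_cv = 0,
                                   seed = 9)
  expect_equal(length(exact$values), 13)  # ceiling(365/30), documented
  expect_equal(exact$values, sim[seq(1, 365, by = 30)])
  noisy1 <- sample_doc_observations(sim, dates, cadence = 30, noise_cv = 0.2,
                                    seed = 9)
  noisy2 <- sample_doc_observations(sim, dates, cadence = 30, noise_cv = 0.2,
                                    seed = 9)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1$values > 0))
  expect_false(identical(noisy1$values, exact$values))
  expect_error(sample_doc_observations(numeric(0)), "empty")
})
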