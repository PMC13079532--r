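test_that("tercile bounds: order, convergence, degeneracy", {
  b <- tercile_bounds(1:3)
  expect_true(b$t1 > 1 && b$t2 < 3 && b$t1 < b$t2)
  set.seed(30)
  u <- runif(20000)
  bu <- tercile_bounds(u)
  expect_equal(bu$t1, 1 / 3, tolerance = 0.02)
  expect_equal(bu$t2, 2 / 3, tolerance = 0.02)
  bc <- tercile_bounds(rep(5, 10))
  expect_true(bc$degenerate)
  expect_error(tercile_bounds(c(1, 2)), ">= 3")
})

test_that("tercile probabilities count members with the normal tie rule", {
  b <- list(t1 = 2, t2 = 5)
  p <- tercile_probabilities(c(1, 3, 4, 6, 6, 7, 8, 9, 10), b)
  expect_equal(c(p$pBN, p$pN, p$pAN), c(1 / 9, 2 / 9, 6 / 9))
  expect_equal(p$label, "above-normal")
  expect_equal(p$pBN + p$pN + p$pAN, 1)

  all_below <- tercile_probabilities(c(0, 1, 1.5), b)
  expect_equal(c(all_below$pBN, all_below$pN, all_below$pAN), c(1, 0, 0))

  # members exactly on a bound count as normal
  on_bound <- tercile_probabilities(c(2, 5), b)
  expect_equal(on_bound$pN, 1)
  expect_error(tercile_probabilities(numeric(0), b), "empty")

  # probabilities are multiples of 1/members
  set.seed(31)
  for (i in 1:20) {
    m <- sample(1:12, 1)
    p <- tercile_probabilities(rnorm(m, 3, 2), list(t1 = 2, t2 = 4))
    expect_true(all(abs(c(p$pBN, p$pN, p$pAN) * m -
                          round(c(p$pBN, p$pN, p$pAN) * m)) < 1e-12))
  }
})

test_that("an ensemble drawn from the climatology is calibrated to ~1/3 each", {
  set.seed(32)
  ref <- rnorm(24, 10, 3)
  b <- tercile_bounds(ref)
  hits <- replicate(400, {
    p <- tercile_probabilities(sample(ref, 15, replace = TRUE), b)
    c(p$pBN, p$pN, p$pAN)
  })
  expect_equal(rowMeans(hits), rep(1 / 3, 3), tolerance = 0.06)
})

test_that("action levels map pAN with the printed boundaries and are monotone", {
  expect_equal(as.character(action_level(0.50)), "watch")
  expect_equal(as.character(action_level(0.60)), "prepare")
  expect_equal(as.character(action_level(0.66)), "prepare")
  expect_equal(as.character(action_level(0.70)), "act")
  expect_equal(as.character(action_level(0.75)), "act")
  expect_equal(as.character(action_level(0.80)), "escalate")
  expect_equal(as.character(action_level(1)), "escalate")
  lv <- action_level(seq(0, 1, by = 0.01))
  expect_true(all(diff(as.integer(lv)) >= 0))
  expect_error(action_level(1.2), "0, 1")
})

test_that("most probable tercile resolves ties toward normal, then lower", {
  expect_equal(most_probable_tercile(c(0.1, 0.2, 0.7)), "above-normal")
  expect_equal(most_probable_tercile(c(1, 1, 1) / 3), "normal")
  expect_equal(most_probable_tercile(c(0.5, 0.5, 0)), "normal")
  expect_equal(most_probable_tercile(c(0.5, 0, 0.5)), "below-normal")
  expect_equal(most_probable_tercile(c(0.6, 0.3, 0.1)), "below-normal")
})

test_that("monthly report: structure, action level, determinism, missing skill", {
  set.seed(33)
  mk_fc <- function(vals_by_lead, b) lapply(vals_by_lead, function(v)
    tercile_probabilities(v, b))
  b <- list(t1 = 2, t2 = 4)
  doc_leads <- list(c(1, 5, 5, 5, 5, 6), rnorm(6, 3), rnorm(6, 3),
                    rnorm(6, 3))
  fc <- list(temperature = mk_fc(rep(list(rnorm(6, 3)), 4), b),
             precipitation = mk_fc(rep(list(rnorm(6, 3)), 4), b),
             streamflow = mk_fc(rep(list(rnorm(6, 3)), 4), b),
             doc = mk_fc(doc_leads, b))
  skill <- data.frame(init_month = 12, lead = 1:3,
                      crpss = c(0.7, 0.4, 0.1), n = 10,
                      class = c("high", "acceptable", "none"))
  rep1 <- assemble_report(2019, 12, fc, skill, n_leads = 4)
  expect_equal(length(rep1$leads), 4)
  for (ld in rep1$leads) {
    expect_equal(ld$doc$pBN + ld$doc$pN + ld$doc$pAN, 1)
    expect_true(!is.null(ld$temperature))
  }
  # lead 1: 5/6 members above normal -> pAN ~ 0.83 -> escalate
  expect_equal(rep1$leads[[1]]$doc$pAN, 5 / 6)
  expect_equal(rep1$leads[[1]]$doc$action_level, "escalate")
  expect_equal(rep1$leads[[1]]$doc$skill, "high")
  # lead 4 has no skill cell -> explicit marker, never a fabricated class
  expect_equal(rep1$leads[[4]]$doc$skill, "no skill information")
  # pAN = 0.66 -> prepare
  doc2 <- doc_leads
  doc2[[1]] <- c(rep(5, 66), rep(3, 34))  # 66 of 100 above
  fc2 <- fc; fc2$doc <- mk_fc(doc2, b)
  rep2 <- assemble_report(2019, 12, fc2, skill, n_leads = 4)
  expect_equal(rep2$leads[[1]]$doc$pAN, 0.66)
  expect_equal(rep2$leads[[1]]$doc$action_level, "prepare")
  # leads cross into the following year
  expect_equal(rep1$leads[[2]]$month, 1)
  expect_equal(rep1$leads[[2]]$year, 2020)

  md1 <- render_report_markdown(rep1)
  md2 <- render_report_markdown(rep1)
  expect_identical(md1, md2)
  expect_true(any(grepl("escalate", md1)))

  tf <- tempfile(fileext = ".json")
  write_report_json(rep1, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$init_month, 12)
  expect_equal(length(back$leads), 4)
  unlink(tf)

  expect_error(assemble_report(2019, 12, fc[-4], skill), "missing")
})

test_that("tercile climatology covers 12 months with the reference window", {
  obs <- expand.grid(month = 1:12, year = 1993:2016)
  set.seed(34)
  obs$value <- rnorm(nrow(obs), 10, 3)
  tc <- tercile_climatology(obs, ref_years = 2000:2016, variable = "doc")
  expect_equal(nrow(tc), 12)
  expect_true(all(tc$t1 < tc$t2))
  expect_equal(attr(tc, "ref_years"), 2000:2016)
  # only the window's years inform the bounds
  obs2 <- obs
  obs2$value[obs2$year < 2000] <- 1e6
  tc2 <- tercile_climatology(obs2, ref_years = 2000:2016)
  expect_equal(tc2$t1, tc$t1)
})
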