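test_that("temperature gradient is the normalized surface-to-air difference", {
  expect_equal(temperature_gradient(283.15, 288.15, 10), -0.5)
  expect_equal(temperature_gradient(280, 280, 5), 0)
  # inversion: air warmer than the surface gives a positive gradient
  expect_equal(temperature_gradient(275.15, 273.15, 2), 1.0)
  expect_error(temperature_gradient(280, 280, 0), "h_e")
})

test_that("work flux carries the sign of heat transport along the gradient", {
  # heat out along a negative gradient: positive work
  expect_equal(work_flux(60, 40, -5), 100)
  # heat out against an inversion: negative work
  expect_equal(work_flux(60, 40, +5), -100)
  # heat in along an inversion gradient: positive work
  expect_equal(work_flux(-20, -10, +5), 30)
  # zero gradient gives zero work regardless of fluxes
  expect_equal(work_flux(500, 500, 0), 0)
})

test_that("the four-case classifier reproduces the narrative sign table", {
  expect_identical(classify_work_case(100, -5), 1L)
  expect_identical(classify_work_case(-30, +5), 3L)
  expect_identical(classify_work_case(100, +5), 4L)
  expect_identical(classify_work_case(-30, -5), 2L)
  # exhaustive sign-combination sweep: work > 0 exactly when heat moves
  # from high to low temperature; cases 1 and 3 positive, 2 and 4 negative
  combos <- expand.grid(net = c(-80, 0, 80), dT = c(-3, 0, 3))
  for (r in seq_len(nrow(combos))) {
    net <- combos$net[r]; dT <- combos$dT[r]
    w <- work_flux(net / 2, net / 2, dT)
    cs <- classify_work_case(net, dT)
    if (net == 0 || dT == 0) {
      expect_true(is.na(cs))
      expect_equal(w, 0)
    } else {
      expect_false(is.na(cs))
      along_gradient <- sign(net) == -sign(dT) # heat moves high -> low T
      expect_identical(w > 0, along_gradient)
      expect_identical(cs %in% c(1L, 3L), w > 0)
      expect_identical(cs %in% c(2L, 4L), w < 0)
    }
  }
})

test_that("work is antisymmetric in the gradient sign", {
  set.seed(4)
  LE <- stats::rnorm(200, sd = 60)
  H <- stats::rnorm(200, sd = 60)
  dT <- stats::rnorm(200, sd = 4)
  dT[dT == 0] <- 1
  expect_equal(work_flux(LE, H, dT), -work_flux(LE, H, -dT))
})

test_that("daily mean work averages complete days and drops partial ones", {
  ts <- as.POSIXct("2001-03-01", tz = "UTC") + 1800 * (0:(48 * 10 - 1))
  th <- data.frame(timestamp = ts, work = rep(10, 480))
  expect_equal(daily_mean_work(th)$work, rep(10, 10))
  th$work <- rep(c(rep(50, 24), rep(-50, 24)), 10)
  expect_equal(daily_mean_work(th)$work, rep(0, 10))
  expect_warning(out <- daily_mean_work(th[1:100, ]), "partial")
  expect_identical(nrow(out), 2L)
})

test_that("daily means match an independent per-day recomputation", {
  set.seed(9)
  n <- 10000
  ts <- as.POSIXct("2001-01-01", tz = "UTC") + 1800 * (0:(n - 1))
  keep <- seq_len(48 * floor(n / 48))
  th <- data.frame(timestamp = ts[keep], work = stats::rnorm(length(keep)))
  got <- daily_mean_work(th)
  want <- oracle_daily_means(as.Date(th$timestamp, tz = "UTC"), th$work)
  expect_equal(got$work, as.numeric(want), tolerance = 1e-12)
})

test_that("inversion episodes equal brute-force run detection", {
  # no inversions: empty table
  ts <- as.POSIXct("2001-01-01", tz = "UTC") + 1800 * (0:99)
  th <- data.frame(timestamp = ts, gradient = -abs(stats::rnorm(100)) - 0.1,
                   work = stats::rnorm(100), swe = 0)
  expect_identical(nrow(inversion_episodes(th)), 0L)
  # a single 10-step block lasts 5 hours
  th$gradient <- c(rep(-1, 40), rep(1, 10), rep(-1, 50))
  ep <- inversion_episodes(th)
  expect_identical(nrow(ep), 1L)
  expect_equal(ep$duration_hours, 5)
  expect_identical(ep$start, ts[41])
  expect_identical(ep$end, ts[50])
  # random signs against the explicit loop, with snow annotation
  set.seed(12)
  n <- 10000
  th <- data.frame(
    timestamp = as.POSIXct("2001-01-01", tz = "UTC") + 1800 * (0:(n - 1)),
    gradient = stats::rnorm(n), work = stats::rnorm(n),
    swe = ifelse(stats::runif(n) < 0.3, stats::runif(n, 0, 50), 0))
  got <- inversion_episodes(th)
  want <- oracle_episodes(th$gradient > 0)
  expect_identical(nrow(got), length(want))
  for (k in seq_along(want)) {
    i <- unname(want[[k]]["start"]); j <- unname(want[[k]]["end"])
    expect_identical(got$start[k], th$timestamp[i])
    expect_identical(got$end[k], th$timestamp[j])
    expect_equal(got$duration_hours[k], (j - i + 1) * 0.5)
    expect_equal(got$mean_work[k], mean(th$work[i:j]))
    expect_identical(got$snow_present[k], any(th$swe[i:j] > 0))
  }
})

test_that("negative-work persistence finds the longest run and flags it", {
  dw <- data.frame(work = c(rep(1, 5), rep(-1, 20), rep(1, 5)))
  got <- negative_work_persistence(dw, 14)
  expect_identical(got$longest_run, 20L)
  expect_true(got$flagged)
  expect_identical(negative_work_persistence(
    data.frame(work = rep(1, 30)), 14)$longest_run, 0L)
  alt <- data.frame(work = rep(c(1, -1), 20))
  got <- negative_work_persistence(alt, 2)
  expect_identical(got$longest_run, 1L)
  expect_false(got$flagged)
  expect_error(negative_work_persistence(dw, 0), "threshold_days")
})

test_that("the work-gradient-LAI summary matches brute-force binning", {
  # single record occupies a single bin holding its work value
  one <- data.frame(gradient = -0.4, work = 33, lai = 2.2)
  s1 <- work_gradient_summary(one)
  expect_identical(nrow(s1), 1L)
  expect_equal(s1$mean_work, 33)
  expect_identical(s1$n, 1L)
  # all records at zero gradient: one occupied bin with zero work
  z <- data.frame(gradient = rep(0, 50), lai = 1)
  z$work <- work_flux(rep(30, 50), rep(20, 50), z$gradient)
  sz <- work_gradient_summary(z)
  expect_identical(nrow(sz), 1L)
  expect_equal(sz$mean_work, 0)
  # two-cluster synthetic series against the explicit double loop
  set.seed(21)
  n <- 10000
  th <- data.frame(gradient = c(stats::rnorm(n / 2, -0.8, 0.2),
                                stats::rnorm(n / 2, 0.6, 0.2)),
                   work = stats::rnorm(n, 20, 40),
                   lai = stats::runif(n, 0.01, 4.99))
  gb <- seq(-2.5, 2.5, by = 0.5)
  lb <- seq(0, 5, by = 1)
  got <- work_gradient_summary(th, gradient_breaks = gb, lai_breaks = lb)
  want <- oracle_bin_means(-th$gradient, th$lai, th$work, gb, lb)
  expect_identical(nrow(got), nrow(want))
  got <- got[order(got$lai_bin, got$minus_gradient_bin), ]
  want <- want[order(want$yj, want$xi), ]
  expect_equal(got$n, want$n)
  expect_equal(got$mean_work, want$mean, tolerance = 1e-12)
  expect_error(work_gradient_summary(th, lai = 1:5), "align")
})

test_that("thermo records recompute bit-for-bit from their source run", {
  run <- tt_alp_run()
  th <- thermo_record(run)
  h_e <- attr(run, "scenario")$h_e
  expect_identical(th$delta_T, run$T_air - run$T_surf)
  expect_identical(th$gradient, (run$T_air - run$T_surf) / h_e)
  expect_identical(th$work,
                   (run$LE + run$H) * -sign(run$T_air - run$T_surf))
  expect_identical(th$case,
                   classify_work_case(run$LE + run$H,
                                      run$T_air - run$T_surf))
})

test_that("feasibility verdicts cover feasible, infeasible and disadvantaged", {
  good_days <- data.frame(work = rep(5, 100))
  bad_days <- data.frame(work = c(rep(5, 30), rep(-2, 30), rep(5, 40)))
  # all-positive work and CO2 above the pair: feasible
  f <- assess_feasibility(good_days, c(10, 12), c(5, 6), 14, "ok")
  expect_identical(f$overall, "feasible")
  expect_false(f$verdict_negative_work || f$verdict_co2)
  # a 30-day negative run crosses the threshold: infeasible
  f <- assess_feasibility(bad_days, c(10, 12), c(5, 6), 14, "runs")
  expect_identical(f$overall, "infeasible")
  expect_true(f$verdict_negative_work)
  # net CO2 loss alone is infeasible
  f <- assess_feasibility(good_days, c(-3, -1), NULL, 14, "co2")
  expect_identical(f$overall, "infeasible")
  expect_true(f$verdict_co2)
  # positive CO2 below the paired existing scenario: disadvantaged
  f <- assess_feasibility(good_days, c(3, 4), c(10, 11), 14, "pair")
  expect_identical(f$overall, "disadvantaged")
  # without a pair the comparison field is flagged absent
  f <- assess_feasibility(good_days, c(3, 4), NULL, 14, "nopair")
  expect_true(is.na(f$co2_below_pair))
  expect_identical(f$overall, "feasible")
  expect_output(print(f), "Feasibility report")
})
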