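test_that("unit flux over one day integrates to the hand-converted totals", {
  fit <- resp_model_coefs("RT", alpha = 1, beta = 0)  # predicts 1 umol m-2 s-1
  ser <- constant_series()
  day1 <- c(as.POSIXct("2012-06-16", tz = "UTC"), as.POSIXct("2012-06-17", tz = "UTC"))
  e <- integrate_emission(fit, ser, window = day1)
  expect_equal(e$total_mol, 86400 * 1e-6)          # 0.0864 mol m-2
  expect_equal(e$total_gC, 86400 * 1e-6 * 12.011)  # 1.03775 g C m-2
  expect_equal(e$total_gCO2, 86400 * 1e-6 * 44.01)
})

test_that("constant model obeys the closed form a * D * 1e-6 and alpha-linearity", {
  ser <- constant_series()
  D <- 14 * 86400
  win <- c(as.POSIXct("2012-07-01", tz = "UTC"),
           as.POSIXct("2012-07-01", tz = "UTC") + D)
  for (a in c(0.5, 3)) {
    e <- integrate_emission(resp_model_coefs("RT", a, 0), ser, window = win)
    expect_equal(e$total_mol, a * D * 1e-6)
  }

  zero <- integrate_emission(resp_model_coefs("RT", 1, 0), ser,
                             window = rep(win[1L], 2))
  expect_equal(zero$total_mol, 0)
})

test_that("integration is additive over adjacent windows", {
  fit <- resp_model_coefs("RT", alpha = 0.3, beta = 0.08)
  ser <- constant_series()
  ser$T <- 20 + 4 * sin(seq_along(ser$T) / 37)  # smooth varying driver
  t0 <- as.POSIXct("2012-06-20", tz = "UTC")
  whole <- integrate_emission(fit, ser, window = c(t0, t0 + 10 * 86400))
  part1 <- integrate_emission(fit, ser, window = c(t0, t0 + 4 * 86400))
  part2 <- integrate_emission(fit, ser, window = c(t0 + 4 * 86400, t0 + 10 * 86400))
  expect_equal(whole$total_mol, part1$total_mol + part2$total_mol, tolerance = 1e-9)
})

test_that("halving the time step barely changes a smooth integral", {
  fit <- resp_model_coefs("RT", alpha = 0.5, beta = 0.07)
  win <- growing_season()
  mk <- function(by_s) {
    ser <- constant_series(by_s = by_s)
    h <- as.numeric(ser$timestamp - ser$timestamp[1L], units = "hours")
    ser$T <- 20 + 3 * sin(2 * pi * h / 24) + 2 * sin(pi * h / max(h))
    ser
  }
  e30 <- integrate_emission(fit, mk(1800), window = win)$total_mol
  e15 <- integrate_emission(fit, mk(900), window = win)$total_mol
  expect_lt(abs(e30 - e15) / e15, 0.001)
})

test_that("coverage failures are reported", {
  fit <- resp_model_coefs("RT", 1, 0)
  ser <- constant_series()
  expect_error(
    integrate_emission(fit, ser, window = growing_season("2012-06-01", "2012-09-19")),
    "outside")
  gap <- ser[ser$timestamp < as.POSIXct("2012-07-01", tz = "UTC") |
               ser$timestamp > as.POSIXct("2012-07-03", tz = "UTC"), ]
  expect_error(integrate_emission(fit, gap, window = growing_season()),
               "gap exceeding 24 h")
})

test_that("constant respiration keeps the whole day representative", {
  ser <- data.frame(timestamp = as.POSIXct("2011-07-01", tz = "UTC") +
                      seq(0, 2 * 86400 - 1800, by = 1800),
                    R = 4.5)
  w <- representative_window(ser)
  expect_equal(w$intervals$width_h, 24)
  expect_equal(w$daily_mean, 4.5)
})

test_that("a sinusoidal cycle yields two bands at the mean crossings", {
  # R(t) = 4.5 + 2.5 sin(2 pi t / 24 h); |R - 4.5| <= 0.45 iff
  # |sin| <= 0.18, giving two intervals of width 2*asin(0.18)*24/(2 pi)
  # = 1.3826 h centred at t = 0 (wrapping midnight) and t = 12
  ser <- data.frame(timestamp = as.POSIXct("2011-07-01", tz = "UTC") +
                      seq(0, 2 * 86400 - 60, by = 60))
  h <- (as.numeric(ser$timestamp) %% 86400) / 3600
  ser$R <- 4.5 + 2.5 * sin(2 * pi * h / 24)
  w <- representative_window(ser, tolerance = 0.10)
  expect_equal(nrow(w$intervals), 2L)
  width_expected <- 2 * asin(0.18) * 24 / (2 * pi)
  expect_equal(w$intervals$width_h, rep(width_expected, 2), tolerance = 0.05)
  # one interval wraps midnight, the other brackets the noon crossing
  expect_true(any(w$intervals$end_h < w$intervals$start_h))
  mid <- w$intervals[w$intervals$end_h > w$intervals$start_h, ]
  expect_lt(abs((mid$start_h + mid$end_h) / 2 - 12), 0.1)
})

test_that("amplitudes inside the band keep the full day representative", {
  ser <- data.frame(timestamp = as.POSIXct("2011-07-01", tz = "UTC") +
                      seq(0, 86400 - 1800, by = 1800))
  h <- (as.numeric(ser$timestamp) %% 86400) / 3600
  ser$R <- 4.5 + 0.4 * sin(2 * pi * h / 24)  # 0.4 < 10% of 4.5
  w <- representative_window(ser, tolerance = 0.10)
  expect_equal(w$intervals$width_h, 24)
})

test_that("less than one full day of data is a coverage error", {
  ser <- data.frame(timestamp = as.POSIXct("2011-07-01", tz = "UTC") +
                      seq(0, 12 * 3600, by = 1800), R = 4.5)
  expect_error(representative_window(ser), "less than one full day")
})
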