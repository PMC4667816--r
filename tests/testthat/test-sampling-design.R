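# Hand enumeration of the forward-difference rule, independent of the
# package implementation.
brute_n_star <- function(cv, threshold = -1) {
  s <- diff(cv)
  for (n in seq_along(s)) if (s[n] > threshold) return(n)
  NA_integer_
}

test_that("threshold rule matches hand enumeration on analytic curves", {
  for (C in c(5, 10, 20, 40)) {
    curve <- list(k = 1:50, cv_percent = C / sqrt(1:50))
    os <- optimal_sample_size(curve)
    expect_equal(os$n_star, brute_n_star(curve$cv_percent))
  }
  # C = 20: s_4 = -1.056 <= -1 < s_5 = -0.779, so n* = 5
  os20 <- optimal_sample_size(list(k = 1:50, cv_percent = 20 / sqrt(1:50)))
  expect_equal(os20$n_star, 5L)
  expect_equal(os20$cv_at_n_star, 20 / sqrt(5))
  expect_equal(os20$slopes$dcv_dn[4], 20 / sqrt(5) - 20 / sqrt(4))
})

test_that("flat and steep curves hit the rule's edge cases", {
  flat <- optimal_sample_size(list(k = 1:10, cv_percent = rep(7, 10)))
  expect_true(flat$obtained)
  expect_equal(flat$n_star, 1L)

  steep <- optimal_sample_size(list(k = 1:10, cv_percent = 200 / (1:10)))
  expect_false(steep$obtained)
  expect_true(is.na(steep$n_star))
  expect_true(is.na(steep$cv_at_n_star))
})

test_that("slopes at exactly the threshold do not count as exceeding", {
  curve <- list(k = 1:3, cv_percent = c(5, 4, 3.5))  # slopes -1, -0.5
  expect_equal(optimal_sample_size(curve, threshold = -1)$n_star, 2L)
})

test_that("n* is monotone non-decreasing as the threshold rises toward 0", {
  set.seed(410)
  for (rep in 1:10) {
    cv <- sort(runif(20, 1, 30), decreasing = TRUE)
    curve <- list(k = 1:20, cv_percent = cv)
    ns <- vapply(c(-5, -2, -1, -0.5, -0.1), function(th) {
      os <- optimal_sample_size(curve, threshold = th)
      if (os$obtained) os$n_star else Inf
    }, numeric(1))
    expect_true(all(diff(ns) >= 0))
  }
})

test_that("described detection behaviour: slopes cross the threshold at n = 3", {
  # slopes below -1 strictly before n = 3 and above -1 from n = 3 on
  cv <- c(10, 8, 6.5, 5.9, 5.4, 5.1)
  os <- optimal_sample_size(list(k = 1:6, cv_percent = cv))
  expect_equal(os$n_star, 3L)
  expect_true(all(os$slopes$dcv_dn[1:2] <= -1))
  expect_true(all(os$slopes$dcv_dn[3:5] > -1))
})

test_that("short curves are rejected", {
  expect_error(optimal_sample_size(list(k = 1, cv_percent = 5)), "at least 2")
  expect_error(optimal_sample_size(list(k = c(1, 3), cv_percent = c(5, 4))),
               "consecutive")
})

test_that("design table reports the plot and strip rows with recomputed densities", {
  sim <- generate_campaign(synthetic_config(), seed = 21)
  parts <- list("5.0 x 5.0 km2 plot" = 1:4,
                "Subplot 1 + 2" = c(1L, 2L),
                "Subplot 2 + 3" = c(2L, 3L),
                "Subplot 1 + 4" = c(1L, 4L),
                "Subplot 3 + 4" = c(3L, 4L))
  dt <- design_table(sim$campaign, sim$continuous, models = "RT",
                     M = 200, seed = 5, partitions = parts)
  expect_equal(dt$n_points, c(51L, 30L, 27L, 24L, 21L))
  expect_equal(dt$density_km2, c(2.04, 2.4, 2.16, 1.92, 1.68))
  expect_true(all(c("n_T", "cv_T", "n_W", "cv_W", "n_RT", "cv_RT") %in% names(dt)))
  curves <- attr(dt, "curves")
  expect_length(curves, 15L)
  expect_equal(curves[[1]]$N, 51L)
})

test_that("a homogeneous campaign needs only one collar everywhere", {
  cfg <- synthetic_config(cv_T_spatial = 0, cv_W_spatial = 0,
                          model_truth = list(model = "RTW", alpha = NULL,
                                             beta = 1.649, gamma = 0.622,
                                             cv_alpha_spatial = 0),
                          noise_sigma = 0, T_noise_sd = 0, w_noise_sigma = 0)
  sim <- generate_campaign(cfg, seed = 31)
  dt <- design_table(sim$campaign, sim$continuous, models = "RTW",
                     M = 100, seed = 6,
                     partitions = list(full = 1:4))
  expect_equal(dt$n_RTW, 1L)
  expect_equal(dt$cv_T, 0)
  expect_equal(dt$cv_W, 0)
  expect_equal(dt$cv_RTW, 0)
})

test_that("partitions with fewer than two collars are rejected", {
  pts <- data.frame(collar_id = c("a", "b", "c"),
                    x_km = c(1, 1.5, 4), y_km = c(1, 1.2, 1),
                    subplot = c(1L, 1L, 2L))
  obs <- expand.grid(collar_id = pts$collar_id,
                     date = as.Date("2012-06-16") + seq(0, 18, 6),
                     stringsAsFactors = FALSE)
  obs$T <- 20 + runif(nrow(obs))
  obs$W <- 25 + runif(nrow(obs))
  obs$R <- 2 * exp(0.1 * obs$T) + runif(nrow(obs), 0, 0.1)
  camp <- campaign(pts, obs)
  ser <- list(a = constant_series(), b = constant_series(), c = constant_series())
  expect_error(design_table(camp, ser, models = "RT", M = 50, seed = 1,
                            partitions = list(east = 2L)),
               "need >= 2")
})
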