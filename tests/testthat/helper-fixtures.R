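# Small in-code fixtures shared across test files.

# A 4-collar, 3-date campaign with one collar per quadrant subplot.
tiny_campaign <- function() {
  points <- data.frame(collar_id = c("a", "b", "c", "d"),
                       x_km = c(1, 4, 4, 1), y_km = c(1, 1, 4, 4),
                       subplot = c(1L, 2L, 3L, 4L))
  obs <- expand.grid(collar_id = points$collar_id,
                     date = as.Date("2012-06-16") + c(0, 6, 12),
                     stringsAsFactors = FALSE)
  obs$R <- 2 + seq_len(nrow(obs)) / 10
  obs$T <- 18 + seq_len(nrow(obs)) / 5
  obs$W <- 20 + seq_len(nrow(obs)) / 2
  campaign(points, obs)
}

# Constant-driver continuous series spanning the default season.
constant_series <- function(T = 20, W = 25, by_s = 1800,
                            window = growing_season()) {
  ts <- seq(window[1L], window[2L], by = by_s)
  data.frame(timestamp = ts, T = T, W = W)
}

# Noiseless observations from a known model, for recovery tests.  The W
# sequence is deliberately decorrelated from T so the interactive model's
# two exponents stay identifiable.
noiseless_obs <- function(model, alpha, beta, gamma = NULL) {
  d <- data.frame(T = seq(10, 30, length.out = 17),
                  W = c(25, 14, 33, 19, 38, 12, 28, 22, 35, 16, 30, 20,
                        26, 36, 13, 24, 31))
  p <- c(alpha = alpha, beta = beta, if (!is.null(gamma)) c(gamma = gamma))
  d$R <- switch(model,
                RT = alpha * exp(beta * d$T),
                RW = alpha * d$W^beta,
                RTW = alpha * d$T^beta * d$W^gamma)
  d
}

# One site-pattern pipeline replicate: simulate the default campaign,
# fit the interactive model per collar, integrate seasonal emissions and
# detect optimal sample sizes for mean T, mean W and emission.
site_pattern_run <- function(seed, M = 2000) {
  sim <- generate_campaign(synthetic_config(), seed = seed)
  ids <- sim$campaign$points$collar_id
  fits <- lapply(ids, function(id) {
    resp_model(sim$campaign$obs[sim$campaign$obs$collar_id == id, ], "RTW")
  })
  names(fits) <- ids
  s <- summarize_points(sim$campaign, sim$continuous, fits)
  n_star <- function(x, salt) {
    cv <- mc_cv_curve(x, M = M, seed = seed * 100 + salt)
    os <- optimal_sample_size(cv)
    if (os$obtained) os$n_star else Inf
  }
  c(T = n_star(s$mean_T, 1), W = n_star(s$mean_W, 2),
    R = n_star(s$emission_gC, 3))
}
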