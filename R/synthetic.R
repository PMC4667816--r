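#' Configuration for the synthetic field campaign
#'
#' Describes the emulated plot-scale campaign: an irrigated oasis maize
#' plot of 5 x 5 km2 divided into four quadrant subplots holding 51 PVC
#' collars in total, chamber surveys once every 6 days during a late-
#' morning window, and continuous half-hourly logger records of soil
#' temperature and moisture over the 16 June -- 19 September growing
#' season.
#'
#' Across-collar heterogeneity is lognormal: collar-level mean temperature
#' (spatial CV ~5%), mean moisture (~10%) and the respiration scale
#' coefficient alpha (4%) vary between collars, which under the default
#' interactive truth model (beta = 1.649, gamma = 0.622) compounds to a
#' spatial CV of seasonal emission of about 11%, i.e.
#' \eqn{\sqrt{cv_\alpha^2 + (\beta\,cv_T)^2 + (\gamma\,cv_W)^2}}.
#' Within a collar, temperature follows a half-sine seasonal trend plus a
#' diurnal cycle, and moisture follows an irrigation sawtooth (sharp rise,
#' exponential decay) -- temperature is comparatively stable while
#' irrigation drives most of the temporal and spatial moisture variation,
#' as in arid oasis farmland.
#'
#' @param n_points total collar count (default 51).
#' @param subplot_counts collars per quadrant subplot (SW, SE, NE, NW);
#'   the default `c(15, 15, 12, 9)` makes the adjacent-pair strips hold
#'   30, 27, 24 and 21 collars.
#' @param plot_extent plot width/height in km.
#' @param season character length 2, first and last day of the growing
#'   season (end inclusive).
#' @param campaign_every_days chamber-survey interval in days.
#' @param campaign_hours numeric length 2, time-of-day window (hours) in
#'   which surveys are taken.
#' @param mean_T,cv_T_spatial plot-mean soil temperature (deg C) and its
#'   across-collar CV (%).
#' @param mean_W,cv_W_spatial plot-mean volumetric water content (%) and
#'   its across-collar CV (%).
#' @param model_truth list: `model` (`"RT"`, `"RW"` or `"RTW"`), `beta`,
#'   `gamma` (RTW only), `alpha` (`NULL` = chosen so the plot-mean
#'   respiration at (`mean_T`, `mean_W`) equals `diurnal$mean`), and
#'   `cv_alpha_spatial` (%).
#' @param noise_sigma sdlog of the multiplicative lognormal observation
#'   noise on chamber respiration.
#' @param seasonal_T_amplitude amplitude (deg C) of the half-sine seasonal
#'   temperature trend peaking mid-season.
#' @param diurnal_T_amplitude,T_noise_sd diurnal temperature amplitude and
#'   white-noise sd (deg C) of the continuous record.
#' @param irrigation_period_days days between irrigation pulses.
#' @param irrigation_decay end-of-cycle moisture as a fraction of the
#'   post-irrigation peak (sets the exponential decay rate).
#' @param w_noise_sigma sdlog of lognormal noise on continuous moisture.
#' @param diurnal list for the preliminary continuous respiration record:
#'   `mean` and `peak` (\eqn{\mu}mol m^-2 s^-1), `peak_hour`,
#'   `peak_jitter_h` (day-to-day sd of the peak time) and `noise_sd`.
#' @param cadence_min logger cadence in minutes.
#' @param seed default seed used by the generators when they are not given
#'   one explicitly.
#' @return A classed list (`synthetic_config`) of validated settings.
#' @seealso [generate_campaign()], [generate_diurnal()]
#' @export
synthetic_config <- function(n_points = 51L,
                             subplot_counts = c(15L, 15L, 12L, 9L),
                             plot_extent = c(5, 5),
                             season = c("2012-06-16", "2012-09-19"),
                             campaign_every_days = 6L,
                             campaign_hours = c(8.5, 12),
                             mean_T = 20, cv_T_spatial = 5,
                             mean_W = 25, cv_W_spatial = 10,
                             model_truth = list(model = "RTW", alpha = NULL,
                                                beta = 1.649, gamma = 0.622,
                                                cv_alpha_spatial = 4),
                             noise_sigma = 0.1,
                             seasonal_T_amplitude = 4,
                             diurnal_T_amplitude = 3,
                             T_noise_sd = 0.5,
                             irrigation_period_days = 12,
                             irrigation_decay = 0.43,
                             w_noise_sigma = 0.05,
                             diurnal = list(mean = 4.5, peak = 7.0,
                                            peak_hour = 15, peak_jitter_h = 1,
                                            noise_sd = 0.1),
                             cadence_min = 30,
                             seed = NULL) {
  if (length(subplot_counts) != 4L || any(subplot_counts < 0)) {
    stopf("`subplot_counts` must be 4 non-negative counts")
  }
  if (sum(subplot_counts) != n_points) {
    stopf("subplot_counts sum to %d but n_points is %d", sum(subplot_counts), n_points)
  }
  for (v in c(cv_T_spatial, cv_W_spatial, model_truth$cv_alpha_spatial %||% 0)) {
    if (v < 0) stopf("spatial CVs must be >= 0")
  }
  if (!model_truth$model %in% c("RT", "RW", "RTW")) {
    stopf("model_truth$model must be RT, RW or RTW")
  }
  if (diurnal$peak < diurnal$mean) stopf("diurnal peak must be >= mean")
  if (is.null(model_truth$alpha)) {
    base <- switch(model_truth$model,
                   RT = exp(model_truth$beta * mean_T),
                   RW = mean_W^model_truth$beta,
                   RTW = mean_T^model_truth$beta * mean_W^model_truth$gamma)
    model_truth$alpha <- diurnal$mean / base
  }
  structure(list(n_points = as.integer(n_points),
                 subplot_counts = as.integer(subplot_counts),
                 plot_extent = plot_extent, season = season,
                 campaign_every_days = campaign_every_days,
                 campaign_hours = campaign_hours,
                 mean_T = mean_T, cv_T_spatial = cv_T_spatial,
                 mean_W = mean_W, cv_W_spatial = cv_W_spatial,
                 model_truth = model_truth, noise_sigma = noise_sigma,
                 seasonal_T_amplitude = seasonal_T_amplitude,
                 diurnal_T_amplitude = diurnal_T_amplitude,
                 T_noise_sd = T_noise_sd,
                 irrigation_period_days = irrigation_period_days,
                 irrigation_decay = irrigation_decay,
                 w_noise_sigma = w_noise_sigma,
                 diurnal = diurnal, cadence_min = cadence_min, seed = seed),
            class = "synthetic_config")
}

# lognormal draws with a given arithmetic mean and CV (in percent);
# degenerates to the constant mean at cv = 0.
rlnorm_cv <- function(n, mean, cv_percent) {
  if (cv_percent == 0) return(rep(mean, n))
  cv <- cv_percent / 100
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# deterministic near-uniform grid of n points inside a square
place_grid <- function(n, x0, y0, size) {
  if (n == 0L) return(cbind(x = numeric(), y = numeric()))
  m <- ceiling(sqrt(n))
  ij <- expand.grid(i = seq_len(m), j = seq_len(m))[seq_len(n), ]
  cbind(x = x0 + (ij$i - 0.5) * size / m,
        y = y0 + (ij$j - 0.5) * size / m)
}

#' Generate a synthetic field campaign
#'
#' Draws one complete, internally consistent campaign from a
#' [synthetic_config()]: collar layout and spatial heterogeneity,
#' continuous half-hourly driver records per collar, and chamber
#' observations of respiration, temperature and moisture on every survey
#' date. The chamber respiration is the truth model evaluated at the
#' collar's instantaneous drivers times multiplicative lognormal noise, so
#' model fits on campaign data recover the generating coefficients up to
#' noise.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the output is fully determined by
#'   (config, seed).
#' @return list with `campaign` (a [campaign]) and `continuous` (named
#'   list of per-collar driver data.frames), plus `truth` (per-collar true
#'   alpha and the shared beta/gamma).
#' @export
generate_campaign <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    n <- config$n_points
    ids <- sprintf("C%02d", seq_len(n))
    hw <- config$plot_extent[1L] / 2
    hh <- config$plot_extent[2L] / 2
    origin <- list(`1` = c(0, 0), `2` = c(hw, 0), `3` = c(hw, hh), `4` = c(0, hh))
    xy <- do.call(rbind, lapply(1:4, function(s) {
      g <- place_grid(config$subplot_counts[s], origin[[s]][1L], origin[[s]][2L], hw)
      cbind(g, subplot = rep(s, nrow(g)))
    }))
    points <- data.frame(collar_id = ids, x_km = xy[, "x"], y_km = xy[, "y"],
                         subplot = as.integer(xy[, "subplot"]),
                         stringsAsFactors = FALSE)

    # across-collar heterogeneity
    mT <- rlnorm_cv(n, config$mean_T, config$cv_T_spatial)
    mW <- rlnorm_cv(n, config$mean_W, config$cv_W_spatial)
    tr <- config$model_truth
    alpha_i <- rlnorm_cv(n, tr$alpha, tr$cv_alpha_spatial %||% 0)

    # shared time grid over the season
    win <- growing_season(config$season[1L], config$season[2L])
    grid <- seq(as.numeric(win[1L]), as.numeric(win[2L]), by = config$cadence_min * 60)
    tsec <- grid - grid[1L]
    frac <- tsec / (tsec[length(tsec)])          # 0..1 through the season
    hour <- (grid %% 86400) / 3600
    seas <- sin(pi * frac)
    seas <- seas - mean(seas)                    # zero-mean seasonal anomaly
    diur <- sin(2 * pi * (hour - 9) / 24)        # peaks mid-afternoon
    sawt_u <- (tsec / 86400) %% config$irrigation_period_days
    tau <- config$irrigation_period_days / -log(config$irrigation_decay)
    sawt <- exp(-sawt_u / tau)
    sawt <- sawt / mean(sawt)                    # mean-one irrigation cycle

    nt <- length(grid)
    ts <- as.POSIXct(grid, origin = "1970-01-01", tz = "UTC")
    continuous <- vector("list", n)
    names(continuous) <- ids
    Tmat <- matrix(0, n, nt)
    Wmat <- matrix(0, n, nt)
    for (i in seq_len(n)) {
      Ti <- mT[i] + config$seasonal_T_amplitude * seas +
        config$diurnal_T_amplitude * diur +
        rnorm(nt, 0, config$T_noise_sd)
      Wi <- mW[i] * sawt * exp(rnorm(nt, 0, config$w_noise_sigma))
      Wi <- pmin(Wi, 100)
      Tmat[i, ] <- Ti
      Wmat[i, ] <- Wi
      continuous[[i]] <- data.frame(timestamp = ts, T = Ti, W = Wi)
    }

    # chamber survey dates and per-collar observation times
    dates <- seq(as.Date(config$season[1L]), as.Date(config$season[2L]),
                 by = config$campaign_every_days)
    nd <- length(dates)
    # one survey time per date, shared by all collars (the whole plot is
    # covered within the same late-morning window)
    hrs <- runif(nd, config$campaign_hours[1L], config$campaign_hours[2L])
    t_obs <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")) + hrs * 3600
    obs <- vector("list", n)
    for (i in seq_len(n)) {
      T_obs <- approx(grid, Tmat[i, ], xout = t_obs)$y
      W_obs <- approx(grid, Wmat[i, ], xout = t_obs)$y
      truth_p <- c(alpha = alpha_i[i], beta = tr$beta,
                   if (tr$model == "RTW") c(gamma = tr$gamma))
      R_true <- resp_eval(tr$model, truth_p, T = T_obs, W = W_obs)
      R_obs <- R_true * exp(rnorm(nd, 0, config$noise_sigma))
      obs[[i]] <- data.frame(collar_id = ids[i], date = dates,
                             R = R_obs, T = T_obs, W = W_obs,
                             stringsAsFactors = FALSE)
    }
    camp <- campaign(points, do.call(rbind, obs), config$plot_extent)
    list(campaign = camp, continuous = continuous,
         truth = list(model = tr$model, alpha = alpha_i, beta = tr$beta,
                      gamma = if (tr$model == "RTW") tr$gamma else NULL,
                      mean_T = mT, mean_W = mW))
  })
}

#' Generate a continuous diurnal respiration record
#'
#' Emulates a preliminary multi-day automated-chamber record: a sinusoidal
#' diurnal cycle with configured daily mean and peak, the peak time
#' jittering from day to day, plus additive noise. Used to determine the
#' representative survey window (see [representative_window()]).
#'
#' @param config a [synthetic_config()] (fields `diurnal`, `cadence_min`).
#' @param days number of whole days to generate.
#' @param seed integer seed.
#' @return data.frame with columns `timestamp`, `R`.
#' @export
generate_diurnal <- function(config = synthetic_config(), days = 5, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  d <- config$diurnal
  with_seed(seed, {
    step <- config$cadence_min * 60
    grid <- seq(0, days * 86400 - step, by = step)
    day <- grid %/% 86400
    hour <- (grid %% 86400) / 3600
    peak_h <- d$peak_hour + rnorm(days, 0, d$peak_jitter_h)
    amp <- d$peak - d$mean
    R <- d$mean + amp * sin(2 * pi * (hour - (peak_h[day + 1L] - 6)) / 24) +
      rnorm(length(grid), 0, d$noise_sd)
    data.frame(timestamp = as.POSIXct("2011-06-19 00:00:00", tz = "UTC") + grid,
               R = R)
  })
}
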