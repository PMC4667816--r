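#' Field-campaign container
#'
#' A `campaign` object holds one plot-scale chamber campaign: the collar
#' metadata (id, coordinates in km from the plot's SW corner, subplot label)
#' and the dated point observations of soil respiration `R`
#' (\eqn{\mu}mol CO2 m\eqn{^{-2}} s\eqn{^{-1}}), soil temperature `T` at
#' 10 cm (deg C) and volumetric soil water content `W` at 0--10 cm (%).
#'
#' @param points data.frame with columns `collar_id`, `x_km`, `y_km`,
#'   `subplot` (labels 1--4: 1 = SW, 2 = SE, 3 = NE, 4 = NW quadrant).
#' @param obs data.frame with columns `collar_id`, `date` (`Date` or
#'   ISO-8601 string), `R`, `T`, `W`.
#' @param plot_extent numeric length 2, plot width and height in km.
#' @return An object of class `campaign` with elements `points`, `obs`
#'   (date-sorted within collar) and `plot_extent`.
#' @details Missing single observations (`NA` in `R`, `T` or `W`) are
#'   permitted and skipped by downstream summaries; a collar whose rows are
#'   all missing is still listed in `points`. Negative or non-finite `R`,
#'   `W` outside \eqn{[0, 100]} (volumetric percent -- fractional water
#'   contents are rejected to avoid silent unit errors), duplicated
#'   (collar, date) pairs, and subplot labels inconsistent with the collar
#'   coordinates are all validation errors.
#' @seealso [read_campaign()], [subset_points()], [summarize_points()]
#' @export
campaign <- function(points, obs, plot_extent = c(5, 5)) {
  req_p <- c("collar_id", "x_km", "y_km", "subplot")
  req_o <- c("collar_id", "date", "R", "T", "W")
  miss <- setdiff(req_p, names(points))
  if (length(miss)) stopf("`points` lacks column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(req_o, names(obs))
  if (length(miss)) stopf("`obs` lacks column(s): %s", paste(miss, collapse = ", "))
  points$collar_id <- as.character(points$collar_id)
  obs$collar_id <- as.character(obs$collar_id)
  if (anyDuplicated(points$collar_id)) stopf("collar_ids are not unique")
  if (!inherits(obs$date, "Date")) obs$date <- as.Date(obs$date)
  if (anyNA(obs$date)) stopf("unparseable date in `obs`")
  if (!all(obs$collar_id %in% points$collar_id)) {
    stopf("observations reference unknown collar_id(s)")
  }
  for (v in c("R", "T", "W")) obs[[v]] <- as.numeric(obs[[v]])
  bad <- which(!is.na(obs$R) & (!is.finite(obs$R) | obs$R < 0))
  if (length(bad)) stopf("R must be finite and >= 0 (row %d)", bad[1L])
  bad <- which(!is.na(obs$W) & (obs$W < 0 | obs$W > 100))
  if (length(bad)) stopf("W must lie in [0, 100] volumetric %% (row %d)", bad[1L])
  key <- paste(obs$collar_id, obs$date)
  if (anyDuplicated(key)) {
    stopf("duplicate (collar, date) observation: %s", key[which(duplicated(key))[1L]])
  }
  plot_extent <- as.numeric(plot_extent)
  if (length(plot_extent) != 2L || any(!is.finite(plot_extent)) || any(plot_extent <= 0)) {
    stopf("`plot_extent` must be two positive numbers (km)")
  }
  lab <- subplot_label(points$x_km, points$y_km, plot_extent)
  mism <- which(as.integer(points$subplot) != lab)
  if (length(mism)) {
    stopf("subplot label of collar '%s' inconsistent with its coordinates",
          points$collar_id[mism[1L]])
  }
  obs <- obs[order(obs$collar_id, obs$date), req_o, drop = FALSE]
  rownames(obs) <- NULL
  rownames(points) <- NULL
  structure(list(points = points[, req_p, drop = FALSE],
                 obs = obs,
                 plot_extent = plot_extent),
            class = "campaign")
}

# Quadrant labelling: 1 = SW, 2 = SE, 3 = NE, 4 = NW; west is x < width/2,
# south is y < height/2 (boundaries go east/north).
subplot_label <- function(x, y, extent) {
  west <- x < extent[1L] / 2
  south <- y < extent[2L] / 2
  ifelse(south, ifelse(west, 1L, 2L), ifelse(west, 4L, 3L))
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("Chamber campaign: %d collars, %d observations, %.1f x %.1f km plot\n",
              nrow(x$points), nrow(x$obs), x$plot_extent[1L], x$plot_extent[2L]))
  tab <- table(factor(x$points$subplot, levels = 1:4))
  cat(sprintf("  collars per subplot (SW,SE,NE,NW): %s\n",
              paste(as.integer(tab), collapse = "/")))
  if (nrow(x$obs)) {
    cat(sprintf("  dates: %s .. %s\n", min(x$obs$date), max(x$obs$date)))
  }
  invisible(x)
}

#' Read / write a campaign CSV
#'
#' The campaign dialect is a flat CSV with mandatory header
#' `collar_id,x_km,y_km,subplot,date,R,T,W`, UTF-8, `.` decimal; one row
#' per collar x date.
#'
#' @param path file path.
#' @param plot_extent plot width/height in km (not stored in the CSV).
#' @return [read_campaign()] returns a [campaign]; [write_campaign()]
#'   invisibly returns `path`.
#' @export
read_campaign <- function(path, plot_extent = c(5, 5)) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("collar_id", "x_km", "y_km", "subplot", "date", "R", "T", "W")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stopf("campaign file lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    return(campaign(points = data.frame(collar_id = character(), x_km = numeric(),
                                        y_km = numeric(), subplot = integer()),
                    obs = data.frame(collar_id = character(), date = as.Date(character()),
                                     R = numeric(), T = numeric(), W = numeric()),
                    plot_extent = plot_extent))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(ifelse(raw[[col]] == "" | raw[[col]] == "NA",
                                            NA, raw[[col]])))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) stopf("non-numeric %s at data row %d: '%s'", col, bad[1L], raw[[col]][bad[1L]])
    v
  }
  obs <- data.frame(collar_id = raw$collar_id, date = raw$date,
                    R = num("R"), T = num("T"), W = num("W"),
                    stringsAsFactors = FALSE)
  first <- !duplicated(raw$collar_id)
  points <- data.frame(collar_id = raw$collar_id[first],
                       x_km = num("x_km")[first],
                       y_km = num("y_km")[first],
                       subplot = as.integer(num("subplot")[first]),
                       stringsAsFactors = FALSE)
  campaign(points, obs, plot_extent)
}

#' @param x a [campaign].
#' @rdname read_campaign
#' @export
write_campaign <- function(x, path) {
  stopifnot(inherits(x, "campaign"))
  m <- merge(x$obs, x$points, by = "collar_id", sort = FALSE)
  m <- m[order(m$collar_id, m$date),
         c("collar_id", "x_km", "y_km", "subplot", "date", "R", "T", "W")]
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write continuous logger series
#'
#' Continuous series are half-hourly averaged soil temperature and moisture
#' records per collar, CSV dialect `collar_id,timestamp,T,W` with ISO-8601
#' timestamps.
#'
#' @param path file path.
#' @return [read_continuous()] returns a named list (one element per collar)
#'   of data.frames with columns `timestamp` (`POSIXct`, UTC), `T`, `W`.
#' @export
read_continuous <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("collar_id", "timestamp", "T", "W")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stopf("continuous file lacks column(s): %s", paste(miss, collapse = ", "))
  ts <- parse_timestamp(raw$timestamp)
  if (anyNA(ts)) stopf("unparseable timestamp at data row %d", which(is.na(ts))[1L])
  raw$timestamp <- ts
  out <- split(raw[, c("timestamp", "T", "W")], raw$collar_id)
  lapply(out, function(d) {
    d <- d[order(d$timestamp), ]
    rownames(d) <- NULL
    d
  })
}

#' @param series named list of per-collar data.frames as returned by
#'   [read_continuous()], or a single such data.frame.
#' @rdname read_continuous
#' @export
write_continuous <- function(series, path) {
  if (is.data.frame(series)) series <- list(collar = series)
  rows <- lapply(names(series), function(id) {
    d <- series[[id]]
    data.frame(collar_id = id,
               timestamp = format(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               T = d$T, W = d$W, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  alt <- is.na(out)
  if (any(alt)) out[alt] <- as.POSIXct(x[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out
}

#' Subset a campaign by subplot labels
#'
#' Restricts a campaign to the collars falling in the chosen quadrant
#' subplots, recomputing the effective extent as the bounding box of the
#' chosen quadrants. Adjacent pairs (e.g. `c(1, 2)`) reproduce the half-plot
#' strip designs used for point-density comparisons.
#'
#' @param x a [campaign].
#' @param subplots integer labels in 1--4.
#' @return A [campaign] containing only the selected collars.
#' @export
subset_points <- function(x, subplots) {
  stopifnot(inherits(x, "campaign"))
  subplots <- unique(as.integer(subplots))
  if (!length(subplots) || any(!subplots %in% 1:4)) {
    stopf("`subplots` must be labels in 1..4")
  }
  keep <- x$points$subplot %in% subplots
  if (!any(keep)) stopf("selection {%s} contains no collars", paste(subplots, collapse = ","))
  pts <- x$points[keep, , drop = FALSE]
  obs <- x$obs[x$obs$collar_id %in% pts$collar_id, , drop = FALSE]
  ext <- subplot_bbox(subplots, x$plot_extent)
  out <- x
  out$points <- pts
  rownames(out$points) <- NULL
  out$obs <- obs
  rownames(out$obs) <- NULL
  out$extent_offset <- ext$offset
  out$plot_extent <- ext$extent
  # quadrant labels of the parent plot are retained; skip re-validation
  class(out) <- "campaign"
  out
}

subplot_bbox <- function(subplots, extent) {
  hw <- extent[1L] / 2
  hh <- extent[2L] / 2
  x0 <- c(0, hw, hw, 0)[subplots]
  y0 <- c(0, 0, hh, hh)[subplots]
  offset <- c(min(x0), min(y0))
  extent2 <- c(max(x0 + hw), max(y0 + hh)) - offset
  list(offset = offset, extent = extent2)
}

# Area in km^2 actually covered by a subplot selection (union of quadrants).
selection_area <- function(subplots, extent) {
  length(unique(subplots)) * (extent[1L] / 2) * (extent[2L] / 2)
}

#' Per-collar campaign summaries
#'
#' Collapses each collar to the arithmetic means of its campaign-day
#' temperature and moisture observations and, when a fitted respiration
#' model and the collar's continuous driver series are supplied, to its
#' seasonal CO2 emission (see [integrate_emission()]).
#'
#' @param x a [campaign].
#' @param continuous optional named list of continuous series (per collar),
#'   as from [read_continuous()].
#' @param fit optional [resp_model] fit used for all collars, or a named
#'   list of per-collar fits.
#' @param window integration window passed to [integrate_emission()].
#' @return data.frame with one row per collar: `collar_id`, `n_obs`,
#'   `mean_T` (deg C), `mean_W` (%), and if emissions were computed
#'   `emission_mol` (mol CO2 m^-2) and `emission_gC` (g C m^-2).
#' @details `NA` observations are skipped in the means; a collar with no
#'   valid observation at all is an error.
#' @export
summarize_points <- function(x, continuous = NULL, fit = NULL,
                             window = growing_season()) {
  stopifnot(inherits(x, "campaign"))
  ids <- x$points$collar_id
  if (!length(ids)) stopf("campaign has no collars")
  mt <- mw <- nn <- numeric(length(ids))
  for (i in seq_along(ids)) {
    o <- x$obs[x$obs$collar_id == ids[i], , drop = FALSE]
    tv <- o$T[!is.na(o$T)]
    wv <- o$W[!is.na(o$W)]
    if (nrow(o) == 0L || (!length(tv) && !length(wv))) {
      stopf("collar '%s' has no valid observations", ids[i])
    }
    mt[i] <- mean(tv)
    mw[i] <- mean(wv)
    nn[i] <- nrow(o)
  }
  out <- data.frame(collar_id = ids, n_obs = as.integer(nn),
                    mean_T = mt, mean_W = mw, stringsAsFactors = FALSE)
  if (!is.null(fit) && !is.null(continuous)) {
    fits <- if (inherits(fit, "resp_model")) {
      stats::setNames(rep(list(fit), length(ids)), ids)
    } else fit
    em <- lapply(ids, function(id) {
      if (is.null(continuous[[id]])) stopf("no continuous series for collar '%s'", id)
      if (is.null(fits[[id]])) stopf("no model fit for collar '%s'", id)
      integrate_emission(fits[[id]], continuous[[id]], window = window,
                         collar_id = id)
    })
    out$emission_mol <- vapply(em, function(e) e$total_mol, numeric(1))
    out$emission_gC <- vapply(em, function(e) e$total_gC, numeric(1))
  }
  out
}
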