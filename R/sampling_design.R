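#' Optimal sample size from a CV curve
#'
#' Applies the slope-threshold rule to a CV curve: with forward differences
#' \eqn{s_n = CV_{n+1} - CV_n} (% per collar), the optimal sample size is
#' the smallest `n` whose slope exceeds the threshold (default -1.0).
#' Below the threshold, adding a collar still buys more than one percentage
#' point of precision; above it, extra collars no longer pay. If every
#' slope is at or below the threshold the optimum is not obtained at this
#' population size.
#'
#' @param curve a [mc_cv_curve()] result, or any data.frame/list with
#'   columns/elements `k` and `cv_percent`.
#' @param threshold slope threshold in % per collar (default -1.0). A slope
#'   exactly equal to the threshold does not exceed it (strict `>`).
#' @return An object of class `optimal_size`: list with `obtained`
#'   (logical), `n_star` (collar count, `NA` if not obtained),
#'   `cv_at_n_star` (%), `threshold` and `slopes` (data.frame `n`,
#'   `dcv_dn`).
#' @examples
#' cv <- list(k = 1:50, cv_percent = 20 / sqrt(1:50))
#' optimal_sample_size(cv)  # n* = 5
#' @export
optimal_sample_size <- function(curve, threshold = -1) {
  if (inherits(curve, "cv_curve")) curve <- curve$cv
  k <- curve$k
  cv <- curve$cv_percent
  if (is.null(k) || is.null(cv)) stopf("`curve` needs elements `k` and `cv_percent`")
  if (length(k) < 2L) stopf("curve needs at least 2 points, got %d", length(k))
  o <- order(k)
  k <- k[o]
  cv <- cv[o]
  if (any(diff(k) != 1L)) stopf("curve sizes `k` must be consecutive integers")
  s <- diff(cv)
  n <- k[-length(k)]
  hit <- which(s > threshold)
  obtained <- length(hit) > 0L
  n_star <- if (obtained) n[hit[1L]] else NA_integer_
  structure(list(obtained = obtained,
                 n_star = n_star,
                 cv_at_n_star = if (obtained) cv[match(n_star, k)] else NA_real_,
                 threshold = threshold,
                 slopes = data.frame(n = n, dcv_dn = s)),
            class = "optimal_size")
}

#' @export
print.optimal_size <- function(x, ...) {
  if (x$obtained) {
    cat(sprintf("Optimal sample size n* = %d (CV %.1f%%) at dCV/dn > %.1f\n",
                x$n_star, x$cv_at_n_star, x$threshold))
  } else {
    cat(sprintf("Optimal sample size not obtained: all dCV/dn <= %.1f\n",
                x$threshold))
  }
  invisible(x)
}

#' Default plot partitions for the density comparison
#'
#' The full plot, the four half-plot strips (adjacent subplot pairs) and
#' the four quadrant subplots.
#' @return Named list of subplot-label vectors.
#' @export
default_partitions <- function() {
  list("5.0 x 5.0 km2 plot" = 1:4,
       "Subplot 1 + 2" = c(1L, 2L),
       "Subplot 2 + 3" = c(2L, 3L),
       "Subplot 1 + 4" = c(1L, 4L),
       "Subplot 3 + 4" = c(3L, 4L),
       "Subplot 1" = 1L, "Subplot 2" = 2L, "Subplot 3" = 3L, "Subplot 4" = 4L)
}

#' Sample-size design table across plot partitions
#'
#' Orchestrates the plot/subplot comparison: for each partition it collapses
#' the campaign to per-collar mean temperature, mean moisture and (per
#' model) seasonal emission, runs the Monte Carlo CV engine on each
#' variable, detects the optimal sample size, and assembles one table row
#' with the point count and density.
#'
#' @param x a [campaign].
#' @param continuous named list of per-collar continuous series (see
#'   [read_continuous()]).
#' @param models character subset of `c("RT", "RW", "RTW")`: respiration
#'   models fitted per collar on its campaign observations and integrated
#'   over the season.
#' @param M subsample draws per size.
#' @param seed base seed; each partition x variable curve gets a distinct
#'   child seed derived from it.
#' @param partitions named list of subplot-label vectors
#'   (default [default_partitions()]).
#' @param threshold dCV/dn threshold for [optimal_sample_size()].
#' @param window integration window for [integrate_emission()].
#' @return An object of class `design_table`: data.frame with columns
#'   `plot`, `n_points`, `density_km2`, and `n_<var>` / `cv_<var>` pairs
#'   for each variable (`T`, `W`, and the requested models); `n_<var>` is
#'   `NA` where the optimum was not obtained. The CV curves are attached as
#'   attribute `"curves"`.
#' @details Densities are recomputed from the subplot geometry (points per
#'   km^2 of the selected quadrants). Partitions with fewer than 2 collars
#'   are an error.
#' @export
design_table <- function(x, continuous, models = c("RT", "RW", "RTW"),
                         M = 10000, seed = NULL,
                         partitions = default_partitions(),
                         threshold = -1, window = growing_season()) {
  stopifnot(inherits(x, "campaign"))
  models <- match.arg(models, c("RT", "RW", "RTW"), several.ok = TRUE)
  if (is.null(names(partitions))) {
    names(partitions) <- vapply(partitions, function(p)
      paste0("Subplot ", paste(p, collapse = "+")), character(1))
  }
  # per-collar summaries and fits are partition-independent: compute once
  ids <- x$points$collar_id
  summ <- summarize_points(x)
  fits <- list()
  emis <- list()
  for (m in models) {
    fits[[m]] <- lapply(ids, function(id) {
      resp_model(x$obs[x$obs$collar_id == id, , drop = FALSE], model = m)
    })
    names(fits[[m]]) <- ids
    emis[[m]] <- vapply(ids, function(id) {
      if (is.null(continuous[[id]])) stopf("no continuous series for collar '%s'", id)
      integrate_emission(fits[[m]][[id]], continuous[[id]], window = window,
                         collar_id = id)$total_gC
    }, numeric(1))
  }
  vars <- c("T", "W", models)
  rows <- vector("list", length(partitions))
  curves <- list()
  sidx <- 0L
  for (p in seq_along(partitions)) {
    labs <- partitions[[p]]
    sel <- x$points$subplot %in% labs
    n_pts <- sum(sel)
    if (n_pts < 2L) stopf("partition '%s' has %d collar(s); need >= 2",
                          names(partitions)[p], n_pts)
    area <- selection_area(labs, x$plot_extent)
    row <- list(plot = names(partitions)[p], n_points = n_pts,
                density_km2 = round(n_pts / area, 2))
    for (v in vars) {
      vals <- switch(v,
                     T = summ$mean_T[match(ids[sel], summ$collar_id)],
                     W = summ$mean_W[match(ids[sel], summ$collar_id)],
                     emis[[v]][sel])
      sidx <- sidx + 1L
      cv <- mc_cv_curve(vals, M = M, seed = child_seed(seed, sidx), variable = v)
      os <- optimal_sample_size(cv, threshold = threshold)
      row[[paste0("n_", v)]] <- os$n_star
      row[[paste0("cv_", v)]] <- if (os$obtained) round(os$cv_at_n_star, 1) else NA_real_
      curves[[paste(names(partitions)[p], v, sep = " | ")]] <- cv
    }
    rows[[p]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "M") <- M
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "threshold") <- threshold
  class(out) <- c("design_table", "data.frame")
  out
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Sampling design table (M = %s, threshold dCV/dn > %.1f):\n",
              attr(x, "M"), attr(x, "threshold")))
  df <- as.data.frame(x)
  attr(df, "curves") <- NULL
  print(df, row.names = FALSE)
  cat("n_* = NA: optimum not obtained (all dCV/dn at or below the threshold)\n")
  invisible(x)
}

#' Write a design table to CSV
#'
#' @param x a [design_table()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_design_table <- function(x, path) {
  df <- as.data.frame(x)
  attr(df, "curves") <- NULL
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
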