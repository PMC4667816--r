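#' Monte Carlo CV curve of the subsample mean
#'
#' The core resampling engine: for every subsample size `k = 1 .. N-1` it
#' draws `M` random subsamples without replacement from the `N` per-collar
#' values (each draw is a fresh uniformly random permutation of `1..N`
#' truncated to its first `k` elements), takes each subsample mean
#' \eqn{E_i}, and estimates the coefficient of variation of the size-`k`
#' subsample mean relative to the full-sample mean \eqn{E_N}:
#' \deqn{CV_k = \frac{1}{E_N}\sqrt{\frac{1}{M-1}\sum_{i=1}^{M}(E_i - E_N)^2}}
#' reported in percent.
#'
#' @param values numeric vector, one value per collar (e.g. per-collar mean
#'   temperature, mean moisture, or seasonal emission).
#' @param M number of subsample draws per size (default 10,000).
#' @param seed integer seed making the curve reproducible; recorded in the
#'   result. `NULL` uses (and advances) the current RNG stream.
#' @param variable label carried into the result (`"T"`, `"W"`, a model
#'   id, or `"custom"`).
#' @return An object of class `cv_curve`: list with `variable`, `N`, `M`,
#'   `E_N`, `cv` (data.frame `k`, `cv_percent` with `N-1` rows) and `seed`.
#' @details Deviations are centred on the full-sample mean \eqn{E_N}, not
#'   on the mean of the \eqn{E_i}, and the divisor is `M - 1`; both choices
#'   follow the estimator's printed definition (they differ from the
#'   conventional sd only at order 1/M). Draws are independent across sizes
#'   and may repeat a subsample -- with M large that has negligible effect.
#'   Preconditions: `N >= 2`, `M >= 2`, and \eqn{E_N \neq 0} (the CV is
#'   undefined for a zero mean).
#' @examples
#' cv <- mc_cv_curve(c(1, 2, 3, 4), M = 2000, seed = 1)
#' cv$cv        # compare exact_cv_enumeration(c(1,2,3,4), k = 2): 25.82%
#' @seealso [exact_cv_enumeration()], [closed_form_cv()],
#'   [optimal_sample_size()]
#' @export
mc_cv_curve <- function(values, M = 10000, seed = NULL, variable = "custom") {
  values <- as.numeric(values)
  N <- length(values)
  if (N < 2L) stopf("need at least 2 values, got %d", N)
  if (any(!is.finite(values))) stopf("values must be finite")
  if (M < 2L) stopf("M must be >= 2")
  E_N <- mean(values)
  if (E_N == 0) stopf("full-sample mean is zero; CV undefined")
  cvs <- with_seed(seed, {
    vapply(seq_len(N - 1L), function(k) {
      ssq <- 0
      for (i in seq_len(M)) {
        perm <- sample.int(N)           # full random permutation ...
        Ei <- sum(values[perm[seq_len(k)]]) / k   # ... truncated to first k
        ssq <- ssq + (Ei - E_N)^2
      }
      sqrt(ssq / (M - 1)) / E_N * 100
    }, numeric(1))
  })
  structure(list(variable = variable, N = N, M = as.integer(M), E_N = E_N,
                 cv = data.frame(k = seq_len(N - 1L), cv_percent = abs(cvs)),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "cv_curve")
}

#' Exact CV of the subsample mean by exhaustive enumeration
#'
#' Brute-force oracle: enumerates every size-`k` subset of the values once
#' and computes \eqn{CV = \sqrt{\mathrm{mean}_i (E_i - E_N)^2}/E_N \times
#' 100} with the divisor equal to the number of subsets -- the infinite-`M`
#' limit of [mc_cv_curve()]'s estimator.
#'
#' @param values numeric vector (length `N`).
#' @param k subset size, `1 <= k <= N`.
#' @return CV in percent.
#' @details Guarded to `choose(N, k) <= 1e6` subsets.
#' @export
exact_cv_enumeration <- function(values, k) {
  values <- as.numeric(values)
  N <- length(values)
  if (k < 1L || k > N) stopf("k must be in 1..N")
  E_N <- mean(values)
  if (E_N == 0) stopf("full-sample mean is zero; CV undefined")
  if (choose(N, k) > 1e6) stopf("choose(%d, %d) exceeds the 1e6 enumeration guard", N, k)
  means <- combn(values, k, mean)
  abs(sqrt(mean((means - E_N)^2)) / E_N) * 100
}

#' Closed-form CV of the subsample mean under SRSWOR
#'
#' Survey-sampling oracle: under simple random sampling without replacement
#' the variance of the size-`k` subsample mean is \eqn{(S^2/k)(1 - k/N)}
#' with \eqn{S^2} the (N-1)-divisor sample variance, so
#' \deqn{CV_k = \sqrt{(S^2/k)\,(1 - k/N)}\,/\,E_N \times 100.}
#' Agrees exactly with [exact_cv_enumeration()] for every population.
#'
#' @inheritParams exact_cv_enumeration
#' @return CV in percent.
#' @export
closed_form_cv <- function(values, k) {
  values <- as.numeric(values)
  N <- length(values)
  if (N < 2L) stopf("need at least 2 values")
  if (k < 1L || k > N) stopf("k must be in 1..N")
  E_N <- mean(values)
  if (E_N == 0) stopf("full-sample mean is zero; CV undefined")
  S2 <- stats::var(values)
  abs(sqrt((S2 / k) * (1 - k / N)) / E_N) * 100
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("Monte Carlo CV curve for %s: N = %d, M = %d, mean = %.4g%s\n",
              x$variable, x$N, x$M, x$E_N,
              if (is.na(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  show <- x$cv[x$cv$k %in% unique(c(1:5, seq(10, x$N - 1L, by = 10), x$N - 1L)), ]
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cv_curve <- function(x, ...) {
  data.frame(variable = x$variable, N = x$N, M = x$M, seed = x$seed,
             k = x$cv$k, cv_percent = x$cv$cv_percent,
             stringsAsFactors = FALSE)
}

#' @param x a `cv_curve`.
#' @param threshold if non-NULL, mark the [optimal_sample_size()] detected
#'   at this dCV/dn threshold.
#' @param ... passed to [plot()].
#' @rdname mc_cv_curve
#' @export
plot.cv_curve <- function(x, threshold = -1, ...) {
  plot(x$cv$k, x$cv$cv_percent, type = "b", pch = 16, cex = 0.6,
       xlab = "Sample size n", ylab = "CV (%)",
       main = sprintf("CV of subsample mean: %s", x$variable), ...)
  if (!is.null(threshold)) {
    os <- optimal_sample_size(x, threshold = threshold)
    if (os$obtained) {
      abline(v = os$n_star, lty = 2, col = 2)
      axis(3, at = os$n_star, labels = sprintf("n* = %d", os$n_star),
           tick = FALSE, line = -1)
    }
  }
  invisible(x)
}

#' Write CV curves to CSV
#'
#' @param curves a `cv_curve` or list of them.
#' @param path output file (`variable,N,M,seed,k,cv_percent`).
#' @return invisibly, the data.frame written.
#' @export
write_cv_curves <- function(curves, path) {
  if (inherits(curves, "cv_curve")) curves <- list(curves)
  out <- do.call(rbind, lapply(curves, as.data.frame))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
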