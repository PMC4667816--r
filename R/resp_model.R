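#' Fit an empirical soil-respiration model
#'
#' Fits one of the three classic empirical response models of soil
#' respiration `R` to soil temperature `T` and/or volumetric soil water
#' content `W` by nonlinear least squares on the untransformed scale:
#'
#' \describe{
#'   \item{`"RT"`}{\eqn{R = \alpha e^{\beta T}} -- exponential temperature
#'     response (`beta` per deg C).}
#'   \item{`"RW"`}{\eqn{R = \alpha W^{\beta}} -- power moisture response.}
#'   \item{`"RTW"`}{\eqn{R = \alpha T^{\beta} W^{\gamma}} -- interactive
#'     temperature-moisture response.}
#' }
#'
#' @param data data.frame with columns `R` (\eqn{\mu}mol CO2 m^-2 s^-1),
#'   `T` (deg C) and/or `W` (volumetric %) as the model requires. Rows with
#'   `NA` in a required variable are dropped.
#' @param model one of `"RT"`, `"RW"`, `"RTW"`.
#' @param control a [minpack.lm::nls.lm.control()] list; the default runs
#'   Levenberg-Marquardt to a relative sum-of-squares tolerance of 1e-10
#'   with at most 500 iterations.
#' @return An object of class `resp_model`: a list with `model`,
#'   `coefficients` (named `alpha`, `beta` and, for `"RTW"`, `gamma`),
#'   `r_squared`, `n_obs`, `fitted`, `residuals`, `data` and `convergence`
#'   information.
#' @details Starting values come from ordinary least squares on the
#'   log-linearised model (`log R ~ T`, `log R ~ log W`, or
#'   `log R ~ log T + log W`), which is exact for noiseless data, so no
#'   user-supplied start is needed. `r_squared` is \eqn{1 - SS_{res}/SS_{tot}}
#'   on the original scale and may be negative for pathological fits.
#'   Preconditions: at least 3 observations (4 for `"RTW"`); `R > 0`
#'   (required by the log-scale initialisation); `W > 0` for `"RW"`/`"RTW"`
#'   and `T > 0` for `"RTW"` (powers of non-positive bases are undefined);
#'   constant `R` (zero total sum of squares) is a degenerate-data error.
#' @examples
#' d <- data.frame(T = seq(10, 30, 2), W = 25)
#' d$R <- 2 * exp(0.1 * d$T)
#' fit <- resp_model(d, "RT")
#' coef(fit)       # alpha = 2, beta = 0.1
#' predict(fit, T = 20)
#' @seealso [predict.resp_model()], [average_r2()], [propagate_error()]
#' @export
resp_model <- function(data, model = c("RT", "RW", "RTW"),
                       control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                           maxiter = 500)) {
  model <- match.arg(model)
  need <- switch(model, RT = c("R", "T"), RW = c("R", "W"), RTW = c("R", "T", "W"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("`data` lacks column(s): %s", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  n_min <- if (model == "RTW") 4L else 3L
  if (nrow(d) < n_min) stopf("need at least %d complete observations, got %d", n_min, nrow(d))
  if (any(d$R <= 0)) stopf("R must be > 0 for log-scale initialisation")
  if (model %in% c("RW", "RTW") && any(d$W <= 0)) stopf("W must be > 0 for model %s", model)
  if (model == "RTW" && any(d$T <= 0)) stopf("T must be > 0 for model RTW")
  if (sd(d$R) == 0) stopf("degenerate data: R is constant (SS_tot = 0)")

  # closed-form start from the log-linearised model
  start <- switch(model,
    RT = {
      cf <- coef(lm(log(R) ~ T, data = d))
      c(alpha = exp(unname(cf[1L])), beta = unname(cf[2L]))
    },
    RW = {
      cf <- coef(lm(log(R) ~ log(W), data = d))
      c(alpha = exp(unname(cf[1L])), beta = unname(cf[2L]))
    },
    RTW = {
      cf <- coef(lm(log(R) ~ log(T) + log(W), data = d))
      c(alpha = exp(unname(cf[1L])), beta = unname(cf[2L]), gamma = unname(cf[3L]))
    })

  fn <- function(p) d$R - resp_eval(model, p, d$T, d$W)
  lower <- c(alpha = .Machine$double.xmin, beta = -Inf, gamma = -Inf)[seq_along(start)]
  res <- minpack.lm::nls.lm(par = start, fn = fn, lower = lower, control = control)
  # info codes 1:4 signal convergence in the MINPACK sense; 5+ are failures
  if (!res$info %in% 1:4) {
    stopf("nonlinear least squares did not converge (info %d after %d iterations; start alpha=%.4g beta=%.4g%s)",
          res$info, res$niter, start["alpha"], start["beta"],
          if (model == "RTW") sprintf(" gamma=%.4g", start["gamma"]) else "")
  }
  p <- res$par
  pred <- resp_eval(model, p, d$T, d$W)
  ss_res <- sum((d$R - pred)^2)
  ss_tot <- sum((d$R - mean(d$R))^2)
  structure(list(model = model,
                 coefficients = p,
                 r_squared = 1 - ss_res / ss_tot,
                 n_obs = nrow(d),
                 fitted = pred,
                 residuals = d$R - pred,
                 data = d,
                 convergence = list(info = res$info, iterations = res$niter,
                                    ss_res = ss_res, start = start)),
            class = "resp_model")
}

# Evaluate a model formula at coefficient vector p (named alpha/beta/gamma).
resp_eval <- function(model, p, T = NULL, W = NULL) {
  switch(model,
         RT = p[["alpha"]] * exp(p[["beta"]] * T),
         RW = p[["alpha"]] * W^p[["beta"]],
         RTW = p[["alpha"]] * T^p[["beta"]] * W^p[["gamma"]])
}

#' @export
print.resp_model <- function(x, digits = 4, ...) {
  form <- switch(x$model,
                 RT = "R = alpha * exp(beta * T)",
                 RW = "R = alpha * W^beta",
                 RTW = "R = alpha * T^beta * W^gamma")
  cat(sprintf("Soil respiration model %s:  %s\n", x$model, form))
  print(signif(x$coefficients, digits))
  cat(sprintf("R-squared %.4f on %d observations\n", x$r_squared, x$n_obs))
  invisible(x)
}

#' @export
coef.resp_model <- function(object, ...) object$coefficients

#' @export
fitted.resp_model <- function(object, ...) object$fitted

#' @export
residuals.resp_model <- function(object, ...) object$residuals

#' @export
summary.resp_model <- function(object, ...) {
  out <- list(model = object$model, coefficients = object$coefficients,
              r_squared = object$r_squared, n_obs = object$n_obs,
              residual_sd = sd(object$residuals),
              convergence = object$convergence)
  class(out) <- "summary.resp_model"
  out
}

#' @export
print.summary.resp_model <- function(x, ...) {
  cat(sprintf("Model %s (n = %d)\n", x$model, x$n_obs))
  print(x$coefficients)
  cat(sprintf("R-squared %.4f, residual sd %.4g, %d LM iterations\n",
              x$r_squared, x$residual_sd, x$convergence$iterations))
  invisible(x)
}

#' Predict respiration from a fitted model
#'
#' @param object a [resp_model].
#' @param newdata optional data.frame with the driver columns the model
#'   needs (`T` and/or `W`); alternatively pass `T`/`W` vectors directly.
#' @param T,W driver vectors, used when `newdata` is not given.
#' @param ... unused.
#' @return Predicted soil respiration (\eqn{\mu}mol CO2 m^-2 s^-1).
#' @export
predict.resp_model <- function(object, newdata = NULL, T = NULL, W = NULL, ...) {
  if (!is.null(newdata)) {
    T <- newdata[["T"]]
    W <- newdata[["W"]]
  }
  if (object$model %in% c("RT", "RTW") && is.null(T)) {
    stopf("model %s requires T", object$model)
  }
  if (object$model %in% c("RW", "RTW") && is.null(W)) {
    stopf("model %s requires W", object$model)
  }
  resp_eval(object$model, object$coefficients, T, W)
}

#' @export
plot.resp_model <- function(x, ...) {
  driver <- if (x$model == "RW") "W" else "T"
  xlab <- if (driver == "T") "Soil temperature (deg C)" else "Soil water content (%)"
  plot(x$data[[driver]], x$data$R, xlab = xlab,
       ylab = expression(R ~ (mu * mol ~ m^-2 ~ s^-1)),
       main = sprintf("Model %s fit", x$model), ...)
  ord <- order(x$data[[driver]])
  lines(x$data[[driver]][ord], x$fitted[ord], col = 2)
  invisible(x)
}

#' Construct a respiration model from known coefficients
#'
#' Builds a `resp_model` object directly from coefficient values without
#' fitting, e.g. for error-propagation scenarios using published
#' coefficients or for driving the synthetic generator.
#'
#' @param model one of `"RT"`, `"RW"`, `"RTW"`.
#' @param alpha,beta,gamma coefficients (`gamma` only for `"RTW"`).
#' @return A [resp_model] with `r_squared`, `n_obs` and residuals `NA`.
#' @export
resp_model_coefs <- function(model = c("RT", "RW", "RTW"), alpha, beta, gamma = NULL) {
  model <- match.arg(model)
  if (alpha <= 0) stopf("alpha must be > 0")
  if (model == "RTW" && is.null(gamma)) stopf("model RTW requires gamma")
  if (model != "RTW" && !is.null(gamma)) stopf("gamma only applies to model RTW")
  p <- c(alpha = alpha, beta = beta)
  if (model == "RTW") p <- c(p, gamma = gamma)
  structure(list(model = model, coefficients = p, r_squared = NA_real_,
                 n_obs = NA_integer_, fitted = NULL, residuals = NULL,
                 data = NULL, convergence = NULL),
            class = "resp_model")
}

#' Average goodness of fit across collars
#'
#' Arithmetic mean and standard error of the coefficients of determination
#' of per-collar fits of one model, the usual plot-level fit summary
#' (mean R-squared +/- SE over collars).
#'
#' @param fits list of [resp_model] objects, all of the same model variant.
#' @return list with `model`, `mean_r2`, `se_r2` (sd across collars divided
#'   by the square root of the number of collars) and `n_fits`.
#' @export
average_r2 <- function(fits) {
  if (length(fits) < 2L) stopf("need at least 2 fits")
  models <- vapply(fits, function(f) f$model, character(1))
  if (length(unique(models)) != 1L) {
    stopf("fits mix models: %s", paste(unique(models), collapse = ", "))
  }
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  list(model = models[1L], mean_r2 = mean(r2),
       se_r2 = sd(r2) / sqrt(length(r2)), n_fits = length(r2))
}

#' Write per-collar fit results to CSV
#'
#' @param fits named list of [resp_model] objects (names = collar ids).
#' @param path output file.
#' @return invisibly, the data.frame written.
#' @export
write_fits <- function(fits, path) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(collar_id = id, model = f$model,
               alpha = f$coefficients[["alpha"]],
               beta = f$coefficients[["beta"]],
               gamma = if (f$model == "RTW") f$coefficients[["gamma"]] else NA_real_,
               r_squared = f$r_squared, n_obs = f$n_obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
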