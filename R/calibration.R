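#' Sensor calibration parameters
#'
#' Container for the equilibrium response model of the nanosensor array. The
#' fractional fluorescence quench at analyte concentration `c` follows a
#' Hill-type adsorption isotherm
#' \deqn{R(c) = \alpha \frac{(c/K_D)^n}{(c/K_D)^n + 1} + \beta}
#' where `R` is the quench magnitude in percent (`-100 (I - I0)/I0`),
#' `alpha` the response amplitude, `beta` the baseline offset, `K_D` the
#' effective dissociation constant and `n` the cooperativity exponent
#' (`n < 1`: negative cooperativity).
#'
#' @param alpha Response amplitude, percent quench. Must be positive.
#' @param beta Baseline offset, percent quench.
#' @param K_D Dissociation constant in mol/L. Must be positive.
#' @param n Cooperativity exponent (dimensionless). Must be positive.
#' @return An object of class `calibration_params`.
#' @seealso [response_at()], [fit_calibration()], [limit_of_detection()]
#' @export
calibration_params <- function(alpha, beta, K_D, n) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(K_D), is.numeric(n),
            length(alpha) == 1, length(beta) == 1, length(K_D) == 1, length(n) == 1)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be a positive finite number")
  if (!is.finite(K_D) || K_D <= 0) stop("`K_D` must be a positive finite number (mol/L)")
  if (!is.finite(n) || n <= 0) stop("`n` must be a positive finite number")
  structure(list(alpha = alpha, beta = beta, K_D = K_D, n = n),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "Sensor calibration: alpha = %.4g %%, beta = %.4g %%, K_D = %.4g M, n = %.4g\n",
    x$alpha, x$beta, x$K_D, x$n))
  invisible(x)
}

#' Default H2O2 calibration of the nanosensor array
#'
#' The published equilibrium constants for the DNA-wrapped carbon-nanotube
#' H2O2 sensor: amplitude 88.74%, offset 2.30%, K_D = 0.00204 M, n = 0.317.
#'
#' @return A [calibration_params()] object.
#' @export
default_calibration <- function() {
  calibration_params(alpha = 88.74, beta = 2.30, K_D = 0.00204, n = 0.317)
}

#' Predicted sensor response at a concentration
#'
#' @param conc Analyte concentration(s) in mol/L, non-negative.
#' @param params A [calibration_params()] object.
#' @return Percent quench magnitude, same length as `conc`. Strictly
#'   increasing in `conc` and equal to `beta` at zero concentration.
#' @export
response_at <- function(conc, params) {
  stopifnot(inherits(params, "calibration_params"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("`conc` must be finite and non-negative (mol/L)")
  h <- (conc / params$K_D)^params$n
  params$alpha * h / (h + 1) + params$beta
}

#' Fit the equilibrium response model to a calibration curve
#'
#' Bounded Levenberg-Marquardt least squares of the Hill-type response model
#' on (concentration, percent-quench) pairs. `K_D` is fitted on a log10 scale
#' for conditioning; bounds are `alpha` in \[0, 200\], `n` in (0, 3\] and
#' `K_D` in \[1e-9, 10\] M, appropriate for a handful of points spanning
#' several decades of concentration.
#'
#' @param measurements Data frame with columns `concentration_M` and
#'   `response_pct` (percent quench magnitude); an optional `sd_pct` column is
#'   carried through but the fit is unweighted.
#' @param initial_guess Optional [calibration_params()] start. Default:
#'   `alpha = max(R)`, `beta = min(R)`, `K_D` = geometric mid-concentration,
#'   `n = 0.5`.
#' @return List with elements `params` (fitted [calibration_params()]),
#'   `r_squared` (unweighted 1 - SS_res/SS_tot) and `fit` (the `nls` object).
#' @export
fit_calibration <- function(measurements, initial_guess = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("concentration_M", "response_pct") %in% names(measurements)))
  conc <- measurements$concentration_M
  resp <- measurements$response_pct
  keep <- is.finite(conc) & is.finite(resp)
  conc <- conc[keep]; resp <- resp[keep]
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations to fit 4 parameters")
  pos <- conc > 0
  if (diff(range(log10(conc[pos]))) < 2)
    stop("calibration concentrations must span at least 2 decades")
  if (diff(range(resp)) < 1e-6 * max(1, abs(mean(resp))))
    stop("response curve is flat: amplitude not identifiable")

  if (is.null(initial_guess)) {
    lk0 <- mean(range(log10(conc[pos])))
    start <- list(alpha = max(resp) - min(resp) + 1e-3, beta = min(resp),
                  lK = lk0, n = 0.5)
  } else {
    stopifnot(inherits(initial_guess, "calibration_params"))
    start <- list(alpha = initial_guess$alpha, beta = initial_guess$beta,
                  lK = log10(initial_guess$K_D), n = initial_guess$n)
  }
  dat <- data.frame(conc = conc, resp = resp)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ alpha * (conc / 10^lK)^n / ((conc / 10^lK)^n + 1) + beta,
      data = dat, start = start,
      lower = c(alpha = 0, beta = -Inf, lK = -9, n = 1e-6),
      upper = c(alpha = 200, beta = Inf, lK = 1, n = 3),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["alpha"]] < 1e-3)
    stop("fitted amplitude is ~0: response not identifiable")
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((resp - mean(resp))^2)
  list(params = calibration_params(cf[["alpha"]], cf[["beta"]],
                                   10^cf[["lK"]], cf[["n"]]),
       r_squared = r2, fit = fit)
}

#' Limit of detection of the calibrated sensor
#'
#' Inverts the response model at the threshold `blank_response + 3 * blank_sd`
#' (blank mean plus three standard deviations) and returns the concentration
#' whose predicted response equals that threshold.
#'
#' @param params A [calibration_params()] object.
#' @param blank_response Mean blank (buffer-only) response, percent.
#' @param blank_sd Standard deviation of the blank response, percent; must be
#'   positive.
#' @return Concentration in mol/L.
#' @export
limit_of_detection <- function(params, blank_response, blank_sd) {
  stopifnot(inherits(params, "calibration_params"))
  if (!is.finite(blank_sd) || blank_sd <= 0) stop("`blank_sd` must be > 0")
  threshold <- blank_response + 3 * blank_sd
  invert_response(threshold, params)
}

#' Invert the response model
#'
#' Concentration at which the predicted percent quench equals `response`.
#'
#' @param response Percent quench, strictly between `beta` and `alpha + beta`.
#' @param params A [calibration_params()] object.
#' @return Concentration in mol/L.
#' @export
invert_response <- function(response, params) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(response <= params$beta))
    stop("response at or below the baseline offset: concentration undefined")
  if (any(response >= params$alpha + params$beta))
    stop("response at or above saturation: concentration unbounded")
  f <- (response - params$beta) / params$alpha
  params$K_D * (f / (1 - f))^(1 / params$n)
}

#' Sensor response time (t90)
#'
#' Time at which a quenching intensity trace first reaches 90% of its total
#' drop, i.e. the first `t` with `I(t) <= I0 - 0.9 (I0 - Imin)`.
#'
#' @param trace An [intensity_trace()] object.
#' @return Time in seconds (linearly interpolated between samples).
#' @export
response_time <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  I <- trace$intensities; t <- trace$times
  I0 <- trace$I0
  Imin <- min(I)
  if (Imin >= I0 - 1e-12 * max(abs(I0), 1))
    stop("trace does not decrease: response time undefined")
  target <- I0 - 0.9 * (I0 - Imin)
  below <- which(I <= target)
  i <- below[1]
  if (i == 1) return(t[1])
  # linear interpolation across the crossing
  t[i - 1] + (t[i] - t[i - 1]) * (I[i - 1] - target) / (I[i - 1] - I[i])
}

#' Read / write calibration curves and parameters
#'
#' Calibration curves are exchanged as CSV with columns `concentration_M`,
#' `response_pct` and optional `sd_pct`; fitted parameters as JSON.
#'
#' @param path File path.
#' @return `read_calibration_csv` returns a data frame;
#'   `read_calibration_json` a [calibration_params()] object.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("concentration_M", "response_pct") %in% names(df)))
  df
}

#' @rdname read_calibration_csv
#' @param curve Data frame as returned by [read_calibration_csv()].
#' @export
write_calibration_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_calibration_csv
#' @param params A [calibration_params()] object.
#' @export
write_calibration_json <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_calibration_csv
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(x$alpha, x$beta, x$K_D, x$n)
}
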