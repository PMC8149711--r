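#' Diffusion-decay parameters of the efflux field
#'
#' Parameters of the instantaneous point-source solution used to translate a
#' burst release of H2O2 at the cell into the concentration field reaching
#' the sensor array,
#' \deqn{C(r,t) = \frac{M}{(\sqrt{4\pi D t})^3}
#'   \exp\!\left(-\frac{r^2}{4Dt} - K t\right).}
#'
#' Two mutually inconsistent decay constants circulate for cellular H2O2:
#' the value `6.93e-4` 1/s and the one implied by a 1 ms half-life
#' (`log(2)/1e-3 = 693` 1/s). Both are selectable via `decay`; the small
#' value is the default since at the ~10 ms transport timescale the large
#' one would extinguish the field entirely.
#'
#' @param M Released amount in mol. Must be positive.
#' @param D Diffusion coefficient in cm^2/s (aqueous H2O2: 1.5e-5).
#' @param K First-order decay constant in 1/s, `>= 0`.
#' @param half_life Informational half-life in seconds (not used in the
#'   field evaluation; see Details).
#' @param decay Which decay constant convention to use when `K` is not given
#'   explicitly: `"slow"` (6.93e-4 1/s, default) or `"half_life"`
#'   (`log(2)/half_life`).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(M = 1e-18, D = 1.5e-5, K = NULL,
                             half_life = 1e-3,
                             decay = c("slow", "half_life")) {
  decay <- match.arg(decay)
  if (is.null(K)) K <- if (decay == "slow") 6.93e-4 else log(2) / half_life
  stopifnot(is.numeric(M), is.numeric(D), is.numeric(K))
  if (M <= 0) stop("`M` must be positive (mol)")
  if (D <= 0) stop("`D` must be positive (cm^2/s)")
  if (K < 0) stop("`K` must be >= 0 (1/s)")
  structure(list(M = M, D = D, K = K, half_life = half_life),
            class = "diffusion_params")
}

#' Source-to-sensor geometry
#'
#' The effective distance between the release point at the cell core and the
#' sensor array is `L_eff = L + L_cell` where `L` is the cell-surface-to-
#' sensor distance and `L_cell` the cell radius.
#'
#' @param L Cell-surface-to-sensor distance, micrometers, `>= 0`.
#' @param L_cell Cell radius, micrometers, `>= 0`.
#' @return An object of class `diffusion_geometry` with derived `L_eff`.
#' @export
diffusion_geometry <- function(L, L_cell) {
  stopifnot(is.numeric(L), is.numeric(L_cell), L >= 0, L_cell >= 0)
  structure(list(L = L, L_cell = L_cell, L_eff = L + L_cell),
            class = "diffusion_geometry")
}

#' Concentration field of an instantaneous point release
#'
#' Radially symmetric heat-kernel solution with first-order decay. Lengths
#' are given in micrometers and times in seconds; the result is in mol/L.
#'
#' @param r Radial distance(s) from the source, micrometers.
#' @param t Time(s) since release, seconds, strictly positive.
#' @param params A [diffusion_params()] object.
#' @return Concentration in mol/L, recycled over `r` and `t`.
#' @export
concentration_field <- function(r, t, params) {
  stopifnot(inherits(params, "diffusion_params"), is.numeric(r), is.numeric(t))
  if (any(t <= 0)) stop("`t` must be strictly positive (s)")
  if (any(r < 0)) stop("`r` must be non-negative (um)")
  D <- params$D * 1e-4          # cm^2/s -> m^2/s
  rm <- r * 1e-6                # um -> m
  mol_per_m3 <- params$M / (sqrt(4 * pi * D * t))^3 *
    exp(-rm^2 / (4 * D * t) - params$K * t)
  mol_per_m3 / 1000             # -> mol/L
}

#' Sensor adsorption/desorption rate constants
#'
#' Forward (`k_f`, 1/(M s)) and backward (`k_r`, 1/s) rate constants of
#' H2O2 binding to the nanotube sensor. Their ratio `k_r/k_f` is the
#' dissociation constant `K_D` of the paired equilibrium calibration. The
#' quench relaxation rate at concentration `c` is `k_s = k_r + k_f c`.
#'
#' @param k_f Forward rate constant, 1/(M s), positive.
#' @param k_r Backward rate constant, 1/s, positive.
#' @return An object of class `sensor_kinetics`.
#' @export
sensor_kinetics <- function(k_f, k_r) {
  stopifnot(is.numeric(k_f), is.numeric(k_r))
  if (k_f <= 0 || k_r <= 0) stop("rate constants must be positive")
  structure(list(k_f = k_f, k_r = k_r, K_D = k_r / k_f),
            class = "sensor_kinetics")
}

#' Default sensor kinetics consistent with the equilibrium calibration
#'
#' Only the ratio `k_r/k_f = K_D = 0.00204 M` is fixed by equilibrium data.
#' The default backward rate `k_r = 4.3e-3` 1/s is set from the observed
#' ~9 min low-concentration response time via `t90 = log(10)/k_s`; `k_f`
#' follows as `k_r / K_D`.
#'
#' @param calibration A [calibration_params()] object supplying `K_D`.
#' @param k_r Backward rate constant, 1/s.
#' @return A [sensor_kinetics()] object.
#' @export
default_kinetics <- function(calibration = default_calibration(),
                             k_r = 4.3e-3) {
  sensor_kinetics(k_f = k_r / calibration$K_D, k_r = k_r)
}

#' Intensity trace container
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param intensities Intensities (camera counts or normalized), `>= 0`.
#' @param I0 Initial (unquenched) intensity; defaults to the first sample.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, intensities, I0 = intensities[1]) {
  stopifnot(is.numeric(times), is.numeric(intensities),
            length(times) == length(intensities))
  if (length(times) && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (!is.finite(I0) || I0 <= 0) stop("`I0` must be positive")
  structure(list(times = times, intensities = intensities, I0 = I0),
            class = "intensity_trace")
}

#' Forward sensor intensity under constant analyte concentration
#'
#' Closed-form solution of the first-order binding kinetics at constant
#' concentration `c`:
#' \deqn{I(t) = \frac{I_0}{k_s}\left(k_r + k_f c\, e^{-k_s t}\right), \quad
#'   k_s = k_r + k_f c.}
#' Starts at `I0`, decays monotonically to `I0 k_r / k_s`.
#'
#' @param t Time(s) in seconds, `>= 0`.
#' @param conc Analyte concentration in mol/L, `>= 0` (scalar).
#' @param kin A [sensor_kinetics()] object.
#' @param I0 Initial intensity (counts).
#' @return Intensity at `t`, same length as `t`.
#' @export
intensity_forward <- function(t, conc, kin, I0 = 1) {
  stopifnot(inherits(kin, "sensor_kinetics"), is.numeric(t), is.numeric(conc),
            length(conc) == 1)
  if (conc < 0) stop("`conc` must be >= 0")
  if (any(t < 0)) stop("`t` must be >= 0")
  ks <- kin$k_r + kin$k_f * conc
  I0 / ks * (kin$k_r + kin$k_f * conc * exp(-ks * t))
}

# Moving least-squares polynomial smoother and derivative (Savitzky-Golay
# with exact edge handling: at each sample a degree-`degree` polynomial is
# fitted to the window clipped to the trace, and the value/slope taken at
# that sample). Interior samples use precomputed convolution weights.
savgol <- function(y, dt, window = 21, degree = 2) {
  n <- length(y)
  if (window %% 2 == 0) window <- window + 1
  if (window > n) window <- if (n %% 2) n else n - 1
  if (window < degree + 2)
    stop("trace too short for the derivative stencil")
  h <- (window - 1) / 2
  k <- seq(-h, h)
  X <- outer(k, 0:degree, `^`)
  W <- solve(crossprod(X), t(X))      # (degree+1) x window
  sm <- stats::filter(y, rev(W[1, ]), sides = 2)
  dv <- stats::filter(y, rev(W[2, ]), sides = 2) / dt
  sm <- as.numeric(sm); dv <- as.numeric(dv)
  for (i in c(seq_len(h), seq(n - h + 1, n))) {   # edges: asymmetric windows
    lo <- max(1, i - h); hi <- min(n, i + h)
    kk <- seq(lo, hi) - i
    Xi <- outer(kk, 0:degree, `^`)
    ci <- solve(crossprod(Xi), crossprod(Xi, y[lo:hi]))
    sm[i] <- ci[1]
    dv[i] <- ci[2] / dt
  }
  list(smooth = sm, deriv = dv)
}

#' Invert an intensity trace to a concentration trace
#'
#' Pointwise inversion of the binding kinetics: with `y = I/I0`,
#' \deqn{[\mathrm{H_2O_2}](t) = \frac{1}{k_f}\frac{1}{y}
#'   \left[k_r (1 - y) - \frac{dy}{dt}\right].}
#' The derivative is taken from a moving quadratic (Savitzky-Golay) fit,
#' which also smooths `y`; the window is configurable because the inversion
#' amplifies frame noise through `dI/dt`. Negative estimates (noise) are
#' clipped to zero and counted.
#'
#' @param trace An [intensity_trace()] object with strictly positive
#'   intensities.
#' @param kin A [sensor_kinetics()] object.
#' @param smoothing_window Odd window length in frames for the moving
#'   quadratic fit (default 21).
#' @return Data frame with columns `time_s` and `conc_M`, with attributes
#'   `n_clipped` (number of negative estimates clipped) and `clipped`
#'   (logical vector).
#' @export
invert_concentration <- function(trace, kin, smoothing_window = 21) {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(kin, "sensor_kinetics"))
  I <- trace$intensities
  if (any(I <= 0)) stop("intensity trace touches zero: cannot invert")
  n <- length(I)
  if (n < 5) stop("trace too short for the derivative stencil")
  dt <- diff(trace$times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("invert_concentration expects uniform sampling")
  y <- I / trace$I0
  sg <- savgol(y, dt[1], window = smoothing_window, degree = 2)
  ysm <- pmax(sg$smooth, .Machine$double.eps)
  conc <- (kin$k_r * (1 - ysm) - sg$deriv) / (kin$k_f * ysm)
  clipped <- conc < 0
  conc[clipped] <- 0
  out <- data.frame(time_s = trace$times, conc_M = conc)
  attr(out, "n_clipped") <- sum(clipped)
  attr(out, "clipped") <- clipped
  out
}

#' Convert a local concentration history to a per-cell efflux rate
#'
#' The sensed end-of-window concentration is multiplied by a reference
#' single-cell volume and divided by the measurement window:
#' `rate = C_end * V / window`, reported in attomole/cell/min. The default
#' `statistic = "end"` averages the trailing `tail_fraction` of the window
#' as a noise-robust estimate of the end value; `"max"` and `"mean"` are
#' selectable alternatives.
#'
#' @param conc_trace Data frame with `time_s` and `conc_M` (as returned by
#'   [invert_concentration()]).
#' @param cell_volume Reference cell volume in m^3 (see [monocyte_volume()]).
#' @param window Measurement window in seconds.
#' @param statistic One of `"end"`, `"max"`, `"mean"`.
#' @param tail_fraction Fraction of the window averaged for `"end"`.
#' @return Efflux rate in attomole/cell/min (clipped at 0).
#' @export
efflux_rate <- function(conc_trace, cell_volume, window,
                        statistic = c("end", "max", "mean"),
                        tail_fraction = 0.1) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(conc_trace),
            all(c("time_s", "conc_M") %in% names(conc_trace)))
  if (nrow(conc_trace) == 0) stop("empty concentration trace")
  if (!is.finite(window) || window <= 0) stop("`window` must be > 0 (s)")
  if (!is.finite(cell_volume) || cell_volume <= 0)
    stop("`cell_volume` must be > 0 (m^3)")
  conc <- conc_trace$conc_M
  c_use <- switch(statistic,
    end = {
      t_end <- max(conc_trace$time_s)
      mean(conc[conc_trace$time_s >= t_end - tail_fraction * window])
    },
    max = max(conc),
    mean = mean(conc))
  mol_per_m3 <- c_use * 1000          # mol/L -> mol/m^3
  mol <- mol_per_m3 * cell_volume     # mol accumulated over the window
  rate_amol_min <- mol / (window / 60) * 1e18
  max(rate_amol_min, 0)
}

#' Reference monocyte volume
#'
#' Sphere volume `(pi/6) d^3` for a cell of diameter `d` micrometers, in m^3.
#' At the 20 um reference diameter this is 4.19e-15 m^3 (printed elsewhere in
#' truncated form as 4.18e-15).
#'
#' @param diameter Cell diameter in micrometers, `>= 0`.
#' @return Volume in m^3.
#' @export
monocyte_volume <- function(diameter = 20) {
  stopifnot(is.numeric(diameter))
  if (any(diameter < 0)) stop("`diameter` must be >= 0 (um)")
  pi / 6 * (diameter * 1e-6)^3
}

#' Read / write intensity traces as CSV
#'
#' Traces are exchanged as CSV with columns `time_s`, `intensity` and
#' optional `background`.
#'
#' @param path File path.
#' @return Data frame with the trace columns.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "intensity") %in% names(df)))
  df
}

#' @rdname read_trace_csv
#' @param trace Data frame with `time_s`, `intensity`, optional `background`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
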