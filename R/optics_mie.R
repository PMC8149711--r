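#' Optical target for the lensing forward model
#'
#' A homogeneous dielectric sphere or spheroid standing in for a cell: the
#' photonic-nanojet regime requires a refractive-index ratio below 2 and a
#' diameter of a few to a few tens of wavelengths.
#'
#' @param radius Transverse radius in micrometers, positive.
#' @param z_semiaxis Semi-axis along the propagation direction, micrometers;
#'   equals `radius` for a sphere.
#' @param n_rel Refractive-index ratio target/medium. A warning is issued
#'   outside the nanojet regime \[1, 2).
#' @param n_medium Absolute refractive index of the surrounding medium
#'   (water-like 1.33 by default).
#' @return An object of class `optical_target`.
#' @export
optical_target <- function(radius, z_semiaxis = radius, n_rel,
                           n_medium = 1.33) {
  stopifnot(is.numeric(radius), is.numeric(z_semiaxis), is.numeric(n_rel),
            is.numeric(n_medium))
  if (radius <= 0 || z_semiaxis <= 0) stop("target semi-axes must be positive")
  if (n_rel < 1 || n_rel >= 2)
    warning("n_rel outside the photonic-nanojet regime [1, 2)")
  ecc <- if (z_semiaxis <= radius)
    sqrt(1 - (z_semiaxis / radius)^2) else sqrt(1 - (radius / z_semiaxis)^2)
  structure(list(radius = radius, z_semiaxis = z_semiaxis, n_rel = n_rel,
                 n_medium = n_medium, eccentricity = ecc),
            class = "optical_target")
}

# ---- Lorenz-Mie machinery (Bohren & Huffman conventions, exp(-i w t)) ----

# Mie coefficients a_n, b_n for size parameter x and relative index m.
# Logarithmic derivative by downward recurrence; Riccati-Bessel psi, chi by
# upward recurrence (stable for real x in this size range).
mie_coefficients <- function(x, m, nmax = NULL) {
  if (is.null(nmax)) nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- max(nmax, ceiling(abs(m) * x)) + 16
  D <- numeric(nmx)
  for (k in seq(nmx - 1, 1)) {
    a <- (k + 1) / (m * x)
    D[k] <- a - 1 / (D[k + 1] + a)
  }
  n <- seq_len(nmax)
  psi <- numeric(nmax); chi <- numeric(nmax)
  p2 <- cos(x); p1 <- sin(x)    # psi_{-1}, psi_0
  c2 <- -sin(x); c1 <- cos(x)   # chi_{-1}, chi_0
  for (k in n) {
    pk <- (2 * k - 1) / x * p1 - p2
    ck <- (2 * k - 1) / x * c1 - c2
    psi[k] <- pk; chi[k] <- ck
    p2 <- p1; p1 <- pk
    c2 <- c1; c1 <- ck
  }
  psim1 <- c(sin(x), psi[-nmax])
  chim1 <- c(cos(x), chi[-nmax])
  xim1 <- psim1 - 1i * chim1
  xi <- psi - 1i * chi
  Dm <- D[n]
  an <- ((Dm / m + n / x) * psi - psim1) / ((Dm / m + n / x) * xi - xim1)
  bn <- ((Dm * m + n / x) * psi - psim1) / ((Dm * m + n / x) * xi - xim1)
  list(a = an, b = bn, nmax = nmax)
}

# Riccati-Bessel xi_n(rho) = rho h_n^(1)(rho) and derivative, for a vector
# of radii; returns n_points x nmax matrices.
ricatti_xi <- function(rho, nmax) {
  np <- length(rho)
  xi <- matrix(0i, np, nmax); dxi <- matrix(0i, np, nmax)
  xim2 <- cos(rho) + 1i * sin(rho)       # xi_{-1} = psi_{-1} - i chi_{-1}
  xim1 <- sin(rho) - 1i * cos(rho)       # xi_0
  for (k in seq_len(nmax)) {
    xik <- (2 * k - 1) / rho * xim1 - xim2
    xi[, k] <- xik
    dxi[, k] <- xim1 - k / rho * xik
    xim2 <- xim1; xim1 <- xik
  }
  list(xi = xi, dxi = dxi)
}

# Angular functions pi_n(mu), tau_n(mu) by recurrence; mu = cos(theta).
angular_pitau <- function(mu, nmax) {
  np <- length(mu)
  pin <- matrix(0, np, nmax); taun <- matrix(0, np, nmax)
  pi_prev <- rep(0, np)   # pi_0
  pi_cur <- rep(1, np)    # pi_1
  for (k in seq_len(nmax)) {
    pin[, k] <- pi_cur
    taun[, k] <- k * mu * pi_cur - (k + 1) * pi_prev
    pi_next <- ((2 * k + 1) * mu * pi_cur - (k + 1) * pi_prev) / k
    pi_prev <- pi_cur; pi_cur <- pi_next
  }
  list(pin = pin, taun = taun)
}

# Unpolarized external intensity |E|^2 (incident = 1) at points given by
# spherical coordinates (r_um, theta) around the sphere center, theta
# measured from the propagation axis. The average over the two incident
# linear polarizations is exactly independent of azimuth, so only (r, theta)
# are needed.
mie_external_intensity <- function(r_um, theta, radius, n_rel,
                                   n_medium = 1.33, lambda = 1.0) {
  k <- 2 * pi * n_medium / lambda
  x <- k * radius
  if (x > 150)
    stop("size parameter ", round(x, 1), " beyond series truncation safety",
         " (150); use propagate_through_target()")
  ab <- mie_coefficients(x, n_rel)
  nmax <- ab$nmax
  n <- seq_len(nmax)
  En <- (0+1i)^n * (2 * n + 1) / (n * (n + 1))
  ca <- En * 1i * ab$a
  cb <- En * ab$b
  rho <- k * r_um
  if (any(rho <= x)) stop("evaluation points must lie outside the sphere")
  rb <- ricatti_xi(rho, nmax)
  pt <- angular_pitau(cos(theta), nmax)
  st <- sin(theta)
  Ar <- as.vector((rb$xi * pt$pin) %*% (ca * n * (n + 1))) * st / rho^2
  At <- as.vector((rb$dxi * pt$taun) %*% ca - (rb$xi * pt$pin) %*% cb) / rho
  Ap <- as.vector((rb$dxi * pt$pin) %*% ca - (rb$xi * pt$taun) %*% cb) / rho
  einc <- exp(1i * k * r_um * cos(theta))
  Ar <- Ar + st * einc
  At <- At + cos(theta) * einc
  Ap <- Ap + einc
  0.5 * (Mod(Ar)^2 + Mod(At)^2 + Mod(Ap)^2)
}

#' Lorenz-Mie near-field map of a dielectric sphere
#'
#' Exact series solution for the external intensity of a plane wave scattered
#' by a homogeneous sphere, evaluated on a meridional half-plane (axial
#' coordinate `z` from the sphere center along propagation, transverse radius
#' `x >= 0`). The unpolarized camera observable (average of the two incident
#' polarizations) is returned, normalized to unit incident intensity. The
#' series is truncated at `x + 4 x^(1/3) + 2` terms.
#'
#' @param target An [optical_target()]; must be a sphere
#'   (`z_semiaxis == radius`).
#' @param lambda Vacuum wavelength in micrometers.
#' @param z Axial sample positions (um from sphere center); defaults to a
#'   0.25 um grid from just outside the sphere to 150 um.
#' @param x Transverse sample positions (um, `>= 0`); defaults to a 0.05 um
#'   grid to 12 um.
#' @return An object of class `field_map`: list with `z`, `x`, `intensity`
#'   (length(z) x length(x) matrix), `lambda`, `n_medium`, `target`,
#'   `solver = "mie"`.
#' @export
mie_near_field <- function(target, lambda = 1.0, z = NULL, x = NULL) {
  stopifnot(inherits(target, "optical_target"))
  if (abs(target$z_semiaxis - target$radius) > 1e-9)
    stop("mie_near_field handles spheres only; use propagate_through_target() for spheroids")
  size_par <- 2 * pi * target$n_medium * target$radius / lambda
  if (size_par > 150)
    stop("size parameter ", round(size_par, 1),
         " beyond series truncation safety (150); use propagate_through_target()")
  if (is.null(z)) z <- seq(target$radius + 0.5, 150, by = 0.25)
  if (is.null(x)) x <- seq(0, 12, by = 0.05)
  stopifnot(all(x >= 0))
  pts_z <- rep(z, times = length(x))
  pts_x <- rep(x, each = length(z))
  r <- sqrt(pts_z^2 + pts_x^2)
  theta <- atan2(pts_x, pts_z)
  I <- mie_external_intensity(r, theta, target$radius, target$n_rel,
                              target$n_medium, lambda)
  structure(list(z = z, x = x,
                 intensity = matrix(I, nrow = length(z)),
                 lambda = lambda, n_medium = target$n_medium,
                 target = target, solver = "mie"),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "field_map (%s): %d z x %d x samples, z in [%.1f, %.1f] um, peak %.2f\n",
    x$solver, length(x$z), length(x$x), min(x$z), max(x$z), max(x$intensity)))
  invisible(x)
}

# Transverse intensity profile of a sphere at its best focus (on-axis
# intensity maximum beyond the surface). Used by the renderer and the sweep.
# Returns list(r, intensity, z_focus, enhancement).
mie_focal_profile <- function(radius, n_rel, n_medium = 1.33, lambda = 1.0,
                              r_max = 14, dr = 0.05, z_max = 220) {
  zs <- seq(radius + 0.5, z_max, by = 0.5)
  Iax <- mie_external_intensity(zs, rep(0, length(zs)), radius, n_rel,
                                n_medium, lambda)
  i0 <- which.max(Iax)
  # refine the axial peak on a finer grid around the coarse maximum
  zf0 <- zs[i0]
  zs2 <- seq(max(radius + 0.3, zf0 - 1), min(z_max, zf0 + 1), by = 0.1)
  Iax2 <- mie_external_intensity(zs2, rep(0, length(zs2)), radius, n_rel,
                                 n_medium, lambda)
  zf <- zs2[which.max(Iax2)]
  r <- seq(0, r_max, by = dr)
  rr <- sqrt(zf^2 + r^2)
  th <- atan2(r, zf)
  I <- mie_external_intensity(rr, th, radius, n_rel, n_medium, lambda)
  list(r = r, intensity = I, z_focus = zf, enhancement = max(Iax2))
}
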