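test_that("heat kernel conserves mass and decays exponentially", {
  dp <- diffusion_params(M = 2.5e-18, K = 0)
  for (t in c(1e-3, 0.01, 0.1)) {
    # 4 pi int r^2 C dr over all space = M (radial quadrature, mol/L -> SI)
    f <- function(r_um) {
      4 * pi * (r_um * 1e-6)^2 *
        concentration_field(r_um, t, dp) * 1000 * 1e-6
    }
    mass <- stats::integrate(f, 0, 2000, rel.tol = 1e-10)$value
    expect_equal(mass, dp$M, tolerance = 1e-3)
  }
  # decay factor identity: C_K = C_0 * exp(-K t) exactly
  dk <- diffusion_params(M = 2.5e-18, K = 6.93e-4)
  d0 <- diffusion_params(M = 2.5e-18, K = 0)
  r <- c(5, 10, 20); t <- 0.37
  expect_equal(concentration_field(r, t, dk),
               concentration_field(r, t, d0) * exp(-dk$K * t),
               tolerance = 1e-12)
})

test_that("field peaks at t* = r^2/(6D) and matches the printed transport ratio", {
  dp <- diffusion_params(M = 1e-18, K = 0)
  r <- 12
  D_um2 <- dp$D * 1e8       # cm^2/s -> um^2/s
  tstar <- r^2 / (6 * D_um2)
  tg <- tstar * seq(0.2, 3, length.out = 2000)
  cc <- concentration_field(r, tg, dp)
  expect_equal(tg[which.max(cc)], tstar, tolerance = 3e-3)
  # ratio of the field at the sensor (14.1 um) vs the cell surface (10 um)
  # at the 10 ms transport time
  dpK <- diffusion_params(M = 1e-18)
  ratio <- concentration_field(14.1, 0.01, dpK) /
    concentration_field(10, 0.01, dpK)
  expect_equal(ratio, 0.193, tolerance = 0.002)
  expect_error(concentration_field(10, 0, dpK), "positive")
})

test_that("both decay-constant conventions are exposed", {
  expect_equal(diffusion_params()$K, 6.93e-4)
  expect_equal(diffusion_params(decay = "half_life", half_life = 1e-3)$K,
               log(2) / 1e-3)
  g <- diffusion_geometry(L = 5, L_cell = 9.3)
  expect_equal(g$L_eff, 14.3)
})

test_that("forward intensity follows the binding-kinetics solution", {
  kin <- default_kinetics()
  expect_equal(kin$K_D, 0.00204, tolerance = 1e-12)
  expect_equal(intensity_forward(0, 1e-3, kin, I0 = 1234), 1234,
               tolerance = 1e-9)
  # at c = K_D the asymptote is I0/2
  expect_equal(intensity_forward(1e9, kin$K_D, kin, I0 = 100), 50,
               tolerance = 1e-6)
  # zero concentration leaves the sensor untouched
  tt <- seq(0, 500, by = 10)
  expect_equal(intensity_forward(tt, 0, kin, I0 = 7), rep(7, length(tt)))
  # monotone decay towards I0 k_r / k_s
  y <- intensity_forward(tt, 5e-3, kin, I0 = 1)
  expect_true(all(diff(y) < 0))
  expect_gt(min(y), kin$k_r / (kin$k_r + kin$k_f * 5e-3) - 1e-9)
})

test_that("concentration inversion is the exact inverse of the forward model", {
  kin <- default_kinetics()
  tt <- seq(0, 600, by = 1)
  for (conc in c(1e-8, 1e-6, 1e-4, 1e-3, 1e-2)) {
    tr <- intensity_trace(tt, intensity_forward(tt, conc, kin, I0 = 1),
                          I0 = 1)
    est <- invert_concentration(tr, kin)
    interior <- 30:570
    expect_lt(max(abs(est$conc_M[interior] / conc - 1)), 0.01)
  }
})

test_that("inversion handles algebraic anchor cases and bad input", {
  kin <- default_kinetics()
  tt <- seq(0, 100, by = 1)
  # constant trace at I0: both bracket terms vanish
  est0 <- invert_concentration(intensity_trace(tt, rep(5, 101), I0 = 5), kin)
  expect_lt(max(abs(est0$conc_M)), 1e-12)
  # constant trace at I0/2: c = k_r/k_f = K_D
  est5 <- invert_concentration(intensity_trace(tt, rep(2.5, 101), I0 = 5),
                               kin)
  expect_equal(mean(est5$conc_M), kin$K_D, tolerance = 1e-6)
  expect_error(invert_concentration(
    intensity_trace(tt[1:4], rep(1, 4), I0 = 1), kin), "short")
  expect_error(intensity_trace(tt, c(rep(1, 100), -1)), ">= 0")
})

test_that("noisy traces invert within 10% at SNR 20", {
  kin <- default_kinetics()
  tt <- seq(0, 600, by = 1.2)
  conc <- 8e-4
  clean <- intensity_forward(tt, conc, kin, I0 = 1)
  quench_depth <- 1 - min(clean)
  errs <- withr::with_seed(42, replicate(20, {
    noisy <- clean + stats::rnorm(length(tt), 0, quench_depth / 20)
    est <- invert_concentration(intensity_trace(tt, pmax(noisy, 1e-3),
                                                I0 = 1), kin)
    tail_mean <- mean(est$conc_M[tt >= 540])
    tail_mean / conc - 1
  }))
  expect_lt(abs(mean(errs)), 0.1)
  # negative estimates were clipped and counted, not dropped
  expect_true(is.numeric(attr(invert_concentration(
    intensity_trace(tt, pmax(clean + stats::rnorm(length(tt), 0, 0.01),
                             1e-3), I0 = 1), kin), "n_clipped")))
})

test_that("efflux conversion matches the worked example and scales", {
  tt <- seq(0, 600, by = 1)
  tr175 <- data.frame(time_s = tt, conc_M = rep(175e-6, length(tt)))
  v <- 4.18e-15
  expect_equal(efflux_rate(tr175, v, 600), 73.15, tolerance = 1e-3)
  expect_equal(efflux_rate(data.frame(time_s = tt, conc_M = 0), v, 600), 0)
  # doubling the window at fixed end concentration halves the rate
  expect_equal(efflux_rate(tr175, v, 1200), 73.15 / 2, tolerance = 1e-3)
  expect_error(efflux_rate(tr175[0, ], v, 600), "empty")
  # alternative statistics are selectable
  ramp <- data.frame(time_s = tt, conc_M = seq(0, 200e-6, length.out = 601))
  expect_gt(efflux_rate(ramp, v, 600, statistic = "max"),
            efflux_rate(ramp, v, 600, statistic = "mean"))
})

test_that("reference cell volume is the sphere volume", {
  expect_equal(monocyte_volume(20), pi / 6 * (20e-6)^3)
  expect_equal(monocyte_volume(0), 0)
  # cube scaling across a decade of diameter
  expect_equal(monocyte_volume(2), monocyte_volume(20) / 1000,
               tolerance = 1e-12)
})
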