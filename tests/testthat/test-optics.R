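test_that("no scatterer means unit intensity everywhere", {
  tg <- optical_target(radius = 8, n_rel = 1.0)
  fm <- mie_near_field(tg, z = seq(9, 40, by = 1), x = seq(0, 8, by = 0.5))
  expect_lt(max(abs(fm$intensity - 1)), 1e-6)
})

test_that("Mie solver rejects invalid geometry and sizes", {
  expect_error(mie_near_field(optical_target(8, 6, 1.04)), "spheres only")
  big <- optical_target(radius = 25, n_rel = 1.04)
  expect_error(mie_near_field(big), "size parameter")
  expect_warning(optical_target(5, n_rel = 2.5), "nanojet")
})

test_that("Mie and angular-spectrum solvers agree on spheres within 15%", {
  cases <- list(c(7.5, 1.04), c(6, 1.06))
  for (cs in cases) {
    fp <- memo(paste0("miefp_", cs[1], "_", cs[2]),
               ncckit:::mie_focal_profile(cs[1], cs[2]))
    fw_mie <- ncckit:::profile_fwhm(fp$r, fp$intensity)
    tg <- optical_target(cs[1], n_rel = cs[2])
    fa <- propagate_through_target(tg, grid = list(n = 256, extent = 40,
                                                   dz = 0.25, z_max = 130,
                                                   dz_out = 0.5))
    nm <- nanojet_metrics(fa, "focus")
    expect_lt(abs(nm$enhancement / fp$enhancement - 1), 0.15)
    expect_lt(abs(nm$fwhm / fw_mie - 1), 0.15)
    expect_lt(abs(nm$focal_distance / fp$z_focus - 1), 0.15)
  }
})

test_that("free-space angular-spectrum steps conserve energy", {
  flux <- ncckit:::asm_energy_check(steps = c(5, 20, 50))
  expect_true(all(abs(flux - 1) < 0.01))
})

test_that("propagation grid resolution is enforced", {
  tg <- optical_target(6, n_rel = 1.04)
  expect_error(propagate_through_target(tg, grid = list(n = 64, extent = 40)),
               "too coarse")
})

test_that("an oblate spheroid lenses more weakly than the equal-radius sphere", {
  sph <- optical_target(6, n_rel = 1.05)
  obl <- optical_target(6, z_semiaxis = 3.5, n_rel = 1.05)
  g <- list(n = 256, extent = 40, dz = 0.25, z_max = 130, dz_out = 0.5)
  ms <- nanojet_metrics(propagate_through_target(sph, grid = g), "focus")
  mo <- nanojet_metrics(propagate_through_target(obl, grid = g), "focus")
  expect_lt(mo$enhancement, ms$enhancement)
})

test_that("enhancement grows and FWHM shrinks with index contrast", {
  rads <- 8
  ns <- c(1.02, 1.04, 1.06, 1.08)
  mets <- lapply(ns, function(n)
    memo(paste0("mono_", n), ncckit:::mie_focal_profile(rads, n)))
  enh <- vapply(mets, `[[`, 0, "enhancement")
  fw <- vapply(mets, function(m)
    ncckit:::profile_fwhm(m$r, m$intensity), 0)
  expect_true(all(diff(enh) > 0))
  expect_true(all(diff(fw) < 0))
})

test_that("nanojet metrics recover closed-form synthetic profiles", {
  # Gaussian transverse profile: FWHM = 2.3548 sigma
  sig <- 1.3
  x <- seq(0, 10, by = 0.01)
  z <- seq(10, 30, by = 0.5)
  prof <- 1 + 8 * exp(-x^2 / (2 * sig^2))
  zshape <- exp(-(z - 20)^2 / 18)
  fm <- structure(list(z = z, x = x,
                       intensity = 1 + outer(zshape, prof - 1),
                       lambda = 1, n_medium = 1.33, solver = "synthetic"),
                  class = "field_map")
  nm <- nanojet_metrics(fm, "focus")
  expect_equal(nm$focal_distance, 20)
  expect_equal(nm$fwhm, 2 * sqrt(2 * log(2)) * sig, tolerance = 1e-3)
  expect_equal(nm$enhancement, 9, tolerance = 1e-6)
  # jinc-squared (Airy) profile: first ring at the first secondary maximum
  airy <- function(r) ifelse(r == 0, 1, (2 * besselJ(r, 1) / r)^2)
  xa <- seq(0, 15, by = 0.005)
  fma <- structure(list(z = z, x = xa,
                        intensity = 1 + outer(zshape, 9 * airy(xa * 2))),
                   class = "field_map")
  fma$n_medium <- 1.33
  nma <- nanojet_metrics(fma, "focus")
  # first secondary maximum of the Airy pattern at x = 5.136/2
  expect_equal(nma$airy_radii[1], 5.13562 / 2, tolerance = 0.01)
  # uniform field is flagged instead of yielding a width
  fmu <- structure(list(z = z, x = x,
                        intensity = matrix(1, length(z), length(x)),
                        n_medium = 1.33),
                   class = "field_map")
  nmu <- nanojet_metrics(fmu, 20)
  expect_true(nmu$flat)
  expect_true(is.na(nmu$fwhm))
  expect_equal(nmu$enhancement, 1)
})

test_that("run_sweep fills the grid, caches, and records failures", {
  path <- withr::local_tempfile(fileext = ".csv")
  sw <- run_sweep(radii = c(7, 8), n_rels = c(1.03, 1.05),
                  cache_path = path)
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$status == "ok"))
  expect_true(all(sw$enhancement >= 1))
  # reload from cache is identical
  sw2 <- run_sweep(radii = c(7, 8), n_rels = c(1.03, 1.05),
                   cache_path = path)
  expect_equal(sw2$fwhm, sw$fwhm, tolerance = 1e-6)
  # a failing cell (size parameter too large) is recorded, sweep continues
  sw3 <- run_sweep(radii = c(7, 40), n_rels = 1.04)
  expect_equal(sum(sw3$status == "ok"), 1)
  expect_match(sw3$status[sw3$radius == 40], "size parameter")
})

test_that("refractive-index estimation round-trips through the sweep", {
  sw <- test_sweep()
  # interpolation identity at a grid node
  node <- sw[sw$radius == 9 & sw$n_rel == 1.04, ]
  est <- estimate_ri(node$fwhm, node$enhancement, 18, sw)
  expect_equal(est$n_rel, 1.04, tolerance = 1e-3)
  expect_equal(est$ri, 1.04 * 1.33, tolerance = 2e-3)
  expect_lt(est$goodness, 1e-6)
  # joint inversion identity at a node
  inv <- invert_lensing(node$fwhm, node$enhancement, sw)
  expect_equal(inv$diameter, 18, tolerance = 0.1)
  expect_equal(inv$n_rel, 1.04, tolerance = 1e-3)
  # unphysical queries are rejected
  expect_error(estimate_ri(3, 0.8, 18, sw), "hull")
  expect_error(estimate_ri(3, 5, 60, sw), "radius range")
})

test_that("forward model at an off-grid index inverts to that index", {
  sw <- test_sweep()
  scene <- scene_spec()
  m <- ncckit:::measure_render(ref_cell(n_rel = 1.0398), scene, "physical")
  est <- estimate_ri(m$fwhm, m$enhancement, 18.574, sw)
  expect_equal(est$ri, 1.383, tolerance = 0.005)
})
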