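test_that("sampled populations match their specified moments", {
  spec <- population_spec("+PMA", n_cells = 10000, seed = 21)
  pop <- sample_population(spec)
  # mean area within 3 SEM at n = 1e4 (sd 24 -> SEM 0.24)
  expect_equal(mean(pop$area_um2), 263, tolerance = 1 / 263)
  expect_equal(stats::sd(pop$area_um2), 24, tolerance = 0.05)
  # truncated-normal calibration hits the printed means
  expect_equal(mean(pop$eccentricity), 0.363, tolerance = 0.01 / 0.363)
  expect_equal(mean(pop$ri), 1.377, tolerance = 0.002 / 1.377)
  expect_true(all(pop$ri >= 1.33 & pop$ri <= 1.45))
  expect_true(all(pop$eccentricity >= 0 & pop$eccentricity < 0.95))
  # lognormal rates: mean and sd within sampling error, truncated at 4000
  expect_equal(mean(pop$rate_amol_min), 624, tolerance = 3 * 497 / 100 / 624)
  expect_equal(stats::sd(pop$rate_amol_min), 497, tolerance = 0.06)
  expect_true(all(pop$rate_amol_min >= 0 & pop$rate_amol_min <= 4000))
})

test_that("the non-activated group is an equal-weight area mixture", {
  pop <- sample_population(population_spec("-PMA", n_cells = 10000,
                                           seed = 22))
  expect_equal(mean(pop$area_um2), 271, tolerance = 1.5 / 271)
  expect_equal(stats::sd(pop$area_um2), 29.2, tolerance = 0.05)
  expect_equal(mean(pop$rate_amol_min), 330, tolerance = 3 * 344 / 100 / 330)
})

test_that("sampling is deterministic and degenerate cases behave", {
  s <- population_spec("+PMA", 200, seed = 7)
  expect_identical(sample_population(s), sample_population(s))
  expect_equal(nrow(sample_population(population_spec("+PMA", 0))), 0)
  expect_error(sample_population(population_spec(
    "+PMA", 10, ri = list(mean = 1.5, sd = 0.05, lo = 1.33, hi = 1.45))),
    "infeasible")
  expect_error(sample_population(population_spec(
    "+PMA", 10, rate = list(mean = -5, sd = 100, upper = 4000))),
    "infeasible")
})

test_that("a unit-enhancement parametric patch is flat", {
  scene <- scene_spec(lensing_enh = 1)
  patch <- render_cell_patch(ref_cell(), scene, "parametric")
  expect_lt(diff(range(patch)), 1e-9 * scene$background)
})

test_that("physical and parametric renders of the reference cell agree", {
  scene <- scene_spec()
  pp <- render_cell_patch(ref_cell(), scene, "parametric")
  ph <- render_cell_patch(ref_cell(), scene, "physical")
  # the contrast anchor matches the parametric peak within 15%
  expect_lt(abs(max(ph) / max(pp) - 1), 0.15)
})

test_that("zero-efflux stacks have flat traces", {
  scene <- scene_spec(frame_dim = c(120, 120), n_frames = 50,
                      frame_interval = 1.2, cells_per_stack = 1)
  cell <- sample_population(population_spec("+PMA", 1, seed = 5))
  cell$rate_amol_min <- 0
  rs <- render_stack(cell, scene, seed = 3, mode = "parametric")
  tr <- extract_traces(rs$stack, c(rs$truth$row, rs$truth$col))
  rel <- stats::sd(tr$normalized) / mean(tr$normalized)
  expect_lt(rel, 0.02)   # noise only
})

test_that("rendered stacks are reproducible from the seed", {
  scene <- scene_spec(frame_dim = c(120, 120), n_frames = 5,
                      cells_per_stack = 2)
  cells <- sample_population(population_spec("+PMA", 2, seed = 8))
  a <- render_stack(cells, scene, seed = 31, mode = "parametric")
  b <- render_stack(cells, scene, seed = 31, mode = "parametric")
  expect_identical(a$stack$frames, b$stack$frames)
  c2 <- render_stack(cells, scene, seed = 32, mode = "parametric")
  expect_false(identical(a$stack$frames, c2$stack$frames))
})

test_that("fixtures survive a write/read round trip losslessly", {
  scene <- scene_spec(frame_dim = c(80, 80), n_frames = 4,
                      cells_per_stack = 1)
  cells <- sample_population(population_spec("-PMA", 1, seed = 13))
  rs <- render_stack(cells, scene, seed = 2, mode = "parametric")
  dir <- file.path(withr::local_tempdir(), "fx")
  write_fixture(rs$stack, rs$truth, dir, scene = scene, seed = 2)
  back <- read_fixture(dir)
  expect_equal(back$stack$frames, rs$stack$frames)
  expect_equal(back$stack$pixel_size, scene$pixel_size)
  expect_equal(back$truth$rate_amol_min, rs$truth$rate_amol_min,
               tolerance = 1e-9)
  expect_equal(back$spec$seed, 2)
  # rewriting the same content produces identical files
  dir2 <- file.path(withr::local_tempdir(), "fx2")
  write_fixture(rs$stack, rs$truth, dir2, scene = scene, seed = 2)
  expect_identical(unname(tools::md5sum(file.path(dir, "stack.tif"))),
                   unname(tools::md5sum(file.path(dir2, "stack.tif"))))
})

test_that("frame stacks enforce their intensity and unit invariants", {
  expect_error(frame_stack(array(-1, c(4, 4, 2)), 0.7, 0.1), "within")
  expect_error(frame_stack(array(70000, c(4, 4, 2)), 0.7, 0.1), "within")
  expect_error(frame_stack(array(1, c(4, 4, 2)), -0.7, 0.1), "pixel_size")
  st <- frame_stack(matrix(5, 4, 4), 0.7, 0.1)
  expect_equal(dim(st$frames), c(4, 4, 1))
})
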