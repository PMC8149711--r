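test_that("LoG detection finds rendered cells to pixel accuracy", {
  scene <- test_scene()
  pop <- sample_population(population_spec("+PMA", 4, seed = 3))
  rs <- render_stack(pop[1:4, ], scene_spec(frame_dim = c(220, 220),
                                            n_frames = 1,
                                            cells_per_stack = 4),
                     seed = 9, mode = "parametric")
  frame <- rs$stack$frames[, , 1]
  det <- detect_cells(frame, scene$pixel_size)
  expect_equal(nrow(det), 4)
  m <- match_detections(rs$truth, det, tol_px = 2)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_true(all(m$matches$dist_px < 1.5))
  # a threshold above the global response maximum yields nothing
  expect_equal(nrow(detect_cells(frame, scene$pixel_size,
                                 threshold = 1e9)), 0)
})

test_that("blank noise frames produce almost no false detections", {
  hits <- withr::with_seed(11, replicate(30, {
    frame <- matrix(stats::rnorm(150 * 150, 2000, 50), 150, 150)
    nrow(detect_cells(frame, 0.7))
  }))
  expect_lt(mean(hits > 0), 0.1)
})

test_that("saturated frames trigger a warning", {
  frame <- matrix(2000, 120, 120)
  frame[1:40, 1:40] <- 65535
  expect_warning(detect_cells(frame, 0.7, threshold = 1e8), "saturated")
})

test_that("patch normalization sets the background annulus to one", {
  scene <- scene_spec()
  patch <- render_cell_patch(ref_cell(), scene, "parametric")
  emb <- embed_patch(patch, scene)
  cp <- normalize_patch(emb$frame, emb$centroid, scene$pixel_size)
  # background annulus mean ~ 1 after normalization
  rr <- sqrt((row(cp$raw) - cp$center_raw[1])^2 +
             (col(cp$raw) - cp$center_raw[2])^2) * cp$pixel_size
  ann <- rr >= cp$bg_inner & rr <= cp$patch_radius - 0.5
  expect_equal(mean(cp$raw[ann]), 1, tolerance = 0.02)
  # scaling the frame by 3x leaves the normalized patch unchanged
  cp3 <- normalize_patch(emb$frame * 3, emb$centroid, scene$pixel_size)
  expect_equal(cp3$fine, cp$fine, tolerance = 1e-9)
  expect_equal(cp3$bg_value, 3 * cp$bg_value, tolerance = 1e-9)
  # patches clipped by the frame edge are refused
  expect_error(normalize_patch(emb$frame, c(3, 3), scene$pixel_size),
               "clipped")
})

test_that("profile metrics recover the parametric defaults", {
  scene <- scene_spec()
  patch <- render_cell_patch(ref_cell(), scene, "parametric")
  emb <- embed_patch(patch, scene)
  cp <- normalize_patch(emb$frame, emb$centroid, scene$pixel_size)
  pm <- profile_metrics(cp)
  expect_equal(pm$fwhm, 3.37, tolerance = 0.05 / 3.37)
  expect_equal(pm$enhancement, 9.43, tolerance = 0.3 / 9.43)
  expect_gt(length(pm$airy_radii), 0)
  # ring spacing matches the renderer geometry (0.132 d); the innermost
  # ring rides the Gaussian shoulder, so the first *detected* maximum is
  # the second ring at (0.199 + 0.132) d
  expect_equal(pm$airy_radii[1], (0.199 + 0.132) * 18.574, tolerance = 0.1)
  # a pure background patch has no peak
  flat <- matrix(2000, 41, 41) + withr::with_seed(4, stats::rnorm(41 * 41, 0, 5))
  frame <- rbind(cbind(flat, flat), cbind(flat, flat))
  cpf <- normalize_patch(frame, c(40, 40), scene$pixel_size,
                         patch_radius = 13)
  expect_error(profile_metrics(cpf), "peak")
})

test_that("shape statistics are scale and rotation invariant", {
  scene <- scene_spec()
  patch <- render_cell_patch(ref_cell(ecc = 0.45, orientation = 0.6),
                             scene, "parametric")
  emb <- embed_patch(patch, scene)
  cp <- normalize_patch(emb$frame, emb$centroid, scene$pixel_size)
  sh <- measure_shape(cp)
  # 90 degree rotation: transpose + reverse rows
  rot <- t(emb$frame)[rev(seq_len(ncol(emb$frame))), ]
  ctr_rot <- c(nrow(rot) - 1 - emb$centroid[2], emb$centroid[1])
  cpr <- normalize_patch(rot, ctr_rot, scene$pixel_size)
  shr <- measure_shape(cpr)
  expect_equal(shr$contour_area, sh$contour_area,
               tolerance = 0.01 * sh$contour_area)
  expect_equal(shr$eccentricity, sh$eccentricity, tolerance = 0.03)
  # intensity scaling changes nothing (normalization divides it out)
  cps <- normalize_patch(emb$frame * 2.5, emb$centroid, scene$pixel_size)
  shs <- measure_shape(cps)
  expect_equal(shs$contour_area, sh$contour_area, tolerance = 1e-6)
})

test_that("circular cells measure as circular and stretched ones recover e", {
  scene <- scene_spec()
  p0 <- render_cell_patch(ref_cell(ecc = 0), scene, "parametric")
  e0 <- embed_patch(p0, scene)
  sh0 <- measure_shape(normalize_patch(e0$frame, e0$centroid,
                                       scene$pixel_size))
  expect_lt(sh0$eccentricity, 0.1)
  for (etrue in c(0.3, 0.55)) {
    p <- render_cell_patch(ref_cell(ecc = etrue, orientation = 1.2),
                           scene, "parametric")
    e <- embed_patch(p, scene)
    sh <- measure_shape(normalize_patch(e$frame, e$centroid,
                                        scene$pixel_size))
    expect_equal(sh$eccentricity, etrue, tolerance = 0.06)
  }
})

test_that("area dilation calibration maps contour area to truth", {
  truth <- c(250, 270, 300)
  contour <- truth / 60
  k <- calibrate_dilation(truth, contour)
  expect_equal(k, 60, tolerance = 1e-9)
})

test_that("trace extraction normalizes away background drift", {
  scene <- test_scene()
  nt <- 60
  frames <- array(0, dim = c(120, 120, nt))
  drift <- 1 + 0.1 * sin(seq_len(nt) / 6)
  base <- matrix(2000, 120, 120)
  patch <- render_cell_patch(ref_cell(), scene, "parametric")
  hw <- attr(patch, "half_width")
  base[(61 - hw):(61 + hw), (61 - hw):(61 + hw)] <- patch
  for (i in seq_len(nt)) frames[, , i] <- base * drift[i]
  st <- frame_stack(frames, scene$pixel_size, scene$frame_interval)
  tr <- extract_traces(st, c(60, 60), ring_radius = scene$ring_radius)
  expect_lt(diff(range(tr$normalized)) / mean(tr$normalized), 0.01)
  expect_equal(length(tr$times), nt)
  # single-frame stack yields length-1 traces
  st1 <- frame_stack(frames[, , 1, drop = FALSE], scene$pixel_size,
                     scene$frame_interval)
  expect_equal(length(extract_traces(st1, c(60, 60))$normalized), 1)
})

test_that("a rendered quenching footprint reproduces the binding kinetics", {
  scene <- scene_spec(frame_dim = c(120, 120), n_frames = 120,
                      frame_interval = 1.2, noise_sd = 0,
                      cells_per_stack = 1)
  cell <- sample_population(population_spec("+PMA", 1, seed = 2))
  cell$rate_amol_min <- 700
  rs <- render_stack(cell, scene, seed = 1, mode = "parametric")
  tr <- extract_traces(rs$stack, c(rs$truth$row, rs$truth$col),
                       ring_radius = scene$ring_radius)
  y_meas <- tr$normalized / tr$normalized[1]
  y_true <- intensity_forward(tr$times, rs$truth$conc_end_M,
                              scene$kinetics, I0 = 1)
  expect_lt(max(abs(y_meas - y_true)), 0.02)
})
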