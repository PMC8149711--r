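# Shared fixture builders. Everything is generated in code at test time;
# expensive objects are memoized for the session.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# small, fast scene for imaging tests
test_scene <- function(...) {
  scene_spec(frame_dim = c(160, 160), n_frames = 60, frame_interval = 1.2,
             cells_per_stack = 4, ...)
}

# embed a rendered patch into a uniform background frame; returns the frame
# and the 0-based centroid
embed_patch <- function(patch, scene, noise_sd = 0) {
  hw <- attr(patch, "half_width")
  pad <- ceiling(scene$ring_radius / scene$pixel_size) + 8
  nfr <- 2 * (hw + pad) + 1
  frame <- matrix(scene$background, nfr, nfr)
  ctr <- hw + pad + 1
  frame[(ctr - hw):(ctr + hw), (ctr - hw):(ctr + hw)] <- patch
  if (noise_sd > 0) frame <- frame + stats::rnorm(length(frame), 0, noise_sd)
  list(frame = frame, centroid = c(ctr - 1, ctr - 1))
}

# default-parameter single cell (reference monocyte)
ref_cell <- function(ecc = 0, orientation = 0, n_rel = 1.383 / 1.33) {
  list(diameter_um = 18.574, n_rel = n_rel, eccentricity = ecc,
       orientation = orientation)
}

test_sweep <- function() {
  memo("sweep_default", {
    scene <- scene_spec()
    calibrated_sweep(scene, radii = seq(8, 10.5, by = 0.5),
                     n_rels = c(1.01, 1.025, 1.04, 1.055, 1.07))
  })
}
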