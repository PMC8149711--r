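#' Run configuration
#'
#' Layered configuration for the end-to-end pipeline. All physical
#' quantities carry their unit in the field name. Unknown fields are
#' rejected.
#'
#' @param seed Master seed; per-stack and bootstrap seeds derive from it.
#' @param groups Population groups to simulate/analyze.
#' @param n_cells Cells per group.
#' @param render_mode `"physical"` (Mie-based patches; enables refractive-
#'   index recovery) or `"parametric"`.
#' @param scene A [scene_spec()].
#' @param sweep_radii_um,sweep_n_rels Grid of the lensing inversion sweep.
#' @param log_threshold Detection threshold (counts) or `NULL` for
#'   automatic.
#' @param smoothing_window_frames Savitzky-Golay window of the
#'   concentration inversion.
#' @param rate_statistic Which point of the concentration history enters
#'   the efflux conversion (`"end"`, `"max"`, `"mean"`).
#' @param calibration_stacks Reference stacks used for the end-to-end
#'   diameter calibration.
#' @param out_dir Optional output directory for tables and the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, groups = c("-PMA", "+PMA"), n_cells = 400,
                       render_mode = "physical",
                       scene = scene_spec(),
                       sweep_radii_um = seq(6.5, 12, by = 0.5),
                       sweep_n_rels = c(1.005, 1.008, 1.012, 1.017,
                                        1.023, 1.03, 1.04, 1.05, 1.06,
                                        1.07, 1.08, 1.09, 1.1),
                       log_threshold = NULL,
                       smoothing_window_frames = 41,
                       rate_statistic = "end",
                       calibration_stacks = 12,
                       out_dir = NULL) {
  stopifnot(inherits(scene, "scene_spec"),
            render_mode %in% c("physical", "parametric"),
            rate_statistic %in% c("end", "max", "mean"),
            n_cells >= 1, all(sweep_radii_um > 0),
            all(sweep_n_rels > 1), smoothing_window_frames >= 5)
  structure(list(seed = as.integer(seed), groups = groups,
                 n_cells = n_cells, render_mode = render_mode,
                 scene = scene, sweep_radii_um = sweep_radii_um,
                 sweep_n_rels = sweep_n_rels, log_threshold = log_threshold,
                 smoothing_window_frames = smoothing_window_frames,
                 rate_statistic = rate_statistic,
                 calibration_stacks = calibration_stacks,
                 out_dir = out_dir),
            class = "run_config")
}

#' As-measured lensing sweep for a scene
#'
#' Builds the (radius, index-ratio) metric sweep used by the lensing
#' inversion in *as-measured* space: each grid node is rendered as a
#' noiseless patch at the scene's pixel size and measured with the same
#' analyzer ([normalize_patch()], [profile_metrics()], [measure_shape()])
#' that is applied to data. Measuring the sweep through the identical
#' render/measure path removes the systematic offset between continuous-
#' field metrics and pixel-level measurements, so the inversion is unbiased
#' by construction. The contour-to-area dilation factor is calibrated on
#' the same renders and attached as an attribute.
#'
#' @param scene A [scene_spec()].
#' @param radii Sweep radii, micrometers.
#' @param n_rels Sweep index ratios (> 1).
#' @param cache_path Optional CSV cache (config-hashed, see [run_sweep()]).
#' @return An `optics_sweep` data frame with `fwhm`, `enhancement`,
#'   `contour_area` columns and attributes `n_medium`, `dilation`, `hash`.
#' @export
calibrated_sweep <- function(scene, radii = seq(6.5, 12, by = 0.5),
                             n_rels = c(1.005, 1.008, 1.012, 1.017,
                                        1.023, 1.03, 1.04, 1.05, 1.06,
                                        1.07, 1.08, 1.09, 1.1),
                             cache_path = NULL) {
  cfg <- list(radii = radii, n_rels = n_rels, px = scene$pixel_size,
              enh = scene$lensing_enh, dref = scene$cell_diameter_ref,
              riref = scene$cell_ri_ref, kind = "as_measured")
  hash <- config_hash(cfg)
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cached <- tryCatch(read_sweep(cache_path), error = function(e) NULL)
    if (!is.null(cached) && identical(attr(cached, "hash"), hash)) {
      attr(cached, "dilation") <- calibrate_dilation(
        pi * cached$radius^2, cached$contour_area)
      return(cached)
    }
  }
  # cells sit at random subpixel offsets, and the pixel-level metrics of
  # narrow (undersampled) spots depend strongly and nonlinearly on that
  # offset; each node is therefore averaged over a 3x3 stratified grid of
  # the uniform offset distribution, which tracks the true offset-averaged
  # expectation to ~0.01 um
  offs <- expand.grid(dr = c(-1, 0, 1) / 3, dc = c(-1, 0, 1) / 3)
  rows <- list()
  for (r in radii) for (nr in n_rels) {
    res <- tryCatch({
      cell <- list(diameter_um = 2 * r, n_rel = nr, eccentricity = 0,
                   orientation = 0)
      ms <- lapply(seq_len(nrow(offs)), function(k)
        tryCatch(measure_render(cell, scene, mode = "physical",
                                offset = c(offs$dr[k], offs$dc[k])),
                 error = function(e) NULL))
      ms <- Filter(Negate(is.null), ms)
      if (length(ms) < 2) stop("node not measurable at subpixel offsets")
      m <- list(fwhm = mean(vapply(ms, `[[`, 0, "fwhm")),
                enhancement = mean(vapply(ms, `[[`, 0, "enhancement")),
                contour_area = mean(vapply(ms, `[[`, 0, "contour_area")))
      data.frame(radius = r, z_semiaxis = r, n_rel = nr, lambda = 1,
                 z_focus = NA_real_, fwhm = m$fwhm,
                 enhancement = m$enhancement, contour_area = m$contour_area,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(radius = r, z_semiaxis = r, n_rel = nr, lambda = 1,
                 z_focus = NA_real_, fwhm = NA_real_,
                 enhancement = NA_real_, contour_area = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1]] <- res
  }
  sweep <- do.call(rbind, rows)
  attr(sweep, "hash") <- hash
  attr(sweep, "n_medium") <- 1.33
  ok <- sweep$status == "ok"
  attr(sweep, "dilation") <- calibrate_dilation(pi * sweep$radius[ok]^2,
                                                sweep$contour_area[ok])
  class(sweep) <- c("optics_sweep", class(sweep))
  if (!is.null(cache_path)) write_sweep(sweep, cache_path)
  sweep
}

# Render one noiseless cell patch into a background frame and measure it
# with the standard analyzer chain. Internal helper for sweep calibration.
measure_render <- function(cell, scene, mode = "physical",
                           offset = c(0, 0)) {
  patch <- render_cell_patch(cell, scene, mode = mode,
                             center_offset = offset)
  hw <- attr(patch, "half_width")
  pad <- ceiling(scene$ring_radius / scene$pixel_size) + 8
  nfr <- 2 * (hw + pad) + 1
  frame <- matrix(scene$background, nfr, nfr)
  ctr <- hw + pad + 1
  frame[(ctr - hw):(ctr + hw), (ctr - hw):(ctr + hw)] <- patch
  cp <- normalize_patch(frame, c(ctr - 1, ctr - 1), scene$pixel_size)
  sh <- measure_shape(cp)
  pm <- profile_metrics(cp, eccentricity = sh$eccentricity,
                        orientation = sh$orientation)
  list(fwhm = pm$fwhm, enhancement = pm$enhancement,
       contour_area = sh$contour_area, eccentricity = sh$eccentricity)
}

#' Analyze one rendered stack
#'
#' Runs the full per-stack measurement chain: cell detection on the first
#' frames, patch normalization and lensing metrics, shape statistics, joint
#' (diameter, refractive index) inversion against the sweep, trace
#' extraction, concentration inversion and efflux-rate conversion. Cells
#' failing any stage are kept with a QC flag and NA measurements.
#'
#' @param stack A [frame_stack()].
#' @param config A [run_config()].
#' @param sweep A [calibrated_sweep()] matching the scene.
#' @return Data frame with one row per detected cell: `row`, `col`
#'   (0-based centroids), `fwhm_um`, `enhancement`, `contour_area_um2`,
#'   `area_um2`, `diameter_um`, `eccentricity`, `ri`, `conc_end_uM`,
#'   `rate_amol_min`, `n_clipped`, `qc`.
#' @export
analyze_stack <- function(stack, config, sweep) {
  stopifnot(inherits(stack, "frame_stack"), inherits(config, "run_config"))
  scene <- config$scene
  nt <- dim(stack$frames)[3]
  # lensing metrics are measured on the average of the first frames (read
  # noise down by sqrt(nref)); the early sensor quench accumulated over
  # those frames is divided back out using the cell's own smoothed trace
  nref <- min(12, nt)
  frame1 <- rowMeans(stack$frames[, , seq_len(nref), drop = FALSE], dims = 2)
  det <- detect_cells(frame1, stack$pixel_size,
                      threshold = config$log_threshold)
  if (!nrow(det)) return(empty_cells_df())
  dcal <- attr(sweep, "diam_factor")
  rows <- lapply(seq_len(nrow(det)), function(i) {
    rec <- list(row = det$row[i], col = det$col[i], fwhm_um = NA_real_,
                enhancement = NA_real_, contour_area_um2 = NA_real_,
                area_um2 = NA_real_, diameter_um = NA_real_,
                eccentricity = NA_real_, ri = NA_real_,
                conc_end_uM = NA_real_, rate_amol_min = NA_real_,
                n_clipped = NA_real_, qc = "")
    ybar <- 1
    tryCatch({
      tr <- extract_traces(stack, c(det$row[i], det$col[i]),
                           ring_radius = scene$ring_radius)
      dt <- stack$frame_interval
      sm <- savgol(tr$normalized, dt,
                   window = config$smoothing_window_frames)$smooth
      trace <- intensity_trace(tr$times, tr$normalized, I0 = sm[1])
      conc <- invert_concentration(trace, scene$kinetics,
                                   config$smoothing_window_frames)
      rate <- efflux_rate(conc, scene$ref_volume, scene$window_s,
                          statistic = config$rate_statistic)
      tail_sel <- conc$time_s >= max(conc$time_s) - 0.1 * scene$window_s
      c_est <- mean(conc$conc_M[tail_sel])
      # model-based early-quench factor over the metric-averaging frames
      ybar <- mean(intensity_forward((seq_len(nref) - 1) * dt, c_est,
                                     scene$kinetics, I0 = 1))
      rec$conc_end_uM <- c_est * 1e6
      rec$rate_amol_min <- rate
      rec$n_clipped <- attr(conc, "n_clipped")
    }, error = function(e)
      rec$qc <<- paste0("trace:", conditionMessage(e)))
    tryCatch({
      cp <- normalize_patch(frame1, c(det$row[i], det$col[i]),
                            stack$pixel_size)
      sh <- measure_shape(cp)
      pm <- profile_metrics(cp, eccentricity = sh$eccentricity,
                            orientation = sh$orientation)
      enh <- pm$enhancement / ybar
      rec$fwhm_um <- pm$fwhm
      rec$enhancement <- enh
      rec$contour_area_um2 <- sh$contour_area
      rec$eccentricity <- sh$eccentricity
      inv <- invert_lensing(pm$fwhm, enh, sweep)
      rec$diameter_um <- inv$diameter * diam_correction(dcal, enh)
      rec$area_um2 <- pi * (rec$diameter_um / 2)^2
      ri <- estimate_ri(pm$fwhm, enh, inv$diameter, sweep)
      rec$ri <- ri$ri
    }, error = function(e)
      rec$qc <<- paste0(rec$qc, if (nzchar(rec$qc)) ";" else "",
                        "optics:", conditionMessage(e)))
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Reference population spanning the cell-relevant size, shape, index and
# efflux ranges; used for the end-to-end diameter calibration. Rates are
# representative so the early-quench conditions of the metric frames match
# the measurement conditions.
reference_cells <- function(n, seed) {
  sample_population(population_spec(
    "+PMA", n, seed = seed,
    area = list(mean = 267, sd = 27),
    eccentricity = list(mean = 0.38, sd = 0.135, lo = 0, hi = 0.95),
    ri = list(mean = 1.380, sd = 0.055, lo = 1.33, hi = 1.45),
    rate = list(mean = 450, sd = 400, upper = 4000)))
}

# End-to-end diameter calibration: renders reference cells through the
# full noisy pipeline (short recordings suffice: the metric frames and
# their early quench are identical to long recordings) and regresses
# true against measured diameter. The noise-induced estimator bias of the
# lensing inversion depends on the spot regime (dim wide spots for low
# index contrast, bright narrow ones for high), so the correction is a
# smooth curve in log enhancement rather than a single factor — the
# end-to-end generalization of the contour-area dilation factor.
calibrate_diameter <- function(scene, config, sweep, n_stacks = 12) {
  cal_scene <- scene
  cal_scene$n_frames <- max(12, min(24, scene$n_frames))
  rows <- list()
  for (i in seq_len(n_stacks)) {
    cells <- reference_cells(scene$cells_per_stack, seed = 42420 + i)
    rs <- render_stack(cells, cal_scene, seed = 51510 + i,
                       mode = config$render_mode)
    meas <- analyze_stack(rs$stack, config, sweep)
    ok <- meas[!is.na(meas$diameter_um) & is.finite(meas$enhancement), ]
    if (!nrow(ok)) next
    m <- match_detections(rs$truth, ok, tol_px = 4)
    rows[[length(rows) + 1]] <- data.frame(
      d_true = rs$truth$diameter_um[m$matches$truth_idx],
      d_meas = ok$diameter_um[m$matches$det_idx],
      enh = ok$enhancement[m$matches$det_idx])
  }
  cal <- do.call(rbind, rows)
  if (is.null(cal) || nrow(cal) < 10)
    return(list(le = c(0, 1), ratio = c(1, 1)))
  le <- log(cal$enh)
  lw <- stats::lowess(le, cal$d_true / cal$d_meas, f = 0.5)
  list(le = lw$x, ratio = lw$y)
}

# Evaluate the diameter calibration curve at a measured enhancement.
diam_correction <- function(cal, enh) {
  if (is.null(cal)) return(1)
  if (is.numeric(cal) && length(cal) == 1) return(cal)
  stats::approx(cal$le, cal$ratio, log(enh), rule = 2)$y
}

empty_cells_df <- function() {
  data.frame(row = numeric(0), col = numeric(0), fwhm_um = numeric(0),
             enhancement = numeric(0), contour_area_um2 = numeric(0),
             area_um2 = numeric(0), diameter_um = numeric(0),
             eccentricity = numeric(0), ri = numeric(0),
             conc_end_uM = numeric(0), rate_amol_min = numeric(0),
             n_clipped = numeric(0), qc = character(0),
             stringsAsFactors = FALSE)
}

#' Match detections to ground truth
#'
#' Nearest-neighbor assignment of detected centroids to ground-truth cells
#' within a tolerance; used for recall/precision accounting and for
#' attaching ground truth to measured rows in validation runs.
#'
#' @param truth Ground truth with `row`, `col` (0-based).
#' @param detections Data frame with `row`, `col` (0-based).
#' @param tol_px Match tolerance in pixels.
#' @return List with `matches` (data frame `truth_idx`, `det_idx`,
#'   `dist_px`), `recall`, `precision`.
#' @export
match_detections <- function(truth, detections, tol_px = 5) {
  if (!nrow(truth) || !nrow(detections))
    return(list(matches = data.frame(truth_idx = integer(0),
                                     det_idx = integer(0),
                                     dist_px = numeric(0)),
                recall = 0, precision = 0))
  d <- outer(truth$row, detections$row, `-`)^2 +
       outer(truth$col, detections$col, `-`)^2
  d <- sqrt(d)
  matches <- data.frame(truth_idx = integer(0), det_idx = integer(0),
                        dist_px = numeric(0))
  used_t <- logical(nrow(truth)); used_d <- logical(nrow(detections))
  repeat {
    d2 <- d
    d2[used_t, ] <- Inf; d2[, used_d] <- Inf
    m <- which.min(d2)
    if (!length(m) || !is.finite(d2[m]) || d2[m] > tol_px) break
    ti <- (m - 1) %% nrow(truth) + 1
    di <- (m - 1) %/% nrow(truth) + 1
    matches <- rbind(matches, data.frame(truth_idx = ti, det_idx = di,
                                         dist_px = d2[m]))
    used_t[ti] <- TRUE; used_d[di] <- TRUE
  }
  list(matches = matches,
       recall = nrow(matches) / nrow(truth),
       precision = nrow(matches) / nrow(detections))
}

#' Run the end-to-end pipeline
#'
#' Simulates the configured populations (in chunks of
#' `scene$cells_per_stack` cells per rendered stack), analyzes every stack,
#' assembles the per-cell population table and computes group summaries and
#' comparisons. With `config$out_dir` set, writes `cells.csv`,
#' `summary.csv`, `comparison.csv` and a `manifest.json` carrying the
#' configuration hash and seeds; a re-run with an identical configuration
#' reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param progress Print per-stage progress lines.
#' @return List with `table` (a [population_table()]), `truth` (the
#'   generator table), `summary`, `comparison` (when both groups are
#'   present), `sweep`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), progress = interactive()) {
  stopifnot(inherits(config, "run_config"))
  scene <- config$scene
  t_start <- proc.time()[["elapsed"]]
  sweep <- calibrated_sweep(scene, config$sweep_radii_um,
                            config$sweep_n_rels)
  if (progress) message("sweep: ", sum(sweep$status == "ok"), "/",
                        nrow(sweep), " nodes ok")
  attr(sweep, "diam_factor") <- calibrate_diameter(
    scene, config, sweep, n_stacks = config$calibration_stacks)
  if (progress) message("diameter calibration: ratio range ",
                        paste(round(range(attr(sweep,
                                               "diam_factor")$ratio), 4),
                              collapse = " - "))
  all_rows <- list(); all_truth <- list()
  counts <- list()
  for (gi in seq_along(config$groups)) {
    gr <- config$groups[gi]
    pspec <- population_spec(gr, n_cells = config$n_cells,
                             seed = config$seed + 1000 * gi)
    truth <- sample_population(pspec)
    chunks <- split(seq_len(nrow(truth)),
                    ceiling(seq_len(nrow(truth)) / scene$cells_per_stack))
    for (ci in seq_along(chunks)) {
      rs <- render_stack(truth[chunks[[ci]], ], scene,
                         seed = config$seed + 100000 * gi + ci,
                         mode = config$render_mode)
      cells <- analyze_stack(rs$stack, config, sweep)
      if (nrow(cells)) cells$group <- gr
      all_rows[[length(all_rows) + 1]] <- cells
      all_truth[[length(all_truth) + 1]] <- rs$truth
      if (progress) message(gr, " stack ", ci, "/", length(chunks), ": ",
                            nrow(cells), " cells")
    }
    counts[[gr]] <- nrow(truth)
  }
  cells <- do.call(rbind, all_rows)
  truth <- do.call(rbind, all_truth)
  table <- population_table(cells, groups = config$groups)
  summary <- summarize_population(table)
  comparison <- if (length(config$groups) >= 2)
    compare_groups(table, config$groups[1], config$groups[2],
                   seed = config$seed) else NULL
  manifest <- list(config_hash = config_hash(config[setdiff(names(config),
                                                            "out_dir")]),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("ncckit")),
                   n_cells_simulated = counts,
                   n_cells_measured = nrow(cells),
                   n_cells_flagged = sum(table$qc != ""),
                   elapsed_s = round(proc.time()[["elapsed"]] - t_start, 1))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(table),
                     file.path(config$out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison,
                       file.path(config$out_dir, "comparison.csv"),
                       row.names = FALSE)
    m <- manifest; m$elapsed_s <- NULL   # keep outputs re-run identical
    jsonlite::write_json(m, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = table, truth = truth, summary = summary,
       comparison = comparison, sweep = sweep, manifest = manifest)
}
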