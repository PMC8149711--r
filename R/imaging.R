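#' Time-lapse frame stack
#'
#' Container for a near-infrared time-lapse recording. Frames are stored as
#' a 3D array indexed `[row, col, frame]` with 16-bit camera counts;
#' `pixel_size` converts pixels to micrometers and `frame_interval` frames
#' to seconds.
#'
#' @param frames Numeric 3D array `[row, col, frame]` (a matrix is promoted
#'   to a single-frame stack), values within \[0, 65535\].
#' @param pixel_size Pixel size in micrometers per pixel, positive.
#' @param frame_interval Frame interval in seconds, positive.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive (um/px)")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be positive (s)")
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("frame intensities must lie within [0, 65535]")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d x %d px, %d frames, %.2f um/px, %.2f s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

# Circular-equivalent (area-preserving elliptical) radius of pixel offsets
# for an in-plane ellipse of the given eccentricity and major-axis
# orientation (radians, row-axis reference).
elliptical_radius <- function(dr, dc, eccentricity = 0, orientation = 0) {
  if (eccentricity <= 0) return(sqrt(dr^2 + dc^2))
  sa <- (1 - eccentricity^2)^(-1 / 4)
  sb <- (1 - eccentricity^2)^(1 / 4)
  u <- dr * cos(orientation) + dc * sin(orientation)
  v <- -dr * sin(orientation) + dc * cos(orientation)
  sqrt((u / sa)^2 + (v / sb)^2)
}

# Radially binned mean profile about a (fractional, 1-based) center.
radial_profile <- function(mat, center, pixel, bin_width = pixel) {
  rr <- sqrt((row(mat) - center[1])^2 + (col(mat) - center[2])^2) * pixel
  bin <- floor(rr / bin_width) + 1
  s <- rowsum(as.vector(mat), as.vector(bin))
  n <- rowsum(rep(1, length(mat)), as.vector(bin))
  list(r = (as.numeric(rownames(s)) - 0.5) * bin_width,
       intensity = as.vector(s / n))
}

# Laplacian-of-Gaussian kernel (scale-normalized, sign flipped so bright
# blobs give positive response).
log_kernel <- function(sigma_px) {
  h <- ceiling(3 * sigma_px)
  g <- outer(-h:h, -h:h, function(i, j) {
    r2 <- i^2 + j^2
    (r2 - 2 * sigma_px^2) / sigma_px^2 * exp(-r2 / (2 * sigma_px^2))
  })
  k <- -g / sum(exp(-(outer((-h:h)^2, (-h:h)^2, `+`)) / (2 * sigma_px^2)))
  k - mean(k)   # zero-mean: flat background gives zero response
}

#' Detect cells in a frame by Laplacian-of-Gaussian filtering
#'
#' Convolves the frame with a blob-scale LoG filter, thresholds the (sign-
#' flipped) response, labels connected components and returns their response-
#' weighted centroids, deduplicated within one cell diameter.
#'
#' @param frame Numeric matrix of camera counts.
#' @param pixel_size Pixel size, um/px.
#' @param log_sigma LoG scale in micrometers (default 2.4, about the lensing
#'   spot FWHM / 1.414).
#' @param threshold Response threshold in counts. This is a per-batch user
#'   choice; `NULL` (default) uses a robust automatic value,
#'   `median + 8 * MAD` of the response map.
#' @param min_separation Minimum distance between detections, micrometers
#'   (default one nominal cell diameter, 18.6 um).
#' @return Data frame with 0-based fractional centroids `row`, `col` and the
#'   peak `response`, ordered by decreasing response.
#' @export
detect_cells <- function(frame, pixel_size, log_sigma = 2.4,
                         threshold = NULL, min_separation = 18.6) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (log_sigma <= 0) stop("`log_sigma` must be positive")
  if (mean(frame >= 65535) >= 0.01)
    warning("frame saturated: >= 1% of pixels at the 16-bit ceiling")
  k <- log_kernel(log_sigma / pixel_size)
  resp <- EBImage::filter2(frame, k)
  if (is.null(threshold))
    threshold <- stats::median(resp) + 8 * stats::mad(resp)
  bw <- resp > threshold
  if (!any(bw))
    return(data.frame(row = numeric(0), col = numeric(0),
                      response = numeric(0)))
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  idx <- which(labm > 0, arr.ind = TRUE)
  w <- resp[labm > 0]
  lb <- labm[labm > 0]
  cent <- data.frame(
    row = tapply(idx[, 1] * w, lb, sum) / tapply(w, lb, sum) - 1,
    col = tapply(idx[, 2] * w, lb, sum) / tapply(w, lb, sum) - 1,
    response = as.numeric(tapply(w, lb, max)))
  cent <- cent[order(-cent$response), ]
  # deduplicate: greedily keep the strongest detection within min_separation
  keep <- logical(nrow(cent))
  min_px <- min_separation / pixel_size
  for (i in seq_len(nrow(cent))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt((cent$row[keep] - cent$row[i])^2 +
              (cent$col[keep] - cent$col[i])^2)
    if (all(d >= min_px)) keep[i] <- TRUE
  }
  rownames(cent) <- NULL
  cent[keep, ]
}

#' Extract and normalize a cell patch
#'
#' Crops a square patch around a detected centroid, refines the center to
#' subpixel precision, interpolates to a fine fixed grid and scales the
#' intensities so the background annulus (outside the secondary Airy peak)
#' has mean 1.
#'
#' @param frame Numeric matrix of camera counts.
#' @param centroid Numeric `c(row, col)`, 0-based (as returned by
#'   [detect_cells()]).
#' @param pixel_size Pixel size, um/px.
#' @param patch_radius Patch half-width, micrometers.
#' @param fine_pixel Target grid spacing of the interpolated patch, um.
#' @return An object of class `cell_patch`: `fine` (interpolated, background-
#'   normalized matrix), `fine_pixel`, `center_fine` (1-based fractional
#'   index into `fine`), `raw` (coarse normalized patch), `pixel_size`,
#'   `center_raw`, `bg_inner` (annulus inner radius, um), `bg_value`
#'   (annulus mean in counts), `patch_radius`.
#' @export
normalize_patch <- function(frame, centroid, pixel_size,
                            patch_radius = 13, fine_pixel = 0.1) {
  stopifnot(is.matrix(frame), length(centroid) == 2)
  r0 <- centroid[1] + 1; c0 <- centroid[2] + 1
  hw <- round(patch_radius / pixel_size)
  ri <- round(r0); ci <- round(c0)
  if (ri - hw < 1 || ri + hw > nrow(frame) ||
      ci - hw < 1 || ci + hw > ncol(frame))
    stop("patch clipped by the frame edge: cell excluded")
  patch <- frame[(ri - hw):(ri + hw), (ci - hw):(ci + hw)]
  # subpixel recenter: intensity-squared centroid over the central 7x7
  cc <- hw + 1
  win <- 3
  sub <- patch[(cc - win):(cc + win), (cc - win):(cc + win)]
  wgt <- pmax(sub - min(sub), 0)^2
  dr <- sum(row(sub) * wgt) / sum(wgt) - (win + 1)
  dc <- sum(col(sub) * wgt) / sum(wgt) - (win + 1)
  center_raw <- c(cc + dr, cc + dc)

  fac <- pixel_size / fine_pixel
  nf <- round((2 * hw + 1) * fac)
  fine <- as.matrix(EBImage::imageData(EBImage::resize(
    EBImage::Image(patch), w = nf, h = nf)))
  center_fine <- (center_raw - 0.5) * fac + 0.5

  # secondary-peak location and background annulus from the coarse patch
  # (exact camera samples; the fine grid is for shape statistics)
  rp <- radial_profile(patch, center_raw, pixel_size)
  sm <- stats::filter(rp$intensity, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- rp$intensity[is.na(sm)]
  peaks <- profile_local_maxima(rp$r, as.numeric(sm), min_radius = 2)
  bg_inner <- if (length(peaks) >= 2) peaks[2] + 2 * pixel_size
              else 0.7 * patch_radius
  bg_inner <- min(bg_inner, 0.85 * patch_radius)
  rr <- sqrt((row(patch) - center_raw[1])^2 +
             (col(patch) - center_raw[2])^2) * pixel_size
  ann <- rr >= bg_inner & rr <= patch_radius - 0.5
  if (sum(ann) < 30) stop("background annulus too small for normalization")
  bg <- mean(patch[ann])
  if (bg <= 0) stop("non-positive background: cannot normalize")
  structure(list(fine = fine / bg, fine_pixel = fine_pixel,
                 center_fine = center_fine,
                 raw = patch / bg, pixel_size = pixel_size,
                 center_raw = center_raw, bg_inner = bg_inner,
                 bg_value = bg, patch_radius = patch_radius),
            class = "cell_patch")
}

#' Lensing-profile metrics of a normalized patch
#'
#' Radially averages the patch about its subpixel center and measures the
#' central peak. The FWHM is taken from the raw (non-interpolated) pixel
#' samples — each coarse pixel is an exact point sample at a known subpixel
#' radius — by a local linear fit around the half-maximum crossing, and the
#' enhancement from an even-polynomial apex fit, both of which avoid the
#' broadening that image interpolation would introduce.
#'
#' When the cell's in-plane eccentricity and orientation are known (from
#' [measure_shape()]), passing them de-stretches the pixel radii so every
#' sample lies on the circular-equivalent profile; the reported FWHM is then
#' the area-preserving circular width, directly comparable to sweeps
#' computed on spheres.
#'
#' @param patch A `cell_patch` from [normalize_patch()].
#' @param eccentricity,orientation In-plane ellipse parameters used to
#'   de-stretch the radii (defaults: circular).
#' @return An object of class `lensing_profile`: `fwhm` (um), `enhancement`
#'   (peak over unit background), `airy_radii` (um), `I0_peak` (peak in
#'   background-normalized units), `profile` (data frame `r_um`,
#'   `intensity`).
#' @export
profile_metrics <- function(patch, eccentricity = 0, orientation = 0) {
  stopifnot(inherits(patch, "cell_patch"))
  raw <- patch$raw
  rr <- elliptical_radius(row(raw) - patch$center_raw[1],
                          col(raw) - patch$center_raw[2],
                          eccentricity, orientation) * patch$pixel_size
  # central peak check: maximum must lie near the patch center
  imax <- which.max(raw)
  if (rr[imax] > 0.25 * patch$patch_radius)
    stop("no central peak in patch")
  peak0 <- max(raw)
  if (peak0 < 1.25)
    stop("no significant peak above background: not a lensing spot")
  half <- (peak0 + 1) / 2
  # fine-grid radial profile (for Airy rings and as FWHM fallback)
  rf <- elliptical_radius(row(patch$fine) - patch$center_fine[1],
                          col(patch$fine) - patch$center_fine[2],
                          eccentricity, orientation) * patch$fine_pixel
  binf <- floor(rf / patch$fine_pixel) + 1
  sf <- rowsum(as.vector(patch$fine), as.vector(binf))
  nf <- rowsum(rep(1, length(rf)), as.vector(binf))
  prof <- as.vector(sf / nf)
  prof_r <- (as.numeric(rownames(sf)) - 0.5) * patch$fine_pixel
  # half-maximum crossing: wide spots from a local linear fit of I vs r on
  # the raw pixel samples (exact point samples, no interpolation bias);
  # narrow spots (under ~3 px across, too few raw samples near half-max)
  # from the fine interpolated profile. The regime split depends only on
  # the spot scale, so sweep nodes and measured cells always use the same
  # estimator.
  fwhm_fine <- profile_fwhm(prof_r, prof, baseline = 1)
  fwhm <- NA_real_
  if (is.finite(fwhm_fine) && fwhm_fine >= 3 * patch$pixel_size) {
    selh <- NULL
    for (wband in c(0.15, 0.25, 0.35)) {
      lo <- 1 + (0.5 - wband) * (peak0 - 1)
      hi <- 1 + (0.5 + wband) * (peak0 - 1)
      selh <- rr < 6 & raw > lo & raw < hi
      if (sum(selh) >= 8) break
    }
    if (sum(selh) >= 4) {
      fitl <- stats::lm.fit(cbind(1, rr[selh]), raw[selh])
      r_half <- (half - fitl$coefficients[1]) / fitl$coefficients[2]
      if (is.finite(r_half) && r_half > 0 && fitl$coefficients[2] < 0)
        fwhm <- 2 * r_half
    }
  }
  if (!is.finite(fwhm)) fwhm <- fwhm_fine
  if (!is.finite(fwhm) || fwhm <= 0) stop("ill-defined half-max crossing")
  fwhm <- unname(fwhm)
  # apex fit: I ~ b0 + b1 r^2 + b2 r^4 within the upper part of the peak
  sela <- rr < max(0.75 * fwhm / 2, 1.1)
  if (sum(sela) < 6) sela <- rr < 1.6
  Xa <- cbind(1, rr[sela]^2, rr[sela]^4)
  enh <- stats::lm.fit(Xa, raw[sela])$coefficients[1]
  smp <- stats::filter(prof, rep(1 / 7, 7), sides = 2)
  smp[is.na(smp)] <- prof[is.na(smp)]
  airy <- profile_local_maxima(prof_r, as.numeric(smp), min_radius = fwhm)
  structure(list(fwhm = unname(fwhm), enhancement = unname(enh),
                 I0_peak = peak0, airy_radii = airy,
                 profile = data.frame(r_um = prof_r, intensity = prof)),
            class = "lensing_profile")
}

#' Shape statistics from the half-maximum contour
#'
#' Thresholds the normalized patch at half its maximum, keeps the connected
#' component containing the center, and reports ellipse statistics of that
#' mask: projected area (scaled by a calibrated dilation factor that maps
#' the lensing-spot contour to the physical cell outline) and eccentricity.
#'
#' The mask-based ellipse statistics follow the classic regionprops recipe,
#' but at camera sampling the half-maximum contour of a narrow spot spans
#' only a few pixels and its binary eccentricity is unreliable; the primary
#' `eccentricity`/`orientation` are therefore taken from the intensity-
#' weighted second moments of the background-subtracted modulation, which
#' use every illuminated pixel and are exact for an affinely stretched
#' profile. The mask value is retained as `eccentricity_mask`.
#'
#' @param patch A `cell_patch`.
#' @param dilation_factor Calibrated multiplicative factor applied to the
#'   contour area (see [calibrate_dilation()]); default 1 reports the raw
#'   contour area.
#' @return List with `projected_area` (um^2, dilated), `contour_area`
#'   (um^2, raw), `eccentricity` (0 = circle; intensity-weighted),
#'   `orientation` (radians, row-axis reference), `eccentricity_mask`
#'   (half-max mask ellipse value).
#' @export
measure_shape <- function(patch, dilation_factor = 1) {
  stopifnot(inherits(patch, "cell_patch"))
  fine <- patch$fine
  mask <- fine >= (max(fine) + 1) / 2
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(
    EBImage::Image(mask * 1))))
  lc <- lab[round(patch$center_fine[1]), round(patch$center_fine[2])]
  if (lc == 0) stop("no closed half-maximum contour at the patch center")
  m <- lab == lc
  if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
    stop("half-maximum contour touches the patch border")
  ft <- EBImage::computeFeatures.moment(matrix(as.integer(m), nrow(m)))
  area <- sum(m) * patch$fine_pixel^2

  # intensity-weighted moments on the raw pixel samples
  raw <- patch$raw
  dr <- (row(raw) - patch$center_raw[1]) * patch$pixel_size
  dc <- (col(raw) - patch$center_raw[2]) * patch$pixel_size
  rrr <- sqrt(dr^2 + dc^2)
  w <- pmax(raw - 1, 0)
  peak <- max(w)
  ann <- rrr >= patch$bg_inner
  noise <- stats::mad(raw[ann] - 1)
  thr <- max(0.05 * peak, 4 * noise)
  w[w < thr | rrr > patch$patch_radius - 1] <- 0
  if (sum(w) <= 0) stop("no signal for weighted shape moments")
  mr <- sum(dr * w) / sum(w); mc <- sum(dc * w) / sum(w)
  crr <- sum((dr - mr)^2 * w) / sum(w)
  ccc <- sum((dc - mc)^2 * w) / sum(w)
  crc <- sum((dr - mr) * (dc - mc) * w) / sum(w)
  ev <- eigen(matrix(c(crr, crc, crc, ccc), 2), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ecc_w <- if (lam[1] <= 0) 0 else sqrt(max(1 - lam[2] / lam[1], 0))
  theta_w <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  st <- fit_stretch(patch, init = c(ecc_w, theta_w))

  list(projected_area = area * dilation_factor, contour_area = area,
       eccentricity = st$eccentricity, orientation = st$orientation,
       eccentricity_moment = ecc_w,
       eccentricity_mask = unname(ft[1, "m.eccentricity"]))
}

# Fit the in-plane elliptical stretch of a lensing spot: at the true
# (eccentricity, orientation, center) every raw pixel sample lies on the
# one-dimensional circular-equivalent profile, so the intensity sequence
# ordered by de-stretched radius is smooth; away from the truth, samples
# from different true radii interleave and the sequence roughens. The
# objective is the bin-free roughness (sum of squared successive
# differences after ordering), minimized over stretch and a subpixel
# center refinement. More statistically efficient than binary-mask or
# moment estimators for spots only a few pixels across.
fit_stretch <- function(patch, gate = 0.5 * patch$patch_radius,
                        init = c(0.2, 0)) {
  raw <- patch$raw
  dr0 <- (row(raw) - patch$center_raw[1]) * patch$pixel_size
  dc0 <- (col(raw) - patch$center_raw[2]) * patch$pixel_size
  sel <- dr0^2 + dc0^2 < (gate * 1.15)^2
  drs <- dr0[sel]; dcs <- dc0[sel]; Is <- raw[sel]
  obj <- function(p) {
    e <- p[1]
    if (e < 0 || e > 0.97 || abs(p[3]) > 1 || abs(p[4]) > 1) return(Inf)
    re <- elliptical_radius(drs - p[3], dcs - p[4], e, p[2])
    keep <- re < gate
    I <- Is[keep][order(re[keep])]
    sum(diff(I)^2)
  }
  grid <- expand.grid(e = c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8),
                      th = seq(0, pi * 7 / 8, by = pi / 8))
  vals <- apply(grid, 1, function(g) obj(c(g[1], g[2], 0, 0)))
  starts <- rbind(c(as.numeric(grid[which.min(vals), ]), 0, 0),
                  c(init, 0, 0))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(eccentricity = max(best$par[1], 0),
       orientation = best$par[2] %% pi, value = best$value)
}

#' Calibrate the area dilation factor
#'
#' The half-maximum contour of the lensing spot is much smaller than the
#' physical cell outline; the mapping between the two is fitted once per
#' optics configuration on synthetic renders with known ground truth, as a
#' least-squares proportionality between true projected area and contour
#' area.
#'
#' @param true_area True projected areas, um^2.
#' @param contour_area Measured half-maximum contour areas, um^2.
#' @return Scalar dilation factor.
#' @export
calibrate_dilation <- function(true_area, contour_area) {
  stopifnot(length(true_area) == length(contour_area), length(true_area) >= 1)
  sum(true_area * contour_area) / sum(contour_area^2)
}

#' Extract centroid and background intensity traces
#'
#' Follows the acquisition-analysis convention for stationary (stopped-flow)
#' cells: the cell trace is the single camera pixel closest to the centroid;
#' the background trace is the mean over 16 pixels equally spaced on a
#' circle outside the secondary Airy peak, after outlier removal
#' (median +/- 3 MAD per frame). The normalized trace is their ratio.
#'
#' @param stack A [frame_stack()].
#' @param centroid Numeric `c(row, col)`, 0-based.
#' @param ring_radius Background-circle radius in micrometers (default 8,
#'   i.e. the secondary Airy radius of a nominal cell plus two pixels).
#' @param n_bg Number of background pixels on the circle (16).
#' @return An object of class `cell_traces`: `times` (s), `I_cell`,
#'   `background`, `normalized` (I_cell / background), `n_outliers`
#'   (outliers removed per frame).
#' @export
extract_traces <- function(stack, centroid, ring_radius = 8, n_bg = 16) {
  stopifnot(inherits(stack, "frame_stack"), length(centroid) == 2)
  d <- dim(stack$frames)
  r0 <- round(centroid[1] + 1); c0 <- round(centroid[2] + 1)
  if (r0 < 1 || r0 > d[1] || c0 < 1 || c0 > d[2])
    stop("centroid outside the frame")
  ang <- 2 * pi * (seq_len(n_bg) - 1) / n_bg
  rad_px <- ring_radius / stack$pixel_size
  br <- round(centroid[1] + 1 + rad_px * sin(ang))
  bc <- round(centroid[2] + 1 + rad_px * cos(ang))
  ok <- br >= 1 & br <= d[1] & bc >= 1 & bc <= d[2]
  if (sum(ok) < n_bg / 2) stop("background ring outside the frame")
  br <- br[ok]; bc <- bc[ok]
  nt <- d[3]
  I_cell <- stack$frames[cbind(rep(r0, nt), rep(c0, nt), seq_len(nt))]
  bgmat <- matrix(stack$frames[cbind(rep(br, nt),
                                     rep(bc, nt),
                                     rep(seq_len(nt), each = length(br)))],
                  nrow = length(br))
  med <- apply(bgmat, 2, stats::median)
  madv <- apply(bgmat, 2, stats::mad)
  medm <- matrix(med, length(br), nt, byrow = TRUE)
  madm <- matrix(madv, length(br), nt, byrow = TRUE)
  keep <- abs(bgmat - medm) <= 3 * pmax(madm, 1e-9)
  n_out <- colSums(!keep)
  if (any(n_out > length(br) / 2))
    stop("more than half of the background pixels rejected in a frame")
  bgmat[!keep] <- NA
  background <- colMeans(bgmat, na.rm = TRUE)
  if (any(background <= 0)) stop("non-positive background trace")
  structure(list(times = (seq_len(nt) - 1) * stack$frame_interval,
                 I_cell = I_cell, background = background,
                 normalized = I_cell / background, n_outliers = n_out),
            class = "cell_traces")
}
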