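# ---- low-level array filters (separable, edge-replicated) -----------------

# Shift an array along one dimension with replicated edges.
shift_dim <- function(a, off, dim) {
  d <- base::dim(a)
  idx <- pmin(pmax(seq_len(d[dim]) + off, 1L), d[dim])
  if (length(d) == 2L) {
    if (dim == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else {
    if (dim == 1L) a[idx, , , drop = FALSE]
    else if (dim == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
}

# 1-D Gaussian convolution along `dim` (kernel truncated at 3 sigma).
conv_gauss_dim <- function(a, sigma, dim) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  out <- array(0, base::dim(a))
  for (j in seq_along(k)) out <- out + k[j] * shift_dim(a, j - r - 1L, dim)
  out
}

#' Separable Gaussian smoothing of a 2D or 3D array
#' @param a numeric matrix or 3D array.
#' @param sigma smoothing sigma (voxels), scalar or per-dimension.
#' @return smoothed array of the same shape (edges replicated).
#' @export
gauss_smooth <- function(a, sigma) {
  nd <- length(base::dim(a))
  if (length(sigma) == 1L) sigma <- rep(sigma, nd)
  for (d in seq_len(nd)) a <- conv_gauss_dim(a, sigma[d], d)
  a
}

# Separable cube maximum filter with radius r (Chebyshev neighbourhood).
max_filter <- function(a, r) {
  nd <- length(base::dim(a))
  for (d in seq_len(nd)) {
    out <- a
    for (off in seq_len(r)) {
      out <- pmax(out, shift_dim(a, off, d), shift_dim(a, -off, d))
    }
    a <- out
  }
  a
}

# ---- single-level 2D Haar transform ---------------------------------------
# Finest-scale detail coefficients of the Haar wavelet; the HH band of pure
# Gaussian noise of sd sigma has sd sigma, which is what the MAD estimator
# reads. Images with odd extent are padded by edge replication.

haar2d <- function(m) {
  d <- base::dim(m)
  if (d[1] %% 2L) m <- rbind(m, m[d[1], ])
  if (d[2] %% 2L) m <- cbind(m, m[, d[2]])
  o1 <- seq(1L, nrow(m), 2L); o2 <- seq(1L, ncol(m), 2L)
  a <- m[o1, o2]; b <- m[o1 + 1L, o2]; c <- m[o1, o2 + 1L]; e <- m[o1 + 1L, o2 + 1L]
  list(LL = (a + b + c + e) / 2, HL = (a - b + c - e) / 2,
       LH = (a + b - c - e) / 2, HH = (a - b - c + e) / 2,
       odd = d %% 2L, dim = d)
}

ihaar2d <- function(w) {
  LL <- w$LL; HL <- w$HL; LH <- w$LH; HH <- w$HH
  nr <- 2L * nrow(LL); nc <- 2L * ncol(LL)
  m <- matrix(0, nr, nc)
  o1 <- seq(1L, nr, 2L); o2 <- seq(1L, nc, 2L)
  m[o1, o2]           <- (LL + HL + LH + HH) / 2
  m[o1 + 1L, o2]      <- (LL - HL + LH - HH) / 2
  m[o1, o2 + 1L]      <- (LL + HL - LH - HH) / 2
  m[o1 + 1L, o2 + 1L] <- (LL - HL - LH + HH) / 2
  m[seq_len(w$dim[1]), seq_len(w$dim[2]), drop = FALSE]
}

# ---- noise analysis -------------------------------------------------------

#' Estimate image noise and assign a processing band
#'
#' Wavelet-based estimator of the Gaussian noise standard deviation: the
#' median absolute deviation of the finest-scale (HH) Haar detail
#' coefficients, pooled over z-slices, divided by 0.6745. A quasi-signal
#' metric — the ratio of the 99th to the 95th intensity percentile — is
#' reported alongside (0 when the 95th percentile is below 1e-6). The noise
#' band routes downstream processing: sigma below 0.01 is `clean` (no
#' denoising needed), within `[0.01, 0.045]` `normal` (wavelet denoising),
#' within `(0.045, 0.1]` `saturated` (thresholding then denoising), and
#' above 0.1 `degenerate` (frame skipped).
#'
#' @param vol normalized volume (3D array, values in `[0, 1]`) or a 2D matrix.
#' @param bands numeric length-3 thresholds separating the four bands.
#' @return an object of class `noise_report`: `sigma`, `signal_metric`,
#'   `band`, `p95`, `p99`.
#' @export
estimate_noise <- function(vol, bands = c(0.01, 0.045, 0.1)) {
  if (!all(is.finite(vol))) stop("estimate_noise: non-finite values")
  dims <- base::dim(vol)
  slices <- if (length(dims) == 3L) lapply(seq_len(dims[3]), function(z) vol[, , z])
            else list(vol)
  hh <- unlist(lapply(slices, function(s) as.numeric(haar2d(s)$HH)))
  sigma <- median(abs(hh)) / 0.6745
  q <- quantile(vol, c(0.95, 0.99), names = FALSE)
  signal_metric <- if (q[1] < 1e-6) 0 else q[2] / q[1]
  band <- if (sigma < bands[1]) "clean"
          else if (sigma <= bands[2]) "normal"
          else if (sigma <= bands[3]) "saturated"
          else "degenerate"
  structure(list(sigma = sigma, signal_metric = signal_metric, band = band,
                 p95 = q[1], p99 = q[2]), class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report sigma=%.4g band=%s signal=%.3g>\n",
              x$sigma, x$band, x$signal_metric))
  invisible(x)
}

# Soft-threshold Haar denoising of one slice (universal threshold).
haar_denoise_slice <- function(m, sigma) {
  w <- haar2d(m)
  thr <- sigma * sqrt(2 * log(length(m)))
  soft <- function(x) sign(x) * pmax(abs(x) - thr, 0)
  w$HL <- soft(w$HL); w$LH <- soft(w$LH); w$HH <- soft(w$HH)
  ihaar2d(w)
}

#' Route a volume through the denoising branch of its noise band
#'
#' `clean` frames pass through unchanged; `normal` frames get per-slice
#' wavelet (Haar, soft universal threshold) denoising; `saturated` frames
#' are percentile-thresholded first (values below the 95th percentile set
#' to zero) and then denoised. The output is clipped back to `[0, 1]`.
#' Degenerate frames are refused.
#'
#' @param vol normalized volume.
#' @param report the frame's [estimate_noise()] report.
#' @param sat_quantile percentile used by the saturated-band pre-threshold.
#' @return processed volume, same shape.
#' @export
route_denoise <- function(vol, report, sat_quantile = 0.95) {
  stopifnot(inherits(report, "noise_report"))
  if (report$band == "degenerate")
    stop("route_denoise: frame marked degenerate (sigma > band limit)")
  if (report$band == "clean") return(vol)
  if (report$band == "saturated") {
    thr <- quantile(vol, sat_quantile, names = FALSE)
    vol[vol < thr] <- 0
  }
  dims <- base::dim(vol)
  out <- if (length(dims) == 3L) {
    for (z in seq_len(dims[3]))
      vol[, , z] <- haar_denoise_slice(vol[, , z], report$sigma)
    vol
  } else haar_denoise_slice(vol, report$sigma)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# ---- region of interest ---------------------------------------------------

#' Isolate the region of interest (root tip) of a frame
#'
#' Sums the volume along z, keeps the narrow intensity band between the two
#' percentile bounds of the projection, smooths aggressively with a Gaussian
#' kernel (default sigma 8) to expose the mesh-like connected region of
#' activity, binarizes (Otsu), and returns the largest connected component
#' as a 2D mask. Its 3D extension is the mask replicated along z.
#'
#' @param vol normalized volume (x, y, z).
#' @param sigma smoothing sigma in pixels (default 8).
#' @param band percentile bounds of the narrow-band filter (default c(.95, .99)).
#' @param min_area minimum component area in pixels (default 100).
#' @return an object of class `roi_mask`: `mask` (logical x-by-y matrix),
#'   `area`, `provenance` (band and sigma used). Frames with no usable
#'   structure raise a condition of class `"registrack_degenerate"`.
#' @export
compute_roi <- function(vol, sigma = 8, band = c(0.95, 0.99), min_area = 100) {
  proj <- if (length(base::dim(vol)) == 3L) rowSums(vol, dims = 2L) else vol
  rng <- range(proj)
  if (rng[2] - rng[1] < 1e-9)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = "degenerate ROI: projection has no structure",
                        call = sys.call())))
  q <- quantile(proj, band, names = FALSE)
  if (q[2] - q[1] < 1e-9)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = "degenerate ROI: percentile band is empty",
                        call = sys.call())))
  bandimg <- (proj >= q[1] & proj <= q[2]) * 1
  sm <- gauss_smooth(bandimg, sigma)
  if (max(sm) <= 0)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = "degenerate ROI: nothing in the narrow band",
                        call = sys.call())))
  smn <- sm / max(sm)
  thr <- EBImage::otsu(EBImage::Image(smn))
  maskall <- smn > thr
  lab <- EBImage::bwlabel(maskall)
  if (max(lab) == 0)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = "degenerate ROI: no connected component",
                        call = sys.call())))
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  if (areas[biggest] < min_area)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = sprintf(
                     "degenerate ROI: largest component area %d < %d",
                     areas[biggest], min_area), call = sys.call())))
  mask <- lab == biggest
  # dilate by the smoothing radius so objects at the region edge are kept
  mask <- max_filter(mask * 1, round(sigma)) > 0
  structure(list(mask = mask, area = sum(mask),
                 provenance = list(band = band, sigma = sigma)),
            class = "roi_mask")
}

# ---- annealing thresholding -----------------------------------------------

# Perimeter (pixel boundary-edge count) of every labelled 2D component.
component_perimeters <- function(lab) {
  nlab <- max(lab)
  if (nlab == 0L) return(integer(0))
  per <- integer(nlab)
  d <- base::dim(lab)
  pad <- matrix(0L, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- lab
  ctr <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad[2:(d[1] + 1L) + sh[1], 2:(d[2] + 1L) + sh[2]]
    edge <- ctr > 0L & nb != ctr
    if (any(edge)) {
      tab <- tabulate(ctr[edge], nbins = nlab)
      per <- per + tab
    }
  }
  per
}

#' Annealing thresholding
#'
#' Iteratively raises an intensity threshold (fixed step on the normalized
#' scale) until no remaining connected component has a perimeter above
#' `perimeter_max`, removing the large dim background while preserving
#' small bright blobs. If no such threshold exists below intensity 1, the
#' 99th percentile is treated as background and removed instead.
#'
#' Volumes are processed per z-slice (each slice anneals its own threshold).
#'
#' @param img 2D matrix or 3D array of normalized intensities.
#' @param perimeter_max maximum allowed component perimeter in pixels.
#'   The default scales with the frame: two thirds of the slice border
#'   perimeter, `2 * (nx + ny) / 3`, which lands in the empirical
#'   1000-2000 px range for full-size light-sheet frames.
#' @param step threshold increment (default 0.01).
#' @return list with `binary` (same shape as `img`) and `threshold`
#'   (scalar, or per-slice vector for volumes).
#' @export
annealing_threshold <- function(img, perimeter_max = NULL, step = 0.01) {
  dims <- base::dim(img)
  if (is.null(perimeter_max)) perimeter_max <- round(2 * (dims[1] + dims[2]) / 3)
  if (length(dims) == 3L) {
    thrs <- numeric(dims[3])
    out <- array(FALSE, dims)
    for (z in seq_len(dims[3])) {
      r <- annealing_threshold(img[, , z], perimeter_max, step)
      out[, , z] <- r$binary
      thrs[z] <- r$threshold
    }
    return(list(binary = out, threshold = thrs))
  }
  thr <- floor(min(img) / step) * step
  while (thr < 1) {
    bin <- img > thr
    if (!any(bin)) return(list(binary = bin, threshold = thr))
    per <- component_perimeters(EBImage::bwlabel(bin))
    if (all(per <= perimeter_max)) return(list(binary = bin, threshold = thr))
    thr <- thr + step
  }
  thr <- quantile(img, 0.99, names = FALSE)   # fallback: p99 is background
  list(binary = img > thr, threshold = thr)
}

# ---- centroid detection ---------------------------------------------------

#' Detect object centroids in a volume
#'
#' Pre-segmentation inside the 3D ROI prism: annealing thresholding removes
#' background, a difference of Gaussians (sigma pair scaled to the expected
#' blob radius, default `eps/4` and `eps/2`) emphasises blob-like objects, a
#' cube maximum filter of radius `eps/2` finds local maxima, and maxima
#' closer than `eps` are merged to their intensity-weighted mean — multiple
#' peaks inside one catchment are read as a single object.
#'
#' @param vol normalized volume (x, y, z).
#' @param roi a [compute_roi()] mask (or NULL to use the whole volume).
#' @param eps catchment radius / minimum object separation (voxels).
#' @param dog_sigma length-2 difference-of-Gaussians sigmas.
#' @param perimeter_max passed to [annealing_threshold()].
#' @param min_rel_peak keep maxima with DoG response at least this fraction
#'   of the strongest (suppresses residual noise maxima; default 0.1).
#' @param t frame index stored in the returned cloud.
#' @return a [frame_cloud] of 0-based continuous centroid coordinates with
#'   per-point intensities (possibly 0 points).
#' @export
detect_centroids <- function(vol, roi = NULL, eps, dog_sigma = c(eps / 4, eps / 2),
                             perimeter_max = NULL, min_rel_peak = 0.1, t = 0L) {
  stopifnot(eps > 0)
  dims <- base::dim(vol)
  # threshold on the full frame (the background statistics live there), then
  # restrict to the ROI prism (mask replicated along z)
  ann <- annealing_threshold(vol, perimeter_max = perimeter_max)
  binary <- ann$binary
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    binary <- binary & array(roi$mask, dims)
  }
  # background-subtract at the annealed threshold so residual just-above-
  # threshold background contributes ~0 response to the DoG
  thr_arr <- if (length(dims) == 3L)
    array(rep(ann$threshold, each = dims[1] * dims[2]), dims)
  else ann$threshold
  vmask <- pmax(vol - thr_arr, 0) * binary
  if (max(vmask) <= 0)
    return(frame_cloud(matrix(numeric(0), 0, 3), t = t))
  dog <- gauss_smooth(vmask, dog_sigma[1]) - gauss_smooth(vmask, dog_sigma[2])
  r <- max(1L, round(eps / 2))
  mx <- max_filter(dog, r)
  peak_thr <- min_rel_peak * max(dog)
  is_peak <- dog >= mx & dog > peak_thr & binary
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(frame_cloud(matrix(numeric(0), 0, 3), t = t))
  pts <- idx - 1                       # 0-based voxel coordinates
  w <- dog[idx]
  # merge maxima closer than eps (single linkage), intensity-weighted mean
  if (nrow(pts) > 1L) {
    cl <- cutree(hclust(dist(pts), method = "single"), h = eps)
  } else cl <- 1L
  merged <- base::t(vapply(split(seq_along(cl), cl), function(g) {
    c(colSums(pts[g, , drop = FALSE] * w[g]) / sum(w[g]), max(w[g]))
  }, numeric(4)))
  frame_cloud(merged[, 1:3, drop = FALSE], t = t, intensity = merged[, 4])
}

# ---- phantom generator ----------------------------------------------------

#' Generate a synthetic 3D image stack from known truth points
#'
#' Sums isotropic Gaussian blobs at the truth positions over a constant
#' background floor (plus an optional linear gradient), adds seeded Gaussian
#' noise, and clips to `[0, 1]`. The nonzero floor mimics the camera /
#' autofluorescence offset of real recordings, so additive noise is not
#' clipped at zero. SNR is `peak / noise_sigma`.
#'
#' @param points truth centroids (n x 3 matrix or [frame_cloud]), 0-based
#'   voxel coordinates inside `dims`.
#' @param dims volume extents (x, y, z).
#' @param blob_sigma Gaussian blob sigma in voxels (default 2).
#' @param peak blob peak intensity above background (default 0.3).
#' @param noise_sigma additive Gaussian noise sd (default 0).
#' @param background constant floor (default 0.4).
#' @param gradient optional per-axis linear background slope (length 3).
#' @param seed optional RNG seed for the noise.
#' @return a 3D array in `[0, 1]`.
#' @export
generate_phantom_stack <- function(points, dims = c(64, 64, 24), blob_sigma = 2,
                                   peak = 0.3, noise_sigma = 0,
                                   background = 0.4, gradient = NULL,
                                   seed = NULL) {
  P <- if (inherits(points, "frame_cloud")) points$xyz else as.matrix(points)
  if (nrow(P) > 0 &&
      (any(P < 0) || any(sweep(P, 2L, dims - 1, ">"))))
    stop("phantom truth points fall outside the volume dims")
  vol <- array(background, dims)
  if (!is.null(gradient)) {
    gx <- (seq_len(dims[1]) - 1) * gradient[1]
    gy <- (seq_len(dims[2]) - 1) * gradient[2]
    gz <- (seq_len(dims[3]) - 1) * gradient[3]
    vol <- vol + outer(outer(gx, gy, "+"), gz, "+")
  }
  r <- ceiling(4 * blob_sigma)
  for (k in seq_len(nrow(P))) {
    c0 <- P[k, ]
    xr <- max(0, floor(c0[1] - r)):min(dims[1] - 1, ceiling(c0[1] + r))
    yr <- max(0, floor(c0[2] - r)):min(dims[2] - 1, ceiling(c0[2] + r))
    zr <- max(0, floor(c0[3] - r)):min(dims[3] - 1, ceiling(c0[3] + r))
    gx <- exp(-(xr - c0[1])^2 / (2 * blob_sigma^2))
    gy <- exp(-(yr - c0[2])^2 / (2 * blob_sigma^2))
    gz <- exp(-(zr - c0[3])^2 / (2 * blob_sigma^2))
    vol[xr + 1, yr + 1, zr + 1] <- vol[xr + 1, yr + 1, zr + 1] +
      peak * outer(outer(gx, gy), gz)
  }
  if (noise_sigma > 0)
    vol <- vol + with_seed(seed, array(rnorm(prod(dims), 0, noise_sigma), dims))
  vol[vol < 0] <- 0; vol[vol > 1] <- 1
  vol
}
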