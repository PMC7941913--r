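test_that("noise estimator reads the generating sigma and assigns bands", {
  # constant image: sigma 0, clean
  nr0 <- estimate_noise(array(0.5, c(32, 32, 4)))
  expect_identical(nr0$sigma, 0)
  expect_equal(nr0$band, "clean")
  # seeded Gaussian noise: estimate within 20% of truth, band normal
  v <- generate_phantom_stack(matrix(c(20, 20, 8), 1, 3), dims = c(48, 48, 16),
                              noise_sigma = 0.03, seed = 1)
  nr <- estimate_noise(v)
  expect_lt(abs(nr$sigma - 0.03) / 0.03, 0.2)
  expect_equal(nr$band, "normal")
  # heavy noise: degenerate
  v2 <- generate_phantom_stack(matrix(c(20, 20, 8), 1, 3), dims = c(48, 48, 16),
                               noise_sigma = 0.12, seed = 2)
  expect_equal(estimate_noise(v2)$band, "degenerate")
  expect_error(estimate_noise(array(NaN, c(8, 8, 2))), "non-finite")
})

test_that("noise estimate is invariant to a clipping-free constant offset", {
  set.seed(5)
  base <- array(0.3, c(40, 40, 6)) + array(rnorm(40 * 40 * 6, 0, 0.02), c(40, 40, 6))
  expect_equal(estimate_noise(base)$sigma, estimate_noise(base + 0.2)$sigma,
               tolerance = 1e-12)
})

test_that("denoise routing honours the band contracts", {
  v <- generate_phantom_stack(matrix(c(24, 24, 8), 1, 3), dims = c(48, 48, 16),
                              noise_sigma = 0.005, seed = 3)
  nr <- estimate_noise(v)
  expect_equal(nr$band, "clean")
  expect_identical(route_denoise(v, nr), v)   # clean passes through untouched
  # normal band: residual noise strictly reduced
  vn <- generate_phantom_stack(matrix(c(24, 24, 8), 1, 3), dims = c(48, 48, 16),
                               noise_sigma = 0.03, seed = 4)
  nrn <- estimate_noise(vn)
  out <- route_denoise(vn, nrn)
  expect_lt(estimate_noise(out)$sigma, nrn$sigma)
  expect_true(all(out >= 0 & out <= 1))
  # degenerate band is refused
  vd <- generate_phantom_stack(matrix(c(24, 24, 8), 1, 3), dims = c(48, 48, 16),
                               noise_sigma = 0.12, seed = 5)
  expect_error(route_denoise(vd, estimate_noise(vd)), "degenerate")
})

test_that("ROI isolates the blob cluster and keeps the largest region only", {
  set.seed(6)
  pts <- pack_points(8, 10, lo = c(18, 18, 6), hi = c(54, 54, 22))
  vol <- generate_phantom_stack(pts, dims = c(72, 72, 28), noise_sigma = 0.02,
                                seed = 6)
  roi <- compute_roi(vol)
  expect_gt(roi$area, 0)
  expect_lte(roi$area, 72 * 72)
  # single connected component
  expect_equal(max(EBImage::bwlabel(roi$mask * 1)), 1)
  # every blob centroid lies inside the mask
  inroi <- roi$mask[cbind(round(pts[, 1]) + 1, round(pts[, 2]) + 1)]
  expect_true(all(inroi))
  # uniform image has no structure
  expect_error(compute_roi(array(0.5, c(64, 64, 8))),
               class = "registrack_degenerate")
})

test_that("ROI keeps the larger of two well-separated clusters", {
  # big cluster of 8 blobs left, single blob far right
  set.seed(8)
  big <- pack_points(8, 8, lo = c(10, 10, 6), hi = c(40, 40, 18))
  lone <- matrix(c(105, 105, 12), 1, 3)
  vol <- generate_phantom_stack(rbind(big, lone), dims = c(120, 120, 24),
                                noise_sigma = 0.01, seed = 8)
  roi <- compute_roi(vol)
  lab <- EBImage::bwlabel(roi$mask * 1)
  expect_equal(max(lab), 1)
  expect_true(all(roi$mask[cbind(round(big[, 1]) + 1, round(big[, 2]) + 1)]))
  expect_false(roi$mask[106, 106])
})

test_that("annealing threshold removes large components and falls back safely", {
  # large dim sheet (perimeter >> bound) plus small bright blobs
  img <- matrix(0, 80, 80)
  img[10:70, 10:70] <- 0.2            # dim sheet, perimeter ~ 244
  img[20:22, 20:22] <- 0.9
  img[50:52, 50:52] <- 0.9
  res <- annealing_threshold(img, perimeter_max = 100, step = 0.01)
  lab <- EBImage::bwlabel(res$binary)
  expect_equal(max(lab), 2)           # only the two blobs remain
  expect_true(res$binary[21, 21] && res$binary[51, 51])
  expect_false(res$binary[40, 40])
  # all-zero image: empty at the first threshold
  res0 <- annealing_threshold(matrix(0, 20, 20))
  expect_false(any(res0$binary))
  # blobs below the bound: lowest threshold accepted, everything retained
  img2 <- matrix(0, 40, 40); img2[5:7, 5:7] <- 0.5
  res2 <- annealing_threshold(img2, perimeter_max = 100)
  expect_true(all(res2$binary[5:7, 5:7]))
  expect_equal(res2$threshold, 0)
})

test_that("centroid detection recovers phantom truth and merges close maxima", {
  set.seed(10)
  pts <- pack_points(8, 10, lo = c(18, 18, 6), hi = c(54, 54, 22))
  vol <- generate_phantom_stack(pts, dims = c(72, 72, 28), blob_sigma = 2,
                                peak = 0.3, noise_sigma = 0.03, seed = 10)
  nr <- estimate_noise(vol)
  vol <- route_denoise(vol, nr)
  roi <- compute_roi(vol)
  cl <- detect_centroids(vol, roi, eps = 5)
  expect_equal(n_points(cl), 8L)
  d <- sqrt(cross_dist2_oracle(cl$xyz, pts))
  expect_true(all(apply(d, 2, min) <= 2))
  # two blobs closer than eps/2 merge into one detection
  close2 <- rbind(c(30, 30, 12), c(32, 30, 12))
  vol2 <- generate_phantom_stack(close2, dims = c(64, 64, 24), blob_sigma = 2,
                                 peak = 0.3)
  cl2 <- detect_centroids(vol2, roi = NULL, eps = 5)
  expect_equal(n_points(cl2), 1L)
  # empty interior: empty cloud
  cl0 <- detect_centroids(array(0.4, c(48, 48, 8)), roi = NULL, eps = 5)
  expect_equal(n_points(cl0), 0L)
})

test_that("phantom generation is deterministic and peak-faithful", {
  p1 <- generate_phantom_stack(matrix(c(20, 25, 10), 1, 3), dims = c(48, 48, 20))
  am <- which(p1 == max(p1), arr.ind = TRUE)[1, ] - 1
  expect_true(all(abs(am - c(20, 25, 10)) <= 1))
  a <- generate_phantom_stack(matrix(c(20, 25, 10), 1, 3), dims = c(48, 48, 20),
                              noise_sigma = 0.05, seed = 42)
  b <- generate_phantom_stack(matrix(c(20, 25, 10), 1, 3), dims = c(48, 48, 20),
                              noise_sigma = 0.05, seed = 42)
  expect_identical(a, b)
  expect_error(generate_phantom_stack(matrix(c(100, 0, 0), 1, 3),
                                      dims = c(48, 48, 20)), "outside")
})
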