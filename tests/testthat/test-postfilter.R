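test_that("ellipse ROI coverage matches the chi-square mass", {
  set.seed(2)
  X <- cbind(x = rnorm(1000, 50, 10), y = rnorm(1000, 40, 5))
  roi <- fit_ellipse_roi(X, n_sigma = 2)
  frac <- mean(in_ellipse(roi, X))
  # theoretical 2D Gaussian mass inside 2 Mahalanobis sd: pchisq(4, df = 2)
  expect_lt(abs(frac - pchisq(4, df = 2)), 0.04)
  # a point 10 Mahalanobis units out is outside
  far <- roi$center + 10 * sqrt(diag(roi$covariance))
  expect_false(in_ellipse(roi, matrix(far, 1, 2)))
  # tight cluster: the bulk of its own members lie inside
  Xt <- cbind(x = rnorm(50, 0, 1), y = rnorm(50, 0, 1))
  expect_gt(mean(in_ellipse(fit_ellipse_roi(Xt, 2), Xt)), 0.8)
})

test_that("degenerate spread is refused with the collapsed axis named", {
  X <- cbind(x = 1:10, y = rep(2, 10))
  expect_error(fit_ellipse_roi(X), "axis y")
})

# Assemble a lifetrack object directly from given per-id step vectors and a
# per-pair global transform: the filter operations are defined on the final
# result (lineages + winning transforms), whatever linked them.
make_fit <- function(tracks, transform, eps = 5, n_frames = 4L) {
  obs <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    P <- tracks[[k]]
    data.frame(id = k, frame = seq_len(nrow(P)), index = k,
               x = P[, 1], y = P[, 2], z = P[, 3])
  }))
  transforms <- vector("list", n_frames)
  for (t in 2:n_frames)
    transforms[[t]] <- structure(list(transform = transform),
                                 class = "scored_transform")
  structure(list(observations = obs, transforms = transforms,
                 n_frames = n_frames,
                 config = tracker_config(eps = eps, seed = 1),
                 life_matrix = build_life_matrix(obs, n_frames)),
            class = "lifetrack")
}

steps_to_track <- function(start, step, n = 4) {
  base::t(vapply(0:(n - 1), function(k) start + k * step, numeric(3)))
}

test_that("angle filter flags counter-moving lineages but not sub-resolution motion", {
  eps <- 5
  shift <- c(6, 0, 0)                       # forward global motion
  Tb <- fit_translation(c(0, 0, 0), -shift) # winner maps t -> t-1
  inlier <- steps_to_track(c(10, 10, 10), shift)
  debris <- steps_to_track(c(80, 80, 15), -3 * eps * c(1, 0, 0))
  fit <- make_fit(list(inlier, debris), Tb, eps = eps)
  rep_angle <- angle_difference_filter(fit, angle_threshold = 90)
  expect_equal(rep_angle$id, 2L)
  expect_equal(rep_angle$reason, "angle-outlier")
  # parallel motion only: no flags
  fit_par <- make_fit(list(inlier), Tb, eps = eps)
  expect_equal(nrow(angle_difference_filter(fit_par)), 0L)
  # antiparallel but sub-eps displacement: kept (no direction evidence)
  slow <- steps_to_track(c(80, 80, 15), -0.5 * c(1, 0, 0))
  fit_sub <- make_fit(list(inlier, slow), Tb, eps = eps)
  expect_equal(nrow(angle_difference_filter(fit_sub)), 0L)
  # zero-length displacement has angle 0 by convention
  still <- steps_to_track(c(40, 40, 12), c(0, 0, 0))
  fit_still <- make_fit(list(still), Tb, eps = eps)
  expect_equal(nrow(angle_difference_filter(fit_still)), 0L)
})

test_that("displacement filter removes tracks far from the global prediction", {
  eps <- 5
  shift <- c(4, 0, 0)
  Tb <- fit_translation(c(0, 0, 0), -shift)
  inlier <- steps_to_track(c(10, 10, 10), shift)
  debris <- steps_to_track(c(85, 85, 15), -5 * eps * c(0, 1, 0))
  fit <- make_fit(list(inlier, debris), Tb, eps = eps)
  rep_disp <- displacement_filter(fit, threshold = 3 * eps)
  expect_equal(rep_disp$id, 2L)
  # threshold = Inf flags nothing
  expect_equal(nrow(displacement_filter(fit, threshold = Inf)), 0L)
  # combined filters assign one primary reason per id
  ff <- apply_track_filters(fit)
  expect_equal(ff$filter_report$id, 2L)
  expect_false(2L %in% ff$observations$id)
  expect_false(any(duplicated(ff$filter_report$id)))
})

test_that("ellipse confinement removes far outliers when enabled", {
  set.seed(15)
  eps <- 5
  shift <- c(4, 0, 0)
  Tb <- fit_translation(c(0, 0, 0), -shift)
  # central Gaussian population plus one far-away static track
  tracks <- lapply(1:30, function(k)
    steps_to_track(c(rnorm(1, 50, 5), rnorm(1, 50, 5), rnorm(1, 12, 2)), shift))
  tracks[[31]] <- steps_to_track(c(500, 500, 12), shift)
  fit <- make_fit(tracks, Tb, eps = eps)
  ff <- apply_track_filters(fit, ellipse = TRUE, n_sigma = 2)
  expect_true(31L %in% ff$filter_report$id)
  expect_equal(ff$filter_report$reason[ff$filter_report$id == 31L],
               "outside-ellipse")
  # idempotent with the stored ellipse
  ff2 <- apply_track_filters(ff, ellipse = TRUE, n_sigma = 2)
  expect_identical(ff2$observations, ff$observations)
})

test_that("filters pass clean surrogate data and are idempotent", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 12, p = 0, u = 0,
                                                     seed = 16), n_frames = 5)
  fit <- track_lineages(sq$frames, eps = 5, seed = 16)
  # zero flags at any positive threshold on noise-free data
  expect_equal(nrow(displacement_filter(fit, threshold = 1e-6 + 0)), 0L)
  f1 <- apply_track_filters(fit)
  expect_equal(nrow(f1$observations), nrow(fit$observations))  # nothing removed
  f2 <- apply_track_filters(f1)
  expect_identical(f2$observations, f1$observations)
  expect_identical(f2$life_matrix, f1$life_matrix)
  # report partition: one primary reason per removed id
  expect_false(any(duplicated(f1$filter_report$id)))
})
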