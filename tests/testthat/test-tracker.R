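test_that("persistent noise-free sequences give one full lineage per object", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 12, p = 0, u = 0,
                                                     seed = 7), n_frames = 5)
  fit <- track_lineages(sq$frames, eps = 5, seed = 7)
  lm <- fit$life_matrix
  expect_equal(nrow(lm), 12L)
  expect_true(all(rowSums(lm) == 5L))
  expect_true(all(lm == 1L))
  # winning transform per pair is the inverse of the generating forward motion
  for (t in 2:5) {
    w <- fit$transforms[[t]]$transform
    g <- invert_transform(sq$gammas[[t]])
    expect_lt(max(abs(w$A - g$A)), 1e-6)
    expect_lt(max(abs(w$b - g$b)), 1e-6)
  }
})

test_that("identifiers partition detections and the life matrix conserves them", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 10, p = 2, u = 0.5,
                                                     seed = 19), n_frames = 6,
                                    death_prob = 0.3)
  fit <- track_lineages(sq$frames, eps = 5, seed = 19)
  total_detections <- sum(vapply(sq$frames, n_points, integer(1)))
  expect_equal(nrow(fit$observations), total_detections)
  # partition: every detection appears exactly once
  expect_false(any(duplicated(fit$observations[c("frame", "index")])))
  # conservation: life-matrix entries = distinct (id, frame) detections
  expect_equal(sum(fit$life_matrix),
               nrow(unique(fit$observations[c("id", "frame")])))
  # identifiers are monotone in creation order
  first_seen <- tapply(fit$observations$frame, fit$observations$id, min)
  expect_true(all(diff(first_seen[order(as.integer(names(first_seen)))] ) >= 0))
})

test_that("tracking is reproducible with the same seed", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 8, p = 3, u = 1,
                                                     seed = 3), n_frames = 5)
  f1 <- track_lineages(sq$frames, eps = 5, seed = 101)
  f2 <- track_lineages(sq$frames, eps = 5, seed = 101)
  expect_identical(f1$observations, f2$observations)
  expect_identical(f1$life_matrix, f2$life_matrix)
})

test_that("link_frame_pair inherits, merges and creates identifiers as specified", {
  # all matched: zero new identifiers
  full <- list(matches = c(2L, 1L, 3L))
  class(full) <- "scored_transform"
  r <- link_frame_pair(full, v_ids = c(10L, 11L, 12L), next_id = 50L)
  expect_equal(r$ids, c(11L, 10L, 12L))
  expect_equal(r$next_id, 50L)
  # 5 points, 3 matched: exactly 2 fresh identifiers
  part <- list(matches = c(1L, NA, 2L, NA, 3L))
  class(part) <- "scored_transform"
  r2 <- link_frame_pair(part, v_ids = c(7L, 8L, 9L), next_id = 100L)
  expect_equal(sum(r2$ids >= 100L), 2L)
  expect_equal(r2$next_id, 102L)
  # two U objects in the same catchment merge into one lineage
  both <- list(matches = c(1L, 1L))
  class(both) <- "scored_transform"
  r3 <- link_frame_pair(both, v_ids = 5L, next_id = 0L)
  expect_equal(r3$ids, c(5L, 5L))
})

test_that("a single-frame object survives tracking but not the min-frames filter", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 10, p = 0, u = 0,
                                                     seed = 2), n_frames = 5)
  # inject a detection present only in frame 3, far from everything
  f3 <- sq$frames[[3]]
  sq$frames[[3]] <- frame_cloud(rbind(f3$xyz, c(500, 500, 200)), t = f3$t)
  fit <- track_lineages(sq$frames, eps = 5, seed = 2)
  lm <- fit$life_matrix
  expect_equal(nrow(lm), 11L)
  expect_equal(sum(rowSums(lm) == 1L), 1L)
  lmf <- filter_min_frames(lm, 2L)
  expect_equal(nrow(lmf), 10L)
  expect_length(attr(lmf, "removed"), 1L)
})

test_that("an empty frame ends all lineages and restarts identities", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 6, p = 0, u = 0,
                                                     seed = 5), n_frames = 4)
  sq$frames[[3]] <- frame_cloud(matrix(numeric(0), 0, 3), t = 3L)
  fit <- track_lineages(sq$frames, eps = 5, seed = 5)
  ids12 <- unique(fit$observations$id[fit$observations$frame <= 2])
  ids4 <- unique(fit$observations$id[fit$observations$frame == 4])
  expect_length(intersect(ids12, ids4), 0L)
})

test_that("life matrix encodes rows directly and filters behave at the bounds", {
  obs <- data.frame(id = c(1L, 1L, 1L), frame = 2:4, index = 1L,
                    x = 0, y = 0, z = 0)
  lm <- build_life_matrix(obs, 5L)
  expect_equal(unname(lm[1, ]), c(0L, 1L, 1L, 1L, 0L))
  expect_equal(nrow(build_life_matrix(obs[0, ], 5L)), 0L)
  lm3 <- rbind(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 1))
  rownames(lm3) <- 1:3
  expect_equal(nrow(filter_min_frames(lm3, 2)), 2L)
  expect_equal(filter_min_frames(lm3, 1), lm3, ignore_attr = TRUE)
  expect_equal(nrow(filter_min_frames(lm3[c(1, 1), ], 2)), 0L)
})

test_that("population series reports counts and mean ages", {
  lm <- matrix(1L, 12, 5, dimnames = list(1:12, 1:5))
  ps <- population_series(lm)
  expect_equal(ps$count, rep(12L, 5))
  expect_equal(ps$mean_age, 1:5)
  expect_equal(population_series(lm[0, ])$count, rep(0L, 5))
  # one long-lived object among early casualties spikes the mean age
  lm2 <- rbind(rep(1L, 10), matrix(c(1L, 1L, rep(0L, 8)), 5, 10, byrow = TRUE))
  rownames(lm2) <- 1:6
  ps2 <- population_series(lm2)
  expect_lt(ps2$mean_age[2], 3)
  expect_equal(ps2$mean_age[10], 10)  # only the survivor remains
})

test_that("lag test reports zero disagreement on rigid noise-free sequences", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 12, p = 0, u = 0,
                                                     seed = 11), n_frames = 8)
  lt <- lag_test(sq$frames, tracker_config(eps = 5, seed = 11))
  expect_equal(lt$fraction, c(0, 0))
  # identical frames (zero motion): also exact
  f <- sq$frames[[1]]
  still <- lapply(1:6, function(t) frame_cloud(f$xyz, t = t))
  lt2 <- lag_test(still, tracker_config(eps = 5, seed = 1))
  expect_equal(lt2$fraction, c(0, 0))
})

test_that("fit methods expose coefficients, residuals and summaries", {
  sq <- generate_surrogate_sequence(surrogate_params(n = 8, p = 0, u = 0.4,
                                                     seed = 23), n_frames = 4)
  fit <- track_lineages(sq$frames, eps = 5, seed = 23)
  co <- coef(fit)
  expect_equal(nrow(co), 3L)
  expect_true(all(c("frame", "kind", "a11", "b3", "cost", "matched") %in% names(co)))
  rs <- residuals(fit)
  expect_true(all(rs$residual >= 0))
  expect_true(all(rs$residual < 5))   # jitter well below eps
  sm <- summary(fit)
  expect_s3_class(sm, "summary.lifetrack")
  expect_equal(sm$n_detections, nrow(fit$observations))
  expect_output(print(fit), "Registration-tracking fit")
  # predict maps frame detections with the winning transform
  pr <- predict(fit, frame = 2)
  expect_equal(dim(pr), c(8L, 3L))
})
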