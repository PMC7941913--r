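#' Surrogate-data parameters
#'
#' Parameters of the ground-truth generator used to validate the tracker:
#' `n` true objects uniformly placed with minimum separation `eps` inside
#' `box`; a random Euclidean transformation with per-axis Euler angles drawn
#' from `[-pi/r, pi/r]` (about the cloud centroid) and per-axis translation
#' from `[0, s]`; per-point uniform jitter from `[0, u]` on each axis of V;
#' and `p` "noise" points added independently to each of U and V at the same
#' minimum separation.
#'
#' @param eps minimum object separation (> 0).
#' @param n number of true points.
#' @param p noise points added to each cloud.
#' @param r rotation-range divisor (angles in `[-pi/r, pi/r]`).
#' @param s translation range upper bound, per axis.
#' @param u per-point jitter bound, per axis.
#' @param box sampling domain extents (length 3).
#' @param seed optional RNG seed.
#' @return an object of class `surrogate_params`.
#' @export
surrogate_params <- function(eps = 5, n = 10L, p = 0L, r = 36, s = 5, u = 0,
                             box = c(100, 100, 50), seed = NULL) {
  stopifnot(eps > 0, n >= 0, p >= 0, r > 0, s >= 0, u >= 0,
            length(box) == 3L, all(box > 0))
  structure(list(eps = eps, n = as.integer(n), p = as.integer(p), r = r,
                 s = s, u = u, box = as.numeric(box), seed = seed),
            class = "surrogate_params")
}

# Rejection-sample points uniform in box with min separation eps from each
# other and from `existing` (matrix or NULL). Errors when packing fails.
sample_packed_points <- function(n, box, eps, existing = NULL,
                                 max_tries = NULL) {
  if (n == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  if (is.null(max_tries)) max_tries <- 500L * n
  pts <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  ref <- existing
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(paste0("packing failure: could not place %d points with ",
                          "separation >= %g in a %g x %g x %g box"),
                   n, eps, box[1], box[2], box[3]))
    cand <- runif(3) * box
    all_ref <- rbind(ref, pts[seq_len(placed), , drop = FALSE])
    if (is.null(all_ref) || nrow(all_ref) == 0L ||
        min(cross_dist2(matrix(cand, 1, 3), all_ref)) >= eps^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

#' Generate a surrogate frame pair with known ground truth
#'
#' Produces clouds `U` and `V = gamma_hat(U) + jitter` plus `p` independent
#' noise points per cloud, and the generating Euclidean transformation.
#' V's rows are randomly permuted so that correspondence is not encoded in
#' point order; the true pairing is returned in `inlier_pairs`.
#'
#' With `u > 0`, jitter draws that would push two points of V closer than
#' `eps` are redrawn (capped retries) so that every generated cloud respects
#' the minimum-separation invariant.
#'
#' @param params a [surrogate_params].
#' @return an object of class `surrogate_truth`: `U`, `V` ([frame_cloud]s),
#'   `gamma_hat` ([affine3]), `inlier_pairs` (n x 2 matrix of (u, v) row
#'   indices), `noise_u`, `noise_v` (noise row indices), `params`.
#' @export
generate_surrogate <- function(params) {
  stopifnot(inherits(params, "surrogate_params"))
  with_seed(params$seed, {
    p <- params
    U_true <- sample_packed_points(p$n, p$box, p$eps)
    center <- if (p$n > 0L) colMeans(U_true) else p$box / 2
    angles <- runif(3, -pi / p$r, pi / p$r)
    shift <- runif(3, 0, p$s)
    gamma_hat <- euler_transform(angles, shift, center)
    V_true <- apply_transform(gamma_hat, U_true)
    if (p$u > 0 && p$n > 0L) {
      for (try in 1:1000) {
        jit <- matrix(runif(3L * p$n, 0, p$u), p$n, 3)
        V_j <- V_true + jit
        if (min_pairwise_dist(V_j) >= p$eps) break
      }
      V_true <- V_j
    }
    U_noise <- sample_packed_points(p$p, p$box, p$eps, existing = U_true)
    V_noise <- sample_packed_points(p$p, p$box, p$eps, existing = V_true)
    U_all <- rbind(U_true, U_noise)
    V_all <- rbind(V_true, V_noise)
    perm <- sample.int(nrow(V_all))
    V_perm <- V_all[perm, , drop = FALSE]
    v_of <- match(seq_len(nrow(V_all)), perm)   # original row -> permuted row
    inlier_pairs <- cbind(u = seq_len(p$n), v = v_of[seq_len(p$n)])
    structure(list(
      U = frame_cloud(U_all, t = 1L, source = "surrogate"),
      V = frame_cloud(V_perm, t = 0L, source = "surrogate"),
      gamma_hat = gamma_hat,
      inlier_pairs = inlier_pairs,
      noise_u = if (p$p > 0L) seq.int(p$n + 1L, p$n + p$p) else integer(0),
      noise_v = if (p$p > 0L) v_of[seq.int(p$n + 1L, p$n + p$p)] else integer(0),
      params = p), class = "surrogate_truth")
  })
}

#' Inlier/outlier classification score against ground truth
#'
#' The validation loss: each U object mapped onto its true partner in V
#' contributes 0, every other object (wrongly matched, unmatched inlier, or
#' noise) contributes -1. The score is the sum, bounded in `[-(n+p), 0]`;
#' the best transformation maximises it. Confusion counts against ground
#' truth are returned alongside.
#'
#' @param matches per-U matched V index or NA (a `scored_transform`'s
#'   `matches` field, or the object itself).
#' @param truth a `surrogate_truth`.
#' @return list with `score`, `per_object` (0/-1 vector), and `confusion`
#'   (named counts: `correct_inlier`, `wrong_match`, `missed_inlier`,
#'   `true_outlier`, `false_match_noise`).
#' @export
classification_loss <- function(matches, truth) {
  if (inherits(matches, "scored_transform")) matches <- matches$matches
  n_all <- n_points(truth$U)
  stopifnot(length(matches) == n_all)
  n <- nrow(truth$inlier_pairs)
  partner <- rep(NA_integer_, n_all)
  partner[truth$inlier_pairs[, 1]] <- truth$inlier_pairs[, 2]
  correct <- !is.na(matches) & !is.na(partner) & matches == partner
  per <- ifelse(correct, 0, -1)
  is_inlier <- seq_len(n_all) <= n
  conf <- c(correct_inlier = sum(correct),
            wrong_match = sum(!is.na(matches) & is_inlier & !correct),
            missed_inlier = sum(is.na(matches) & is_inlier),
            true_outlier = sum(is.na(matches) & !is_inlier),
            false_match_noise = sum(!is.na(matches) & !is_inlier))
  list(score = sum(per), per_object = per, confusion = conf)
}

#' Robustness sweep over translation and rotation magnitudes
#'
#' For each grid cell (s, r), generates `reps` seeded surrogate pairs, runs
#' the full proposal-and-ranking pipeline, and averages the classification
#' score. Reproduces the qualitative robustness map: scores stay near 0 for
#' small rotations and degrade as the rotation range widens.
#'
#' @param s_values,r_values grid of translation bounds and rotation-range
#'   divisors.
#' @param reps replicates per cell.
#' @param base a [surrogate_params] providing all other fields.
#' @param seed base RNG seed; each replicate derives its own.
#' @param n_samples constellation samples in the registration.
#' @return list with `mean` and `se` matrices (rows = s, cols = r) and
#'   `scores` (reps-deep array).
#' @export
robustness_sweep <- function(s_values, r_values, reps = 10L, base = surrogate_params(),
                             seed = 1L, n_samples = 50L) {
  stopifnot(reps >= 1L)
  scores <- array(NA_real_, c(length(s_values), length(r_values), reps),
                  dimnames = list(s = s_values, r = r_values, NULL))
  for (i in seq_along(s_values)) for (j in seq_along(r_values)) {
    for (k in seq_len(reps)) {
      pp <- base
      pp$s <- s_values[i]; pp$r <- r_values[j]
      pp$seed <- child_seed(seed, (i - 1L) * length(r_values) * reps +
                                    (j - 1L) * reps + k)
      tr <- generate_surrogate(pp)
      w <- register_frames(tr$U, tr$V, eps = pp$eps, n_samples = n_samples,
                           seed = child_seed(pp$seed, 1L))
      scores[i, j, k] <- classification_loss(w, tr)$score
    }
  }
  list(mean = apply(scores, c(1, 2), mean),
       se = apply(scores, c(1, 2), function(x) stats::sd(x) / sqrt(length(x))),
       scores = scores)
}

#' Generate a surrogate frame sequence with truth lineages
#'
#' Extends the two-frame scheme to sequences: an independent Euclidean
#' transformation per consecutive pair moves the surviving objects, objects
#' die according to a geometric lifetime model (death probability applied
#' once an object has lived `min_lifetime` frames), and births keep the
#' population at `n` — except when fewer than `min_lifetime` frames remain,
#' so every truth lineage can reach the minimum observable lifetime.
#' `p` transient noise points are added per frame at fresh locations.
#'
#' @param params a [surrogate_params] (`n`, `p`, `r`, `s`, `u`, `eps`, `box`,
#'   `seed`).
#' @param n_frames number of frames (>= 2).
#' @param death_prob per-frame death probability after `min_lifetime`
#'   (default 0: persistent objects).
#' @param min_lifetime minimum truth lifetime in frames (default 2).
#' @return list with `frames` (list of [frame_cloud]s carrying truth ids;
#'   noise points have id NA), `truth` (data.frame id, frame, x, y, z),
#'   `gammas` (per-pair generating [affine3]s; `gammas[[t]]` is the forward
#'   motion from frame t-1 to t, so the tracker's backward winner at t
#'   should recover its inverse).
#' @export
generate_surrogate_sequence <- function(params, n_frames, death_prob = 0,
                                        min_lifetime = 2L) {
  stopifnot(inherits(params, "surrogate_params"), n_frames >= 2L)
  with_seed(params$seed, {
    p <- params
    pos <- sample_packed_points(p$n, p$box, p$eps)
    ids <- seq_len(p$n)
    ages <- rep(1L, p$n)
    next_id <- p$n + 1L
    frames <- vector("list", n_frames)
    gammas <- vector("list", n_frames)
    truth <- list()
    emit <- function(t, pos, ids) {
      noise <- sample_packed_points(p$p, p$box, p$eps, existing = pos)
      all_pos <- rbind(pos, noise)
      all_ids <- c(ids, rep(NA_integer_, nrow(noise)))
      ord <- sample.int(nrow(all_pos))
      frames[[t]] <<- frame_cloud(all_pos[ord, , drop = FALSE], t = t,
                                  ids = all_ids[ord], source = "surrogate")
      if (length(ids))
        truth[[length(truth) + 1L]] <<-
          data.frame(id = ids, frame = t, x = pos[, 1], y = pos[, 2],
                     z = pos[, 3])
    }
    emit(1L, pos, ids)
    for (t in seq.int(2L, n_frames)) {
      center <- if (nrow(pos)) colMeans(pos) else p$box / 2
      g <- euler_transform(runif(3, -pi / p$r, pi / p$r), runif(3, 0, p$s),
                           center)
      gammas[[t]] <- g
      # survival
      die <- ages >= min_lifetime & runif(length(ids)) < death_prob
      pos <- pos[!die, , drop = FALSE]; ids <- ids[!die]; ages <- ages[!die]
      # move survivors (jitter redrawn if it would break the eps packing)
      if (nrow(pos)) {
        pos <- apply_transform(g, pos)
        if (p$u > 0) {
          for (try in 1:1000) {
            cand <- pos + matrix(runif(3L * nrow(pos), 0, p$u), nrow(pos), 3)
            if (min_pairwise_dist(cand) >= p$eps) break
          }
          pos <- cand
        }
      }
      # births (only when a full minimum lifetime still fits)
      want <- p$n - nrow(pos)
      if (want > 0L && (n_frames - t + 1L) >= min_lifetime) {
        born <- sample_packed_points(want, p$box, p$eps, existing = pos)
        pos <- rbind(pos, born)
        ids <- c(ids, seq.int(next_id, length.out = want))
        ages <- c(ages, rep(0L, want))
        next_id <- next_id + want
      }
      ages <- ages + 1L
      emit(t, pos, ids)
    }
    list(frames = frames,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(id = integer(0), frame = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0)),
         gammas = gammas)
  })
}
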