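#' Tracker configuration
#'
#' Bundles the tunable parameters of the tracking pipeline. `eps` is the
#' catchment radius — the central scale of the whole method, chosen slightly
#' larger than the average object radius. `sigma0` documents the assumed
#' per-object Gaussian fluctuation scale underlying the consensus-translation
#' model; it is not used numerically but should inform the choice of `eps`.
#'
#' @param eps catchment radius (> 0), in (isotropic) voxel units.
#' @param lag frame offset tau linked by each registration (default 1).
#' @param lambda_reg displacement regularisation weight (default 0).
#' @param n_samples maximum constellation samples per frame pair.
#' @param consensus_m top translations averaged into the consensus prior.
#' @param min_frames minimum lifetime (frames) kept by the Life-Matrix
#'   filter; single-frame detections are discarded at the default 2.
#' @param sigma0 assumed per-object fluctuation scale (documentation only).
#' @param seed integer RNG seed; every random draw in a tracking run derives
#'   from it.
#' @param variant Eq. cost variant, `"literal"` or `"squared-cap"`.
#' @param mode constellation fit mode, `"rigid"` or `"affine"`.
#' @param carry_forward add the previous pair's winner as a prior candidate.
#' @return an object of class `tracker_config`.
#' @export
tracker_config <- function(eps, lag = 1L, lambda_reg = 0, n_samples = 50L,
                           consensus_m = 5L, min_frames = 2L, sigma0 = NULL,
                           seed = 1L, variant = c("literal", "squared-cap"),
                           mode = c("rigid", "affine"), carry_forward = TRUE) {
  variant <- match.arg(variant); mode <- match.arg(mode)
  stopifnot(eps > 0, lag >= 1L, min_frames >= 1L, lambda_reg >= 0)
  structure(list(eps = eps, lag = as.integer(lag), lambda_reg = lambda_reg,
                 n_samples = as.integer(n_samples),
                 consensus_m = as.integer(consensus_m),
                 min_frames = as.integer(min_frames), sigma0 = sigma0,
                 seed = as.integer(seed), variant = variant, mode = mode,
                 carry_forward = carry_forward),
            class = "tracker_config")
}

#' Link one frame pair and assign identifiers
#'
#' Applies the winning transformation's matches: every matched U object
#' inherits the identifier of its V partner; several U objects matched into
#' the same V catchment are merged into that single lineage (multiple points
#' in one epsilon-ball are read as the same object); every unmatched U object
#' receives a fresh identifier from a monotone counter.
#'
#' @param winner `scored_transform` for the pair (from [register_frames()]).
#' @param v_ids identifiers of the V-frame detections.
#' @param next_id next fresh identifier (integer).
#' @return list with `ids` (per-U identifiers) and `next_id`.
#' @export
link_frame_pair <- function(winner, v_ids, next_id) {
  n <- length(winner$matches)
  ids <- integer(n)
  for (i in seq_len(n)) {
    j <- winner$matches[i]
    if (!is.na(j)) {
      ids[i] <- v_ids[j]
    } else {
      ids[i] <- next_id
      next_id <- next_id + 1L
    }
  }
  list(ids = ids, next_id = next_id)
}

#' Track lineages across a frame sequence
#'
#' The central fit. For each frame pair (t, t - lag) the registration core
#' proposes and ranks candidate transformations (pair translations,
#' linkage-seeded constellations, identity / carry-forward / consensus
#' priors), picks the winner, and propagates identifiers: matched objects
#' inherit their partner's identity, unmatched objects found fresh ones.
#' A frame with zero detections ends all running lineages; the next frame's
#' objects all receive fresh identifiers.
#'
#' @param frames list of [frame_cloud]s in time order (>= 2 frames for
#'   lag 1; generally `lag + 1` frames).
#' @param config a [tracker_config]; alternatively pass `eps` and friends
#'   via `...` and leave `config` missing.
#' @param ... fields forwarded to [tracker_config()] when `config` is missing.
#' @return an object of class `lifetrack` with fields:
#'   `observations` (data.frame id, frame, index, x, y, z),
#'   `transforms` (per-pair winning `scored_transform`s, NULL where
#'   degenerate), `life_matrix` (unfiltered binary matrix),
#'   `n_frames`, `config`, `frame_times`.
#' @examples
#' seq6 <- generate_surrogate_sequence(surrogate_params(n = 8, seed = 3),
#'                                     n_frames = 4)
#' fit <- track_lineages(seq6$frames, eps = 5, seed = 3)
#' summary(fit)
#' @export
track_lineages <- function(frames, config, ...) {
  if (missing(config)) config <- tracker_config(...)
  stopifnot(inherits(config, "tracker_config"))
  nT <- length(frames)
  tau <- config$lag
  if (nT < tau + 1L) stop("tracking requires at least lag + 1 frames")

  ids <- vector("list", nT)
  transforms <- vector("list", nT)   # transforms[[t]] links t -> t - tau
  next_id <- 0L
  # frames 1..tau start the sequence: all identifiers are fresh
  for (t in seq_len(min(tau, nT))) {
    n <- n_points(frames[[t]])
    ids[[t]] <- if (n > 0L) seq.int(next_id, length.out = n) else integer(0)
    next_id <- next_id + n
  }
  for (t in seq.int(tau + 1L, nT)) {
    U <- frames[[t]]; V <- frames[[t - tau]]
    nU <- n_points(U)
    if (nU == 0L) { ids[[t]] <- integer(0); next }
    if (n_points(V) == 0L) {
      # degenerate pair: every lineage ended, everything here is new
      ids[[t]] <- seq.int(next_id, length.out = nU)
      next_id <- next_id + nU
      next
    }
    priors <- list()
    if (config$carry_forward && t - 1L >= tau + 1L &&
        !is.null(transforms[[t - 1L]]))
      priors <- list(transforms[[t - 1L]]$transform)
    winner <- register_frames(U, V, eps = config$eps,
                              lambda_reg = config$lambda_reg,
                              n_samples = config$n_samples,
                              consensus_m = config$consensus_m,
                              mode = config$mode, variant = config$variant,
                              priors = priors,
                              seed = child_seed(config$seed, t))
    linked <- link_frame_pair(winner, ids[[t - tau]], next_id)
    ids[[t]] <- linked$ids
    next_id <- linked$next_id
    transforms[[t]] <- winner
  }

  obs <- do.call(rbind, lapply(seq_len(nT), function(t) {
    n <- n_points(frames[[t]])
    if (n == 0L) return(NULL)
    data.frame(id = ids[[t]], frame = t, index = seq_len(n),
               x = frames[[t]]$xyz[, 1], y = frames[[t]]$xyz[, 2],
               z = frames[[t]]$xyz[, 3])
  }))
  if (is.null(obs))
    obs <- data.frame(id = integer(0), frame = integer(0), index = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  fit <- structure(list(observations = obs, transforms = transforms,
                        ids = ids, n_frames = nT, config = config,
                        frame_times = vapply(frames, function(f) f$t, integer(1)),
                        next_id = next_id),
                   class = "lifetrack")
  fit$life_matrix <- build_life_matrix(fit$observations, nT)
  fit
}

#' Build the Life Matrix
#'
#' The binary objects-by-frames matrix: entry (r, c) is 1 iff lineage r was
#' detected in frame c. Rows are ordered by identifier (creation order).
#'
#' @param observations data.frame with columns `id` and `frame` (as in a
#'   `lifetrack`'s `observations`), or a `lifetrack`.
#' @param n_frames number of frames (columns).
#' @return binary integer matrix with rownames = identifiers.
#' @export
build_life_matrix <- function(observations, n_frames) {
  if (inherits(observations, "lifetrack")) {
    n_frames <- observations$n_frames
    observations <- observations$observations
  }
  uid <- sort(unique(observations$id))
  lm <- matrix(0L, length(uid), n_frames,
               dimnames = list(uid, seq_len(n_frames)))
  if (nrow(observations) > 0L) {
    r <- match(observations$id, uid)
    lm[cbind(r, observations$frame)] <- 1L
  }
  lm
}

#' Filter short-lived rows from a Life Matrix
#'
#' Debris moves uncorrelated with the global motion and typically shows up
#' as single-frame events; rows observed for fewer than `min_frames` frames
#' are removed.
#'
#' @param lm binary Life Matrix.
#' @param min_frames minimum row sum kept (default 2).
#' @return filtered matrix, with attribute `"removed"` holding the removed
#'   identifiers.
#' @export
filter_min_frames <- function(lm, min_frames = 2L) {
  stopifnot(min_frames >= 1L)
  keep <- rowSums(lm) >= min_frames
  out <- lm[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(lm)[!keep]
  out
}

#' Population time series from a Life Matrix
#'
#' @param lm binary Life Matrix.
#' @return data.frame with `frame`, `count` (objects alive) and `mean_age`
#'   (mean frames since first appearance, inclusive; 0 for empty frames).
#' @export
population_series <- function(lm) {
  nT <- ncol(lm)
  if (nrow(lm) == 0L)
    return(data.frame(frame = seq_len(nT), count = 0L, mean_age = 0))
  first <- apply(lm, 1L, function(r) which(r == 1L)[1L])
  counts <- colSums(lm)
  mean_age <- vapply(seq_len(nT), function(t) {
    alive <- lm[, t] == 1L
    if (!any(alive)) return(0)
    mean(t - first[alive] + 1)
  }, numeric(1))
  data.frame(frame = seq_len(nT), count = as.integer(counts),
             mean_age = mean_age)
}

#' Lag consistency test
#'
#' Runs the tracking independently at several lags and checks the chain
#' identity: linking t to t - k through k successive lag-1 registrations
#' should agree with the direct lag-k registration. For each detection the
#' chained lag-1 partner set at frame t - k is compared with the direct
#' lag-k partner set; a lineage disagrees if any of its detections
#' disagrees. Single-frame detections are excluded, and lag-3 disagreements
#' are counted after excluding the lineages already disagreeing at lag 2.
#'
#' @param frames list of [frame_cloud]s.
#' @param config a [tracker_config] (its `lag` field is overridden per run).
#' @param lags integer lags to compare against the lag-1 chain (default 2:3).
#' @return data.frame with columns `lag`, `n_objects`, `n_disagree`,
#'   `fraction`; a lag whose tracking is degenerate is reported as NA.
#' @export
lag_test <- function(frames, config, lags = c(2L, 3L)) {
  stopifnot(length(frames) > max(lags))
  base_cfg <- config; base_cfg$lag <- 1L
  fit1 <- track_lineages(frames, base_cfg)
  ids1 <- fit1$ids
  lm1 <- filter_min_frames(fit1$life_matrix, 2L)
  valid_ids <- as.integer(rownames(lm1))   # exclude single-frame detections

  excluded <- integer(0)
  out <- data.frame(lag = integer(0), n_objects = integer(0),
                    n_disagree = integer(0), fraction = numeric(0))
  for (k in sort(lags)) {
    cfgk <- config; cfgk$lag <- as.integer(k)
    fitk <- tryCatch(track_lineages(frames, cfgk), error = function(e) NULL)
    if (is.null(fitk)) {
      out <- rbind(out, data.frame(lag = k, n_objects = NA_integer_,
                                   n_disagree = NA_integer_, fraction = NA_real_))
      next
    }
    idsk <- fitk$ids
    objs <- setdiff(valid_ids, excluded)
    disagree <- logical(length(objs)); names(disagree) <- objs
    for (t in seq.int(k + 1L, length(frames))) {
      for (i in seq_along(ids1[[t]])) {
        oid <- ids1[[t]][i]
        pos <- match(oid, objs)
        if (is.na(pos) || disagree[pos]) next
        chained <- which(ids1[[t - k]] == oid)
        direct <- which(idsk[[t - k]] == idsk[[t]][i])
        if (!identical(sort(chained), sort(direct))) disagree[pos] <- TRUE
      }
    }
    nd <- sum(disagree)
    out <- rbind(out, data.frame(lag = k, n_objects = length(objs),
                                 n_disagree = nd,
                                 fraction = if (length(objs)) nd / length(objs) else 0))
    excluded <- c(excluded, as.integer(names(disagree)[disagree]))
  }
  out
}
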