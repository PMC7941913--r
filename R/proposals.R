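#' Candidate transformation
#'
#' A candidate global frame-to-frame map together with its provenance:
#' `"pair-translation"` (generated from one (u, v) object pair),
#' `"constellation"` (fitted to a sampled triangle of linked pairs), or
#' `"prior"` (identity, carried-forward winner, consensus, refit).
#'
#' @param transform an [affine3].
#' @param provenance one of `"pair-translation"`, `"constellation"`, `"prior"`.
#' @param generator the generating pair indices or constellation index sets.
#' @return an object of class `candidate_transform`.
#' @export
candidate_transform <- function(transform,
                                provenance = c("pair-translation", "constellation", "prior"),
                                generator = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(transform, "affine3"))
  if (provenance == "pair-translation" && transform$kind != "translation")
    stop("pair-translation candidates must be of translation kind")
  structure(list(transform = transform, provenance = provenance,
                 generator = generator), class = "candidate_transform")
}

#' Propose all pairwise translations between two frames
#'
#' One translation candidate `v - u` per ordered pair (u in U, v in V);
#' duplicates (within 1e-9 per axis) are removed. These are the k = 1
#' single-object samples: each assumes one specific object correspondence
#' and lets the cost function judge the rest.
#'
#' @param U,V [frame_cloud]s at times t and t - tau.
#' @return list of [candidate_transform]s (empty if either cloud is empty).
#' @export
propose_translations <- function(U, V) {
  if (n_points(U) == 0L || n_points(V) == 0L) return(list())
  nu <- n_points(U); nv <- n_points(V)
  iu <- rep(seq_len(nu), times = nv)
  iv <- rep(seq_len(nv), each = nu)
  D <- V$xyz[iv, , drop = FALSE] - U$xyz[iu, , drop = FALSE]
  keep <- !duplicated(round(D / 1e-9))
  lapply(which(keep), function(k)
    candidate_transform(affine3(diag(3), D[k, ], "translation"),
                        "pair-translation", generator = c(u = iu[k], v = iv[k])))
}

#' Linkages induced by a candidate transformation
#'
#' Projects U under the candidate and greedily matches projected points to
#' their nearest V neighbour within radius `eps`, one-to-one, by ascending
#' distance with index-order tie-breaking. The resulting pairs are the
#' likely inliers used to seed constellation sampling.
#'
#' @param U,V [frame_cloud]s.
#' @param candidate a [candidate_transform] or [affine3].
#' @param eps catchment radius (> 0).
#' @return integer matrix with columns `u`, `v` (possibly 0 rows); no index
#'   repeats on either side.
#' @export
seed_linkages <- function(U, V, candidate, eps) {
  stopifnot(eps > 0)
  T <- if (inherits(candidate, "candidate_transform")) candidate$transform else candidate
  if (n_points(U) == 0L || n_points(V) == 0L)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("u", "v"))))
  P <- apply_transform(T, U$xyz)
  d2 <- cross_dist2(P, V$xyz)
  ok <- which(d2 <= eps^2, arr.ind = TRUE)
  if (nrow(ok) == 0L)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("u", "v"))))
  ord <- order(d2[ok], ok[, 1L], ok[, 2L])
  ok <- ok[ord, , drop = FALSE]
  used_u <- logical(nrow(P)); used_v <- logical(nrow(V$xyz))
  keep <- logical(nrow(ok))
  for (k in seq_len(nrow(ok))) {
    i <- ok[k, 1L]; j <- ok[k, 2L]
    if (!used_u[i] && !used_v[j]) {
      keep[k] <- TRUE; used_u[i] <- TRUE; used_v[j] <- TRUE
    }
  }
  out <- ok[keep, , drop = FALSE]
  out <- out[order(out[, 1L]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("u", "v"))
  out
}

#' Propose constellation-based transformations
#'
#' Samples size-3 subsets of the linked pairs (matched triangles on both
#' sides) and fits one transformation per subset with
#' [fit_constellation_transform()]. When the number of distinct triangles
#' `choose(L, 3)` does not exceed `n_samples` all of them are enumerated;
#' otherwise subsets are drawn at random (without replacement within a
#' subset), deduplicated by their canonical sorted form, with degenerate
#' (collinear) draws skipped and redrawn up to a retry cap.
#'
#' @param U,V [frame_cloud]s.
#' @param linkage integer matrix of linked (u, v) index pairs, as returned
#'   by [seed_linkages()].
#' @param n_samples maximum number of constellation candidates.
#' @param mode passed to [fit_constellation_transform()].
#' @param seed optional RNG seed for reproducible sampling.
#' @return list of [candidate_transform]s; empty if fewer than 3 linkages.
#' @export
propose_constellation_transforms <- function(U, V, linkage, n_samples = 50L,
                                             mode = c("rigid", "affine"),
                                             seed = NULL) {
  mode <- match.arg(mode)
  L <- nrow(linkage)
  if (is.null(L) || L < 3L) return(list())
  stopifnot(n_samples >= 1L)
  triples <- if (choose(L, 3) <= n_samples) {
    combn(L, 3, simplify = FALSE)
  } else {
    with_seed(seed, {
      seen <- character(0); out <- list()
      tries <- 0L; cap <- 20L * n_samples
      while (length(out) < n_samples && tries < cap) {
        tries <- tries + 1L
        tri <- sort(sample.int(L, 3L))
        key <- paste(tri, collapse = ",")
        if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- tri }
      }
      out
    })
  }
  cands <- list()
  for (tri in triples) {
    src <- U$xyz[linkage[tri, 1L], , drop = FALSE]
    dst <- V$xyz[linkage[tri, 2L], , drop = FALSE]
    T <- tryCatch(fit_constellation_transform(src, dst, mode = mode),
                  registrack_degenerate = function(e) NULL)
    if (!is.null(T))
      cands[[length(cands) + 1L]] <- candidate_transform(
        T, "constellation",
        generator = list(u = linkage[tri, 1L], v = linkage[tri, 2L]))
  }
  cands
}

#' Prior (model-based) candidate transformations
#'
#' Candidates injected from modelling assumptions rather than from the data:
#' always the identity (no-motion prior); optionally the previous frame
#' pair's winning transformation (carry-forward) and a consensus translation.
#'
#' @param previous_winner optional [affine3] from the previous frame pair.
#' @param consensus optional consensus translation [affine3]
#'   (see [consensus_translation()]).
#' @param include_identity include the identity transform (default TRUE).
#' @return list of [candidate_transform]s with provenance `"prior"`.
#' @export
prior_candidates <- function(previous_winner = NULL, consensus = NULL,
                             include_identity = TRUE) {
  out <- list()
  if (include_identity)
    out[[length(out) + 1L]] <- candidate_transform(identity_transform(), "prior",
                                                   generator = "identity")
  if (!is.null(previous_winner))
    out[[length(out) + 1L]] <- candidate_transform(previous_winner, "prior",
                                                   generator = "carry-forward")
  if (!is.null(consensus))
    out[[length(out) + 1L]] <- candidate_transform(consensus, "prior",
                                                   generator = "consensus")
  out
}
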