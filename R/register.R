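#' Register one frame pair
#'
#' The registration core: proposes candidate transformations from the data
#' (all pair translations, then rigid fits to triangular constellations of
#' linkage-seeded likely inliers, plus prior candidates), ranks them with the
#' epsilon-capped nearest-neighbour cost, and returns the winner. The
#' convention follows the tracking direction: the winner maps `U` (time t)
#' backward onto `V` (time t - tau).
#'
#' A final refinement completes the least-squares fit: the winner's matched
#' pairs (when at least 3 and non-degenerate) are refit by orthogonal
#' Procrustes over all matches, and the refit replaces the winner only when
#' it scores strictly better.
#'
#' @param U [frame_cloud] at time t.
#' @param V [frame_cloud] at time t - tau.
#' @param eps catchment radius (> 0), slightly larger than the average
#'   object radius.
#' @param lambda_reg displacement regularisation weight (default 0).
#' @param n_samples maximum constellation samples (default 50).
#' @param consensus_m top translations averaged into the consensus prior.
#' @param mode constellation fit mode, `"rigid"` (default) or `"affine"`.
#' @param variant cost variant, see [capped_nn_cost()].
#' @param priors optional list of extra prior [affine3]s (e.g. the previous
#'   pair's winner).
#' @param seed optional RNG seed (constellation sampling only).
#' @param refine logical; run the Procrustes refinement step (default TRUE).
#' @return the winning `scored_transform`, with attribute `"n_candidates"`.
#' @examples
#' s <- generate_surrogate(surrogate_params(n = 8, seed = 1))
#' w <- register_frames(s$U, s$V, eps = 5)
#' w$cost   # 0 on noise-free surrogate data
#' @export
register_frames <- function(U, V, eps, lambda_reg = 0, n_samples = 50L,
                            consensus_m = 5L, mode = c("rigid", "affine"),
                            variant = c("literal", "squared-cap"),
                            priors = list(), seed = NULL, refine = TRUE) {
  mode <- match.arg(mode); variant <- match.arg(variant)
  trans <- propose_translations(U, V)
  pri <- prior_candidates(include_identity = TRUE)
  for (p in priors)
    pri[[length(pri) + 1L]] <- candidate_transform(p, "prior", "user-prior")
  cands <- c(trans, pri)
  ranked0 <- rank_candidates(cands, U, V, eps, lambda_reg, variant)

  # consensus translation from the translation ranking
  cons <- consensus_translation(ranked0, m = consensus_m)

  # seed constellations with linkages pooled from the top-ranked candidates:
  # a single translation may explain only part of a rotated cloud, so pairs
  # from several good translations are merged (one-to-one, rank order)
  lk <- pool_linkages(U, V, ranked0, eps)
  const <- if (nrow(lk) >= 3L)
    propose_constellation_transforms(U, V, lk, n_samples = n_samples,
                                     mode = mode, seed = seed)
  else list()

  all_cands <- c(cands, const,
                 list(candidate_transform(cons, "prior", "consensus")))
  ranked <- rank_candidates(all_cands, U, V, eps, lambda_reg, variant)
  winner <- ranked[[1L]]

  if (refine) {
    for (iter in 1:5) {
      mi <- which(!is.na(winner$matches))
      if (length(mi) < 3L) break
      src <- U$xyz[mi, , drop = FALSE]
      dst <- V$xyz[winner$matches[mi], , drop = FALSE]
      Tr <- tryCatch(
        if (mode == "rigid") fit_rigid_lsq(src, dst)
        else fit_constellation_transform(src[1:3, ], dst[1:3, ], mode = "affine"),
        error = function(e) NULL)
      if (is.null(Tr)) break
      cand <- candidate_transform(Tr, "prior", "refit")
      sc <- capped_nn_cost(cand, U, V, eps, variant)
      sc$reg_cost <- regularized_cost(sc, lambda_reg)
      if (sc$reg_cost < winner$reg_cost - 1e-12) winner <- sc else break
    }
  }
  attr(winner, "n_candidates") <- length(all_cands)
  winner
}

# Union of seed_linkages() over the best-ranked candidates, kept one-to-one
# (first occurrence in rank order wins), capped at `max_candidates` sources.
pool_linkages <- function(U, V, ranked, eps, max_candidates = 10L) {
  used_u <- logical(n_points(U)); used_v <- logical(n_points(V))
  pool <- matrix(integer(), 0, 2, dimnames = list(NULL, c("u", "v")))
  for (s in head(ranked, max_candidates)) {
    lk <- seed_linkages(U, V, s$transform, eps)
    for (k in seq_len(nrow(lk))) {
      i <- lk[k, 1L]; j <- lk[k, 2L]
      if (!used_u[i] && !used_v[j]) {
        pool <- rbind(pool, lk[k, , drop = FALSE])
        used_u[i] <- TRUE; used_v[j] <- TRUE
      }
    }
    if (nrow(pool) >= min(n_points(U), n_points(V))) break
  }
  pool[order(pool[, 1L]), , drop = FALSE]
}
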