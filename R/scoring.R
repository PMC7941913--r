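#' Epsilon-capped nearest-neighbour cost of a candidate transformation
#'
#' The ranking objective. Each object u_i of U is projected back by the
#' candidate, `u~_i = T(u_i)`, and compared with its nearest neighbour in V:
#' if that neighbour lies within radial distance `eps` the per-object cost is
#' `min(eps, d^2)` and the neighbour is recorded as the object's match;
#' otherwise the capped penalty `eps + 1` is attributed and the object is
#' unmatched — strictly worse than any matched object. The total cost is the
#' sum over U. The `"squared-cap"` variant uses `min(eps^2, d^2)` with
#' penalty `eps^2 + 1` instead.
#'
#' @param candidate a [candidate_transform] or bare [affine3].
#' @param U,V [frame_cloud]s (V must be non-empty).
#' @param eps catchment radius (> 0).
#' @param variant `"literal"` (default) or `"squared-cap"`.
#' @return an object of class `scored_transform`: fields `candidate`,
#'   `transform`, `provenance`, `cost`, `matches` (per-U V index or NA),
#'   `matched_count`, `match_dist` (distance to match, NA if none).
#' @export
capped_nn_cost <- function(candidate, U, V, eps, variant = c("literal", "squared-cap")) {
  variant <- match.arg(variant)
  stopifnot(eps > 0)
  cand <- if (inherits(candidate, "candidate_transform")) candidate
          else candidate_transform(candidate, "prior")
  if (n_points(V) == 0L) stop("capped_nn_cost: V is empty")
  n <- n_points(U)
  if (n == 0L) {
    return(structure(list(candidate = cand, transform = cand$transform,
                          provenance = cand$provenance, cost = 0,
                          matches = integer(0), matched_count = 0L,
                          match_dist = numeric(0)),
                     class = "scored_transform"))
  }
  P <- apply_transform(cand$transform, U$xyz)
  d2 <- cross_dist2(P, V$xyz)
  nn <- max.col(-d2, ties.method = "first")
  # recompute the winning distance directly: the expanded quadratic form
  # above suffers cancellation, and an exact-overlap pair must cost exactly 0
  nn_d2 <- rowSums((P - V$xyz[nn, , drop = FALSE])^2)
  inside <- nn_d2 <= eps^2
  cap <- if (variant == "literal") eps else eps^2
  per <- ifelse(inside, pmin(cap, nn_d2), cap + 1)
  matches <- ifelse(inside, nn, NA_integer_)
  structure(list(candidate = cand, transform = cand$transform,
                 provenance = cand$provenance, cost = sum(per),
                 matches = as.integer(matches),
                 matched_count = sum(inside),
                 match_dist = ifelse(inside, sqrt(nn_d2), NA_real_)),
            class = "scored_transform")
}

#' @export
print.scored_transform <- function(x, ...) {
  cat(sprintf("<scored_transform %s: cost=%.6g, matched %d/%d>\n",
              x$provenance, x$cost, x$matched_count, length(x$matches)))
  invisible(x)
}

#' Displacement-regularised cost
#'
#' Adds a quadratic penalty on the translation component so that, among
#' near-equal explanations, the smaller displacement is preferred:
#' `cost + lambda_reg * ||b||^2`.
#'
#' @param scored a `scored_transform`.
#' @param lambda_reg non-negative penalty weight (0 leaves the cost unchanged).
#' @return numeric regularised cost.
#' @export
regularized_cost <- function(scored, lambda_reg = 0) {
  stopifnot(lambda_reg >= 0)
  scored$cost + lambda_reg * sum(scored$transform$b^2)
}

# provenance sort order for deterministic tie-breaking
.prov_rank <- c("pair-translation" = 1L, "constellation" = 2L, "prior" = 3L)

#' Score and rank candidate transformations
#'
#' Scores every candidate with [capped_nn_cost()] and orders by ascending
#' regularised cost; exact ties are broken by smaller translation norm, then
#' provenance (translation < constellation < prior), then insertion order.
#' The first element is the winning transformation.
#'
#' @inheritParams capped_nn_cost
#' @param candidates non-empty list of [candidate_transform]s.
#' @param lambda_reg passed to [regularized_cost()].
#' @return list of `scored_transform`s, best first, each with a `reg_cost`
#'   field added.
#' @export
rank_candidates <- function(candidates, U, V, eps, lambda_reg = 0,
                            variant = c("literal", "squared-cap")) {
  variant <- match.arg(variant)
  if (length(candidates) == 0L)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = "no candidate transformations for this frame pair",
                        call = sys.call())))
  scored <- lapply(candidates, capped_nn_cost, U = U, V = V, eps = eps,
                   variant = variant)
  reg <- vapply(scored, regularized_cost, numeric(1), lambda_reg = lambda_reg)
  tnorm <- vapply(scored, function(s) sum(s$transform$b^2), numeric(1))
  prov <- .prov_rank[vapply(scored, function(s) s$provenance, character(1))]
  ord <- order(reg, tnorm, prov, seq_along(scored))
  out <- scored[ord]
  for (k in seq_along(out)) out[[k]]$reg_cost <- reg[ord][k]
  out
}

#' Consensus translation
#'
#' Object displacements are modelled as a global translation plus small
#' Gaussian per-object fluctuations; averaging the top-m ranked translations
#' filters the fluctuations out and reveals the global movement. Returns the
#' component-wise mean of the top-m translation-kind candidates as a new
#' translation; with fewer than m available all are used, and with none the
#' identity is returned.
#'
#' @param ranked list of `scored_transform`s, best first
#'   (from [rank_candidates()]).
#' @param m number of top translations to average.
#' @return an [affine3] of kind `"translation"`.
#' @export
consensus_translation <- function(ranked, m = 5L) {
  stopifnot(m >= 1L)
  is_tr <- vapply(ranked, function(s) s$transform$kind == "translation", logical(1))
  tr <- ranked[is_tr]
  if (length(tr) == 0L) return(identity_transform())
  tr <- tr[seq_len(min(m, length(tr)))]
  B <- do.call(rbind, lapply(tr, function(s) s$transform$b))
  affine3(diag(3), colMeans(B), "translation")
}
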