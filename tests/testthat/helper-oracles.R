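# Independent oracles and small constructors used across the tests.
# These deliberately use naive loops / different code paths than the package.

# Brute-force Eq.-style cost of one transform: explicit double loop.
brute_cost <- function(T, U, V, eps) {
  P <- apply_transform(T, U$xyz)
  total <- 0
  matches <- rep(NA_integer_, nrow(P))
  for (i in seq_len(nrow(P))) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(nrow(V$xyz))) {
      d <- sqrt(sum((P[i, ] - V$xyz[j, ])^2))
      if (d < best) { best <- d; bj <- j }
    }
    if (best <= eps) {
      total <- total + min(eps, best^2)
      matches[i] <- bj
    } else total <- total + eps + 1
  }
  list(cost = total, matches = matches)
}

# Brute-force nearest-neighbour matching (no greedy one-to-one constraint).
brute_nn <- function(P, Q) {
  vapply(seq_len(nrow(P)), function(i)
    which.min(colSums((base::t(Q) - P[i, ])^2)), integer(1))
}

# Random cloud of n points in a box (no separation constraint).
random_cloud <- function(n, t = 0L, box = c(50, 50, 25)) {
  frame_cloud(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                    runif(n, 0, box[3])), t = t)
}

unit_triangle <- function() {
  matrix(c(0, 0, 0,
           1, 0, 0,
           0, 1, 0), 3, 3, byrow = TRUE)
}

cross_dist2_oracle <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% base::t(Q)
  pmax(d2, 0)
}

# Pack points with a minimum separation inside given per-axis ranges.
pack_points <- function(n, sep, lo, hi) {
  P <- matrix(NA_real_, 0, 3)
  while (nrow(P) < n) {
    c0 <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
    if (nrow(P) == 0 || min(sqrt(rowSums(sweep(P, 2, c0)^2))) >= sep)
      P <- rbind(P, c0)
  }
  unname(P)
}
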