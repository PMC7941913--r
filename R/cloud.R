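#' A frame's detected point cloud
#'
#' Container for the object centroids detected at one time point. An optional
#' per-axis scale (physical voxel size) is applied once at construction so
#' that all downstream distances are Euclidean in a single isotropic unit;
#' this is how anisotropic z-spacing is handled.
#'
#' @param xyz n x 3 numeric matrix (or data.frame with columns x, y, z) of
#'   centroid coordinates, 0-based continuous voxel units.
#' @param t non-negative integer frame index.
#' @param ids optional per-point identifiers.
#' @param intensity optional per-point intensity.
#' @param scale optional per-axis scale vector applied multiplicatively once.
#' @param source provenance tag: `"detected"`, `"surrogate"` or `"file"`.
#' @return an object of class `frame_cloud` with fields `t`, `xyz`, `ids`,
#'   `intensity`, `source`.
#' @export
frame_cloud <- function(xyz, t = 0L, ids = NULL, intensity = NULL, scale = NULL,
                        source = c("detected", "surrogate", "file")) {
  source <- match.arg(source)
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), ncol = 3)
  xyz <- matrix(as.numeric(xyz), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  stopifnot(all(is.finite(xyz)), length(t) == 1L, t >= 0)
  if (!is.null(scale)) {
    stopifnot(length(scale) == 3L, all(scale > 0))
    xyz <- sweep(xyz, 2L, as.numeric(scale), "*")
  }
  if (!is.null(ids)) stopifnot(length(ids) == nrow(xyz))
  if (!is.null(intensity)) stopifnot(length(intensity) == nrow(xyz))
  structure(list(t = as.integer(t), xyz = xyz, ids = ids,
                 intensity = intensity, source = source),
            class = "frame_cloud")
}

#' @export
print.frame_cloud <- function(x, ...) {
  cat(sprintf("<frame_cloud t=%d, %d points, source=%s>\n",
              x$t, nrow(x$xyz), x$source))
  invisible(x)
}

#' Number of points in a frame cloud
#' @param cloud a [frame_cloud].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$xyz)

# Squared Euclidean cross-distance matrix between row-point matrices P, Q.
cross_dist2 <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  d2[d2 < 0] <- 0
  d2
}

# Minimum pairwise distance within a point matrix (Inf for < 2 points).
min_pairwise_dist <- function(P) {
  if (nrow(P) < 2L) return(Inf)
  d2 <- cross_dist2(P, P)
  diag(d2) <- Inf
  sqrt(min(d2))
}
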