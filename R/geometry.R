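#' Affine transformations in 3D
#'
#' An `affine3` object represents the map `p -> A p + b` with a 3x3 linear
#' part `A`, a translation 3-vector `b`, and a `kind` tag. Kinds:
#' `"translation"` (A is the identity), `"rigid"` (A orthogonal with
#' determinant +1, i.e. a proper rotation), `"affine"` (any nonsingular A).
#'
#' @param A 3x3 numeric matrix (linear part).
#' @param b numeric length-3 translation.
#' @param kind one of `"translation"`, `"rigid"`, `"affine"`.
#' @return an object of class `affine3`.
#' @examples
#' T <- affine3(diag(3), c(3, 4, 0), "translation")
#' apply_transform(T, c(1, 2, 3))
#' @export
affine3 <- function(A = diag(3), b = c(0, 0, 0), kind = c("affine", "rigid", "translation")) {
  kind <- match.arg(kind)
  A <- matrix(as.numeric(A), 3, 3)
  b <- as.numeric(b)
  stopifnot(length(b) == 3L, all(is.finite(A)), all(is.finite(b)))
  if (kind == "translation" && max(abs(A - diag(3))) > 1e-8)
    stop("translation kind requires an identity linear part")
  if (kind == "rigid") {
    if (max(abs(crossprod(A) - diag(3))) > 1e-8 || abs(det(A) - 1) > 1e-8)
      stop("rigid kind requires an orthogonal linear part with determinant +1")
  }
  if (abs(det(A)) < 1e-12) stop("linear part is singular")
  structure(list(A = A, b = b, kind = kind), class = "affine3")
}

#' @export
print.affine3 <- function(x, ...) {
  cat(sprintf("<affine3 kind=%s>\n", x$kind))
  m <- cbind(x$A, x$b)
  dimnames(m) <- list(c("x", "y", "z"), c("a.x", "a.y", "a.z", "b"))
  print(round(m, 6))
  invisible(x)
}

#' Identity transformation
#' @return the identity `affine3` of kind `"translation"`.
#' @export
identity_transform <- function() affine3(diag(3), c(0, 0, 0), "translation")

#' Apply a transformation to points
#'
#' @param T an [affine3] transformation.
#' @param points numeric length-3 vector, or an n x 3 matrix of coordinates.
#' @return points of the same shape, mapped by `A p + b`; order preserved.
#' @export
apply_transform <- function(T, points) {
  stopifnot(inherits(T, "affine3"))
  vec <- is.null(dim(points))
  P <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  stopifnot(ncol(P) == 3L, all(is.finite(P)))
  out <- P %*% t(T$A)
  out <- sweep(out, 2L, T$b, "+")
  if (vec) drop(out) else out
}

#' Translation taking one point onto another
#'
#' The elementary data-driven proposal: the pure translation `v - u`, which
#' maps `u` exactly onto `v`.
#'
#' @param u,v numeric length-3 points.
#' @return an `affine3` of kind `"translation"`.
#' @export
fit_translation <- function(u, v) {
  affine3(diag(3), as.numeric(v) - as.numeric(u), "translation")
}

# Triangle area spanned by three 3D points (half cross-product norm).
triangle_area <- function(P) {
  e1 <- P[2, ] - P[1, ]
  e2 <- P[3, ] - P[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  sqrt(sum(cr^2)) / 2
}

#' Fit a transformation to a matched 3-point constellation
#'
#' Least-squares fit of the map taking `src` onto `dst`. In `"rigid"` mode
#' this is the orthogonal Procrustes (Kabsch) solution — the proper rotation
#' plus translation minimising the summed squared residual; reflections are
#' excluded. In `"affine"` mode three point pairs under-determine the 12
#' affine parameters, so the minimum-norm least-squares deviation from the
#' identity is returned (exact interpolation, nonsingular linear part).
#' Rotations are fitted about the source centroid and re-expressed about the
#' origin for conditioning.
#'
#' @param src,dst 3 x 3 matrices, one point per row, matched by row.
#' @param mode `"rigid"` (default) or `"affine"`.
#' @param area_tol degenerate (collinear/coincident) constellations have
#'   triangle area at or below this tolerance and are rejected with a
#'   condition of class `"registrack_degenerate"`.
#' @return an [affine3].
#' @export
fit_constellation_transform <- function(src, dst, mode = c("rigid", "affine"),
                                        area_tol = 1e-8) {
  mode <- match.arg(mode)
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == 3L, ncol(src) == 3L, nrow(dst) == 3L, ncol(dst) == 3L)
  if (triangle_area(src) <= area_tol)
    stop(structure(class = c("registrack_degenerate", "error", "condition"),
                   list(message = "degenerate constellation: source points are collinear or coincident",
                        call = sys.call())))
  if (mode == "rigid") {
    fit_rigid_lsq(src, dst)
  } else {
    # Three point pairs leave the 12 affine parameters under-determined
    # (9 consistent equations); take the minimum-norm least-squares
    # deviation from the identity map, which interpolates the three pairs
    # exactly while keeping the linear part nonsingular.
    P <- cbind(src, 1)
    Pp <- pseudo_inverse(P)
    Daug <- t(Pp %*% (dst - src))       # 3 x 4, rows are output axes
    affine3(diag(3) + Daug[, 1:3], Daug[, 4], "affine")
  }
}

# Orthogonal Procrustes / Kabsch over >= 3 matched points (rows).
fit_rigid_lsq <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2L, cs), sweep(dst, 2L, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  b <- cd - drop(R %*% cs)
  kind <- if (max(abs(R - diag(3))) < 1e-12) "translation" else "rigid"
  affine3(R, b, kind)
}

pseudo_inverse <- function(M, tol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Compose two transformations
#'
#' `compose(T2, T1)` is the transformation applying `T1` first, then `T2`:
#' `compose(T2, T1)(p) == T2(T1(p))`.
#'
#' @param T2,T1 [affine3] objects.
#' @return an [affine3]; two translations compose to a translation and two
#'   rigid maps to a rigid map.
#' @export
compose <- function(T2, T1) {
  stopifnot(inherits(T2, "affine3"), inherits(T1, "affine3"))
  A <- T2$A %*% T1$A
  b <- drop(T2$A %*% T1$b) + T2$b
  kind <- if (T1$kind == "translation" && T2$kind == "translation") "translation"
  else if (T1$kind != "affine" && T2$kind != "affine") "rigid"
  else "affine"
  if (kind == "rigid" && max(abs(A - diag(3))) < 1e-12) kind <- "translation"
  affine3(A, b, kind)
}

#' Invert a transformation
#' @param T an [affine3].
#' @return the inverse map, of the same kind.
#' @export
invert_transform <- function(T) {
  Ai <- solve(T$A)
  affine3(Ai, -drop(Ai %*% T$b), T$kind)
}

#' Rotation angle of a transformation
#'
#' The total rotation angle (radians) of the linear part, from its trace.
#' Meaningful for rigid maps; for a pure translation the angle is 0.
#'
#' @param T an [affine3].
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(T) {
  tr <- sum(diag(T$A))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

# Small rotation constructors used across tests and the surrogate generator.
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Build a rigid transformation from Euler angles
#'
#' Rotation `Rz(az) Ry(ay) Rx(ax)` about a centre point, followed by a
#' translation; the result is expressed as a single (linear, translation)
#' pair about the origin.
#'
#' @param angles numeric length-3 Euler angles (radians), applied x-first.
#' @param translation numeric length-3 shift.
#' @param center point about which the rotation acts (default origin).
#' @return an [affine3] of kind `"rigid"` (or `"translation"` for zero angles).
#' @export
euler_transform <- function(angles, translation = c(0, 0, 0), center = c(0, 0, 0)) {
  R <- rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])
  b <- as.numeric(center) - drop(R %*% as.numeric(center)) + as.numeric(translation)
  kind <- if (max(abs(R - diag(3))) < 1e-12) "translation" else "rigid"
  affine3(R, b, kind)
}
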