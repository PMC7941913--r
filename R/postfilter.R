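#' Fit an elliptical region of interest to tracked detections
#'
#' Objects of interest are expected near the centre of the field of view;
#' under a normality assumption the detections' mean and sample covariance
#' define an elliptical confinement region, membership being Mahalanobis
#' distance at most `n_sigma`. Fitted on the (x, y) projection by default,
#' as a 3D ellipsoid with `three_d = TRUE`.
#'
#' @param xy detections: matrix/data.frame with columns x, y (and z if
#'   `three_d`), or a `lifetrack` fit.
#' @param n_sigma confinement level, typically 1 or 2 (default 2).
#' @param three_d fit in 3D instead of the (x, y) plane.
#' @return an object of class `ellipse_roi`: `center`, `covariance`,
#'   `n_sigma`.
#' @export
fit_ellipse_roi <- function(xy, n_sigma = 2, three_d = FALSE) {
  if (inherits(xy, "lifetrack"))
    xy <- xy$observations[, c("x", "y", "z")]
  cols <- if (three_d) c("x", "y", "z") else c("x", "y")
  X <- as.matrix(as.data.frame(xy)[, cols])
  stopifnot(n_sigma > 0)
  if (nrow(X) < 3L) stop("fit_ellipse_roi: need at least 3 detections")
  ctr <- colMeans(X)
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev), 1)) {
    ax <- cols[which.min(diag(S))]
    stop(sprintf("degenerate spread: covariance collapsed along axis %s", ax))
  }
  structure(list(center = ctr, covariance = S, n_sigma = n_sigma),
            class = "ellipse_roi")
}

#' Test membership in an elliptical ROI
#' @param roi an [fit_ellipse_roi()] object.
#' @param pts matrix/data.frame with the same columns the ROI was fitted on.
#' @return logical vector: Mahalanobis distance <= `n_sigma`.
#' @export
in_ellipse <- function(roi, pts) {
  X <- as.matrix(as.data.frame(pts)[, seq_along(roi$center)])
  d2 <- mahalanobis(X, roi$center, roi$covariance)
  d2 <= roi$n_sigma^2
}

# Per-lineage step geometry shared by the angle and displacement filters:
# observed backward displacement, transform-predicted backward displacement,
# angle between them (deg) and residual distance.
lineage_steps <- function(fit) {
  tau <- fit$config$lag
  obs <- fit$observations
  out <- list()
  for (t in seq.int(tau + 1L, fit$n_frames)) {
    s <- fit$transforms[[t]]
    if (is.null(s)) next
    cur <- obs[obs$frame == t, , drop = FALSE]
    prev <- obs[obs$frame == t - tau, , drop = FALSE]
    common <- intersect(cur$id, prev$id)
    if (!length(common)) next
    p_t <- as.matrix(cur[match(common, cur$id), c("x", "y", "z")])
    p_v <- as.matrix(prev[match(common, prev$id), c("x", "y", "z")])
    pred <- apply_transform(s$transform, p_t)
    v_obs <- p_v - p_t
    v_pred <- pred - p_t
    no <- sqrt(rowSums(v_obs^2)); np <- sqrt(rowSums(v_pred^2))
    cosang <- rowSums(v_obs * v_pred) / (no * np)
    ang <- ifelse(no < 1e-12 | np < 1e-12, 0,
                  acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
    out[[length(out) + 1L]] <- data.frame(
      id = common, frame = t, angle = ang, disp = no,
      residual = sqrt(rowSums((p_v - pred)^2)))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id = integer(0), frame = integer(0), angle = numeric(0),
                  disp = numeric(0), residual = numeric(0))
}

#' Angle-difference outlier filter
#'
#' Debris moves uncorrelated with — often opposite to — the global motion.
#' Per linked step the angle between the object's observed displacement and
#' the displacement predicted by the winning global transformation at that
#' location is computed; a lineage is flagged when its median angle exceeds
#' `angle_threshold` AND its median displacement magnitude exceeds `eps`
#' (sub-resolution motion carries no direction evidence). Zero-length
#' displacements have angle 0.
#'
#' @param fit a `lifetrack`.
#' @param angle_threshold degrees (default 90).
#' @param eps displacement floor; defaults to the fit's `eps`.
#' @return data.frame `id`, `reason` (`"angle-outlier"`), one row per
#'   flagged lineage.
#' @export
angle_difference_filter <- function(fit, angle_threshold = 90, eps = NULL) {
  if (is.null(eps)) eps <- fit$config$eps
  st <- lineage_steps(fit)
  if (nrow(st) == 0L) return(data.frame(id = integer(0), reason = character(0)))
  med <- aggregate(cbind(angle, disp) ~ id, data = st, FUN = median)
  bad <- med$id[med$angle > angle_threshold & med$disp > eps]
  data.frame(id = bad,
             reason = rep("angle-outlier", length(bad)))
}

#' Displacement (residual) outlier filter
#'
#' Flags steps whose residual — the distance between the observed earlier
#' position and the position predicted by the global transformation —
#' exceeds `threshold`; a lineage is removed when a majority of its steps
#' are flagged.
#'
#' @param fit a `lifetrack`.
#' @param threshold residual threshold; defaults to `3 * eps`.
#' @return data.frame `id`, `reason` (`"displacement-outlier"`).
#' @export
displacement_filter <- function(fit, threshold = NULL) {
  if (is.null(threshold)) threshold <- 3 * fit$config$eps
  stopifnot(threshold > 0)
  st <- lineage_steps(fit)
  if (nrow(st) == 0L) return(data.frame(id = integer(0), reason = character(0)))
  frac <- aggregate((residual > threshold) ~ id, data = st, FUN = mean)
  names(frac)[2] <- "frac"
  bad <- frac$id[frac$frac > 0.5]
  data.frame(id = bad, reason = rep("displacement-outlier", length(bad)))
}

#' Apply the post-tracking filters
#'
#' Runs, in order: elliptical ROI confinement (a lineage is removed when a
#' majority of its detections fall outside the ellipse), the
#' angle-difference filter, and the displacement filter. Each removed
#' identifier carries exactly one primary reason — the first filter that
#' flagged it. Filters run post hoc on the final result and are idempotent:
#' the fitted ellipse is stored on the filtered object and reused when the
#' filters are re-applied with the same settings.
#'
#' The ellipse confinement assumes the population is centrally concentrated
#' (approximately Gaussian); on spatially uniform populations a 2-sigma
#' ellipse necessarily excludes peripheral objects, so it is opt-in.
#'
#' @param fit a `lifetrack`.
#' @param ellipse logical: apply the ellipse filter (default FALSE; see
#'   Details).
#' @param n_sigma ellipse confinement level (default 2).
#' @param angle_threshold degrees (default 90); NA disables the filter.
#' @param displacement_threshold residual threshold (default `3 * eps`);
#'   NA disables the filter.
#' @return the filtered `lifetrack`, with a `filter_report` field
#'   (data.frame `id`, `reason`) and the ellipse stored in `filters`.
#' @export
apply_track_filters <- function(fit, ellipse = FALSE, n_sigma = 2,
                                angle_threshold = 90,
                                displacement_threshold = NULL) {
  report <- data.frame(id = integer(0), reason = character(0))
  if (ellipse && nrow(fit$observations) >= 3L) {
    roi <- if (!is.null(fit$filters$ellipse) &&
               isTRUE(all.equal(fit$filters$n_sigma, n_sigma)))
      fit$filters$ellipse
    else fit_ellipse_roi(fit$observations[, c("x", "y")], n_sigma = n_sigma)
    inside <- in_ellipse(roi, fit$observations[, c("x", "y")])
    frac_in <- tapply(inside, fit$observations$id, mean)
    bad <- as.integer(names(frac_in))[frac_in < 0.5]
    report <- rbind(report, data.frame(id = bad,
                                       reason = rep("outside-ellipse", length(bad))))
  } else roi <- fit$filters$ellipse
  af <- angle_difference_filter(fit, angle_threshold = angle_threshold)
  af <- af[!af$id %in% report$id, , drop = FALSE]
  report <- rbind(report, af)
  df <- displacement_filter(fit, threshold = displacement_threshold)
  df <- df[!df$id %in% report$id, , drop = FALSE]
  report <- rbind(report, df)

  keep <- !fit$observations$id %in% report$id
  fit$observations <- fit$observations[keep, , drop = FALSE]
  fit$ids <- lapply(fit$ids, function(v) v)   # per-frame ids retained as-is
  fit$life_matrix <- build_life_matrix(fit$observations, fit$n_frames)
  fit$filter_report <- report
  fit$filters <- list(ellipse = roi, n_sigma = n_sigma)
  fit
}
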