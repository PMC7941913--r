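#' @export
print.lifetrack <- function(x, ...) {
  lmf <- filter_min_frames(x$life_matrix, x$config$min_frames)
  cat(sprintf("Registration-tracking fit: %d frames, %d detections\n",
              x$n_frames, nrow(x$observations)))
  cat(sprintf("  lineages: %d total, %d with >= %d frames\n",
              nrow(x$life_matrix), nrow(lmf), x$config$min_frames))
  cat(sprintf("  eps = %g, lag = %d, seed = %d\n",
              x$config$eps, x$config$lag, x$config$seed))
  invisible(x)
}

#' @export
summary.lifetrack <- function(object, ...) {
  lm <- object$life_matrix
  lmf <- filter_min_frames(lm, object$config$min_frames)
  costs <- vapply(object$transforms,
                  function(s) if (is.null(s)) NA_real_ else s$cost, numeric(1))
  res <- structure(list(
    n_frames = object$n_frames,
    n_detections = nrow(object$observations),
    n_lineages = nrow(lm),
    n_lineages_filtered = nrow(lmf),
    lifetimes = as.integer(rowSums(lm)),
    pair_costs = costs[!is.na(costs)],
    config = object$config), class = "summary.lifetrack")
  res
}

#' @export
print.summary.lifetrack <- function(x, ...) {
  cat(sprintf("Frames: %d   Detections: %d\n", x$n_frames, x$n_detections))
  cat(sprintf("Lineages: %d (%d survive the %d-frame minimum)\n",
              x$n_lineages, x$n_lineages_filtered, x$config$min_frames))
  if (length(x$lifetimes)) {
    cat("Lifetime distribution (frames):\n")
    print(table(x$lifetimes))
  }
  if (length(x$pair_costs))
    cat(sprintf("Winning-transform cost: median %.4g, max %.4g\n",
                median(x$pair_costs), max(x$pair_costs)))
  invisible(x)
}

#' Winning transformation coefficients
#'
#' One row per linked frame pair: the frame index, transform kind, the 9
#' linear coefficients (row-major), the 3 translation components, the cost
#' and the matched count.
#'
#' @param object a `lifetrack` fit.
#' @param ... unused.
#' @return data.frame (0 rows if no pair was linked).
#' @export
coef.lifetrack <- function(object, ...) {
  rows <- lapply(seq_along(object$transforms), function(t) {
    s <- object$transforms[[t]]
    if (is.null(s)) return(NULL)
    A <- s$transform$A
    d <- data.frame(frame = t, kind = s$transform$kind)
    d[paste0("a", rep(1:3, each = 3), rep(1:3, 3))] <- as.numeric(t(A))
    d[c("b1", "b2", "b3")] <- as.list(s$transform$b)
    d$cost <- s$cost
    d$matched <- s$matched_count
    d
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Residual displacements of a tracking fit
#'
#' For every linked step the residual is the distance between the observed
#' position of the object at the earlier frame and the position predicted by
#' the winning global transformation from the later frame. Small residuals
#' mean the global motion explains the step; large residuals flag debris or
#' mis-classified inliers.
#'
#' @param object a `lifetrack` fit.
#' @param ... unused.
#' @return data.frame with `id`, `frame`, `residual`.
#' @export
residuals.lifetrack <- function(object, ...) {
  tau <- object$config$lag
  obs <- object$observations
  rows <- list()
  for (t in seq.int(tau + 1L, object$n_frames)) {
    s <- object$transforms[[t]]
    if (is.null(s)) next
    cur <- obs[obs$frame == t, , drop = FALSE]
    prev <- obs[obs$frame == t - tau, , drop = FALSE]
    common <- intersect(cur$id, prev$id)
    for (oid in common) {
      p_t <- as.numeric(cur[match(oid, cur$id), c("x", "y", "z")])
      p_v <- as.numeric(prev[match(oid, prev$id), c("x", "y", "z")])
      pred <- apply_transform(s$transform, p_t)
      rows[[length(rows) + 1L]] <-
        data.frame(id = oid, frame = t, residual = sqrt(sum((p_v - pred)^2)))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(0), frame = integer(0), residual = numeric(0))
  out
}

#' Predict positions under a fitted frame-pair transformation
#'
#' Maps points with the winning transformation of the pair linking `frame`
#' to `frame - lag` (the backward tracking direction); with
#' `direction = "forward"` the inverse map is applied instead.
#'
#' @param object a `lifetrack` fit.
#' @param newdata n x 3 matrix of points (default: the detections at `frame`).
#' @param frame later frame index of the pair.
#' @param direction `"backward"` (default, t to t - lag) or `"forward"`.
#' @param ... unused.
#' @return n x 3 matrix of predicted positions.
#' @export
predict.lifetrack <- function(object, newdata = NULL, frame,
                              direction = c("backward", "forward"), ...) {
  direction <- match.arg(direction)
  s <- object$transforms[[frame]]
  if (is.null(s)) stop("no fitted transformation for frame ", frame)
  if (is.null(newdata)) {
    obs <- object$observations
    newdata <- as.matrix(obs[obs$frame == frame, c("x", "y", "z")])
  }
  T <- if (direction == "backward") s$transform else invert_transform(s$transform)
  apply_transform(T, newdata)
}

#' Plot a tracking fit
#'
#' `which = 1` draws the Life Matrix (rows = lineages, columns = frames);
#' `which = 2` the population time series (object count and mean age).
#'
#' @param x a `lifetrack` fit.
#' @param which plots to draw (subset of 1:2).
#' @param min_frames minimum lifetime displayed (default: the fit's setting).
#' @param ... unused.
#' @export
plot.lifetrack <- function(x, which = 1:2, min_frames = NULL, ...) {
  if (is.null(min_frames)) min_frames <- x$config$min_frames
  lm <- filter_min_frames(x$life_matrix, min_frames)
  op <- par(no.readonly = TRUE); on.exit(par(op))
  par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  if (1 %in% which) {
    if (nrow(lm) > 0) {
      image(x = seq_len(ncol(lm)), y = seq_len(nrow(lm)), z = t(lm),
            col = c("white", "navy"), xlab = "frame", ylab = "lineage",
            main = "Life Matrix")
    } else {
      plot.new(); mtext("empty Life Matrix")
    }
  }
  if (2 %in% which) {
    ps <- population_series(lm)
    plot(ps$frame, ps$count, type = "s", xlab = "frame", ylab = "count",
         main = "Population / mean age")
    lines(ps$frame, ps$mean_age, col = "firebrick", lty = 2, type = "l")
    legend("topright", legend = c("count", "mean age"),
           col = c("black", "firebrick"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
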