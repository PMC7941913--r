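# CSV and config IO. All writers emit plain RFC-4180 CSV with a header row;
# coordinates are 0-based continuous voxel units throughout.

#' Write / read a centroid cloud CSV (t, x, y, z, intensity)
#' @param clouds list of [frame_cloud]s (or a single one).
#' @param path output file.
#' @export
write_centroids <- function(clouds, path) {
  if (inherits(clouds, "frame_cloud")) clouds <- list(clouds)
  df <- do.call(rbind, lapply(clouds, function(cl) {
    n <- n_points(cl)
    if (n == 0L) return(NULL)
    data.frame(t = cl$t, x = cl$xyz[, 1], y = cl$xyz[, 2], z = cl$xyz[, 3],
               intensity = if (is.null(cl$intensity)) NA_real_ else cl$intensity)
  }))
  if (is.null(df))
    df <- data.frame(t = integer(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), intensity = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @return `read_centroids`: a list of [frame_cloud]s, one per distinct `t`,
#'   in time order.
#' @export
read_centroids <- function(path) {
  df <- read.csv(path)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("malformed centroid CSV: expected header with columns t,x,y,z, got: ",
         paste(names(df), collapse = ","))
  ts <- sort(unique(df$t))
  lapply(ts, function(tt) {
    sub <- df[df$t == tt, , drop = FALSE]
    frame_cloud(as.matrix(sub[, c("x", "y", "z")]), t = tt,
                intensity = if ("intensity" %in% names(sub)) sub$intensity else NULL,
                source = "file")
  })
}

#' Write / read a Life Matrix CSV
#'
#' Header row of frame indices, first column the lineage identifier,
#' binary entries.
#' @param lm binary Life Matrix (rownames = identifiers).
#' @param path output file.
#' @export
write_life_matrix <- function(lm, path) {
  df <- data.frame(id = rownames(lm), lm, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_matrix
#' @export
read_life_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "id") stop("malformed Life Matrix CSV: first column must be 'id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Write tracks CSV (id, t, x, y, z)
#' @param fit a `lifetrack` (or its `observations` data.frame).
#' @param path output file.
#' @export
write_tracks <- function(fit, path) {
  obs <- if (inherits(fit, "lifetrack")) fit$observations else fit
  write.csv(obs[, c("id", "frame", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' Write the per-pair transform log CSV
#'
#' Columns: frame t, transform kind, the 12 affine coefficients, the cost
#' and the matched count of the winning transformation.
#' @param fit a `lifetrack`.
#' @param path output file.
#' @export
write_transform_log <- function(fit, path) {
  write.csv(coef(fit), path, row.names = FALSE)
  invisible(path)
}

#' Write surrogate truth CSV (t, x, y, z, truth_id, is_noise)
#' @param truth a `surrogate_truth` (frame pair) or the result of
#'   [generate_surrogate_sequence()].
#' @param path output file.
#' @export
write_surrogate_truth <- function(truth, path) {
  if (inherits(truth, "surrogate_truth")) {
    partner <- rep(NA_integer_, n_points(truth$U))
    partner[truth$inlier_pairs[, 1]] <- truth$inlier_pairs[, 1]
    dfU <- data.frame(t = truth$U$t, truth$U$xyz, truth_id = partner,
                      is_noise = seq_len(n_points(truth$U)) %in% truth$noise_u)
    idV <- rep(NA_integer_, n_points(truth$V))
    idV[truth$inlier_pairs[, 2]] <- truth$inlier_pairs[, 1]
    dfV <- data.frame(t = truth$V$t, truth$V$xyz, truth_id = idV,
                      is_noise = seq_len(n_points(truth$V)) %in% truth$noise_v)
    df <- rbind(dfV, dfU)
  } else {
    df <- do.call(rbind, lapply(truth$frames, function(f)
      data.frame(t = f$t, f$xyz, truth_id = f$ids, is_noise = is.na(f$ids))))
  }
  names(df)[2:4] <- c("x", "y", "z")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a run configuration
#'
#' The effective configuration is echoed into every output directory so a
#' run can be reproduced bit-for-bit; the round trip is lossless for all
#' numeric, integer, character and logical fields.
#' @param config a [tracker_config] (or plain named list).
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(tracker_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Read a 3D TIFF stack as a normalized volume
#'
#' Multi-page TIFF, one page per z-slice; returned as an (x, y, z) array
#' rescaled to `[0, 1]` (pages arrive as y-by-x matrices and are transposed).
#' @param path TIFF file.
#' @return 3D array in `[0, 1]`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  vol <- simplify2array(lapply(pages, base::t))   # (x, y, z)
  mx <- max(vol)
  if (mx > 0) vol / mx else vol
}

#' Write a volume (or 2D mask) as TIFF
#' @param vol 3D array or 2D matrix with values in `[0, 1]` (logical masks
#'   are converted).
#' @param path output file.
#' @export
write_stack <- function(vol, path) {
  vol[] <- pmin(pmax(as.numeric(vol), 0), 1)
  if (length(dim(vol)) == 2L) {
    tiff::writeTIFF(base::t(vol), path)
  } else {
    pages <- lapply(seq_len(dim(vol)[3]), function(z) base::t(vol[, , z]))
    tiff::writeTIFF(pages, path)
  }
  invisible(path)
}
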