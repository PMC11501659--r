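#' Tracking configuration
#'
#' @param spot_diameter Spot mask diameter (px, odd, >= 3); should span the
#'   Airy core and first ring (default 15 px for the reference optics).
#' @param threshold Absolute detection threshold (counts); `NULL` (default)
#'   uses an adaptive per-frame threshold background + `thresh_sigma` * MAD.
#' @param thresh_sigma Multiplier for the adaptive threshold.
#' @param search_radius Maximum frame-to-frame displacement when linking
#'   (px).
#' @param memory Number of consecutive missing frames a track may bridge.
#' @param max_spots Maximum detections per frame.
#' @return Object of class `tracking_config`.
#' @export
tracking_config <- function(spot_diameter = 15, threshold = NULL,
                            thresh_sigma = 8, search_radius = 5,
                            memory = 1, max_spots = 5) {
  if (spot_diameter < 3 || spot_diameter %% 2 == 0)
    stop("spot_diameter must be odd and >= 3", call. = FALSE)
  if (search_radius <= 0) stop("search_radius must be > 0", call. = FALSE)
  structure(list(spot_diameter = spot_diameter, threshold = threshold,
                 thresh_sigma = thresh_sigma, search_radius = search_radius,
                 memory = as.integer(memory),
                 max_spots = as.integer(max_spots)),
            class = "tracking_config")
}

#' Locate diffraction-limited spots in a single frame
#'
#' Median background estimation, candidate local maxima above threshold, and
#' iterated circular-mask centroid refinement (re-centering the mask on the
#' running centroid removes the truncation bias of a fixed window).
#' Saturated spots (any pixel at or above the saturation level) are flagged,
#' not dropped.
#'
#' @param frame Numeric or integer matrix (rows = transverse x, cols =
#'   axial z).
#' @param config A [tracking_config()].
#' @param saturation Saturation level used for flagging (counts).
#' @return data.frame with zero or more rows: `x_px`, `z_px` (subpixel,
#'   0-based), `mass` (background-subtracted integrated counts),
#'   `background`, `saturated`.
#' @export
locate_spots <- function(frame, config = tracking_config(),
                         saturation = 65000) {
  stopifnot(is.matrix(frame))
  if (min(dim(frame)) < config$spot_diameter)
    stop("frame smaller than spot_diameter", call. = FALSE)
  res <- cpp_locate_frames(
    as.integer(frame), nrow(frame), ncol(frame), 1L,
    config$spot_diameter / 2,
    if (is.null(config$threshold)) NA_real_ else config$threshold,
    config$thresh_sigma, config$max_spots, 4L, saturation)
  data.frame(x_px = res[, 2], z_px = res[, 3], mass = res[, 4],
             background = res[, 5], saturated = res[, 6] > 0)
}

#' Locate spots in every frame of a stack
#'
#' Runs the [locate_spots()] detector over all frames of a `frame_stack`
#' and converts positions to channel coordinates: `x_um` is the transverse
#' offset from the channel axis, `z_um` the absolute axial position
#' (window origin + local pixel position).
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param config A [tracking_config()].
#' @return data.frame of detections with columns `frame`, `t`, `x_px`,
#'   `z_px`, `x_um`, `z_um`, `mass`, `background`, `saturated`.
#' @export
locate_stack <- function(stack, config = tracking_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  res <- cpp_locate_frames(
    as.integer(stack$frames), d[1], d[2], d[3],
    config$spot_diameter / 2,
    if (is.null(config$threshold)) NA_real_ else config$threshold,
    config$thresh_sigma, config$max_spots, 4L, stack$camera$saturation)
  fr <- as.integer(res[, 1])
  pitch <- stack$pixel_pitch
  data.frame(
    frame = stack$frame_index[fr],
    t = stack$times[fr],
    x_px = res[, 2], z_px = res[, 3],
    x_um = (res[, 2] - (d[1] - 1) / 2) * pitch,
    z_um = stack$origin_z_um[fr] + res[, 3] * pitch,
    mass = res[, 4], background = res[, 5], saturated = res[, 6] > 0)
}

#' Link detections into trajectories
#'
#' Greedy nearest-neighbor linking: each open track claims the closest
#' detection in the next frame within `search_radius` (µm distance computed
#' in the image plane, x and z); ties in distance are resolved toward the
#' higher-mass detection. Tracks survive up to `memory` consecutive frames
#' without a detection. Intended for the sparse single-particle regime.
#'
#' @param detections data.frame from [locate_stack()], sorted by frame.
#' @param config A [tracking_config()]; `search_radius` is interpreted in
#'   pixels and converted with `pixel_pitch`.
#' @param pixel_pitch µm per pixel, for the search radius.
#' @return `detections` with an integer `track_id` column, ordered by track
#'   then frame.
#' @export
link_trajectories <- function(detections, config = tracking_config(),
                              pixel_pitch = 0.345) {
  if (nrow(detections) == 0) {
    detections$track_id <- integer(0)
    return(detections)
  }
  if (is.unsorted(detections$frame))
    stop("detections must be sorted by frame", call. = FALSE)
  r_um <- config$search_radius * pixel_pitch
  n <- nrow(detections)
  track_id <- integer(n)
  # open tracks: id, last x, last z, last frame, last mass
  open <- data.frame(id = integer(0), x = numeric(0), z = numeric(0),
                     frame = integer(0))
  next_id <- 1L
  idx_by_frame <- split(seq_len(n), detections$frame)
  for (fr_chr in names(idx_by_frame)) {
    fr <- as.integer(fr_chr)
    idx <- idx_by_frame[[fr_chr]]
    # drop expired tracks
    open <- open[fr - open$frame <= config$memory + 1L, , drop = FALSE]
    # candidate (track, detection) pairs within the search radius, assigned
    # greedily by distance; distance ties go to the higher-mass detection
    taken_det <- rep(FALSE, length(idx))
    if (nrow(open) > 0 && length(idx) > 0) {
      pairs <- expand.grid(j = seq_len(nrow(open)), k = seq_along(idx))
      pairs$dist <- sqrt(
        (open$x[pairs$j] - detections$x_um[idx[pairs$k]])^2 +
          (open$z[pairs$j] - detections$z_um[idx[pairs$k]])^2)
      pairs <- pairs[pairs$dist <= r_um, , drop = FALSE]
      pairs <- pairs[order(pairs$dist, -detections$mass[idx[pairs$k]]), ,
                     drop = FALSE]
      claimed <- rep(FALSE, nrow(open))
      for (p in seq_len(nrow(pairs))) {
        j <- pairs$j[p]; k <- pairs$k[p]
        if (claimed[j] || taken_det[k]) next
        i <- idx[k]
        track_id[i] <- open$id[j]
        open$x[j] <- detections$x_um[i]
        open$z[j] <- detections$z_um[i]
        open$frame[j] <- fr
        claimed[j] <- TRUE
        taken_det[k] <- TRUE
      }
    }
    for (k in which(!taken_det)) {
      i <- idx[k]
      track_id[i] <- next_id
      open <- rbind(open, data.frame(id = next_id,
                                     x = detections$x_um[i],
                                     z = detections$z_um[i],
                                     frame = fr))
      next_id <- next_id + 1L
    }
  }
  detections$track_id <- track_id
  detections[order(detections$track_id, detections$frame), ]
}

#' Normalize an intensity series to unit mean
#'
#' Divides the series by its mean so distributions from different runs are
#' directly comparable; idempotent.
#'
#' @param x Numeric vector of intensities (length >= 2), or a data.frame
#'   with a `mass` column (a linked trajectory), in which case the
#'   normalized `mass` series is returned.
#' @return Numeric vector with mean exactly 1.
#' @export
normalize_intensity <- function(x) {
  if (is.data.frame(x)) x <- x$mass
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("cannot normalize a zero-mean series", call. = FALSE)
  x / m
}
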