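# Dark-field video renderer: bright anisotropic-Gaussian head blobs on a
# dark noisy background, with optional out-of-band distractor particles.
# Photometric model: I = background + peak * exp(-(u^2/(2 su^2) + v^2/(2 sv^2)))
# with (u, v) the head-frame coordinates (u along the instantaneous heading),
# plus Gaussian read noise, rounded and clipped to the bit depth. At a
# threshold halfway between background and peak the blob's above-threshold
# area is 2 ln 2 * pi * su * sv (um^2), which the constructor checks against
# the target area band.

#' Optical / rendering configuration for synthetic dark-field video
#'
#' @param pixel_size_um Calibration, um per pixel (> 0).
#' @param frame_shape Frame size `(rows, cols)` in pixels.
#' @param head_semi_axes_um Gaussian RMS half-widths `(along, across)` of the
#'   head blob, um. The default (1.8, 1.1) gives a mid-threshold apparent
#'   area of about 8.6 um^2, inside the 3-30 um^2 sperm-head band.
#' @param head_peak_intensity Peak head intensity above zero, gray levels.
#' @param background_level Mean background, gray levels (< peak).
#' @param noise_sd Gaussian read-noise SD, gray levels.
#' @param n_distractors Number of distractor particles (non-sperm debris).
#' @param distractor_area_range_um2 Range the distractors' mid-threshold
#'   areas are drawn from, um^2. Choose it outside the segmentation band to
#'   exercise the area filter.
#' @param distractor_peak_intensity Peak distractor intensity, gray levels.
#' @param distractor_jitter_sd_um Per-frame positional jitter of distractors,
#'   um (they are debris, not swimmers).
#' @param distractor_clearance_um Minimum distance between a distractor and
#'   any sperm-head position across the whole clip, um, so distractors never
#'   merge with heads.
#' @param area_band_um2 Target apparent-area band used to validate
#'   `head_semi_axes_um`, um^2.
#' @param bit_depth Bits per pixel (8 or 16).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_um = 0.5,
                          frame_shape = c(512L, 512L),
                          head_semi_axes_um = c(1.8, 1.1),
                          head_peak_intensity = 200,
                          background_level = 20,
                          noise_sd = 8,
                          n_distractors = 0L,
                          distractor_area_range_um2 = c(0.5, 1.5),
                          distractor_peak_intensity = 200,
                          distractor_jitter_sd_um = 0.2,
                          distractor_clearance_um = 10,
                          area_band_um2 = c(3, 30),
                          bit_depth = 8L) {
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  if (length(frame_shape) != 2L || any(frame_shape < 8)) {
    abort("`frame_shape` must be (rows, cols), each >= 8 px.")
  }
  if (length(head_semi_axes_um) != 2L || any(head_semi_axes_um <= 0)) {
    abort("`head_semi_axes_um` must be two positive numbers.")
  }
  if (head_peak_intensity <= background_level) {
    abort("`head_peak_intensity` must exceed `background_level`.")
  }
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  mid_area <- 2 * log(2) * pi * prod(head_semi_axes_um)
  if (mid_area < area_band_um2[1] || mid_area > area_band_um2[2]) {
    abort(sprintf(
      "Head mid-threshold area %.2f um^2 lies outside the target band [%g, %g].",
      mid_area, area_band_um2[1], area_band_um2[2]
    ))
  }
  structure(
    list(
      pixel_size_um = pixel_size_um,
      frame_shape = as.integer(frame_shape),
      head_semi_axes_um = as.numeric(head_semi_axes_um),
      head_peak_intensity = head_peak_intensity,
      background_level = background_level,
      noise_sd = noise_sd,
      n_distractors = as.integer(n_distractors),
      distractor_area_range_um2 = as.numeric(distractor_area_range_um2),
      distractor_peak_intensity = distractor_peak_intensity,
      distractor_jitter_sd_um = distractor_jitter_sd_um,
      distractor_clearance_um = distractor_clearance_um,
      area_band_um2 = as.numeric(area_band_um2),
      bit_depth = as.integer(bit_depth)
    ),
    class = "optics_config"
  )
}

#' Video stack container
#'
#' @param frames Integer array `(rows, cols, n_frames)`.
#' @param fps Frame rate, Hz.
#' @param pixel_size_um Calibration, um/px.
#' @param bit_depth Bits per pixel.
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, fps, pixel_size_um, bit_depth = 8L) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3-d array (rows, cols, n_frames).")
  }
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  maxv <- 2^bit_depth - 1
  if (min(frames) < 0 || max(frames) > maxv) {
    abort(sprintf("Frame intensities must lie in [0, %d].", maxv))
  }
  structure(
    list(frames = frames, fps = fps, pixel_size_um = pixel_size_um,
         bit_depth = as.integer(bit_depth)),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<video_stack> %d frames of %d x %d px, %g fps, %g um/px, %d-bit\n",
    d[3], d[1], d[2], x$fps, x$pixel_size_um, x$bit_depth
  ))
  invisible(x)
}

# add one Gaussian blob to `img` (modified in place by the caller):
# returns img. cx, cy in um; sigma_u along heading, sigma_v across.
add_blob <- function(img, cx, cy, theta, sigma_u, sigma_v, peak, px) {
  nr <- nrow(img); nc <- ncol(img)
  col0 <- cx / px + 1  # sub-pixel 1-based indices
  row0 <- cy / px + 1
  half <- ceiling(4 * max(sigma_u, sigma_v) / px)
  rows <- max(1L, floor(row0) - half):min(nr, ceiling(row0) + half)
  cols <- max(1L, floor(col0) - half):min(nc, ceiling(col0) + half)
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  dx <- (cols - col0) * px
  dy <- (rows - row0) * px
  u <- outer(dy, dx, function(yy, xx) xx * cos(theta) + yy * sin(theta))
  v <- outer(dy, dx, function(yy, xx) -xx * sin(theta) + yy * cos(theta))
  img[rows, cols] <- img[rows, cols] +
    peak * exp(-(u^2 / (2 * sigma_u^2) + v^2 / (2 * sigma_v^2)))
  img
}

#' Render ground-truth tracks into a dark-field video
#'
#' Each head is drawn as an anisotropic Gaussian intensity profile oriented
#' along its instantaneous heading (finite-difference direction of the
#' track), on a uniform background; distractor blobs (isotropic Gaussians
#' with mid-threshold areas drawn from the configured range, jittering about
#' fixed positions) are superimposed, Gaussian read noise is added, and the
#' result is rounded and clipped to the bit depth. Deterministic for a fixed
#' seed.
#'
#' @param tracks A track table whose `x_um`, `y_um` lie inside (or near) the
#'   field of view implied by `optics`.
#' @param optics An [optics_config()].
#' @param seed Integer seed controlling noise, distractor placement and
#'   jitter.
#' @param fps Frame rate stored in the output (defaults to the track table's
#'   `fps` attribute).
#' @param n_frames Number of frames; defaults to `max(tracks$frame) + 1`.
#' @return A [video_stack()].
#' @examples
#' tr <- simulate_tracks(n_sperm = 3, fps = 30, field_of_view_um = c(128, 128),
#'                       seed = 1)
#' vid <- render_video(tr, optics_config(frame_shape = c(256, 256)), seed = 2)
#' @export
render_video <- function(tracks, optics = optics_config(), seed = 1L,
                         fps = NULL, n_frames = NULL) {
  check_track_table(tracks)
  stopifnot(inherits(optics, "optics_config"))
  fps <- tracks_fps(tracks, fps)
  n_frames <- n_frames %||% (max(tracks$frame) + 1L)
  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  px <- optics$pixel_size_um
  maxv <- 2^optics$bit_depth - 1
  net_peak <- optics$head_peak_intensity

  # per-track headings by finite differences (last segment repeated)
  tr <- tracks |>
    arrange(.data$track_id, .data$frame) |>
    group_by(.data$track_id) |>
    mutate(theta = {
      dx <- diff(.data$x_um); dy <- diff(.data$y_um)
      th <- atan2(c(dy, dy[length(dy)] %||% 0), c(dx, dx[length(dx)] %||% 1))
      if (n() == 1L) 0 else th
    }) |>
    ungroup()
  by_frame <- split(tr, tr$frame)

  frames <- array(0L, dim = c(nr, nc, n_frames))
  withr::with_seed(seed, {
    # distractors: fixed anchors away from every head position
    nd <- optics$n_distractors
    if (nd > 0L) {
      anchors <- matrix(NA_real_, nd, 2)
      sigmas <- sqrt(runif(nd, optics$distractor_area_range_um2[1],
                           optics$distractor_area_range_um2[2]) /
                       (2 * log(2) * pi))
      fov <- c((nc - 1) * px, (nr - 1) * px)
      clr <- optics$distractor_clearance_um
      for (i in seq_len(nd)) {
        repeat {
          cand <- c(runif(1, 0, fov[1]), runif(1, 0, fov[2]))
          if (min(sqrt((tracks$x_um - cand[1])^2 +
                         (tracks$y_um - cand[2])^2)) >= clr) break
        }
        anchors[i, ] <- cand
      }
      jitter <- array(rnorm(nd * 2 * n_frames, 0, optics$distractor_jitter_sd_um),
                      dim = c(nd, 2, n_frames))
    }
    for (f in seq_len(n_frames)) {
      img <- matrix(as.numeric(optics$background_level), nr, nc)
      rows_f <- by_frame[[as.character(f - 1L)]]
      if (!is.null(rows_f)) {
        for (i in seq_len(nrow(rows_f))) {
          img <- add_blob(img, rows_f$x_um[i], rows_f$y_um[i], rows_f$theta[i],
                          optics$head_semi_axes_um[1],
                          optics$head_semi_axes_um[2], net_peak, px)
        }
      }
      if (nd > 0L) {
        for (i in seq_len(nd)) {
          img <- add_blob(img, anchors[i, 1] + jitter[i, 1, f],
                          anchors[i, 2] + jitter[i, 2, f],
                          0, sigmas[i], sigmas[i],
                          optics$distractor_peak_intensity, px)
        }
      }
      if (optics$noise_sd > 0) {
        img <- img + rnorm(nr * nc, 0, optics$noise_sd)
      }
      frames[, , f] <- pmin(pmax(round(img), 0), maxv)
    }
  })
  storage.mode(frames) <- "integer"
  video_stack(frames, fps, px, optics$bit_depth)
}

#' Temporally subsample a video
#'
#' Keeps every `fps / target_fps`-th frame starting from the first; the
#' stride must be an integer (e.g. 100 -> 50, 25, 20, 10 fps, but not
#' 30 -> 20 fps).
#'
#' @param video A [video_stack()].
#' @param target_fps Target frame rate, Hz.
#' @return A [video_stack()] at `target_fps`.
#' @export
subsample_fps <- function(video, target_fps) {
  stopifnot(inherits(video, "video_stack"))
  stride <- video$fps / target_fps
  if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
    abort(sprintf("`target_fps` (%g) must divide the video fps (%g) evenly.",
                  target_fps, video$fps))
  }
  stride <- as.integer(round(stride))
  keep <- seq(1L, dim(video$frames)[3], by = stride)
  video_stack(video$frames[, , keep, drop = FALSE], target_fps,
              video$pixel_size_um, video$bit_depth)
}
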