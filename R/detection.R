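# Per-frame sperm-head extraction: threshold segmentation (Otsu by default,
# bright objects on a dark background), 8-connected component labeling, and
# the area-band particle filter that keeps only blobs with apparent areas in
# the sperm-head range (3-30 um^2 by default), discarding debris and noise.

#' Segmentation configuration
#'
#' @param threshold_method `"background"` (default: threshold at the frame's
#'   median plus `background_k` robust standard deviations, estimated by the
#'   median absolute deviation -- the standard choice for sparse bright
#'   objects on a dark background, where heads occupy well under 1% of the
#'   pixels), `"otsu"` (per-frame Otsu threshold on the intensity histogram;
#'   appropriate when foreground and background populations are comparable
#'   in size) or `"fixed"`.
#' @param fixed_threshold Gray-level threshold used when
#'   `threshold_method = "fixed"`; pixels strictly above it are foreground.
#' @param background_k Number of robust background SDs above the median for
#'   `threshold_method = "background"` (default 6: about one false pixel per
#'   10^9 under Gaussian read noise).
#' @param min_area_um2,max_area_um2 Closed area band of the particle filter,
#'   um^2 (defaults 3 and 30).
#' @param blur_sigma_px Optional Gaussian pre-smoothing SD in px before
#'   thresholding (0 = off).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("background", "otsu", "fixed"),
                                fixed_threshold = NULL,
                                background_k = 6,
                                min_area_um2 = 3,
                                max_area_um2 = 30,
                                blur_sigma_px = 0) {
  threshold_method <- match.arg(threshold_method)
  check_number(background_k, "background_k", min = 0, strict_min = TRUE)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold)) {
      abort("`fixed_threshold` is required when `threshold_method = \"fixed\"`.")
    }
    check_number(fixed_threshold, "fixed_threshold", min = 0)
  }
  check_number(min_area_um2, "min_area_um2", min = 0, strict_min = TRUE)
  if (max_area_um2 <= min_area_um2) {
    abort("`max_area_um2` must exceed `min_area_um2`.")
  }
  check_number(blur_sigma_px, "blur_sigma_px", min = 0)
  structure(
    list(threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         background_k = background_k,
         min_area_um2 = min_area_um2,
         max_area_um2 = max_area_um2,
         blur_sigma_px = blur_sigma_px),
    class = "segmentation_config"
  )
}

#' Threshold-segment one frame
#'
#' Foreground = pixels strictly above the threshold (dark-field convention:
#' heads are bright on a dark background). The default `"background"` method
#' thresholds at `median + background_k * mad` of the frame, which is robust
#' to the extreme class imbalance of dark-field frames; `"otsu"` uses
#' [EBImage::otsu()] on the full-depth histogram. A constant-intensity frame
#' yields an all-`FALSE` mask, with a warning for the data-driven methods.
#'
#' @param frame Integer intensity matrix.
#' @param config A [segmentation_config()].
#' @param bit_depth Bits per pixel of `frame` (sets the histogram range).
#' @return A logical mask, same dimensions as `frame`.
#' @export
segment_frame <- function(frame, config = segmentation_config(), bit_depth = 8L) {
  if (!is.matrix(frame) || length(frame) == 0L) {
    abort("`frame` must be a non-empty matrix.")
  }
  if (config$blur_sigma_px > 0) {
    frame <- EBImage::gblur(frame, sigma = config$blur_sigma_px)
  }
  if (config$threshold_method == "fixed") {
    return(frame > config$fixed_threshold)
  }
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    warn("Constant-intensity frame: data-driven threshold undefined, returning empty mask.")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  if (config$threshold_method == "background") {
    th <- stats::median(frame) + config$background_k * stats::mad(frame)
    return(frame > th)
  }
  maxv <- 2^bit_depth - 1
  th <- EBImage::otsu(EBImage::Image(frame / maxv), range = c(0, 1),
                      levels = 2^bit_depth)
  frame > th * maxv
}

# 8-connected labeling of a sparse binary mask via union-find on the
# above-threshold pixels (EBImage's bwlabel is 4-connected, which splits
# diagonally touching blobs).
label_components <- function(mask) {
  nr <- nrow(mask)
  idx <- which(mask)
  k <- length(idx)
  if (k == 0L) {
    return(list(labels = integer(0), pixel_index = integer(0), n = 0L))
  }
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  pos <- seq_len(k)

  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  nc <- ncol(mask)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ok <- r + off[1] >= 1L & r + off[1] <= nr & c + off[2] <= nc
    nb_idx <- (c[ok] + off[2] - 1L) * nr + (r[ok] + off[1])
    hit <- match(nb_idx, idx)
    src <- pos[ok][!is.na(hit)]
    dst <- hit[!is.na(hit)]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(pos, find, integer(1))
  labels <- match(roots, sort(unique(roots)))
  list(labels = labels, pixel_index = idx, n = max(labels))
}

#' Extract particles from a segmented frame
#'
#' One detection per 8-connected component of the mask: intensity-weighted
#' (sub-pixel) centroid, apparent area `n_px * pixel_size^2` and mean
#' intensity. Micrometre coordinates put the origin at the center of pixel
#' `[1, 1]`, with x along columns and y along rows.
#'
#' @param mask Logical mask from [segment_frame()].
#' @param frame The intensity matrix the mask came from (same shape).
#' @param pixel_size_um Calibration, um/px.
#' @param frame_index 0-based frame index recorded in the output.
#' @return A tibble: `frame`, `row_px`, `col_px` (sub-pixel, 1-based),
#'   `x_um`, `y_um`, `area_um2`, `mean_intensity`, `n_px`.
#' @export
extract_particles <- function(mask, frame, pixel_size_um, frame_index = 0L) {
  if (!all(dim(mask) == dim(frame))) {
    abort("`mask` and `frame` must have the same dimensions.")
  }
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  lab <- label_components(mask)
  if (lab$n == 0L) {
    return(tibble(frame = integer(), row_px = numeric(), col_px = numeric(),
                  x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                  mean_intensity = numeric(), n_px = integer()))
  }
  nr <- nrow(frame)
  rr <- ((lab$pixel_index - 1L) %% nr) + 1L
  cc <- ((lab$pixel_index - 1L) %/% nr) + 1L
  w <- as.numeric(frame[lab$pixel_index])
  g <- lab$labels
  wsum <- tapply(w, g, sum)
  row_px <- as.numeric(tapply(w * rr, g, sum) / wsum)
  col_px <- as.numeric(tapply(w * cc, g, sum) / wsum)
  n_px <- as.integer(tapply(w, g, length))
  tibble(
    frame = as.integer(frame_index),
    row_px = row_px,
    col_px = col_px,
    x_um = (col_px - 1) * pixel_size_um,
    y_um = (row_px - 1) * pixel_size_um,
    area_um2 = n_px * pixel_size_um^2,
    mean_intensity = as.numeric(wsum) / n_px,
    n_px = n_px
  )
}

#' Area-band particle filter
#'
#' Keeps detections whose apparent area lies in the closed interval
#' `[min_area_um2, max_area_um2]`; input order is preserved. This removes
#' background noise (below the band) and debris/aggregates (above it).
#'
#' @param detections A detection tibble with an `area_um2` column.
#' @param config A [segmentation_config()].
#' @return The filtered detections.
#' @examples
#' d <- tibble::tibble(area_um2 = c(2, 10, 31))
#' area_filter(d)$area_um2
#' @export
area_filter <- function(detections, config = segmentation_config()) {
  if (!is.data.frame(detections) || !"area_um2" %in% names(detections)) {
    abort("`detections` must have an `area_um2` column.")
  }
  detections |>
    filter(.data$area_um2 >= config$min_area_um2,
           .data$area_um2 <= config$max_area_um2)
}

#' Detect sperm heads in every frame of a video
#'
#' Runs [segment_frame()], [extract_particles()] and (optionally)
#' [area_filter()] on each frame and binds the results.
#'
#' @param video A [video_stack()].
#' @param config A [segmentation_config()].
#' @param filter Apply the area-band filter (default `TRUE`).
#' @return A detection tibble with an `fps` attribute (one row per particle
#'   per frame).
#' @examples
#' tr <- simulate_tracks(n_sperm = 3, fps = 30, field_of_view_um = c(128, 128),
#'                       seed = 1)
#' vid <- render_video(tr, optics_config(frame_shape = c(256, 256)), seed = 2)
#' head(detect_video(vid))
#' @export
detect_video <- function(video, config = segmentation_config(), filter = TRUE) {
  stopifnot(inherits(video, "video_stack"))
  n <- dim(video$frames)[3]
  out <- purrr::map(seq_len(n), function(f) {
    frame <- video$frames[, , f]
    mask <- segment_frame(frame, config, bit_depth = video$bit_depth)
    det <- extract_particles(mask, frame, video$pixel_size_um,
                             frame_index = f - 1L)
    if (filter) det <- area_filter(det, config)
    det
  }) |> purrr::list_rbind()
  attr(out, "fps") <- video$fps
  out
}

#' Write / read detections as CSV
#'
#' @param detections A detection tibble.
#' @param path CSV path.
#' @return `path` invisibly / the detection tibble.
#' @export
write_detections <- function(detections, path) {
  fps <- attr(detections, "fps", exact = TRUE)
  header <- if (is.null(fps)) character(0) else sprintf("# fps: %s", format(fps))
  writeLines(header, path)
  readr::write_csv(as_tibble(detections), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_detections
#' @param fps Frame-rate override when the file has no `# fps:` header.
#' @export
read_detections <- function(path, fps = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# fps:", first)) {
    fps <- fps %||% as.numeric(sub("^# fps:\\s*", "", first))
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE) |>
    mutate(frame = as.integer(.data$frame))
  attr(out, "fps") <- fps
  out
}
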