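# Video I/O: multi-page TIFF with a YAML sidecar carrying acquisition
# metadata (fps, um/px, bit depth). The sidecar lives at <video>.yaml;
# loading without it requires fps and pixel size explicitly -- there is no
# silent default, because every velocity downstream depends on both.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a video stack to multi-page TIFF
#'
#' Frames are written as one grayscale TIFF page each at the stack's bit
#' depth; fps, pixel size and bit depth go to a `<path>.yaml` sidecar.
#'
#' @param video A [video_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  maxv <- 2^video$bit_depth - 1
  pages <- purrr::map(seq_len(dim(video$frames)[3]),
                      function(i) video$frames[, , i] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = video$bit_depth)
  yaml::write_yaml(
    list(fps = video$fps, pixel_size_um = video$pixel_size_um,
         bit_depth = video$bit_depth),
    sidecar_path(path)
  )
  invisible(path)
}

#' Read a video stack from multi-page TIFF
#'
#' Metadata comes from the `<path>.yaml` sidecar when present; otherwise
#' `fps` and `pixel_size_um` must be supplied (an error is raised if either
#' is missing -- velocities cannot be computed without them). RGB pages are
#' converted to grayscale by Rec. 709 luminance.
#'
#' @param path TIFF path.
#' @param fps,pixel_size_um,bit_depth Metadata overrides (take precedence
#'   over the sidecar).
#' @return A [video_stack()].
#' @export
read_video <- function(path, fps = NULL, pixel_size_um = NULL, bit_depth = NULL) {
  if (!file.exists(path)) abort(sprintf("Video file '%s' does not exist.", path))
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else {
    list()
  }
  fps <- fps %||% meta$fps
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  bit_depth <- bit_depth %||% meta$bit_depth %||% 8L
  if (is.null(fps)) {
    abort(sprintf("No fps for '%s': supply `fps` or provide a sidecar.", path))
  }
  if (is.null(pixel_size_um)) {
    abort(sprintf("No pixel size for '%s': supply `pixel_size_um` or a sidecar.",
                  path))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  maxv <- 2^bit_depth - 1
  mats <- purrr::map(pages, function(p) {
    if (length(dim(p)) == 3L) {
      p <- 0.2126 * p[, , 1] + 0.7152 * p[, , 2] + 0.0722 * p[, , 3]
    }
    as.integer(round(p * maxv))
  })
  shp <- dim(pages[[1]])[1:2]
  if (!all(purrr::map_lgl(pages, function(p) all(dim(p)[1:2] == shp)))) {
    abort(sprintf("Inconsistent frame shapes in '%s'.", path))
  }
  frames <- array(unlist(mats), dim = c(shp[1], shp[2], length(mats)))
  video_stack(frames, fps, pixel_size_um, as.integer(bit_depth))
}

#' Clip duration of a video stack
#'
#' `(n_frames - 1) / fps`: a 31-frame clip at 30 fps spans exactly 1 s (30
#' inter-frame intervals), matching the `(M - 1) * dt` normalisation of the
#' velocity formulas.
#'
#' @param video A [video_stack()].
#' @return Duration in seconds.
#' @export
video_duration <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  (dim(video$frames)[3] - 1) / video$fps
}
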