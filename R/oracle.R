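# Independently coded, brute-force motility reference. Used to validate the
# vectorised production implementation in motility.R: every quantity here is
# computed by explicit element-wise loops, sharing no code with
# compute_motility(). Slow on purpose; intended for ground-truth tables and
# tests, not routine analysis.

ref_path_length <- function(x, y) {
  s <- 0
  for (j in seq_len(length(x) - 1L)) {
    s <- s + sqrt((x[j + 1L] - x[j])^2 + (y[j + 1L] - y[j])^2)
  }
  s
}

ref_smooth <- function(v) {
  m <- length(v)
  out <- numeric(m)
  for (k in seq_len(m)) {
    h <- min(2L, k - 1L, m - k)   # window shrinks symmetrically at the ends
    acc <- 0; cnt <- 0L
    for (i in (k - h):(k + h)) {
      acc <- acc + v[i]; cnt <- cnt + 1L
    }
    out[k] <- acc / cnt
  }
  out
}

#' Brute-force motility reference for ground-truth tracks
#'
#' Computes VCL, VSL, VAP, LIN, STR and WOB for each track by direct
#' summation: VCL is the summed point-to-point path length over `(M - 1) *
#' dt`; VSL the start-to-end distance over the same time; VAP the path length
#' of the 5-point moving-average path (symmetrically shrinking windows at the
#' ends) over the same time; LIN = VSL/VCL, STR = VSL/VAP, WOB = VAP/VCL. This function
#' is an independent re-implementation of [compute_motility()] kept free of
#' shared code so the two can check each other.
#'
#' @param tracks A track table (`track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`).
#' @param fps Frame rate, Hz (defaults to the table's `fps` attribute).
#' @param min_frames_vap Minimum track length (frames) for VAP and the
#'   VAP-based ratios; shorter tracks get `NA` there.
#' @return A tibble with one row per track: `track_id`, `n_frames`,
#'   `vcl_um_s`, `vsl_um_s`, `vap_um_s`, `lin`, `str`, `wob` (ratios as
#'   fractions, `NA` where undefined).
#' @examples
#' tr <- simulate_tracks(n_sperm = 3, fps = 30, seed = 1)
#' ground_truth_motility(tr)
#' @export
ground_truth_motility <- function(tracks, fps = NULL, min_frames_vap = 7L) {
  check_track_table(tracks)
  fps <- tracks_fps(tracks, fps)
  dt <- 1 / fps
  ids <- unique(tracks$track_id)
  rows <- vector("list", length(ids))
  for (n in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[n], ]
    tr <- tr[order(tr$frame), ]
    m <- nrow(tr)
    if (m < 2L) {
      abort(sprintf("Track %s has fewer than 2 points.", format(ids[n])))
    }
    elapsed <- (m - 1L) * dt
    vcl <- ref_path_length(tr$x_um, tr$y_um) / elapsed
    vsl <- sqrt((tr$x_um[m] - tr$x_um[1L])^2 + (tr$y_um[m] - tr$y_um[1L])^2) /
      elapsed
    if (m >= min_frames_vap) {
      vap <- ref_path_length(ref_smooth(tr$x_um), ref_smooth(tr$y_um)) / elapsed
    } else {
      vap <- NA_real_
    }
    lin <- if (vcl > 0) vsl / vcl else NA_real_
    str <- if (!is.na(vap) && vap > 0) vsl / vap else NA_real_
    wob <- if (!is.na(vap) && vcl > 0) vap / vcl else NA_real_
    rows[[n]] <- tibble(track_id = ids[n], n_frames = m,
                        vcl_um_s = vcl, vsl_um_s = vsl, vap_um_s = vap,
                        lin = lin, str = str, wob = wob)
  }
  purrr::list_rbind(rows)
}
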