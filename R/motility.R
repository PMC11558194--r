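# WHO-style CASA motility parameters. For a track sampled at M uniformly
# spaced times dt apart:
#   VCL = sum_j |p_{j+1} - p_j| / ((M - 1) dt)        curvilinear velocity
#   VSL = |p_M - p_1| / ((M - 1) dt)                  straight-line velocity
#   VAP = VCL applied to the 5-point moving average   average path velocity
#   LIN = VSL/VCL, STR = VSL/VAP, WOB = VAP/VCL       path-shape ratios
# The smoothing window is truncated (shrunk) at the track ends so the
# smoothed path keeps all M points and the (M - 1) dt normalisation.

path_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Curvilinear velocity of one path
#'
#' Total point-to-point path length divided by the elapsed time
#' `(M - 1) * dt`, in um/s.
#'
#' @param x,y Coordinates in um, equally spaced in time.
#' @param dt Inter-frame interval, s.
#' @return VCL in um/s.
#' @export
vcl <- function(x, y, dt) {
  m <- check_path(x, y, 2L)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  path_length(x, y) / ((m - 1) * dt)
}

#' Straight-line velocity of one path
#'
#' Start-to-end displacement divided by the elapsed time `(M - 1) * dt`.
#'
#' @inheritParams vcl
#' @return VSL in um/s.
#' @export
vsl <- function(x, y, dt) {
  m <- check_path(x, y, 2L)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  sqrt((x[m] - x[1])^2 + (y[m] - y[1])^2) / ((m - 1) * dt)
}

#' 5-point moving-average smoothing of a coordinate sequence
#'
#' Centered 5-point mean at interior points; near the ends the window
#' shrinks symmetrically (half-width `min(2, k - 1, M - k)`), so the output
#' has the same length as the input and the first and last points are
#' preserved. Endpoint preservation matters: it keeps the smoothed path at
#' least as long as the start-end chord, so `VSL <= VAP` and a straight
#' constant-speed path has `VAP = VCL` exactly. Computed with cumulative
#' sums.
#'
#' @param v Numeric coordinate sequence.
#' @param window Odd window width (default 5).
#' @return Smoothed sequence, same length as `v`.
#' @export
smooth_path <- function(v, window = 5L) {
  if (window < 1L || window %% 2L == 0L) abort("`window` must be odd and >= 1.")
  m <- length(v)
  if (m == 0L) return(v)
  half <- (window - 1L) %/% 2L
  k <- seq_len(m)
  h <- pmin(half, k - 1L, m - k)
  cs <- cumsum(c(0, v))
  (cs[k + h + 1L] - cs[k - h]) / (2L * h + 1L)
}

#' Average path velocity of one path
#'
#' VCL applied to the 5-point smoothed path, same `(M - 1) * dt`
#' normalisation. Requires at least `min_frames` points so the smoothing
#' window has interior support.
#'
#' @inheritParams vcl
#' @param min_frames Minimum number of points (default 7).
#' @return VAP in um/s.
#' @export
vap <- function(x, y, dt, min_frames = 7L) {
  m <- check_path(x, y, min_frames)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  path_length(smooth_path(x), smooth_path(y)) / ((m - 1) * dt)
}

check_path <- function(x, y, min_len) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < min_len) {
    abort(sprintf("Path has %d points; at least %d are required.",
                  length(x), min_len))
  }
  length(x)
}

#' Per-track CASA motility parameters
#'
#' Computes VCL, VSL, VAP and the shape ratios LIN = VSL/VCL, STR = VSL/VAP,
#' WOB = VAP/VCL for every track. Tracks shorter than `min_frames` are
#' dropped (with a message); tracks shorter than `min_frames_vap` get `NA`
#' for VAP and the VAP-based ratios; ratios are `NA` whenever their
#' denominator is zero (a stationary track has well-defined zero velocities
#' but undefined shape). Ratios are returned as fractions; see
#' [summarize_motility()] for percent-formatted population tables.
#'
#' @param tracks A track table (`track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`).
#' @param fps Frame rate, Hz (defaults to the table's `fps` attribute).
#' @param min_frames Minimum track length for any statistic (default 2).
#' @param min_frames_vap Minimum track length for VAP/STR/WOB (default 7,
#'   giving the 5-point window at least two fully interior points).
#' @return A tibble of class `casa_motility`: `track_id`, `n_frames`,
#'   `vcl_um_s`, `vsl_um_s`, `vap_um_s`, `lin`, `str`, `wob`.
#' @examples
#' simulate_tracks(n_sperm = 5, fps = 30, seed = 2) |> compute_motility()
#' @export
compute_motility <- function(tracks, fps = NULL, min_frames = 2L,
                             min_frames_vap = 7L) {
  check_track_table(tracks)
  fps <- tracks_fps(tracks, fps)
  if (min_frames < 2L) abort("`min_frames` must be >= 2.")
  dt <- 1 / fps

  n_short <- tracks |>
    count(.data$track_id) |>
    filter(.data$n < min_frames) |>
    nrow()
  if (n_short > 0) {
    inform(sprintf("Dropping %d track(s) shorter than %d frames.",
                   n_short, min_frames))
  }

  out <- tracks |>
    arrange(.data$track_id, .data$frame) |>
    group_by(.data$track_id) |>
    filter(n() >= min_frames) |>
    summarise(
      n_frames = n(),
      vcl_um_s = path_length(.data$x_um, .data$y_um) / ((n() - 1) * dt),
      vsl_um_s = sqrt((last(.data$x_um) - first(.data$x_um))^2 +
                        (last(.data$y_um) - first(.data$y_um))^2) /
        ((n() - 1) * dt),
      vap_um_s = if (n() >= min_frames_vap) {
        path_length(smooth_path(.data$x_um), smooth_path(.data$y_um)) /
          ((n() - 1) * dt)
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      lin = ifelse(.data$vcl_um_s > 0, .data$vsl_um_s / .data$vcl_um_s, NA_real_),
      str = ifelse(!is.na(.data$vap_um_s) & .data$vap_um_s > 0,
                   .data$vsl_um_s / .data$vap_um_s, NA_real_),
      wob = ifelse(!is.na(.data$vap_um_s) & .data$vcl_um_s > 0,
                   .data$vap_um_s / .data$vcl_um_s, NA_real_)
    )
  attr(out, "fps") <- fps
  class(out) <- c("casa_motility", class(out))
  out
}

#' Population summary of motility records
#'
#' Mean, sample SD (`n - 1` denominator) and count per parameter over
#' tracks, in the mean +/- SD layout of CASA reports. `NA` entries
#' (undefined ratios, short tracks) are excluded per parameter.
#'
#' @param records A motility table from [compute_motility()] or
#'   [ground_truth_motility()].
#' @param percent If `TRUE`, report LIN/STR/WOB in percent.
#' @return A tibble: `parameter`, `mean`, `sd`, `n`. With a single record the
#'   SD is reported as 0.
#' @export
summarize_motility <- function(records, percent = FALSE) {
  req <- c("vcl_um_s", "vsl_um_s", "vap_um_s", "lin", "str", "wob")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort("`records` must be a motility table (see `compute_motility()`).")
  }
  if (nrow(records) == 0L) abort("`records` is empty.")
  out <- records |>
    select(all_of(req)) |>
    tidyr::pivot_longer(everything(), names_to = "parameter") |>
    filter(!is.na(.data$value)) |>
    group_by(.data$parameter) |>
    summarise(mean = mean(.data$value),
              sd = if (n() > 1L) sd(.data$value) else 0,
              n = n(), .groups = "drop") |>
    mutate(parameter = factor(.data$parameter, levels = req)) |>
    arrange(.data$parameter) |>
    mutate(parameter = as.character(.data$parameter))
  if (percent) {
    ratio <- out$parameter %in% c("lin", "str", "wob")
    out$mean[ratio] <- out$mean[ratio] * 100
    out$sd[ratio] <- out$sd[ratio] * 100
    out$parameter[ratio] <- paste0(out$parameter[ratio], "_pct")
  }
  out
}
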