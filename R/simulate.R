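# Synthetic sperm kinematics: ground-truth head trajectories that stand in
# for real dark-field semen videos. The head follows a constant-speed center
# path whose heading performs a random walk, plus a sinusoidal lateral wobble
# along the path normal; a configurable fraction of cells is immotile.

#' Kinematic parameters of the simulated sperm population
#'
#' Defaults emulate a normospermic dark-field recording: progressive speed
#' 30 +/- 5 um/s, lateral head wobble of 2 um amplitude at 5 Hz, a gentle
#' heading random walk, and a 20% immotile fraction. Speeds are drawn from a
#' normal distribution truncated at zero.
#'
#' @param progressive_speed_mean Mean progressive (center-path) speed, um/s.
#' @param progressive_speed_sd SD of progressive speed across cells, um/s.
#' @param wobble_amplitude_um Amplitude of the sinusoidal lateral head
#'   displacement about the center path, um.
#' @param wobble_frequency_hz Wobble (head-beat) frequency, Hz.
#' @param heading_diffusion Heading diffusion coefficient of the center-path
#'   random walk, rad^2/s. 0 gives straight center paths.
#' @param immotile_fraction Fraction of cells with zero progressive speed and
#'   no wobble (positional noise only), in `[0, 1]`.
#' @param positional_noise_sd SD of independent per-frame positional jitter of
#'   the head, um.
#' @return An object of class `kinematics_params`.
#' @export
kinematics_params <- function(progressive_speed_mean = 30,
                              progressive_speed_sd = 5,
                              wobble_amplitude_um = 2,
                              wobble_frequency_hz = 5,
                              heading_diffusion = 0.3,
                              immotile_fraction = 0.2,
                              positional_noise_sd = 0.05) {
  check_number(progressive_speed_mean, "progressive_speed_mean", min = 0)
  check_number(progressive_speed_sd, "progressive_speed_sd", min = 0)
  check_number(wobble_amplitude_um, "wobble_amplitude_um", min = 0)
  check_number(wobble_frequency_hz, "wobble_frequency_hz", min = 0)
  check_number(heading_diffusion, "heading_diffusion", min = 0)
  check_number(immotile_fraction, "immotile_fraction", min = 0, max = 1)
  check_number(positional_noise_sd, "positional_noise_sd", min = 0)
  structure(
    list(
      progressive_speed_mean = progressive_speed_mean,
      progressive_speed_sd = progressive_speed_sd,
      wobble_amplitude_um = wobble_amplitude_um,
      wobble_frequency_hz = wobble_frequency_hz,
      heading_diffusion = heading_diffusion,
      immotile_fraction = immotile_fraction,
      positional_noise_sd = positional_noise_sd
    ),
    class = "kinematics_params"
  )
}

#' Linear temperature dependence of progressive speed
#'
#' Chamber temperature shifts the mean progressive speed linearly; wobble
#' parameters are unaffected (wobble amplitude shows no systematic
#' temperature response in dark-field recordings).
#'
#' @param reference_temperature_c Temperature at which the base
#'   [kinematics_params()] apply, deg C.
#' @param speed_slope Speed change per degree, (um/s)/degC; >= 0 for the
#'   default model. The 1.5 default gives a 37 degC chamber a ~16 um/s mean
#'   speed advantage over a 26 degC one, in line with reported warming
#'   responses.
#' @return An object of class `temperature_model`.
#' @export
temperature_model <- function(reference_temperature_c = 26, speed_slope = 1.5) {
  check_number(reference_temperature_c, "reference_temperature_c")
  check_number(speed_slope, "speed_slope", min = 0)
  structure(
    list(reference_temperature_c = reference_temperature_c,
         speed_slope = speed_slope),
    class = "temperature_model"
  )
}

#' Apply a temperature model to kinematic parameters
#'
#' Returns the parameters with the mean progressive speed shifted by
#' `speed_slope * (temperature - reference)`; all other fields unchanged.
#' Temperatures outside the 20-40 degC physiological band raise a warning.
#'
#' @param params A [kinematics_params()].
#' @param model A [temperature_model()].
#' @param temperature_c Chamber temperature, deg C.
#' @return A [kinematics_params()] at the requested temperature.
#' @examples
#' p <- kinematics_params(progressive_speed_mean = 20)
#' apply_temperature(p, temperature_model(26, 1), 37)$progressive_speed_mean
#' @export
apply_temperature <- function(params, model, temperature_c) {
  stopifnot(inherits(params, "kinematics_params"),
            inherits(model, "temperature_model"))
  check_number(temperature_c, "temperature_c")
  if (temperature_c < 20 || temperature_c > 40) {
    warn(sprintf("Temperature %.1f degC is outside the advisory 20-40 degC range.",
                 temperature_c))
  }
  shift <- model$speed_slope * (temperature_c - model$reference_temperature_c)
  params$progressive_speed_mean <- max(0, params$progressive_speed_mean + shift)
  params
}

# speeds from a normal truncated at 0, by rejection (vectorised rounds)
draw_truncated_speeds <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

# rejection-sample start positions with a minimum pairwise separation
draw_start_positions <- function(n, fov, margin, min_separation, max_tries = 5000) {
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, margin, fov[1] - margin)
      y <- runif(1, margin, fov[2] - margin)
      if (i == 1L || min_separation <= 0 ||
          min(sqrt((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2)) >=
            min_separation) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) {
      abort(sprintf(
        "Could not place %d cells with min separation %.1f um in a %.0f x %.0f um field.",
        n, min_separation, fov[1], fov[2]
      ))
    }
  }
  tibble(x0 = xs, y0 = ys)
}

#' Simulate ground-truth sperm head trajectories
#'
#' Each motile cell's center path advances at its drawn speed while its
#' heading performs a Gaussian random walk; the head is displaced from the
#' center path by `A * sin(2*pi*f*t + phi)` along the instantaneous path
#' normal (phase `phi` uniform per cell), plus independent positional noise.
#' Immotile cells stay at their start position with positional noise only.
#' Cells whose head leaves the field of view are truncated at the exit frame
#' (tracks shorter than 2 frames are dropped), mirroring real cells swimming
#' out of frame.
#'
#' @param params A [kinematics_params()].
#' @param n_sperm Number of cells to simulate (>= 1).
#' @param duration_s Clip duration in seconds; a clip of `duration_s` at
#'   `fps` has `round(duration_s * fps) + 1` samples, so the elapsed time
#'   `(M - 1) / fps` equals `duration_s` exactly.
#' @param fps Frame rate, Hz.
#' @param field_of_view_um Numeric length-2, field of view (width, height) um.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param min_separation_um Minimum pairwise distance between start
#'   positions, um (0 disables the constraint).
#' @return A tibble of class `casa_tracks` with columns `track_id`, `frame`
#'   (0-based), `time_s`, `x_um`, `y_um`, carrying attributes `fps` and
#'   `meta` (per-cell tibble: `track_id`, `motile`, `speed_um_s`).
#' @examples
#' tr <- simulate_tracks(n_sperm = 5, duration_s = 1, fps = 30, seed = 1)
#' dplyr::count(tr, track_id)
#' @export
simulate_tracks <- function(params = kinematics_params(),
                            n_sperm,
                            duration_s = 1,
                            fps = 30,
                            field_of_view_um = c(256, 256),
                            seed = 1L,
                            min_separation_um = 0) {
  stopifnot(inherits(params, "kinematics_params"))
  if (!is.numeric(n_sperm) || n_sperm < 1) abort("`n_sperm` must be >= 1.")
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  if (length(field_of_view_um) != 2L || any(field_of_view_um <= 0)) {
    abort("`field_of_view_um` must be two positive numbers (width, height).")
  }
  n_sperm <- as.integer(n_sperm)
  dt <- 1 / fps
  m <- as.integer(round(duration_s * fps)) + 1L
  t_s <- (seq_len(m) - 1L) * dt

  withr::with_seed(seed, {
    motile <- runif(n_sperm) >= params$immotile_fraction
    speeds <- draw_truncated_speeds(n_sperm, params$progressive_speed_mean,
                                    params$progressive_speed_sd)
    speeds[!motile] <- 0
    heading0 <- runif(n_sperm, 0, 2 * pi)
    phase <- runif(n_sperm, 0, 2 * pi)
    margin <- min(5, 0.1 * min(field_of_view_um))
    starts <- draw_start_positions(n_sperm, field_of_view_um, margin,
                                   min_separation_um)

    pieces <- purrr::map(seq_len(n_sperm), function(i) {
      if (motile[i]) {
        steps <- rnorm(m - 1L, 0, sqrt(params$heading_diffusion * dt))
        theta <- heading0[i] + cumsum(c(0, steps))
        cx <- starts$x0[i] + cumsum(c(0, speeds[i] * dt * cos(theta[-m])))
        cy <- starts$y0[i] + cumsum(c(0, speeds[i] * dt * sin(theta[-m])))
        lat <- params$wobble_amplitude_um *
          sin(2 * pi * params$wobble_frequency_hz * t_s + phase[i])
        x <- cx - lat * sin(theta)
        y <- cy + lat * cos(theta)
      } else {
        x <- rep(starts$x0[i], m)
        y <- rep(starts$y0[i], m)
      }
      if (params$positional_noise_sd > 0) {
        x <- x + rnorm(m, 0, params$positional_noise_sd)
        y <- y + rnorm(m, 0, params$positional_noise_sd)
      }
      outside <- x < 0 | x > field_of_view_um[1] | y < 0 | y > field_of_view_um[2]
      keep <- if (any(outside)) seq_len(which(outside)[1] - 1L) else seq_len(m)
      if (length(keep) < 2L) return(NULL)
      tibble(track_id = i, frame = keep - 1L, time_s = t_s[keep],
             x_um = x[keep], y_um = y[keep])
    })
    out <- purrr::list_rbind(purrr::compact(pieces))
  })

  attr(out, "fps") <- fps
  attr(out, "meta") <- tibble(track_id = seq_len(n_sperm),
                              motile = motile, speed_um_s = speeds)
  class(out) <- c("casa_tracks", class(out))
  out
}

#' Temporally subsample a track table
#'
#' Keeps every `fps / target_fps`-th sample of each track, starting at its
#' first retained global frame index, and renumbers frames on the new grid.
#' The stride must be an integer.
#'
#' @param tracks A track table (`track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`) with an `fps` attribute, or pass `fps`.
#' @param target_fps Target frame rate, Hz; must divide `fps` evenly.
#' @param fps Source frame rate (defaults to the table's attribute).
#' @return A track table at `target_fps`.
#' @export
subsample_tracks <- function(tracks, target_fps, fps = NULL) {
  check_track_table(tracks)
  fps <- tracks_fps(tracks, fps)
  stride <- fps / target_fps
  if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
    abort(sprintf("`target_fps` (%g) must divide fps (%g) evenly.", target_fps, fps))
  }
  stride <- as.integer(round(stride))
  meta <- attr(tracks, "meta", exact = TRUE)
  out <- tracks |>
    filter(.data$frame %% stride == 0L) |>
    mutate(frame = .data$frame %/% stride)
  attr(out, "fps") <- target_fps
  attr(out, "meta") <- meta
  if (!inherits(out, "casa_tracks")) class(out) <- c("casa_tracks", class(out))
  out
}

#' Write / read a track table as CSV
#'
#' The on-disk schema is `track_id, frame, time_s, x_um, y_um` (the same
#' schema for simulated ground truth and recovered tracks, so the two can be
#' diffed directly). The frame rate is stored in a `# fps:` comment line.
#'
#' @param tracks A track table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  check_track_table(tracks)
  fps <- attr(tracks, "fps", exact = TRUE)
  header <- if (is.null(fps)) character(0) else sprintf("# fps: %s", format(fps))
  writeLines(header, path)
  readr::write_csv(as_tibble(tracks)[c("track_id", "frame", "time_s", "x_um", "y_um")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_tracks
#' @param fps Frame rate override when the file has no `# fps:` header.
#' @export
read_tracks <- function(path, fps = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# fps:", first)) {
    fps <- fps %||% as.numeric(sub("^# fps:\\s*", "", first))
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  check_track_table(out, name = basename(path))
  out <- out |> mutate(track_id = as.integer(.data$track_id),
                       frame = as.integer(.data$frame))
  attr(out, "fps") <- fps
  class(out) <- c("casa_tracks", class(out))
  out
}
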