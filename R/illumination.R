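# LED-array illumination geometry: which imaging mode (bright-field,
# dark-field, mixed) a given LED pattern produces for a given objective.
#
# Geometry: a point-source LED at lateral offset r from the optical axis, a
# distance d below the sample, illuminates the specimen at angle
# alpha = atan(r / d). The objective accepts rays up to theta = asin(NA).
# LEDs with alpha < theta contribute bright-field illumination; LEDs with
# alpha > theta only contribute scattered (dark-field) light.

#' LED array configuration
#'
#' Describes a concentric-ring LED array used as the illumination source of a
#' compact transmission microscope. The default geometry is a 61-LED array in
#' five rings (1, 8, 12, 16 and 24 LEDs) with a 4 mm radial pitch, mounted
#' 20 mm below the sample, so that at NA = 0.3 the two innermost rings fall
#' inside the objective's acceptance cone (bright-field) and the three outer
#' rings fall outside it (dark-field).
#'
#' @param ring_radii_mm Radial distance of each ring from the array center,
#'   in mm. Must be strictly increasing; the central LED is ring 1 at 0 mm.
#' @param ring_counts Number of LEDs in each ring.
#' @param distance_mm Array-to-sample distance in mm (> 0).
#' @return An object of class `led_array_config`.
#' @examples
#' arr <- led_array_config()
#' led_angle(arr, 3) # third ring, degrees
#' @export
led_array_config <- function(ring_radii_mm = c(0, 4, 8, 12, 16),
                             ring_counts = c(1L, 8L, 12L, 16L, 24L),
                             distance_mm = 20) {
  if (length(ring_radii_mm) != length(ring_counts)) {
    abort("`ring_radii_mm` and `ring_counts` must have the same length.")
  }
  if (any(diff(ring_radii_mm) <= 0)) {
    abort("`ring_radii_mm` must be strictly increasing.")
  }
  if (any(ring_counts < 1)) abort("`ring_counts` must all be >= 1.")
  check_number(distance_mm, "distance_mm", min = 0, strict_min = TRUE)
  structure(
    list(
      ring_radii_mm = as.numeric(ring_radii_mm),
      ring_counts = as.integer(ring_counts),
      distance_mm = distance_mm
    ),
    class = "led_array_config"
  )
}

#' Objective specification
#'
#' @param magnification Nominal magnification (informational).
#' @param numerical_aperture Numerical aperture; must lie in (0, 1) for an
#'   air objective. The acceptance half-angle is `asin(numerical_aperture)`.
#' @return An object of class `objective_spec`.
#' @examples
#' objective_spec(10, 0.3)
#' @export
objective_spec <- function(magnification = 10, numerical_aperture = 0.3) {
  check_number(magnification, "magnification", min = 0, strict_min = TRUE)
  if (!is.numeric(numerical_aperture) || length(numerical_aperture) != 1L ||
      numerical_aperture <= 0 || numerical_aperture >= 1) {
    abort("`numerical_aperture` must lie strictly between 0 and 1.")
  }
  structure(
    list(magnification = magnification, numerical_aperture = numerical_aperture),
    class = "objective_spec"
  )
}

#' Acceptance half-angle of an objective
#'
#' @param objective An [objective_spec()].
#' @return Half-angle `asin(NA)` in degrees.
#' @export
acceptance_half_angle <- function(objective) {
  stopifnot(inherits(objective, "objective_spec"))
  asin(objective$numerical_aperture) * 180 / pi
}

#' Illumination angle of a ring of LEDs
#'
#' The angle at which LEDs of ring `ring` illuminate the sample,
#' `atan(ring_radius / distance)`, in degrees.
#'
#' @param array An [led_array_config()].
#' @param ring Ring index, 1-based (1 is the central LED).
#' @return Angle in degrees, in `[0, 90)`.
#' @export
led_angle <- function(array, ring) {
  stopifnot(inherits(array, "led_array_config"))
  if (!is.numeric(ring) || any(ring != as.integer(ring)) ||
      any(ring < 1) || any(ring > length(array$ring_radii_mm))) {
    abort(sprintf(
      "`ring` must be an integer in 1..%d.", length(array$ring_radii_mm)
    ))
  }
  atan(array$ring_radii_mm[ring] / array$distance_mm) * 180 / pi
}

#' Illumination pattern
#'
#' A set of active LEDs given as (ring, position) pairs, optionally with an
#' RGB color label per LED (colors describe Rheinberg-style patterns; they do
#' not affect mode classification).
#'
#' @param ring Integer vector of ring indices (1-based).
#' @param position Integer vector of LED positions within each ring (1-based).
#' @param color Optional character vector of color labels, recycled.
#' @param array The [led_array_config()] used to validate indices.
#' @return A tibble with columns `ring`, `position`, `color`, of class
#'   `illumination_pattern`.
#' @examples
#' arr <- led_array_config()
#' center <- illumination_pattern(1, 1, array = arr)
#' third_ring <- illumination_pattern(rep(3, 12), 1:12, array = arr)
#' @export
illumination_pattern <- function(ring, position, color = NA_character_,
                                 array = led_array_config()) {
  stopifnot(inherits(array, "led_array_config"))
  ring <- as.integer(ring)
  position <- as.integer(position)
  if (length(ring) != length(position)) {
    abort("`ring` and `position` must have the same length.")
  }
  n_rings <- length(array$ring_counts)
  if (any(ring < 1 | ring > n_rings)) {
    abort(sprintf("`ring` indices must lie in 1..%d.", n_rings))
  }
  bad <- position < 1 | position > array$ring_counts[ring]
  if (any(bad)) {
    abort("`position` indices exceed the LED count of their ring.")
  }
  out <- tibble(ring = ring, position = position,
                color = rep_len(as.character(color), length(ring)))
  class(out) <- c("illumination_pattern", class(out))
  out
}

#' Classify the imaging mode of an illumination pattern
#'
#' Compares the illumination angle of every active LED with the objective's
#' acceptance half-angle `theta = asin(NA)`. If all LEDs sit strictly inside
#' the acceptance cone the image is bright-field; if all sit strictly outside
#' it, only scattered light is collected and the image is dark-field; any mix
#' (including an LED exactly at `theta`, whose marginal rays are not reliably
#' collected) yields `"mixed"`.
#'
#' @param pattern An [illumination_pattern()] (non-empty).
#' @param array An [led_array_config()].
#' @param objective An [objective_spec()].
#' @return One of `"bright_field"`, `"dark_field"`, `"mixed"`.
#' @examples
#' arr <- led_array_config()
#' obj <- objective_spec(10, 0.3)
#' classify_mode(illumination_pattern(1, 1, array = arr), arr, obj)
#' @export
classify_mode <- function(pattern, array = led_array_config(),
                          objective = objective_spec()) {
  stopifnot(inherits(array, "led_array_config"),
            inherits(objective, "objective_spec"))
  if (!is.data.frame(pattern) || !all(c("ring", "position") %in% names(pattern))) {
    abort("`pattern` must have columns `ring` and `position`.")
  }
  if (nrow(pattern) == 0L) {
    abort("`pattern` is empty: cannot classify an illumination mode.")
  }
  alpha <- led_angle(array, pattern$ring)
  theta <- acceptance_half_angle(objective)
  if (all(alpha < theta)) return("bright_field")
  if (all(alpha > theta)) return("dark_field")
  "mixed"
}

#' Read an illumination pattern from a YAML file
#'
#' The file holds a list `leds:` of entries with fields `ring`, `position`
#' and optional `color`.
#'
#' @param path Path to a YAML pattern file.
#' @param array The [led_array_config()] used to validate indices.
#' @return An [illumination_pattern()].
#' @export
read_pattern <- function(path, array = led_array_config()) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$leds) || length(spec$leds) == 0L) {
    abort(sprintf("No `leds` entries found in '%s'.", path))
  }
  leds <- purrr::map(spec$leds, function(l) {
    tibble(ring = as.integer(l$ring), position = as.integer(l$position),
           color = as.character(l$color %||% NA_character_))
  }) |> purrr::list_rbind()
  illumination_pattern(leds$ring, leds$position, leds$color, array = array)
}
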