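# ggplot2 visualisations for track tables and motility records.

#' Plot sperm trajectories
#'
#' Paths in the image coordinate frame (x right, y down -- the y axis is
#' reversed to match how the frames display), one colour per track.
#'
#' @param tracks A track table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, ...) {
  check_track_table(tracks)
  ggplot2::ggplot(tracks,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(linewidth = 0.4, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tracks
#' @param object A `casa_tracks` table.
#' @export
autoplot.casa_tracks <- function(object, ...) plot_tracks(object, ...)

#' Plot the distribution of motility parameters
#'
#' Histograms of the per-track velocities (um/s) and shape ratios
#' (fractions), one facet per parameter.
#'
#' @param records A motility table from [compute_motility()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_motility <- function(records, bins = 20, ...) {
  long <- records |>
    select(any_of(c("vcl_um_s", "vsl_um_s", "vap_um_s", "lin", "str", "wob"))) |>
    tidyr::pivot_longer(everything(), names_to = "parameter") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "tracks") +
    ggplot2::theme_minimal()
}

#' @rdname plot_motility
#' @param object A `casa_motility` table.
#' @export
autoplot.casa_motility <- function(object, ...) plot_motility(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
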