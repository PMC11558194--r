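# Validation statistics for comparing trackers / platforms: paired
# coefficient of variation, two-sample t-test, one-way ANOVA, and a linear
# trend test for temperature sweeps. Normality (Shapiro-Wilk) and variance
# homogeneity (Levene) checks are computed as advisory diagnostics only.

#' Coefficient of variation between two paired measurement series
#'
#' `100 * SD(a - b) / mean(c(a, b))`: the SD of the paired differences
#' (sample SD, `n - 1` denominator) over the pooled mean of both series.
#' Used to quantify agreement between two trackers measuring the same
#' fields of view; values below 10% are conventionally taken as acceptable
#' agreement.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2,
#'   same units.
#' @return CV in percent (scale-invariant: rescaling both series leaves it
#'   unchanged).
#' @examples
#' coefficient_of_variation(c(10, 11, 9), c(10.5, 10.5, 9.2))
#' @export
coefficient_of_variation <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must be paired (equal length).")
  }
  if (length(values_a) < 2L) abort("At least 2 pairs are required.")
  overall <- mean(c(values_a, values_b))
  if (overall == 0) abort("Overall mean is zero: CV undefined.")
  100 * sd(values_a - values_b) / overall
}

#' Compare two trackers / methods on one parameter
#'
#' Computes the paired coefficient of variation and an independent-samples
#' t-test (pooled variance by default; Welch via `var_equal = FALSE`)
#' between two series of per-field-of-view means of the same motility
#' parameter. Shapiro-Wilk normality p-values per group and a Levene
#' homogeneity p-value are attached as advisory diagnostics. When both
#' groups are constant the t statistic is reported as 0 (identical groups)
#' or `NA` (different constants).
#'
#' @param values_a,values_b Numeric vectors (paired and equal length for the
#'   CV; the t-test itself only needs >= 2 values per group).
#' @param parameter Label for the compared parameter.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return An object of class `method_comparison` with [tidy()] and
#'   [glance()] methods.
#' @examples
#' cmp <- compare_methods(c(26.1, 27.0, 25.8), c(26.4, 27.2, 25.6), "vcl")
#' tidy(cmp)
#' @export
compare_methods <- function(values_a, values_b, parameter = "value",
                            var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  cv <- if (length(values_a) == length(values_b)) {
    coefficient_of_variation(values_a, values_b)
  } else {
    NA_real_
  }
  sd_a <- sd(values_a); sd_b <- sd(values_b)
  if (sd_a == 0 && sd_b == 0) {
    if (mean(values_a) == mean(values_b)) {
      tt <- list(statistic = 0, parameter = length(values_a) +
                   length(values_b) - 2L, p.value = 1)
    } else {
      tt <- list(statistic = NA_real_, parameter = NA_real_,
                 p.value = NA_real_)
    }
  } else {
    tt <- t.test(values_a, values_b, var.equal = var_equal)
  }
  sw <- function(v) {
    if (length(v) >= 3L && length(v) <= 5000L && sd(v) > 0) {
      shapiro.test(v)$p.value
    } else NA_real_
  }
  lev_p <- if (sd_a > 0 || sd_b > 0) {
    grp <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    as.numeric(car::leveneTest(c(values_a, values_b), grp)[1, "Pr(>F)"])
  } else NA_real_
  structure(
    list(
      parameter = parameter,
      n_a = length(values_a), n_b = length(values_b),
      mean_a = mean(values_a), mean_b = mean(values_b),
      sd_a = sd_a, sd_b = sd_b,
      cv_percent = cv,
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = unname(tt$p.value),
      var_equal = var_equal,
      shapiro_p_a = sw(values_a), shapiro_p_b = sw(values_b),
      levene_p = lev_p
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "<method_comparison> %s: %.3f +/- %.3f vs %.3f +/- %.3f\n  CV = %s%%, t = %s (df = %s), p = %s\n",
    x$parameter, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
    format(round(x$cv_percent, 2)), format(round(x$t_statistic, 3)),
    format(round(x$df, 1)), format(signif(x$p_value, 3))
  ))
  invisible(x)
}

#' @rdname compare_methods
#' @param x A `method_comparison` object.
#' @param ... Unused.
#' @export
tidy.method_comparison <- function(x, ...) {
  tibble(
    parameter = x$parameter,
    mean_a = x$mean_a, sd_a = x$sd_a,
    mean_b = x$mean_b, sd_b = x$sd_b,
    cv_percent = x$cv_percent,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value
  )
}

#' @rdname compare_methods
#' @export
glance.method_comparison <- function(x, ...) {
  tibble(parameter = x$parameter, n_a = x$n_a, n_b = x$n_b,
         cv_percent = x$cv_percent, p_value = x$p_value,
         significant_at_0.05 = !is.na(x$p_value) && x$p_value < 0.05)
}

#' One-way ANOVA across several groups
#'
#' Classic (equal-variance) one-way ANOVA F-test across >= 2 groups, e.g.
#' repeated preparations of one sample or the same sample on different
#' microscope platforms.
#'
#' @param groups A named or unnamed list of numeric vectors (each >= 2
#'   values), or a data frame with `value` and `group` columns.
#' @param value,group Column names when `groups` is a data frame.
#' @return An object of class `group_comparison` with [tidy()]/[glance()].
#' @examples
#' cmp <- compare_groups(list(a = c(29, 30, 28), b = c(29.5, 28.6, 29.1)))
#' glance(cmp)
#' @export
compare_groups <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  if (!is.list(groups) || length(groups) < 2L) {
    abort("`groups` must hold at least 2 groups.")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    abort("Every group needs at least 2 values.")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  lev_p <- tryCatch(
    as.numeric(car::leveneTest(values, g)[1, "Pr(>F)"]),
    error = function(e) NA_real_
  )
  structure(
    list(
      n_groups = length(groups),
      group_means = vapply(groups, mean, numeric(1)),
      f_statistic = unname(ow$statistic),
      df_between = unname(ow$parameter[1]),
      df_within = unname(ow$parameter[2]),
      p_value = unname(ow$p.value),
      levene_p = lev_p
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d groups: F(%g, %g) = %.3f, p = %s\n",
              x$n_groups, x$df_between, x$df_within, x$f_statistic,
              format(signif(x$p_value, 3))))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(group = names(x$group_means) %||% as.character(seq_along(x$group_means)),
         mean = unname(x$group_means))
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(n_groups = x$n_groups, f_statistic = x$f_statistic,
         df_between = x$df_between, df_within = x$df_within,
         p_value = x$p_value, levene_p = x$levene_p)
}

#' Linear trend of a motility parameter against temperature
#'
#' Least-squares regression of per-chamber parameter means on chamber
#' temperature. `increasing` reports whether the slope is positive with
#' one-sided p < `alpha`.
#'
#' @param data A data frame with columns `temperature_c` and `value` (e.g.
#'   mean VCL per chamber).
#' @param alpha Significance level for the one-sided increase test.
#' @return An object of class `temperature_trend` with [tidy()]/[glance()].
#' @export
temperature_trend <- function(data, alpha = 0.05) {
  if (!all(c("temperature_c", "value") %in% names(data))) {
    abort("`data` must have columns `temperature_c` and `value`.")
  }
  if (nrow(data) < 3L) abort("At least 3 temperature points are required.")
  fit <- lm(value ~ temperature_c, data = data)
  sm <- summary(fit)$coefficients
  slope <- sm["temperature_c", "Estimate"]
  p_two <- sm["temperature_c", "Pr(>|t|)"]
  p_one <- if (slope > 0) p_two / 2 else 1 - p_two / 2
  structure(
    list(slope = slope, intercept = sm["(Intercept)", "Estimate"],
         p_two_sided = p_two, p_one_sided_increase = p_one,
         increasing = slope > 0 && p_one < alpha,
         n = nrow(data), fit = fit),
    class = "temperature_trend"
  )
}

#' @export
print.temperature_trend <- function(x, ...) {
  cat(sprintf(
    "<temperature_trend> slope = %.4f per degC (one-sided p = %s): %s\n",
    x$slope, format(signif(x$p_one_sided_increase, 3)),
    if (x$increasing) "increasing" else "no significant increase"
  ))
  invisible(x)
}

#' @rdname temperature_trend
#' @param x A `temperature_trend` object.
#' @param ... Unused.
#' @export
tidy.temperature_trend <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname temperature_trend
#' @export
glance.temperature_trend <- function(x, ...) {
  tibble(slope = x$slope, p_two_sided = x$p_two_sided,
         p_one_sided_increase = x$p_one_sided_increase,
         increasing = x$increasing, n = x$n)
}

#' Read a TrackMate spot export into the track schema
#'
#' Parses the CSV TrackMate exports for spots (columns `TRACK_ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`; the three repeated header rows of newer
#' TrackMate versions are skipped automatically). Positions are assumed
#' calibrated; pass `position_scale` to convert.
#'
#' @param path CSV path.
#' @param fps Frame rate, Hz, used for `time_s`.
#' @param position_scale Multiplier applied to positions (default 1:
#'   positions already in um).
#' @return A track table (`track_id`, `frame`, `time_s`, `x_um`, `y_um`).
#' @export
read_trackmate <- function(path, fps, position_scale = 1) {
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(req %in% names(raw))) {
    abort(sprintf("'%s' lacks TrackMate columns %s.", path,
                  paste(setdiff(req, names(raw)), collapse = ", ")))
  }
  out <- raw |>
    filter(!is.na(suppressWarnings(as.numeric(.data$FRAME)))) |>
    transmute(
      track_id = as.integer(as.numeric(.data$TRACK_ID)),
      frame = as.integer(as.numeric(.data$FRAME)),
      x_um = as.numeric(.data$POSITION_X) * position_scale,
      y_um = as.numeric(.data$POSITION_Y) * position_scale
    ) |>
    mutate(time_s = .data$frame / fps, .after = "frame") |>
    arrange(.data$track_id, .data$frame)
  attr(out, "fps") <- fps
  class(out) <- c("casa_tracks", class(out))
  out
}
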