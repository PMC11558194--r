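# Fixtures are built in code: small deterministic tracks, rendered scenes,
# and a brute-force gated-assignment oracle used to validate the Hungarian
# linker.

# a track table from explicit coordinates
make_track <- function(x, y, fps = 10, track_id = 1L) {
  out <- tibble::tibble(
    track_id = as.integer(track_id),
    frame = seq_along(x) - 1L,
    time_s = (seq_along(x) - 1L) / fps,
    x_um = as.numeric(x),
    y_um = as.numeric(y)
  )
  attr(out, "fps") <- fps
  class(out) <- c("casa_tracks", class(out))
  out
}

# deterministic straight swimmer: speed um/s along +x
straight_track <- function(speed = 30, duration_s = 1, fps = 30, y0 = 50,
                           x0 = 10) {
  m <- round(duration_s * fps) + 1
  t <- (seq_len(m) - 1) / fps
  make_track(x0 + speed * t, rep(y0, m), fps = fps)
}

# closed loop returning exactly to the start point
loop_track <- function(radius = 10, n = 21, fps = 10) {
  ang <- seq(0, 2 * pi, length.out = n)
  make_track(50 + radius * cos(ang), 50 + radius * sin(ang), fps = fps)
}

# the 4-segment zigzag used as a hand-checked motility example
zigzag_track <- function() {
  make_track(c(0, 1, 2, 3, 4), c(0, 1, 0, 1, 0), fps = 10)
}

# random non-physical coordinate tracks for oracle-equivalence checks
random_tracks <- function(n_tracks, m_range = c(7, 101), fps = 30, seed = 1) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n_tracks), function(i) {
      m <- sample(seq(m_range[1], m_range[2]), 1)
      make_track(cumsum(stats::rnorm(m, 0, 2)), cumsum(stats::rnorm(m, 0, 2)),
                 fps = fps, track_id = i)
    }) |> purrr::list_rbind()
  }) -> out
  attr(out, "fps") <- fps
  class(out) <- c("casa_tracks", class(out))
  out
}

# Brute-force gated assignment: enumerates every one-to-one partial matching
# between a and b with all pair distances <= gate, minimising
# sum(matched distances) + gate * n_unmatched. Independent of the
# Hungarian implementation; only usable for small scenes.
brute_force_assignment <- function(ax, ay, bx, by, gate) {
  n <- length(ax); m <- length(bx)
  d <- outer(seq_len(n), seq_len(m),
             function(i, j) sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2))
  best <- list(cost = Inf, pairs = NULL)
  recurse <- function(i, used_b, pairs, cost) {
    if (i > n) {
      total <- cost + gate * (n - nrow(pairs)) + gate * (m - nrow(pairs))
      if (total < best$cost) best <<- list(cost = total, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used_b, pairs, cost)        # leave i unmatched
    for (j in seq_len(m)) {
      if (!used_b[j] && d[i, j] <= gate) {
        recurse(i + 1L, replace(used_b, j, TRUE),
                rbind(pairs, c(i, j)), cost + d[i, j])
      }
    }
  }
  recurse(1L, rep(FALSE, m), matrix(integer(0), 0, 2), 0)
  best
}

# total objective achieved by a link_frames() result (same cost model)
assignment_cost <- function(links, n_a, n_b, gate) {
  sum(links$distance_um) + gate * (n_a - nrow(links)) + gate * (n_b - nrow(links))
}
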