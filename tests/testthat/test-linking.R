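det_points <- function(x, y, frame = 0L) {
  tibble::tibble(frame = as.integer(frame), x_um = x, y_um = y)
}

test_that("well-separated cells link to their own successors", {
  cur <- det_points(c(0, 50), c(0, 0))
  nxt <- det_points(c(1, 51), c(0, 0))
  links <- link_frames(cur, nxt, gate_um = 10)
  expect_equal(links$idx_current, c(1L, 2L))
  expect_equal(links$idx_next, c(1L, 2L))
})

test_that("detections beyond the gate stay unmatched", {
  cur <- det_points(0, 0)
  nxt <- det_points(30, 0)
  expect_equal(nrow(link_frames(cur, nxt, gate_um = 10)), 0L)
  expect_equal(nrow(link_frames(cur[0, ], nxt, gate_um = 10)), 0L)
})

test_that("optimal assignment beats greedy nearest-neighbour on crossings", {
  # greedy from B would grab A' (distance 1) and force A to B' (total 7);
  # the optimum pairs A-A' and B-B' (total 5)
  cur <- det_points(c(0, 4), c(0, 0))
  nxt <- det_points(c(3, 6), c(0, 0))
  links <- link_frames(cur, nxt, gate_um = 10)
  expect_equal(links$idx_next[links$idx_current == 1L], 1L)
  expect_equal(links$idx_next[links$idx_current == 2L], 2L)
  oracle <- brute_force_assignment(cur$x_um, cur$y_um, nxt$x_um, nxt$y_um, 10)
  expect_equal(assignment_cost(links, 2, 2, 10), oracle$cost, tolerance = 1e-12)
})

test_that("gated assignment matches exhaustive enumeration on random small scenes", {
  for (seed in 1:40) {
    scene <- withr::with_seed(seed, {
      n <- sample(0:4, 1); m <- sample(0:4, 1)
      list(ax = runif(n, 0, 30), ay = runif(n, 0, 30),
           bx = runif(m, 0, 30), by = runif(m, 0, 30))
    })
    gate <- 12
    links <- link_frames(det_points(scene$ax, scene$ay),
                         det_points(scene$bx, scene$by, 1L), gate_um = gate)
    oracle <- brute_force_assignment(scene$ax, scene$ay, scene$bx, scene$by,
                                     gate)
    expect_equal(
      assignment_cost(links, length(scene$ax), length(scene$bx), gate),
      oracle$cost, tolerance = 1e-9
    )
    expect_true(all(links$distance_um <= gate))
  }
})

test_that("linking is invariant to detection order within frames", {
  tr <- simulate_tracks(n_sperm = 6, fps = 30, field_of_view_um = c(300, 300),
                        seed = 31, min_separation_um = 40)
  det <- tr |>
    dplyr::transmute(frame, x_um, y_um)
  attr(det, "fps") <- 30
  shuffled <- withr::with_seed(1, det[sample(nrow(det)), ])
  attr(shuffled, "fps") <- 30
  a <- link_tracks(det)
  b <- link_tracks(shuffled)
  key <- function(t) {
    t |>
      dplyr::arrange(track_id, frame) |>
      dplyr::group_by(track_id) |>
      dplyr::summarise(sig = paste(round(x_um, 9), round(y_um, 9),
                                   collapse = ";")) |>
      dplyr::pull(sig) |>
      sort()
  }
  expect_identical(key(a), key(b))
})

test_that("tracks are assembled, truncated and filtered as configured", {
  # one cell visible in all 10 frames, one exiting after frame 4
  full <- purrr::map(0:9, function(f) det_points(10 + f, 10, f))
  partial <- purrr::map(0:4, function(f) det_points(60 + f, 10, f))
  det <- dplyr::bind_rows(c(full, partial))
  attr(det, "fps") <- 30
  tracks <- link_tracks(det, linking_config(max_link_distance_um = 5))
  lens <- dplyr::count(tracks, track_id)
  expect_equal(sort(lens$n), c(5L, 10L))
  # no resurrection with max_frame_gap = 0: a 2-frame hole splits the track
  holey <- dplyr::bind_rows(purrr::map(c(0:3, 6:9),
                                       function(f) det_points(10 + f, 10, f)))
  attr(holey, "fps") <- 30
  split_tracks <- link_tracks(holey, linking_config(max_link_distance_um = 5))
  expect_equal(sort(dplyr::count(split_tracks, track_id)$n), c(4L, 4L))
  # min_track_length discards stubs
  stub <- dplyr::bind_rows(det_points(0, 0, 0L), det_points(1, 0, 1L),
                           det_points(0.5, 0, 2L))
  attr(stub, "fps") <- 30
  kept <- link_tracks(stub, linking_config(max_link_distance_um = 5,
                                           min_track_length = 4))
  expect_equal(nrow(kept), 0L)
})

test_that("gap closing bridges single-frame dropouts when enabled", {
  det <- dplyr::bind_rows(purrr::map(c(0:3, 5:9),
                                     function(f) det_points(10 + f, 10, f)))
  attr(det, "fps") <- 30
  bridged <- link_tracks(det, linking_config(max_link_distance_um = 5,
                                             max_frame_gap = 1))
  expect_equal(length(unique(bridged$track_id)), 1L)
  expect_equal(nrow(bridged), 9L)
})

test_that("every detection lands in at most one track", {
  tr <- simulate_tracks(n_sperm = 10, fps = 30, field_of_view_um = c(400, 400),
                        seed = 37, min_separation_um = 35)
  det <- dplyr::transmute(tr, frame, x_um, y_um)
  attr(det, "fps") <- 30
  tracks <- link_tracks(det)
  expect_lte(nrow(tracks), nrow(det))
  expect_false(any(duplicated(tracks[c("frame", "x_um", "y_um")])))
  # well-separated scene: identities recovered perfectly
  joined <- dplyr::inner_join(
    tracks, dplyr::rename(tr, true_id = track_id),
    by = c("frame", "x_um", "y_um")
  )
  expect_equal(nrow(joined), nrow(tracks))
  map <- joined |>
    dplyr::distinct(track_id, true_id)
  expect_equal(nrow(map), length(unique(tracks$track_id)))
})

test_that("linking config invariants are enforced", {
  expect_error(linking_config(max_link_distance_um = 0))
  expect_error(linking_config(max_frame_gap = -1), ">= 0")
  expect_error(linking_config(min_track_length = 1), ">= 2")
})
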