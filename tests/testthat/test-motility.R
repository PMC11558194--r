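test_that("velocity primitives match hand calculations", {
  expect_equal(vcl(c(0, 3), c(0, 4), dt = 1), 5)
  z <- zigzag_track()
  expect_equal(vcl(z$x_um, z$y_um, dt = 0.1), 4 * sqrt(2) / 0.4, tolerance = 1e-12)
  expect_equal(vsl(z$x_um, z$y_um, dt = 0.1), 10, tolerance = 1e-12)
  expect_equal(vcl(rep(1, 5), rep(2, 5), dt = 0.1), 0)
  s <- straight_track(speed = 25, fps = 50)
  expect_equal(vsl(s$x_um, s$y_um, dt = 0.02), vcl(s$x_um, s$y_um, dt = 0.02),
               tolerance = 1e-12)
  expect_error(vcl(1, 1, dt = 0.1), "at least 2")
  expect_error(vap(1:5, 1:5, dt = 0.1), "at least 7")
})

test_that("path smoothing shrinks the window symmetrically at the ends", {
  expect_equal(smooth_path(rep(3, 10)), rep(3, 10))
  lin <- as.numeric(1:20)
  expect_equal(smooth_path(lin), lin) # arithmetic sequences are fixed points
  v <- c(0, 0, 5, 0, 0)
  expect_equal(smooth_path(v), c(0, 5 / 3, 1, 5 / 3, 0))
  expect_error(smooth_path(1:5, window = 4), "odd")
  # endpoints preserved -> straight swimmers keep VAP = VCL exactly
  s <- straight_track(speed = 30, fps = 30)
  expect_equal(vap(s$x_um, s$y_um, 1 / 30), 30, tolerance = 1e-12)
})

test_that("smoothing attenuates wobble: VAP between VSL and VCL for gentle sinusoids", {
  t <- seq(0, 2, by = 0.01)
  x <- 30 * t
  y <- 1 * sin(2 * pi * 5 * t)
  v_cl <- vcl(x, y, dt = 0.01)
  v_sl <- vsl(x, y, dt = 0.01)
  v_ap <- vap(x, y, dt = 0.01)
  expect_lt(v_sl, v_ap)
  expect_lt(v_ap, v_cl)
})

test_that("vectorised motility equals the brute-force reference on random tracks", {
  tr <- random_tracks(60, seed = 21)
  fast <- compute_motility(tr)
  slow <- ground_truth_motility(tr)
  for (col in c("vcl_um_s", "vsl_um_s", "vap_um_s", "lin", "str", "wob")) {
    rel <- abs(fast[[col]] - slow[[col]]) / pmax(abs(slow[[col]]), 1e-12)
    expect_lt(max(rel, na.rm = TRUE), 1e-9)
  }
})

test_that("shape ratios obey their algebraic identity and degenerate rules", {
  tr <- random_tracks(40, seed = 33)
  rec <- compute_motility(tr)
  ok <- !is.na(rec$lin) & !is.na(rec$str) & !is.na(rec$wob)
  expect_true(any(ok))
  expect_equal(rec$lin[ok], rec$str[ok] * rec$wob[ok], tolerance = 1e-12)
  expect_true(all(rec$vsl_um_s <= rec$vcl_um_s + 1e-12))
  expect_true(all(rec$vap_um_s <= rec$vcl_um_s + 1e-9, na.rm = TRUE))
  expect_true(all(rec$vsl_um_s <= rec$vap_um_s + 1e-9, na.rm = TRUE))

  still <- make_track(rep(5, 10), rep(5, 10), fps = 10)
  rec0 <- compute_motility(still)
  expect_equal(rec0$vcl_um_s, 0)
  expect_equal(rec0$vsl_um_s, 0)
  expect_true(is.na(rec0$lin) && is.na(rec0$str) && is.na(rec0$wob))
})

test_that("velocities are scale-equivariant and ratios scale-invariant", {
  tr <- random_tracks(10, seed = 8)
  rec1 <- compute_motility(tr)
  tr3 <- dplyr::mutate(tr, x_um = 3 * x_um, y_um = 3 * y_um)
  attr(tr3, "fps") <- attr(tr, "fps")
  rec3 <- compute_motility(tr3)
  expect_equal(rec3$vcl_um_s, 3 * rec1$vcl_um_s, tolerance = 1e-12)
  expect_equal(rec3$vsl_um_s, 3 * rec1$vsl_um_s, tolerance = 1e-12)
  expect_equal(rec3$vap_um_s, 3 * rec1$vap_um_s, tolerance = 1e-12)
  expect_equal(rec3$lin, rec1$lin, tolerance = 1e-12)
  expect_equal(rec3$wob, rec1$wob, tolerance = 1e-12)
})

test_that("short tracks are handled per the configured minimums", {
  tr <- dplyr::bind_rows(
    make_track(1:10, rep(0, 10), track_id = 1L),
    make_track(1:4, rep(0, 4), track_id = 2L),
    make_track(1, 0, track_id = 3L)
  )
  attr(tr, "fps") <- 10
  expect_message(rec <- compute_motility(tr), "shorter than 2")
  expect_equal(sort(rec$track_id), c(1L, 2L))
  expect_true(is.na(rec$vap_um_s[rec$track_id == 2L])) # below VAP minimum
  expect_false(is.na(rec$vap_um_s[rec$track_id == 1L]))
})

test_that("temporal subsampling never raises VCL of wobbly tracks", {
  p <- kinematics_params(immotile_fraction = 0)
  tr <- simulate_tracks(p, n_sperm = 20, duration_s = 1, fps = 100,
                        field_of_view_um = c(2000, 2000), seed = 13)
  full <- compute_motility(tr)
  sub <- compute_motility(subsample_tracks(tr, 10))
  joined <- dplyr::inner_join(full, sub, by = "track_id",
                              suffix = c("_full", "_sub"))
  expect_true(all(joined$vcl_um_s_sub <= joined$vcl_um_s_full + 1e-9))
})

test_that("population summaries use mean and n-1 SD", {
  rec <- tibble::tibble(
    track_id = 1:2, n_frames = 31L,
    vcl_um_s = c(20, 30), vsl_um_s = c(10, 10), vap_um_s = c(15, 16),
    lin = c(0.5, 1 / 3), str = c(2 / 3, 0.625), wob = c(0.75, 8 / 15)
  )
  s <- summarize_motility(rec)
  expect_equal(s$mean[s$parameter == "vcl_um_s"], 25)
  expect_equal(s$sd[s$parameter == "vcl_um_s"], sqrt(50), tolerance = 1e-12)
  expect_equal(s$n, rep(2L, 6))

  one <- summarize_motility(rec[1, ])
  expect_equal(one$sd, rep(0, 6))
  expect_equal(one$n, rep(1L, 6))

  same <- summarize_motility(rec[c(1, 1), ])
  expect_equal(same$sd, rep(0, 6))

  pct <- summarize_motility(rec, percent = TRUE)
  expect_equal(pct$mean[pct$parameter == "lin_pct"], mean(c(0.5, 1 / 3)) * 100)
  expect_error(summarize_motility(rec[0, ]), "empty")
})
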