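test_that("a deterministic straight swimmer travels exactly speed * duration", {
  p <- kinematics_params(progressive_speed_mean = 30, progressive_speed_sd = 0,
                         wobble_amplitude_um = 0, heading_diffusion = 0,
                         immotile_fraction = 0, positional_noise_sd = 0)
  tr <- simulate_tracks(p, n_sperm = 1, duration_s = 1, fps = 30,
                        field_of_view_um = c(500, 500), seed = 7)
  expect_equal(nrow(tr), 31L)
  seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(sum(seg), 30, tolerance = 1e-9)
  rec <- ground_truth_motility(tr)
  expect_equal(rec$vcl_um_s, 30, tolerance = 1e-9)
  expect_equal(rec$vsl_um_s, 30, tolerance = 1e-9)
  expect_equal(rec$vap_um_s, 30, tolerance = 1e-9)
  expect_equal(c(rec$lin, rec$str, rec$wob), c(1, 1, 1), tolerance = 1e-9)
})

test_that("a fully immotile noiseless population never moves", {
  p <- kinematics_params(immotile_fraction = 1, positional_noise_sd = 0)
  tr <- simulate_tracks(p, n_sperm = 10, duration_s = 1, fps = 30, seed = 3)
  disp <- tr |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(d = max(sqrt((x_um - x_um[1])^2 + (y_um - y_um[1])^2)))
  expect_equal(max(disp$d), 0)
})

test_that("simulation is seed-deterministic", {
  a <- simulate_tracks(n_sperm = 20, fps = 30, seed = 42)
  b <- simulate_tracks(n_sperm = 20, fps = 30, seed = 42)
  c <- simulate_tracks(n_sperm = 20, fps = 30, seed = 43)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("drawn speeds follow the requested sampling distribution", {
  p <- kinematics_params(progressive_speed_mean = 30, progressive_speed_sd = 5,
                         immotile_fraction = 0)
  tr <- simulate_tracks(p, n_sperm = 500, duration_s = 0.2, fps = 30,
                        field_of_view_um = c(2000, 2000), seed = 11)
  speeds <- attr(tr, "meta")$speed_um_s
  se <- 5 / sqrt(500)
  expect_lt(abs(mean(speeds) - 30), 3 * se)
  expect_true(all(speeds >= 0))
})

test_that("the brute-force reference reproduces hand-computed path metrics", {
  zig <- zigzag_track() # dt = 0.1 s, four sqrt(2) segments over 0.4 s
  rec <- ground_truth_motility(zig, min_frames_vap = 5)
  expect_equal(rec$vcl_um_s, 4 * sqrt(2) / 0.4, tolerance = 1e-12)
  expect_equal(rec$vcl_um_s, 14.142136, tolerance = 1e-6)
  expect_equal(rec$vsl_um_s, 10, tolerance = 1e-12)
  expect_equal(rec$lin, sqrt(0.5), tolerance = 1e-12)

  lp <- loop_track()
  rec_loop <- ground_truth_motility(lp)
  expect_equal(rec_loop$vsl_um_s, 0, tolerance = 1e-9)
  expect_equal(rec_loop$lin, 0, tolerance = 1e-9)
})

test_that("temperature scaling shifts mean speed linearly and nothing else", {
  p <- kinematics_params(progressive_speed_mean = 20)
  model <- temperature_model(reference_temperature_c = 26, speed_slope = 1)
  expect_identical(apply_temperature(p, model, 26), p)
  p37 <- apply_temperature(p, model, 37)
  expect_equal(p37$progressive_speed_mean, 31)
  expect_equal(p37$wobble_amplitude_um, p$wobble_amplitude_um)
  flat <- temperature_model(26, 0)
  expect_identical(apply_temperature(p, flat, 37), p)
  expect_warning(apply_temperature(p, model, 45), "advisory")
})

test_that("stronger wobble lowers average linearity", {
  mean_lin <- vapply(c(0, 2, 4), function(a) {
    p <- kinematics_params(wobble_amplitude_um = a, immotile_fraction = 0,
                           positional_noise_sd = 0)
    tr <- simulate_tracks(p, n_sperm = 100, duration_s = 1, fps = 30,
                          field_of_view_um = c(2000, 2000), seed = 5)
    mean(ground_truth_motility(tr)$lin)
  }, numeric(1))
  expect_true(all(diff(mean_lin) < 0))
})

test_that("a positive temperature slope yields increasing recovered speed across the gradient", {
  temps <- c(26, 28, 30, 32, 34, 37)
  model <- temperature_model(26, 1.5)
  base <- kinematics_params(immotile_fraction = 0)
  mean_vcl <- vapply(seq_along(temps), function(i) {
    p <- apply_temperature(base, model, temps[i])
    tr <- simulate_tracks(p, n_sperm = 60, duration_s = 1, fps = 30,
                          field_of_view_um = c(2000, 2000), seed = 100 + i)
    mean(ground_truth_motility(tr)$vcl_um_s)
  }, numeric(1))
  expect_true(all(diff(mean_vcl) > 0))
})

test_that("track subsampling keeps every stride-th sample", {
  tr <- simulate_tracks(n_sperm = 3, duration_s = 1, fps = 100, seed = 2,
                        field_of_view_um = c(1000, 1000))
  sub <- subsample_tracks(tr, 10)
  expect_equal(attr(sub, "fps"), 10)
  one <- sub[sub$track_id == sub$track_id[1], ]
  expect_equal(one$time_s, seq(0, 1, by = 0.1), tolerance = 1e-12)
  expect_error(subsample_tracks(tr, 30), "evenly")
})

test_that("track tables survive a CSV round trip", {
  tr <- simulate_tracks(n_sperm = 4, fps = 30, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(attr(back, "fps"), 30)
  expect_equal(as.data.frame(back), as.data.frame(tr)[names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate simulation inputs are rejected", {
  expect_error(simulate_tracks(n_sperm = 0, seed = 1), ">= 1")
  expect_error(simulate_tracks(n_sperm = 2, fps = 0, seed = 1))
  expect_error(simulate_tracks(n_sperm = 2, duration_s = 0, seed = 1))
  expect_error(kinematics_params(immotile_fraction = 1.5))
  expect_error(kinematics_params(progressive_speed_mean = -1))
})
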