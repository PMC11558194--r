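test_that("segmentation masks follow the threshold contract", {
  flat <- matrix(20L, 32, 32)
  cfg_fixed <- segmentation_config(threshold_method = "fixed", fixed_threshold = 50)
  expect_false(any(segment_frame(flat, cfg_fixed)))
  expect_warning(m <- segment_frame(flat, segmentation_config("background")),
                 "Constant")
  expect_false(any(m))
  expect_warning(m2 <- segment_frame(flat, segmentation_config("otsu")),
                 "Constant")
  expect_false(any(m2))
})

test_that("one rendered blob gives one component, two give two", {
  opt <- optics_config(frame_shape = c(80, 80), noise_sd = 0, pixel_size_um = 0.5)
  cfg <- segmentation_config(threshold_method = "fixed",
                             fixed_threshold = opt$background_level +
                               opt$head_peak_intensity / 2)
  one <- make_track(rep(20, 2), rep(20, 2), fps = 30)
  f1 <- render_video(one, opt, seed = 1)$frames[, , 1]
  expect_equal(nrow(extract_particles(segment_frame(f1, cfg), f1, 0.5)), 1L)

  two <- dplyr::bind_rows(make_track(rep(10, 2), rep(10, 2), track_id = 1L),
                          make_track(rep(30, 2), rep(30, 2), track_id = 2L))
  attr(two, "fps") <- 30
  f2 <- render_video(two, opt, seed = 1)$frames[, , 1]
  expect_equal(nrow(extract_particles(segment_frame(f2, cfg), f2, 0.5)), 2L)
})

test_that("component labeling is 8-connected", {
  mask <- matrix(FALSE, 6, 6)
  mask[2, 2] <- TRUE
  mask[3, 3] <- TRUE # touches only diagonally
  mask[5, 5] <- TRUE # separate
  frame <- matrix(1L, 6, 6)
  det <- extract_particles(mask, frame, pixel_size_um = 1)
  expect_equal(nrow(det), 2L)
})

test_that("particle properties follow the calibration and weighting rules", {
  mask <- matrix(FALSE, 10, 10)
  mask[3, 3:7] <- TRUE
  mask[4, 3:7] <- TRUE # 10-pixel rectangle
  frame <- matrix(0L, 10, 10)
  frame[mask] <- 100L
  det <- extract_particles(mask, frame, pixel_size_um = 1, frame_index = 5L)
  expect_equal(det$area_um2, 10)
  expect_equal(det$frame, 5L)
  expect_equal(det$row_px, 3.5)  # uniform weights -> geometric center
  expect_equal(det$col_px, 5)
  expect_equal(det$x_um, 4)      # (col - 1) * pixel_size
  expect_equal(det$y_um, 2.5)
  expect_equal(det$mean_intensity, 100)

  empty <- extract_particles(matrix(FALSE, 5, 5), matrix(0L, 5, 5), 1)
  expect_equal(nrow(empty), 0L)
  expect_error(extract_particles(matrix(FALSE, 5, 5), matrix(0L, 4, 4), 1),
               "same dimensions")
})

test_that("the area filter keeps the closed 3-30 um2 band in order", {
  d <- tibble::tibble(area_um2 = c(2, 10, 31, 3, 30, 29))
  kept <- area_filter(d)
  expect_equal(kept$area_um2, c(10, 3, 30, 29)) # order preserved
  expect_equal(nrow(area_filter(d[0, ])), 0L)
  cfg <- segmentation_config(min_area_um2 = 5, max_area_um2 = 20)
  expect_equal(area_filter(d, cfg)$area_um2, c(10))
})

test_that("noiseless distractor-free detection counts equal in-frame truth", {
  p <- kinematics_params(positional_noise_sd = 0)
  tr <- simulate_tracks(p, n_sperm = 6, duration_s = 0.3, fps = 30,
                        field_of_view_um = c(150, 150), seed = 17,
                        min_separation_um = 25)
  opt <- optics_config(frame_shape = c(300, 300), noise_sd = 0)
  vid <- render_video(tr, opt, seed = 1)
  cfg <- segmentation_config(threshold_method = "fixed",
                             fixed_threshold = opt$background_level +
                               opt$head_peak_intensity / 2)
  det <- detect_video(vid, cfg)
  truth_counts <- dplyr::count(tr, frame)
  det_counts <- dplyr::count(det, frame)
  joined <- dplyr::left_join(truth_counts, det_counts, by = "frame",
                             suffix = c("_truth", "_det"))
  expect_equal(joined$n_det, joined$n_truth)
})

test_that("sub-pixel centroids track ground truth within 0.5 px RMS at default SNR", {
  tr <- simulate_tracks(n_sperm = 5, duration_s = 0.3, fps = 30,
                        field_of_view_um = c(150, 150), seed = 19,
                        min_separation_um = 30)
  opt <- optics_config(frame_shape = c(300, 300))
  vid <- render_video(tr, opt, seed = 23)
  det <- detect_video(vid)
  err2 <- purrr::map_dbl(seq_len(nrow(det)), function(i) {
    frame_truth <- tr[tr$frame == det$frame[i], ]
    min((frame_truth$x_um - det$x_um[i])^2 + (frame_truth$y_um - det$y_um[i])^2)
  })
  rms_px <- sqrt(mean(err2)) / vid$pixel_size_um
  expect_lt(rms_px, 0.5)
})

test_that("detections survive a CSV round trip", {
  tr <- simulate_tracks(n_sperm = 3, fps = 30, field_of_view_um = c(100, 100),
                        seed = 2)
  vid <- render_video(tr, optics_config(frame_shape = c(200, 200)), seed = 3)
  det <- detect_video(vid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read_detections(path)
  expect_equal(attr(back, "fps"), 30)
  expect_equal(as.data.frame(back), as.data.frame(det), tolerance = 1e-9)
})
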