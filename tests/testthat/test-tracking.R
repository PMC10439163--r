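test_that("detection contracts: uniform frames, parameter validation", {
  expect_equal(nrow(detect_particles(matrix(7, 30, 30), 9)), 0L)
  expect_error(detect_particles(matrix(0, 30, 30), 8), "odd")
  expect_error(detect_particles(matrix(0, 30, 30), 1), "odd")
})

test_that("noise-free well-separated blobs are detected at subpixel accuracy", {
  fx <- render_moving_cells(10, 125, blob_sigma_px = 2, noise_sd = 0,
                            n_frames = 3, seed = 13)
  truth <- fx$truth$positions[fx$truth$positions$frame == 2, ]
  det <- detect_particles(fx$stack$frames[[2]], diameter = 9,
                          min_mass = 10)
  expect_equal(nrow(det), 10L)
  m <- match_detections(det, truth, tol = 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lt(m$rmse, 0.5)
})

test_that("mass, intensity, and size filters exclude what they should", {
  m <- matrix(0, 40, 40)
  m <- microflowq:::render_gaussian_spot(m, 20, 20, 2, 200)
  det <- detect_particles(m, 9, min_mass = 10)
  expect_equal(nrow(det), 1L)
  expect_equal(nrow(detect_particles(m, 9, min_mass = det$mass * 2)), 0L)
  expect_equal(nrow(detect_particles(m, 9, min_intensity = 500)), 0L)
  # a wide cluster-like blob is excluded by the max-diameter rule
  wide <- matrix(0, 60, 60)
  wide <- microflowq:::render_gaussian_spot(wide, 30, 30, 6, 200)
  d_wide <- detect_particles(wide, 19, min_mass = 10)
  expect_equal(nrow(d_wide), 1L)
  expect_equal(nrow(detect_particles(wide, 19, min_mass = 10,
                                     max_diameter = 2 * d_wide$size - 1)),
               0L)
})

test_that("inverted detection finds dark-on-light cells", {
  m <- matrix(200, 40, 40)
  m <- m - microflowq:::render_gaussian_spot(matrix(0, 40, 40), 20.3, 19.6,
                                             2, 150)
  det <- detect_particles(m, 9, min_mass = 10, invert = TRUE)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 20.3), 0.3)
  expect_lt(abs(det$y - 19.6), 0.3)
})

test_that("linking follows cells and keeps identities apart", {
  fx <- render_moving_cells(2, 75, blob_sigma_px = 2, n_frames = 10,
                            fps = 25, um_per_px = 1, seed = 21)
  det <- detect_particles_stack(fx$stack, diameter = 9, min_mass = 10)
  ts <- link_and_filter(det, search_range_px = 5, min_frames = 2)
  expect_equal(nrow(ts$trajectories), 2L)
  expect_equal(ts$trajectories$n_frames_present, c(10L, 10L))
  # identities match truth: each linked path stays on one planted row
  for (id in 1:2) {
    d <- ts$detections[ts$detections$cell_id == id, ]
    expect_lt(diff(range(d$y)), 1)
  }
  # empty input is an empty result, not an error
  empty <- link_and_filter(det[0, ], search_range_px = 5)
  expect_equal(nrow(empty$trajectories), 0L)
})

test_that("short or short-ranged trajectories are filtered, monotonically", {
  fx <- render_moving_cells(4, c(20, 60, 100, 140), n_frames = 8,
                            fps = 25, um_per_px = 1, seed = 5)
  det <- detect_particles_stack(fx$stack, diameter = 9, min_mass = 10)
  # cell present only in 2 frames is removed when min_frames = 3
  det2 <- det[!(round(det$y) == round(fx$truth$cells$y[1]) &
                  det$frame > 2), ]
  ts <- link_and_filter(det2, search_range_px = 8, min_frames = 3)
  expect_equal(nrow(ts$trajectories), 3L)
  # raising min_frames / min_distance never increases trajectory count
  counts_f <- vapply(2:8, function(mf) {
    nrow(link_and_filter(det, 8, min_frames = mf)$trajectories)
  }, integer(1))
  expect_true(all(diff(counts_f) <= 0))
  counts_d <- vapply(c(0, 5, 10, 20, 30, 50), function(md) {
    nrow(link_and_filter(det, 8, min_frames = 2,
                         min_distance_px = md)$trajectories)
  }, integer(1))
  expect_true(all(diff(counts_d) <= 0))
  # trajectories below the threshold are provably absent
  ts_d <- link_and_filter(det, 8, min_frames = 2, min_distance_px = 10)
  expect_true(all(ts_d$trajectories$path_distance >= 10))
  ts_f <- link_and_filter(det, 8, min_frames = 5)
  expect_true(all(ts_f$trajectories$n_frames_present >= 5))
})

test_that("linking memory bridges detection gaps", {
  fx <- render_moving_cells(1, 50, n_frames = 9, fps = 25, um_per_px = 1,
                            seed = 3)
  det <- detect_particles_stack(fx$stack, diameter = 9, min_mass = 10)
  det_gap <- det[det$frame != 5, ]
  no_mem <- link_and_filter(det_gap, search_range_px = 5,
                            memory_frames = 0, min_frames = 2)
  expect_equal(nrow(no_mem$trajectories), 2L)
  with_mem <- link_and_filter(det_gap, search_range_px = 5,
                              memory_frames = 1, min_frames = 2)
  expect_equal(nrow(with_mem$trajectories), 1L)
  expect_equal(with_mem$trajectories$n_frames_present, 8L)
})

test_that("velocity arithmetic is exact on constructed trajectories", {
  det <- data.frame(frame = 1:10, x = 5 * (0:9), y = 0, mass = 1,
                    size = 1, ecc = 0, peak_intensity = 1)
  ts <- link_and_filter(det, search_range_px = 6)
  v <- compute_cell_velocity(ts, fps = 25, um_per_px = 1,
                             mode = "x_channel_flow")
  expect_equal(v$velocity_um_s, 125)
  expect_false(v$negative_x)
  vf <- compute_cell_velocity(ts, fps = 25, um_per_px = 1, mode = "free")
  expect_equal(vf$velocity_um_s, 125)
  # stationary cell
  det0 <- transform(det, x = 3)
  v0 <- compute_cell_velocity(link_and_filter(det0, 6), 25, 1)
  expect_equal(v0$velocity_um_s, 0)
  # negative x-velocity is flagged in channel-flow mode
  detn <- transform(det, x = rev(x))
  vn <- compute_cell_velocity(link_and_filter(detn, 6), 25, 1,
                              mode = "x_channel_flow")
  expect_true(vn$negative_x)
  expect_error(compute_cell_velocity(ts, fps = NULL, um_per_px = 1), "fps")
  expect_error(compute_cell_velocity(ts, fps = 25, um_per_px = NULL),
               "um_per_px")
})

test_that("velocity recovery over planted speeds has < 5% error", {
  for (v_true in c(50, 125, 250)) {
    fx <- render_moving_cells(5, v_true, n_frames = 20, fps = 25,
                              um_per_px = 1, seed = 17)
    det <- detect_particles_stack(fx$stack, diameter = 9, min_mass = 10)
    ts <- link_and_filter(det, search_range_px = v_true / 25 + 3,
                          min_frames = 5)
    rec <- compute_cell_velocity(ts, fps = 25, um_per_px = 1,
                                 mode = "x_channel_flow")
    expect_equal(nrow(rec), 5L)
    mare <- mean(abs(rec$velocity_um_s - v_true) / v_true)
    expect_lt(mare, 0.05)
  }
})

test_that("eccentricity agrees with a pixel-moment oracle", {
  disk <- disk_image(60, 60, 30, 30, 10)
  dd <- detect_particles(disk, 21, min_mass = 10)
  expect_lt(dd$ecc, 0.1)
  ell <- ellipse_image(60, 80, 40, 30, 16, 8)
  de <- detect_particles(ell, 41, min_mass = 10)
  expect_lt(abs(de$ecc - pixel_moment_ecc(ell)), 0.05)
  # cross-check the oracle itself against EBImage moments
  lab <- matrix(as.integer(ell > 0), 60, 80)
  mom <- EBImage::computeFeatures.moment(lab)
  expect_lt(abs(pixel_moment_ecc(ell) - mom[1, "m.eccentricity"]), 0.02)
})

test_that("cell fluorescence is the mean of per-frame aperture sums", {
  h <- 40; w <- 40
  g <- matrix(0, h, w)
  g[(18:22) + 1, (18:22) + 1] <- 100   # 5x5 uniform block, sum 2500
  frames <- lapply(1:4, function(i) {
    a <- array(0, c(h, w, 3)); a[, , 2] <- g; a[, , 1] <- 1
    a
  })
  st <- frame_stack(frames, fps = 25, um_per_px = 1)
  det <- data.frame(frame = 1:4, x = 20, y = 20, mass = 1, size = 1,
                    ecc = 0, peak_intensity = 1)
  ts <- link_and_filter(det, search_range_px = 2)
  fl <- measure_cell_fluorescence(ts, st, channel = "green",
                                  aperture_radius_px = 6)
  expect_equal(fl$mean_fluorescence_sum, 2500)
  # zero-intensity channel sums to zero
  frames0 <- lapply(frames, function(a) { a[, , 3] <- 0; a })
  fl0 <- measure_cell_fluorescence(ts, frame_stack(frames0), "blue", 6)
  expect_equal(fl0$mean_fluorescence_sum, 0)
})

test_that("a tracked stained cell recovers its integrated signal within 2%", {
  # reticulocyte-like stain: Gaussian spot of known integrated intensity
  n_frames <- 8; amp <- 180; sigma <- 2
  S <- amp * 2 * pi * sigma^2   # analytic integral of the 2-D Gaussian
  fx <- render_moving_cells(1, 75, blob_sigma_px = sigma, amplitude = amp,
                            n_frames = n_frames, fps = 25, um_per_px = 1,
                            seed = 29)
  gray <- fx$stack
  det <- detect_particles_stack(gray, diameter = 9, min_mass = 10)
  ts <- link_and_filter(det, search_range_px = 5)
  fl <- measure_cell_fluorescence(ts, gray, channel = 1,
                                  aperture_radius_px = 8)
  expect_lt(abs(fl$mean_fluorescence_sum - S) / S, 0.02)
})
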