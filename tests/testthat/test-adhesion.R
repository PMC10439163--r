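test_that("brightfield morphology matches rasterized truth", {
  img <- disk_image(60, 60, 30, 30, 10)
  res <- measure_brightfield_cells(img, 21, um_per_px = 0.5,
                                   min_mass = 10)
  expect_equal(nrow(res$cells), 1L)
  expect_lt(res$cells$circularity, 0.1)
  # rasterized disk truth: 317 px * 0.25 um^2/px = 79.25 um^2
  expect_lt(abs(res$cells$area_um2 - 78.5) / 78.5, 0.1)
  expect_equal(res$field_density, 1 / (60 * 60 * 0.25e-6))
  # cells outside the area window are excluded
  none <- measure_brightfield_cells(img, 21, min_area_um2 = 200,
                                    um_per_px = 0.5, min_mass = 10)
  expect_equal(nrow(none$cells), 0L)
})

test_that("ellipse circularity tracks the intensity-moment oracle", {
  img <- ellipse_image(60, 80, 40, 30, 16, 8)
  res <- measure_brightfield_cells(img, 41, um_per_px = 1, min_mass = 10)
  expect_equal(nrow(res$cells), 1L)
  expect_lt(abs(res$cells$circularity - pixel_moment_ecc(img)), 0.05)
})

test_that("fluorescent region measurements match planted truth", {
  specs <- list(
    list(shape = "disk", center = c(25, 25), r = 10, intensity = 180,
         secondary = list(intensity = 150, r = 4)),
    list(shape = "disk", center = c(75, 70), r = 14, intensity = 150,
         lobes = list(n = 3, sep_px = 12, sigma = 2.5, intensity = 220)))
  fx <- render_adhesion_scene(specs, frame_dim = c(110, 110),
                              um_per_px = 0.5, seed = 2)
  cells <- measure_fluorescent_cells(
    fx$stack, membrane_channel = "membrane", membrane_threshold = 50,
    secondary_channel = "secondary", secondary_threshold = 50,
    lobe_channel = "lobes", lobe_threshold = 50, min_peak_sep_px = 8,
    um_per_px = 0.5)
  expect_equal(nrow(cells), 2L)
  truth <- fx$truth$cells
  expect_equal(cells$area_px2, truth$area_px)
  expect_equal(cells$x, truth$x, tolerance = 1e-9)
  # uniform membrane intensity: texture exactly zero
  expect_equal(cells$membrane_texture, c(0, 0))
  expect_equal(cells$secondary_sum, truth$secondary_sum)
  expect_equal(cells$lobe_count, truth$lobe_count)
})

test_that("secondary signal below threshold contributes nothing", {
  fx <- render_adhesion_scene(
    list(list(shape = "disk", center = c(20, 20), r = 8, intensity = 180,
              secondary = list(intensity = 40, r = 4))),
    frame_dim = c(48, 48), um_per_px = 1, seed = 1)
  cells <- measure_fluorescent_cells(fx$stack, "membrane", 50,
                                     secondary_channel = "secondary",
                                     secondary_threshold = 60,
                                     um_per_px = 1)
  expect_equal(cells$secondary_sum, 0)
  expect_error(
    measure_fluorescent_cells(fx$stack, "nonexistent", 50, um_per_px = 1),
    "channel")
})

test_that("membrane texture equals the s.d. of rendered region pixels", {
  fx <- render_adhesion_scene(
    list(list(shape = "disk", center = c(24, 24), r = 10, intensity = 150,
              membrane_texture_sd = 20)),
    frame_dim = c(50, 50), um_per_px = 1, seed = 8)
  mem <- fx$stack$frames[[1]][, , 1]
  cells <- measure_fluorescent_cells(fx$stack, "membrane", 50,
                                     um_per_px = 1)
  oracle <- sd(mem[mem > 50])
  expect_equal(cells$membrane_texture, oracle, tolerance = 1e-9)
  expect_gt(cells$membrane_texture, 5)
})

test_that("planted lobe counts 1 through 5 are recovered exactly", {
  for (n in 1:5) {
    fx <- render_adhesion_scene(
      list(list(shape = "disk", center = c(30, 30), r = 16,
                intensity = 150,
                lobes = list(n = n, sep_px = 12, sigma = 2.5,
                             intensity = 220))),
      frame_dim = c(64, 64), um_per_px = 1, seed = n)
    cells <- measure_fluorescent_cells(fx$stack, "membrane", 50,
                                       lobe_channel = "lobes",
                                       lobe_threshold = 50,
                                       min_peak_sep_px = 8, um_per_px = 1)
    expect_equal(cells$lobe_count, n)
  }
})

test_that("star protrusion counts 3 through 8 are recovered exactly", {
  for (k in 3:8) {
    fx <- render_adhesion_scene(
      list(list(shape = "star", center = c(30, 30), k = k, r_outer = 14,
                r_inner = 6, intensity = 170,
                tip_angles = 2 * pi * (seq_len(k) - 1) / k + 0.2)),
      frame_dim = c(60, 60), um_per_px = 1, seed = k)
    mem <- fx$stack$frames[[1]][, , 1]
    pr <- count_protrusions(mem > 50, corner_sharpness = 0.2,
                            min_separation_px = 6, um_per_px = 1)
    expect_equal(pr$protrusion_count, k)
    # each measured tip lies near a distinct planted tip
    tr <- fx$truth$tips
    m <- match_detections(data.frame(x = pr$tips$x, y = pr$tips$y),
                          tr, tol = 2.5)
    expect_equal(m$recall, 1)
    expect_true(pr$dist_min_um <= pr$dist_mean_um &&
                  pr$dist_mean_um <= pr$dist_max_um)
  }
})

test_that("tips closer than the separation rule merge; disks count zero", {
  ta <- c(0, 4 / 14, 2 * pi * 2 / 5, 2 * pi * 3 / 5, 2 * pi * 4 / 5)
  fx <- render_adhesion_scene(
    list(list(shape = "star", center = c(30, 30), k = 5, r_outer = 14,
              r_inner = 6, intensity = 170, tip_angles = ta)),
    frame_dim = c(60, 60), um_per_px = 1, seed = 1)
  mem <- fx$stack$frames[[1]][, , 1]
  merged <- count_protrusions(mem > 50, 0.2, min_separation_px = 6)
  # against the evenly spaced reference star, the two 4-px tips collapse
  # into one: the count drops by exactly one
  ref <- render_adhesion_scene(
    list(list(shape = "star", center = c(30, 30), k = 5, r_outer = 14,
              r_inner = 6, intensity = 170)),
    frame_dim = c(60, 60), um_per_px = 1, seed = 1)
  ref_n <- count_protrusions(ref$stack$frames[[1]][, , 1] > 50, 0.2,
                             min_separation_px = 6)$protrusion_count
  expect_equal(merged$protrusion_count, ref_n - 1L)
  disk <- disk_image(50, 50, 25, 25, 12) > 0
  expect_equal(count_protrusions(disk, 0.2, 6)$protrusion_count, 0L)
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_equal(count_protrusions(tiny, 0.2, 6)$protrusion_count, 0L)
})

test_that("area grows strictly under dilation of the planted shape", {
  a1 <- measure_fluorescent_cells(
    render_adhesion_scene(list(list(shape = "disk", center = c(25, 25),
                                    r = 8, intensity = 150)),
                          frame_dim = c(50, 50))$stack,
    "membrane", 50, um_per_px = 1)$area_px2
  a2 <- measure_fluorescent_cells(
    render_adhesion_scene(list(list(shape = "disk", center = c(25, 25),
                                    r = 10, intensity = 150)),
                          frame_dim = c(50, 50))$stack,
    "membrane", 50, um_per_px = 1)$area_px2
  expect_gt(a2, a1)
})

test_that("raising the membrane threshold never grows regions or counts", {
  # graded-intensity fixture: Gaussian-profile cells have nested
  # super-threshold masks
  m <- matrix(0, 60, 90)
  m <- microflowq:::render_gaussian_spot(m, 20, 30, 5, 220)
  m <- microflowq:::render_gaussian_spot(m, 60, 30, 4, 160)
  arr <- array(0, c(60, 90, 3)); arr[, , 1] <- m
  st <- frame_stack(list(arr))
  prev_area <- Inf; prev_n <- Inf
  for (thr in c(40, 80, 120, 150, 190)) {
    cells <- measure_fluorescent_cells(st, 1, thr, um_per_px = 1)
    tot <- if (nrow(cells)) sum(cells$area_px2) else 0
    expect_lte(tot, prev_area)
    expect_lte(nrow(cells), prev_n)
    prev_area <- tot; prev_n <- nrow(cells)
  }
})

test_that("transient adhesion times follow the frame-span arithmetic", {
  # one cell present frames 10..34 inclusive at 25 fps -> 1.0 s
  h <- 40; w <- 40
  frames <- lapply(1:40, function(t) {
    m <- matrix(0, h, w)
    if (t >= 10 && t <= 34) {
      m <- microflowq:::render_gaussian_spot(m, 20, 20, 2, 200)
    }
    m
  })
  st <- frame_stack(frames, fps = 25, um_per_px = 1)
  rec <- measure_transient_adhesion(st, 9, min_mass = 10, min_frames = 3)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$adhesion_time_s, 1.0)
  # all reported times are exact multiples of 1/fps
  expect_equal(rec$adhesion_time_s * 25, round(rec$adhesion_time_s * 25))
  expect_error(
    measure_transient_adhesion(frame_stack(frames), 9, min_mass = 10),
    "fps")
})

test_that("debris and short-lived objects are excluded", {
  h <- 60; w <- 120
  set.seed(31)
  xs <- seq(15, 105, length.out = 6); ys <- rep(c(15, 45), 3)
  frames <- lapply(1:12, function(t) {
    m <- matrix(0, h, w)
    for (i in 1:5) {   # five real cells, present throughout
      m <- microflowq:::render_gaussian_spot(m, xs[i], ys[i], 2, 180)
    }
    # one very bright debris particle
    m <- microflowq:::render_gaussian_spot(m, xs[6], ys[6], 2, 2000)
    # one flicker present just 2 frames
    if (t <= 2) m <- microflowq:::render_gaussian_spot(m, 60, 30, 2, 180)
    m
  })
  st <- frame_stack(frames, fps = 25, um_per_px = 1)
  debris_mass <- detect_particles(frames[[1]], 9, min_mass = 10)
  big <- max(debris_mass$mass)
  rec <- measure_transient_adhesion(st, 9, min_mass = 10,
                                    max_intensity = big * 0.5,
                                    min_frames = 3)
  expect_equal(nrow(rec), 5L)
  expect_true(all(rec$adhesion_time_s == 12 / 25))
})
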