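# One full-stencil reference frame (device stain in blue) lets map
# inference recover the complete geometry in several tests below.

test_that("binarization is strictly-greater-than per plane", {
  arr <- array(0, c(10, 10, 3))
  arr[, , 1] <- matrix(c(rep(50, 25), rep(150, 75)), 10, 10)
  st <- frame_stack(list(arr))
  ms <- binarize_channels(st, c(red = 100))
  expect_equal(sum(ms$masks[[1]]$red), 75L)
  expect_equal(sum(binarize_channels(st, c(red = 200))$masks[[1]]$red), 0L)
  # threshold 0 marks every nonzero pixel
  expect_equal(sum(binarize_channels(st, c(red = 0))$masks[[1]]$red), 100L)
  expect_error(binarize_channels(st, c(100)), "named")
})

test_that("planted coverage is measured exactly after binarization", {
  st <- comb_stencil(4)
  fx <- render_occlusion_series(st, list(red = c(0.25)), seed = 3)
  ms <- binarize_channels(fx$stack, c(red = 100))
  expect_equal(sum(ms$masks[[1]]$red), round(0.25 * sum(st)))
})

test_that("device map is the count-thresholded union across everything", {
  arr1 <- array(0, c(8, 8, 3)); arr1[1:4, , 1] <- 200
  arr2 <- array(0, c(8, 8, 3)); arr2[3:8, , 1] <- 200
  st <- frame_stack(list(arr1, arr2))
  ms <- binarize_channels(st, c(red = 100))
  dm1 <- build_device_map(ms, map_threshold = 1)
  expect_equal(sum(dm1$mask), 8L * 8L)       # union
  dm2 <- build_device_map(ms, map_threshold = 2)
  expect_equal(sum(dm2$mask), 2L * 8L)       # intersection rows 3:4
  # single mask with threshold 1 is the identity
  stm <- frame_stack(list(arr1))
  expect_equal(build_device_map(binarize_channels(stm, c(red = 100)))$mask,
               arr1[, , 1] > 100)
  arr0 <- array(0, c(8, 8, 3))
  expect_error(build_device_map(
    binarize_channels(frame_stack(list(arr0)), c(red = 100))),
    "no device signal")
})

test_that("partial per-frame coverage still recovers the full stencil", {
  sten <- y_stencil()
  fx <- render_occlusion_series(sten, list(red = rep(0.4, 10)),
                                nested = FALSE, seed = 9)
  dm <- build_device_map(binarize_channels(fx$stack, c(red = 100)))
  expect_identical(dm$mask, sten == 1L)
})

test_that("map never shrinks as timepoints are appended", {
  sten <- y_stencil()
  fx <- render_occlusion_series(sten, list(red = seq(0.1, 0.5, 0.1)),
                                seed = 2)
  prev <- 0L
  for (t in 1:5) {
    sub <- frame_stack(fx$stack$frames[1:t])
    ms <- binarize_channels(sub, c(red = 100))
    area <- sum(build_device_map(ms)$mask)
    expect_gte(area, prev)
    prev <- area
  }
})

test_that("microchannel detection finds channels and constant walls", {
  arr <- array(0, c(30, 40, 3)); arr[10:20, 5:35, 1] <- 200
  dm <- build_device_map(binarize_channels(frame_stack(list(arr)),
                                           c(red = 100)))
  dm <- detect_microchannels(dm)
  expect_equal(length(dm$channels), 1L)
  ch <- dm$channels[[1]]
  expect_equal(ch$x0, 4L); expect_equal(ch$x1, 34L)
  expect_true(all(ch$y_top == 9))
  expect_true(all(ch$y_bottom == 19))
  # 32-channel comb
  sten <- comb_stencil(32)
  fx <- render_occlusion_series(sten, list(red = c(1)), seed = 1)
  dm32 <- detect_microchannels(build_device_map(
    binarize_channels(fx$stack, c(red = 100))))
  expect_equal(length(dm32$channels), 32L)
})

test_that("ragged walls are smoothed to within 1 px of the stencil", {
  sten <- comb_stencil(2, ragged = TRUE)
  fx <- render_occlusion_series(sten, list(red = c(1)), seed = 1)
  dm <- detect_microchannels(build_device_map(
    binarize_channels(fx$stack, c(red = 100))))
  # nominal (unragged) walls of channel 1: rows 4 and 9 (0-based)
  ch <- dm$channels[[1]]
  expect_true(all(abs(ch$y_top - 4) <= 1))
  expect_true(all(abs(ch$y_bottom - 9) <= 1))
})

test_that("occlusion percentages and accumulation rates are exact", {
  sten <- comb_stencil(4)
  fx <- render_occlusion_series(sten, list(red = c(0, 0.25, 0.5)),
                                device_stain = TRUE, seed = 4)
  dm <- build_device_map(binarize_channels(fx$stack,
                                           c(red = 100, blue = 100)))
  ms <- binarize_channels(fx$stack, c(red = 100))
  oc <- compute_occlusion_accumulation(ms, dm, timestamps_min = 0:2,
                                       um_per_px = 0.5)
  expect_equal(oc$series$occlusion_pct, c(0, 25, 50))
  n_px <- sum(sten)
  expect_equal(oc$series$accumulation_um2[-1],
               c(0.25, 0.25) * n_px * 0.25)
  # growth of 100 px^2 per 1-min step at 0.5 um/px is 25 um^2/min
  sched <- c(0, 100, 200) / n_px
  fx2 <- render_occlusion_series(sten, list(red = sched),
                                 device_stain = TRUE, seed = 5)
  dm2 <- build_device_map(binarize_channels(fx2$stack,
                                            c(red = 100, blue = 100)))
  oc2 <- compute_occlusion_accumulation(
    binarize_channels(fx2$stack, c(red = 100)), dm2,
    timestamps_min = 0:2, um_per_px = 0.5)
  expect_equal(oc2$rates$rate_um2_min, 25)
  # constant signal: zero accumulation, zero rate
  fx3 <- render_occlusion_series(sten, list(red = c(0.3, 0.3, 0.3)),
                                 seed = 6)
  oc3 <- compute_occlusion_accumulation(
    binarize_channels(fx3$stack, c(red = 100)),
    build_device_map(binarize_channels(fx3$stack, c(red = 100))),
    timestamps_min = 0:2)
  expect_equal(oc3$series$accumulation_um2[-1], c(0, 0))
  expect_equal(oc3$rates$rate_um2_min, 0)
  expect_error(compute_occlusion_accumulation(
    binarize_channels(fx3$stack, c(red = 100)),
    build_device_map(binarize_channels(fx3$stack, c(red = 100))),
    timestamps_min = c(0, 0, 1)), "increasing")
})

test_that("occlusion is bounded and saturates exactly at full coverage", {
  sten <- comb_stencil(2)
  for (f in c(0, 0.37, 1)) {
    fx <- render_occlusion_series(sten, list(red = c(f)),
                                  device_stain = TRUE, seed = 8)
    dm <- build_device_map(binarize_channels(fx$stack,
                                             c(red = 100, blue = 100)))
    oc <- compute_occlusion_accumulation(
      binarize_channels(fx$stack, c(red = 100)), dm, 0)
    expect_gte(oc$series$occlusion_pct, 0)
    expect_lte(oc$series$occlusion_pct, 100)
    if (f == 1) expect_equal(oc$series$occlusion_pct, 100)
  }
})

test_that("spatial occlusion resolves a planted distal step profile", {
  sten <- comb_stencil(3)
  fx <- render_occlusion_series(sten, list(red = c(0.5)),
                                device_stain = TRUE, fill_order = "right",
                                seed = 2)
  dm <- detect_microchannels(build_device_map(
    binarize_channels(fx$stack, c(red = 100, blue = 100))))
  mask <- binarize_channels(fx$stack, c(red = 100))$masks[[1]]$red
  so <- spatial_occlusion(mask, dm$channels[[2]])
  # distal (large-x) half fully occluded, proximal half empty
  n <- nrow(so)
  boundary <- so$x_rel[min(which(so$occlusion_pct > 50))]
  expect_lt(abs(boundary - n / 2), 1.5)
  expect_true(all(so$occlusion_pct[so$x_rel < boundary - 1] == 0))
  expect_true(all(so$occlusion_pct[so$x_rel > boundary + 1] == 100))
})

test_that("span-weighted mean of per-x occlusion equals the channel total", {
  sten <- comb_stencil(2)
  fx <- render_occlusion_series(sten, list(red = c(0.4)),
                                device_stain = TRUE, seed = 11)
  dm <- detect_microchannels(build_device_map(
    binarize_channels(fx$stack, c(red = 100, blue = 100))))
  ms <- binarize_channels(fx$stack, c(red = 100))
  for (i in seq_along(dm$channels)) {
    so <- spatial_occlusion(ms$masks[[1]]$red, dm$channels[[i]])
    oc <- compute_occlusion_accumulation(ms, dm, 0, channel = i)
    weighted <- sum(so$occlusion_pct * so$span_px) / sum(so$span_px)
    expect_equal(weighted, oc$series$occlusion_pct, tolerance = 1e-12)
  }
})

test_that("occlusion curves for nearby thresholds never cross", {
  # graded-intensity growth: later-arriving signal is dimmer, so a higher
  # threshold sees a subset at every timepoint
  sten <- comb_stencil(2)
  inside <- which(sten != 0, arr.ind = TRUE)
  set.seed(3)
  ord <- sample.int(nrow(inside))
  n <- nrow(inside)
  fracs <- c(0.2, 0.5, 0.8)
  frames <- lapply(fracs, function(f) {
    arr <- array(0, c(dim(sten), 3))
    k <- round(f * n)
    sel <- inside[ord[seq_len(k)], , drop = FALSE]
    plane <- matrix(0, dim(sten)[1], dim(sten)[2])
    plane[sel] <- 220 - 100 * (seq_len(k) / n)   # graded intensity
    arr[, , 1] <- plane
    arr
  })
  st <- frame_stack(frames)
  dm <- build_device_map(binarize_channels(st, c(red = 60)))
  occ_at <- function(thr) {
    compute_occlusion_accumulation(binarize_channels(st, c(red = thr)),
                                   dm, 0:2)$series$occlusion_pct
  }
  o1 <- occ_at(120); o2 <- occ_at(140)
  expect_true(all(o1 >= o2))
  expect_true(all(diff(o1) >= 0) && all(diff(o2) >= 0))
})
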