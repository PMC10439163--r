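# Synthetic-microscopy fixture generators.
#
# Each generator renders a ground-truthed scene for one analysis workflow:
# moving Gaussian-blob cells for tracking, adherent cells with controllable
# morphology for adhesion scoring, advected speckle texture for optical-flow
# velocimetry, and growing multi-channel signal inside a device stencil for
# occlusion quantification. Truth quantities are computed analytically or by
# exhaustive rasterization at render time, never by the analysis modules, so
# they can serve as independent oracles. All generators are deterministic
# under a fixed seed. Sub-pixel motion is rendered by evaluating profiles at
# continuous positions; no nearest-pixel snapping. Noise is additive
# Gaussian, clipped at zero.

add_noise <- function(m, noise_sd) {
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  pmax(m, 0)
}

# Add a 2-D Gaussian spot at continuous (cx, cy) into matrix m (in place
# semantics via return). Rendered over a +/- 4 sigma window.
render_gaussian_spot <- function(m, cx, cy, sigma, amplitude) {
  nr <- nrow(m); nc <- ncol(m)
  r <- ceiling(4 * sigma)
  xs <- max(0, floor(cx) - r):min(nc - 1, ceiling(cx) + r)
  ys <- max(0, floor(cy) - r):min(nr - 1, ceiling(cy) + r)
  if (length(xs) == 0L || length(ys) == 0L) return(m)
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  m[ys + 1, xs + 1] <- m[ys + 1, xs + 1] +
    amplitude * exp(-(dx2 + dy2) / (2 * sigma^2))
  m
}

#' Render moving Gaussian-blob cells in a channel
#'
#' Cells are 2-D Gaussian spots translating in +x at prescribed speeds, each
#' on its own streamline so that pairwise separation always exceeds
#' `4 * blob_sigma_px`. Returns the rendered stack together with a truth
#' table of per-frame centroids and per-cell speeds.
#'
#' @param n_cells number of cells.
#' @param velocity_um_s speed in micrometers per second; scalar (all cells)
#'   or one value per cell.
#' @param blob_sigma_px Gaussian sigma of the rendered spot, pixels.
#' @param amplitude peak spot intensity, arbitrary units.
#' @param noise_sd additive Gaussian noise s.d. (clipped at 0).
#' @param n_frames,fps,um_per_px acquisition geometry; displacement per frame
#'   is `velocity_um_s / um_per_px / fps` pixels.
#' @param seed random seed; renders are bit-identical for a fixed seed.
#' @param frame_dim optional `c(height, width)`; sized automatically to
#'   contain all trajectories when omitted.
#' @param background optional static scalar or matrix added to every frame
#'   (e.g. a channel-wall pattern for background-subtraction tests).
#' @return A list with elements `stack` ([frame_stack]) and `truth`
#'   (list with `cells` and per-frame `positions` data frames).
#' @export
render_moving_cells <- function(n_cells, velocity_um_s, blob_sigma_px = 2,
                                amplitude = 200, noise_sd = 0,
                                n_frames = 50, fps = 25, um_per_px = 1,
                                seed = 1, frame_dim = NULL,
                                background = NULL) {
  set.seed(seed)
  v <- rep_len(velocity_um_s, n_cells)
  v_px <- v / um_per_px / fps
  sep <- 4 * blob_sigma_px
  margin <- ceiling(4 * blob_sigma_px) + 2
  if (is.null(frame_dim)) {
    h <- ceiling(2 * margin + (n_cells - 1) * (sep + 2))
    w <- ceiling(2 * margin + 20 + max(v_px) * (n_frames - 1))
    frame_dim <- c(h, w)
  }
  h <- frame_dim[1]; w <- frame_dim[2]
  ys <- margin + seq(0, by = sep + 2, length.out = n_cells)
  if (max(ys) > h - margin) {
    stop("overcrowded fixture: ", n_cells, " cells at separation > ",
         sep, " px do not fit in a ", h, "-px-tall frame")
  }
  x0 <- margin + stats::runif(n_cells, 0, 20)
  if (max(x0 + v_px * (n_frames - 1)) > w - margin) {
    stop("fixture frame too narrow for the requested speeds")
  }
  bg <- if (is.null(background)) 0 else background
  frames <- vector("list", n_frames)
  pos <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    m <- matrix(0, h, w) + bg
    cx <- x0 + v_px * (t - 1)
    for (i in seq_len(n_cells)) {
      m <- render_gaussian_spot(m, cx[i], ys[i], blob_sigma_px, amplitude)
    }
    frames[[t]] <- add_noise(m, noise_sd)
    pos[[t]] <- data.frame(cell_id = seq_len(n_cells), frame = t,
                           x = cx, y = ys)
  }
  list(
    stack = frame_stack(frames, fps = fps, um_per_px = um_per_px),
    truth = list(
      cells = data.frame(cell_id = seq_len(n_cells), velocity_um_s = v,
                         sigma_px = blob_sigma_px, amplitude = amplitude,
                         y = ys, x0 = x0),
      positions = do.call(rbind, pos)
    )
  )
}

# Even-odd point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Rasterize one adhesion-cell spec into a logical mask over the full frame.
# Returns list(mask, tips = data.frame(x, y) for stars).
rasterize_shape <- function(spec, h, w) {
  cx <- spec$center[1]; cy <- spec$center[2]
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  dx <- outer(rep(1, h), xs - cx)
  dy <- outer(ys - cy, rep(1, w))
  tips <- NULL
  if (spec$shape == "disk") {
    mask <- dx^2 + dy^2 <= spec$r^2
  } else if (spec$shape == "ellipse") {
    th <- if (is.null(spec$angle)) 0 else spec$angle
    u <- dx * cos(th) + dy * sin(th)
    vv <- -dx * sin(th) + dy * cos(th)
    mask <- (u / spec$a)^2 + (vv / spec$b)^2 <= 1
  } else if (spec$shape == "star") {
    k <- spec$k
    tip_angles <- if (is.null(spec$tip_angles)) {
      2 * pi * (seq_len(k) - 1) / k
    } else spec$tip_angles
    if (length(tip_angles) != k) stop("need one tip angle per star point")
    tip_angles <- sort(tip_angles %% (2 * pi))
    # alternating tip / valley vertices; valleys at angular midpoints
    next_a <- c(tip_angles[-1], tip_angles[1] + 2 * pi)
    valley_angles <- (tip_angles + next_a) / 2
    ang <- as.vector(rbind(tip_angles, valley_angles))
    rad <- rep(c(spec$r_outer, spec$r_inner), k)
    vx <- cx + rad * cos(ang); vy <- cy + rad * sin(ang)
    mask <- matrix(point_in_polygon(as.vector(dx) + cx, as.vector(dy) + cy,
                                    vx, vy), h, w)
    tips <- data.frame(x = cx + spec$r_outer * cos(tip_angles),
                       y = cy + spec$r_outer * sin(tip_angles))
  } else {
    stop("unknown shape: ", spec$shape)
  }
  list(mask = mask, tips = tips)
}

shape_bound_radius <- function(spec) {
  switch(spec$shape,
         disk = spec$r,
         ellipse = max(spec$a, spec$b),
         star = spec$r_outer)
}

#' Render an adhered-cell scene with membrane, secondary, and lobe stains
#'
#' Produces a single 3-plane frame (planes tagged `membrane`, `secondary`,
#' `lobes`) plus analytic ground truth per cell: rasterized pixel area,
#' moment eccentricity of the rendered mask, protrusion count and tip
#' positions for stars, lobe count and positions, and summed secondary
#' stain.
#'
#' @param cell_specs list of per-cell specs. Each spec is a list with
#'   `shape` (`"disk"`, `"ellipse"`, `"star"`), `center = c(x, y)` (0-based
#'   px), shape parameters (`r`; `a`, `b`, `angle`; `k`, `r_outer`,
#'   `r_inner`, optional `tip_angles`), membrane `intensity`, optional
#'   `membrane_texture_sd`, optional `secondary = list(intensity, r)`, and
#'   optional `lobes = list(n, sep_px, sigma, intensity)`.
#' @param frame_dim `c(height, width)` pixels.
#' @param noise_sd additive Gaussian noise s.d. applied to every plane.
#' @param um_per_px calibration attached to the stack.
#' @param seed random seed.
#' @return list(stack, truth); `truth$cells` has one row per spec.
#' @export
render_adhesion_scene <- function(cell_specs, frame_dim = c(128, 128),
                                  noise_sd = 0, um_per_px = 0.5, seed = 1) {
  set.seed(seed)
  h <- frame_dim[1]; w <- frame_dim[2]
  centers <- t(vapply(cell_specs, function(s) s$center, numeric(2)))
  radii <- vapply(cell_specs, shape_bound_radius, numeric(1))
  n <- length(cell_specs)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (d <= radii[i] + radii[j]) {
        stop("cells ", i, " and ", j, " overlap; adhesion fixtures require ",
             "non-overlapping shapes")
      }
    }
  }
  membrane <- matrix(0, h, w)
  secondary <- matrix(0, h, w)
  lobes_plane <- matrix(0, h, w)
  rows <- vector("list", n)
  lobe_pos <- vector("list", n)
  for (i in seq_len(n)) {
    s <- cell_specs[[i]]
    ras <- rasterize_shape(s, h, w)
    mask <- ras$mask
    vals <- rep(s$intensity, sum(mask))
    if (!is.null(s$membrane_texture_sd) && s$membrane_texture_sd > 0) {
      vals <- pmax(vals + stats::rnorm(length(vals), 0,
                                       s$membrane_texture_sd), 1)
    }
    membrane[mask] <- vals
    sec_sum <- 0
    if (!is.null(s$secondary)) {
      sdx <- outer(rep(1, h), (0:(w - 1)) - s$center[1])
      sdy <- outer((0:(h - 1)) - s$center[2], rep(1, w))
      smask <- (sdx^2 + sdy^2 <= s$secondary$r^2) & mask
      secondary[smask] <- s$secondary$intensity
      sec_sum <- s$secondary$intensity * sum(smask)
    }
    lobe_n <- 0L
    if (!is.null(s$lobes)) {
      lb <- s$lobes
      lobe_n <- as.integer(lb$n)
      if (lobe_n == 1L) {
        lx <- s$center[1]; ly <- s$center[2]
      } else {
        ring_r <- lb$sep_px / (2 * sin(pi / lobe_n))
        ang <- 2 * pi * (seq_len(lobe_n) - 1) / lobe_n
        lx <- s$center[1] + ring_r * cos(ang)
        ly <- s$center[2] + ring_r * sin(ang)
      }
      for (q in seq_len(lobe_n)) {
        lobes_plane <- render_gaussian_spot(lobes_plane, lx[q], ly[q],
                                            lb$sigma, lb$intensity)
      }
      lobe_pos[[i]] <- data.frame(cell_id = i, x = lx, y = ly)
    }
    pix <- which(mask, arr.ind = TRUE)
    xs <- pix[, 2L] - 1; ys <- pix[, 1L] - 1
    rows[[i]] <- data.frame(
      cell_id = i,
      shape = s$shape,
      x = mean(xs), y = mean(ys),
      area_px = sum(mask),
      area_um2 = sum(mask) * um_per_px^2,
      eccentricity = moment_eccentricity(xs, ys),
      protrusion_count = if (s$shape == "star") s$k else 0L,
      lobe_count = lobe_n,
      secondary_sum = sec_sum,
      membrane_intensity = s$intensity
    )
  }
  planes <- array(0, c(h, w, 3))
  planes[, , 1] <- add_noise(membrane, noise_sd)
  planes[, , 2] <- add_noise(secondary, noise_sd)
  planes[, , 3] <- add_noise(lobes_plane, noise_sd)
  tips <- lapply(seq_len(n), function(i) {
    ras <- rasterize_shape(cell_specs[[i]], h, w)
    if (is.null(ras$tips)) return(NULL)
    cbind(cell_id = i, ras$tips)
  })
  list(
    stack = frame_stack(list(planes), um_per_px = um_per_px,
                        channel_tags = c("1" = "membrane", "2" = "secondary",
                                         "3" = "lobes")),
    truth = list(
      cells = do.call(rbind, rows),
      tips = do.call(rbind, tips[!vapply(tips, is.null, logical(1))]),
      lobes = do.call(rbind, lobe_pos[!vapply(lobe_pos, is.null,
                                              logical(1))])
    )
  )
}

#' Render texture-rich suspension flow with a prescribed velocity profile
#'
#' Speckle texture (random Gaussian grains) is advected horizontally, each
#' grain at the speed given by the profile function evaluated at its own
#' distance from the channel centerline. Grain positions wrap around the
#' frame width.
#'
#' @param profile_fn function of signed distance from the channel center in
#'   micrometers, returning velocity in micrometers per second.
#' @param frame_dim `c(height, width)`; the channel spans the full height.
#' @param texture_density grains per pixel of frame area.
#' @param n_frames,fps,um_per_px acquisition geometry.
#' @param noise_sd additive Gaussian noise s.d.
#' @param speed_scale optional per-step multiplier (length `n_frames - 1`)
#'   applied to all grain displacements, e.g. a ramp toward stasis.
#' @param seed random seed.
#' @return list(stack, truth); truth stores the profile function, the
#'   channel span, per-grain rows, and the per-step scale.
#' @export
render_suspension_flow <- function(profile_fn, frame_dim = c(64, 128),
                                   texture_density = 0.02, n_frames = 20,
                                   fps = 100, um_per_px = 0.5,
                                   noise_sd = 0, speed_scale = NULL,
                                   seed = 1) {
  set.seed(seed)
  h <- frame_dim[1]; w <- frame_dim[2]
  if (is.null(speed_scale)) speed_scale <- rep(1, n_frames - 1)
  if (length(speed_scale) != n_frames - 1) {
    stop("`speed_scale` needs one value per frame step")
  }
  n_grain <- max(10L, round(texture_density * h * w))
  gx <- stats::runif(n_grain, 0, w - 1)
  gy <- stats::runif(n_grain, 0, h - 1)
  amp <- stats::runif(n_grain, 80, 220)
  sig <- stats::runif(n_grain, 1.0, 1.6)
  center <- (h - 1) / 2
  v_um <- vapply((gy - center) * um_per_px, profile_fn, numeric(1))
  v_px <- v_um / um_per_px / fps
  if (max(abs(v_px)) >= w) {
    stop("per-frame displacement exceeds the frame width")
  }
  frames <- vector("list", n_frames)
  x <- gx
  for (t in seq_len(n_frames)) {
    m <- matrix(0, h, w)
    for (i in seq_len(n_grain)) {
      m <- render_gaussian_spot(m, x[i] %% w, gy[i], sig[i], amp[i])
    }
    frames[[t]] <- add_noise(m, noise_sd)
    if (t < n_frames) x <- x + v_px * speed_scale[t]
  }
  list(
    stack = frame_stack(frames, fps = fps, um_per_px = um_per_px),
    truth = list(
      profile_fn = profile_fn,
      channel_span = c(0, h - 1),
      center_px = center,
      grains = data.frame(grain_id = seq_len(n_grain), x0 = gx, y = gy,
                          velocity_um_s = v_um, v_px_per_frame = v_px),
      speed_scale = speed_scale
    )
  )
}

#' Comb stencil: parallel straight microchannels
#'
#' @param n_channels number of parallel channels.
#' @param channel_height,channel_length channel size in pixels.
#' @param gap vertical gap between channels, pixels.
#' @param margin border margin, pixels.
#' @param ragged add +/-1 px wall raggedness (deterministic pattern) for
#'   wall-smoothing tests.
#' @return binary matrix (1 = device region) with attribute `n_channels`.
#' @export
comb_stencil <- function(n_channels = 32, channel_height = 6,
                         channel_length = 40, gap = 4, margin = 4,
                         ragged = FALSE) {
  h <- 2 * margin + n_channels * channel_height + (n_channels - 1) * gap
  w <- 2 * margin + channel_length
  m <- matrix(0L, h, w)
  for (i in seq_len(n_channels)) {
    y0 <- margin + (i - 1) * (channel_height + gap)
    rows <- (y0 + 1):(y0 + channel_height)
    cols <- (margin + 1):(margin + channel_length)
    m[rows, cols] <- 1L
    if (ragged) {
      # alternate columns gain one pixel above/below the nominal walls
      up <- cols[seq(1, length(cols), by = 2)]
      dn <- cols[seq(2, length(cols), by = 2)]
      m[y0, up] <- 1L
      m[y0 + channel_height + 1, dn] <- 1L
    }
  }
  attr(m, "n_channels") <- n_channels
  m
}

#' Y-junction stencil for device-map inference tests
#'
#' @param size `c(height, width)` of the stencil.
#' @param arm_width width of each arm in pixels.
#' @return binary matrix (1 = device region).
#' @export
y_stencil <- function(size = c(80, 80), arm_width = 8) {
  h <- size[1]; w <- size[2]
  m <- matrix(0L, h, w)
  half <- arm_width %/% 2
  cx <- w %/% 2
  # stem: vertical from bottom to middle
  m[(h %/% 2):(h - 4), (cx - half):(cx + half)] <- 1L
  # arms: diagonals from middle to top corners
  for (t in seq(0, 1, length.out = 2 * h)) {
    y <- round(h / 2 - t * (h / 2 - 4))
    x1 <- round(cx - t * (cx - 6)); x2 <- round(cx + t * (w - 6 - cx))
    for (x in c(x1, x2)) {
      rows <- max(1, y - half):min(h, y + half)
      cols <- max(1, x - half):min(w, x + half)
      m[rows, cols] <- 1L
    }
  }
  m
}

#' Render a multi-channel occlusion/accumulation time series
#'
#' Signal grows inside a binary device stencil following a per-channel
#' schedule of signal-area fractions. Growth is nested over time (the mask
#' at a later timepoint contains all earlier signal) and constrained to the
#' stencil, so planted occlusion percentages are exact by construction.
#'
#' @param stencil binary device mask, e.g. from [comb_stencil()].
#' @param growth_schedule named list of numeric vectors in `[0, 1]`, one per
#'   color plane (`red`, `green`, `blue`), all the same length (number of
#'   timepoints).
#' @param intensity rendered signal intensity, arbitrary units.
#' @param noise_sd additive Gaussian noise s.d.
#' @param fill_order `"random"` (seeded), `"left"` (fill from smallest x) or
#'   `"right"` (fill from largest x, emulating distal occlusion).
#' @param nested when `TRUE` (default) signal grows cumulatively (the mask
#'   at a later timepoint contains all earlier signal); when `FALSE` each
#'   timepoint covers its own block of a fixed random pixel cycle, so
#'   repeated partial coverage tiles the whole stencil once the cumulative
#'   fraction reaches 1.
#' @param device_stain render a stain delineating the full device (e.g. an
#'   endothelial membrane stain) into the blue plane at every timepoint, so
#'   map inference recovers the complete geometry; the blue plane is then
#'   reserved and may not appear in `growth_schedule`.
#' @param seed random seed.
#' @return list(stack, truth); truth has per-timepoint per-plane true signal
#'   areas and fractions plus the stencil.
#' @export
render_occlusion_series <- function(stencil, growth_schedule,
                                    intensity = 200, noise_sd = 0,
                                    fill_order = c("random", "left",
                                                   "right"),
                                    nested = TRUE, device_stain = FALSE,
                                    seed = 1) {
  fill_order <- match.arg(fill_order)
  set.seed(seed)
  if (device_stain && "blue" %in% names(growth_schedule)) {
    stop("the blue plane is reserved for the device stain")
  }
  plane_idx <- c(red = 1L, green = 2L, blue = 3L)
  if (is.null(names(growth_schedule)) ||
      !all(names(growth_schedule) %in% names(plane_idx))) {
    stop("`growth_schedule` must be a named list over red/green/blue")
  }
  lens <- vapply(growth_schedule, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all growth schedules must have the same number of timepoints")
  }
  if (any(unlist(growth_schedule) < 0 | unlist(growth_schedule) > 1)) {
    stop("growth fractions must lie in [0, 1]")
  }
  n_t <- lens[[1L]]
  inside <- which(stencil != 0, arr.ind = TRUE)
  n_in <- nrow(inside)
  if (n_in == 0L) stop("stencil has no device pixels")
  h <- nrow(stencil); w <- ncol(stencil)
  orders <- lapply(names(growth_schedule), function(nm) {
    switch(fill_order,
           random = sample.int(n_in),
           left = order(inside[, 2L], stats::runif(n_in)),
           right = order(-inside[, 2L], stats::runif(n_in)))
  })
  names(orders) <- names(growth_schedule)
  frames <- vector("list", n_t)
  rows <- list()
  cum_start <- stats::setNames(rep(0, length(growth_schedule)),
                               names(growth_schedule))
  for (t in seq_len(n_t)) {
    arr <- array(0, c(h, w, 3))
    for (nm in names(growth_schedule)) {
      f <- growth_schedule[[nm]][t]
      k <- round(f * n_in)
      p <- plane_idx[[nm]]
      plane <- matrix(0, h, w)
      if (k > 0) {
        if (nested) {
          pick <- seq_len(k)
        } else {
          pick <- ((cum_start[[nm]] + seq_len(k) - 1L) %% n_in) + 1L
          cum_start[[nm]] <- cum_start[[nm]] + k
        }
        sel <- inside[orders[[nm]][pick], , drop = FALSE]
        plane[sel] <- intensity
      }
      arr[, , p] <- add_noise(plane, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = t, channel = nm, area_px = k,
        fraction = k / n_in, occlusion_pct = 100 * k / n_in
      )
    }
    if (device_stain) {
      dev <- matrix(0, h, w)
      dev[inside] <- intensity
      arr[, , 3] <- add_noise(dev, noise_sd)
    }
    frames[[t]] <- arr
  }
  list(
    stack = frame_stack(frames),
    truth = list(
      stencil = stencil,
      device_area_px = n_in,
      n_channels = attr(stencil, "n_channels"),
      schedule = do.call(rbind, rows)
    )
  )
}

#' Persist a fixture as a TIFF sequence plus truth CSV
#'
#' @param fixture a list(stack, truth) from any `render_*` generator.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_stack(fixture$stack, dir, as_sequence = TRUE)
  for (nm in names(fixture$truth)) {
    obj <- fixture$truth[[nm]]
    if (is.data.frame(obj)) {
      utils::write.csv(obj, file.path(dir, paste0("truth_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
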