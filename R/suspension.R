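# Suspension velocimetry: Shi-Tomasi corner seeding, pyramidal
# Kanade-Lucas-Tomasi optical flow, per-frame velocity statistics, and
# spatial velocity profiles across the channel.

# Shi-Tomasi corner detection: minimum eigenvalue of the local structure
# tensor, thresholded at quality * max response, greedy minimum-separation
# suppression. Returns data.frame(x, y, response), 0-based coordinates.
shi_tomasi_corners <- function(frame, max_features = 200, quality = 0.05,
                               min_sep = 5, block = 5) {
  nr <- nrow(frame); nc <- ncol(frame)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (frame[, 3:nc] - frame[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (frame[3:nr, ] - frame[1:(nr - 2), ]) / 2
  sxx <- box_blur(gx * gx, block)
  syy <- box_blur(gy * gy, block)
  sxy <- box_blur(gx * gy, block)
  tr2 <- (sxx + syy) / 2
  lam_min <- tr2 - sqrt(((sxx - syy) / 2)^2 + sxy^2)
  # suppress responses in the border where gradients are undefined
  b <- (block + 1) %/% 2 + 1
  lam_min[c(1:b, (nr - b + 1):nr), ] <- 0
  lam_min[, c(1:b, (nc - b + 1):nc)] <- 0
  mx <- max(lam_min)
  if (mx <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  pk <- find_peaks(lam_min, threshold = quality * mx, min_sep = min_sep)
  names(pk)[3] <- "response"
  utils::head(pk, max_features)
}

# 2x image pyramid by 2x2 block averaging.
build_pyramid <- function(frame, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- frame
  for (l in seq_len(levels - 1L)) {
    f <- pyr[[l]]
    nr2 <- nrow(f) %/% 2L; nc2 <- ncol(f) %/% 2L
    if (nr2 < 8L || nc2 < 8L) return(pyr[seq_len(l)])
    f <- f[seq_len(2L * nr2), seq_len(2L * nc2), drop = FALSE]
    pyr[[l + 1L]] <- (f[seq(1, 2 * nr2, 2), seq(1, 2 * nc2, 2)] +
                        f[seq(2, 2 * nr2, 2), seq(1, 2 * nc2, 2)] +
                        f[seq(1, 2 * nr2, 2), seq(2, 2 * nc2, 2)] +
                        f[seq(2, 2 * nr2, 2), seq(2, 2 * nc2, 2)]) / 4
  }
  pyr
}

# Pyramidal Lucas-Kanade: track points from frame `prev` to frame `nxt`.
# pts: data.frame/matrix with x, y (0-based). Returns data.frame(x, y,
# status) where status FALSE marks lost features (left the frame, flat
# patch, no convergence).
lk_track <- function(prev, nxt, pts, window = 15, levels = 3,
                     max_iter = 15, eps = 0.01) {
  n <- nrow(pts)
  out <- data.frame(x = rep(NA_real_, n), y = rep(NA_real_, n),
                    status = rep(FALSE, n))
  if (n == 0L) return(out)
  half <- (window - 1) / 2
  pyr_a <- build_pyramid(prev, levels)
  pyr_b <- build_pyramid(nxt, levels)
  levels <- length(pyr_a)
  offs <- expand.grid(dx = -half:half, dy = -half:half)
  for (i in seq_len(n)) {
    g <- c(0, 0)  # accumulated displacement at current level scale
    lost <- FALSE
    for (l in levels:1) {
      sc <- 2^(l - 1)
      a <- pyr_a[[l]]; b <- pyr_b[[l]]
      px <- pts$x[i] / sc; py <- pts$y[i] / sc
      ax <- px + offs$dx; ay <- py + offs$dy
      tmpl <- bilinear_sample(a, ax, ay)
      ix <- (bilinear_sample(a, ax + 1, ay) -
               bilinear_sample(a, ax - 1, ay)) / 2
      iy <- (bilinear_sample(a, ax, ay + 1) -
               bilinear_sample(a, ax, ay - 1)) / 2
      ok <- !is.na(tmpl) & !is.na(ix) & !is.na(iy)
      if (sum(ok) < 0.5 * length(tmpl)) { lost <- l == 1L; next }
      gxx <- sum(ix[ok]^2); gyy <- sum(iy[ok]^2); gxy <- sum(ix[ok] * iy[ok])
      det <- gxx * gyy - gxy^2
      if (det < 1e-12) { lost <- l == 1L; next }
      d <- c(0, 0)
      for (it in seq_len(max_iter)) {
        bx <- px + g[1] + d[1] + offs$dx
        by <- py + g[2] + d[2] + offs$dy
        cur <- bilinear_sample(b, bx, by)
        okb <- ok & !is.na(cur)
        if (sum(okb) < 0.5 * length(tmpl)) { lost <- l == 1L; break }
        diff <- cur[okb] - tmpl[okb]
        ex <- sum(diff * ix[okb]); ey <- sum(diff * iy[okb])
        step <- c(gyy * ex - gxy * ey, gxx * ey - gxy * ex) / det
        d <- d - step
        if (sqrt(sum(step^2)) < eps) break
      }
      g <- g + d
      if (l > 1L) g <- g * 2
    }
    if (!lost) {
      nx <- pts$x[i] + g[1]; ny <- pts$y[i] + g[2]
      if (nx < 0 || ny < 0 || nx > ncol(nxt) - 1 || ny > nrow(nxt) - 1 ||
          !all(is.finite(g))) {
        lost <- TRUE
      } else {
        out$x[i] <- nx; out$y[i] <- ny; out$status[i] <- TRUE
      }
    }
  }
  out
}

#' Seed and track texture features through a flowing suspension video
#'
#' Shi-Tomasi corners are detected on the first frame and re-seeded
#' periodically so fast flow does not deplete the tracked set; each feature
#' is followed frame-to-frame by pyramidal Kanade-Lucas-Tomasi optical flow
#' with an integration window of `window_size_px`. The window also acts as
#' the maximum credible travel distance between consecutive frames: steps
#' whose displacement exceeds it are flagged invalid from that point on,
#' which reproduces the documented under-capture failure when features move
#' farther per frame than the window allows.
#'
#' @param stack a [frame_stack] with at least 2 frames (grayscale view used).
#' @param max_features maximum features alive at any time.
#' @param quality corner quality fraction (of the maximum corner response).
#' @param min_corner_sep_px minimum separation between seeded corners.
#' @param window_size_px odd optical-flow integration window, >= 3.
#' @param reseed_every re-detect corners every this many frames.
#' @return data.frame of per-step records: `feature_id`, `frame` (step start,
#'   1-based), `x`, `y` (position at step start), `x1`, `y1` (step end),
#'   `step_px` (displacement), `valid`, and `y0` (row where the feature was
#'   first seeded).
#' @export
detect_and_track_flow <- function(stack, max_features = 300,
                                  quality = 0.05, min_corner_sep_px = 5,
                                  window_size_px = 15, reseed_every = 10) {
  nf <- n_frames(stack)
  if (nf < 2L) stop("optical flow requires at least 2 frames")
  if (window_size_px < 3) stop("`window_size_px` must be >= 3")
  frames <- lapply(seq_len(nf), function(i) gray_frame(stack, i))
  empty <- data.frame(feature_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), step_px = numeric(0),
                      valid = logical(0), y0 = numeric(0))
  seed_feats <- function(frame, existing_xy, n_needed) {
    co <- shi_tomasi_corners(frame, max_features = max_features,
                             quality = quality,
                             min_sep = min_corner_sep_px)
    if (nrow(co) == 0L || n_needed <= 0L) return(co[0, ])
    if (!is.null(existing_xy) && nrow(existing_xy) > 0L) {
      keep <- vapply(seq_len(nrow(co)), function(j) {
        all((existing_xy$x - co$x[j])^2 + (existing_xy$y - co$y[j])^2 >=
              min_corner_sep_px^2)
      }, logical(1))
      co <- co[keep, , drop = FALSE]
    }
    utils::head(co, n_needed)
  }
  active <- seed_feats(frames[[1]], NULL, max_features)
  if (nrow(active) == 0L) {
    warning("no trackable texture found in the first frame")
    return(empty)
  }
  active <- data.frame(feature_id = seq_len(nrow(active)),
                       x = active$x, y = active$y, y0 = active$y)
  next_id <- nrow(active) + 1L
  recs <- list()
  for (f in seq_len(nf - 1L)) {
    if (f > 1L && (f - 1L) %% reseed_every == 0L) {
      fresh <- seed_feats(frames[[f]], active,
                          max_features - nrow(active))
      if (nrow(fresh) > 0L) {
        active <- rbind(active,
                        data.frame(feature_id = next_id +
                                     seq_len(nrow(fresh)) - 1L,
                                   x = fresh$x, y = fresh$y, y0 = fresh$y))
        next_id <- next_id + nrow(fresh)
      }
    }
    if (nrow(active) == 0L) next
    tracked <- lk_track(frames[[f]], frames[[f + 1L]], active,
                        window = window_size_px)
    step <- sqrt((tracked$x - active$x)^2 + (tracked$y - active$y)^2)
    valid <- tracked$status & !is.na(step) & step <= window_size_px
    recs[[length(recs) + 1L]] <- data.frame(
      feature_id = active$feature_id, frame = f,
      x = active$x, y = active$y,
      x1 = tracked$x, y1 = tracked$y,
      step_px = step, valid = valid, y0 = active$y0
    )
    active <- data.frame(feature_id = active$feature_id[valid],
                         x = tracked$x[valid], y = tracked$y[valid],
                         y0 = active$y0[valid])
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Per-frame mean and maximum suspension velocity
#'
#' Steps below `min_step_px` displacement are treated as detection noise and
#' excluded. Frames (steps) with no remaining valid feature are reported as
#' `NA`, not zero.
#'
#' @param features per-step records from [detect_and_track_flow()].
#' @param fps,um_per_px calibration (strictly positive).
#' @param min_step_px minimum per-step displacement, pixels.
#' @return data.frame `frame`, `n_features`, `mean_velocity_um_s`,
#'   `max_velocity_um_s`.
#' @export
summarize_timecourse <- function(features, fps, um_per_px,
                                 min_step_px = 0) {
  stopifnot(fps > 0, um_per_px > 0)
  frames <- sort(unique(features$frame))
  rows <- lapply(frames, function(f) {
    d <- features[features$frame == f & features$valid &
                    features$step_px >= min_step_px, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(frame = f, n_features = 0L,
                        mean_velocity_um_s = NA_real_,
                        max_velocity_um_s = NA_real_))
    }
    v <- d$step_px * um_per_px * fps
    data.frame(frame = f, n_features = nrow(d),
               mean_velocity_um_s = mean(v), max_velocity_um_s = max(v))
  })
  do.call(rbind, rows)
}

#' Spatial velocity profile across the channel
#'
#' Each feature's mean velocity (over its valid steps) is assigned to the
#' bin containing its seeding position `y0`, expressed as signed distance
#' from the channel centerline. The bluntness ratio is the mean of the two
#' outermost non-empty bins (the wall velocity estimate) divided by the
#' frame maximum velocity (estimated robustly as the 95th percentile of
#' valid step velocities); plug-like (blunted) profiles give larger values
#' than parabolic ones.
#'
#' @param features per-step records from [detect_and_track_flow()].
#' @param channel_span `c(y_top, y_bottom)` pixel rows bounding the channel;
#'   the center is their midpoint.
#' @param bin_width_um profile bin width in micrometers.
#' @param fps,um_per_px calibration.
#' @return object of class `velocity_profile`: list with `bins`
#'   (`bin_center_um`, `mean_velocity_um_s`, `n_features`),
#'   `bluntness_ratio`, `vmax_um_s`, `channel_span`.
#' @export
build_velocity_profile <- function(features, channel_span, bin_width_um,
                                   fps, um_per_px) {
  stopifnot(bin_width_um > 0, fps > 0, um_per_px > 0,
            length(channel_span) == 2L)
  center <- mean(channel_span)
  val <- features[features$valid, , drop = FALSE]
  if (nrow(val) == 0L) stop("no valid feature steps; all bins empty")
  per_feat <- stats::aggregate(
    cbind(step_px = val$step_px) ~ feature_id + y0, data = val, FUN = mean
  )
  per_feat$velocity_um_s <- per_feat$step_px * um_per_px * fps
  per_feat$d_um <- (per_feat$y0 - center) * um_per_px
  half_span_um <- (channel_span[2] - channel_span[1]) / 2 * um_per_px
  breaks <- seq(-half_span_um, half_span_um + bin_width_um,
                by = bin_width_um)
  breaks <- breaks - (max(breaks) - half_span_um) / 2  # center the tiling
  idx <- findInterval(per_feat$d_um, breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx >= length(breaks)] <- length(breaks) - 1L
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bins <- data.frame(bin_center_um = centers,
                     mean_velocity_um_s = NA_real_, n_features = 0L)
  agg <- tapply(per_feat$velocity_um_s, idx, mean)
  cnt <- tapply(per_feat$velocity_um_s, idx, length)
  bins$mean_velocity_um_s[as.integer(names(agg))] <- agg
  bins$n_features[as.integer(names(cnt))] <- cnt
  occ <- which(!is.na(bins$mean_velocity_um_s))
  if (length(occ) == 0L) stop("all bins empty")
  # frame maximum velocity, estimated robustly as the 95th percentile of
  # valid step velocities so a single mis-tracked feature cannot inflate it
  vmax <- unname(stats::quantile(val$step_px, 0.95)) * um_per_px * fps
  wall <- mean(c(bins$mean_velocity_um_s[occ[1L]],
                 bins$mean_velocity_um_s[occ[length(occ)]]))
  structure(
    list(bins = bins, bluntness_ratio = wall / vmax, vmax_um_s = vmax,
         channel_span = channel_span),
    class = "velocity_profile"
  )
}

#' @export
print.velocity_profile <- function(x, ...) {
  occ <- sum(!is.na(x$bins$mean_velocity_um_s))
  cat(sprintf(
    "<velocity_profile> %d/%d occupied bins, vmax %.1f um/s, bluntness %.3f\n",
    occ, nrow(x$bins), x$vmax_um_s, x$bluntness_ratio))
  invisible(x)
}
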