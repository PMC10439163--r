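# Single-cell tracking: centroid detection of Gaussian-like particles,
# trajectory linking with gap bridging, quality filtering, and per-cell
# velocity / size / fluorescence measurement.

#' Detect Gaussian-like particles in one frame
#'
#' Crocker-Grier style centroid detection: the frame is bandpass filtered
#' (short-scale Gaussian smoothing minus a boxcar average at the expected
#' particle diameter), candidate peaks are taken as grayscale-dilation local
#' maxima, and each candidate is refined to a subpixel centroid by iterated
#' intensity-weighted averaging within the diameter window. Each detection
#' reports integrated brightness (mass), radius of gyration, and moment
#' eccentricity; detections failing the mass, intensity, or size filters are
#' excluded.
#'
#' @param frame 2-D numeric matrix of pixel intensities (arbitrary units).
#' @param diameter expected particle diameter in pixels; odd integer >= 3.
#' @param min_mass minimum integrated (bandpassed) brightness.
#' @param max_diameter optional upper bound on `2 * radius of gyration`,
#'   used to exclude cell clusters.
#' @param min_intensity optional minimum raw peak intensity, used to exclude
#'   dim debris.
#' @param invert set `TRUE` for dark-on-light cells (e.g. dense RBCs in
#'   brightfield); intensities are inverted before detection.
#' @param noise_sigma sigma (px) of the short-scale smoothing kernel.
#' @return data.frame with columns `x`, `y` (0-based subpixel centroid),
#'   `mass`, `size` (radius of gyration, px), `ecc` in `[0, 1)`, and
#'   `peak_intensity` (raw units, after any inversion).
#' @export
detect_particles <- function(frame, diameter, min_mass = 0,
                             max_diameter = NULL, min_intensity = NULL,
                             invert = FALSE, noise_sigma = 1) {
  if (diameter < 3 || diameter %% 2 == 0) {
    stop("`diameter` must be an odd integer >= 3")
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), mass = numeric(0),
                      size = numeric(0), ecc = numeric(0),
                      peak_intensity = numeric(0))
  if (invert) frame <- max(frame) - frame
  bp <- pmax(gauss_blur(frame, noise_sigma) - box_blur(frame, diameter), 0)
  half <- (diameter - 1L) %/% 2L
  dil <- dilate_max(bp, half)
  # strict positivity excludes flat background plateaus
  cand <- which(bp >= dil & bp > 1e-8, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  nr <- nrow(frame); nc <- ncol(frame)
  # disk mask offsets within the refinement window
  off <- expand.grid(dy = -half:half, dx = -half:half)
  off <- off[off$dx^2 + off$dy^2 <= half^2 + 1e-9, ]
  hw <- half + 1L
  offw <- expand.grid(dy = -hw:hw, dx = -hw:hw)
  res <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    py <- cand[i, 1L]; px <- cand[i, 2L]  # 1-based window center
    for (iter in 1:10) {
      yy <- py + off$dy; xx <- px + off$dx
      ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
      wts <- bp[cbind(yy[ok], xx[ok])]
      m <- sum(wts)
      if (m <= 0) break
      cx <- sum(wts * xx[ok]) / m
      cy <- sum(wts * yy[ok]) / m
      sx <- round(cx) - px; sy <- round(cy) - py
      if (sx == 0 && sy == 0) break
      px <- px + sign(sx) * (abs(sx) > 0)
      py <- py + sign(sy) * (abs(sy) > 0)
    }
    yy <- py + off$dy; xx <- px + off$dx
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    wts <- bp[cbind(yy[ok], xx[ok])]
    m <- sum(wts)
    if (m <= 0) next
    cx <- sum(wts * xx[ok]) / m
    cy <- sum(wts * yy[ok]) / m
    # final moments over a disk centered on the continuous centroid; an
    # integer-centered mask would bias eccentricity for off-grid particles
    yy2 <- round(cy) + offw$dy; xx2 <- round(cx) + offw$dx
    rr <- sqrt((xx2 - cx)^2 + (yy2 - cy)^2)
    ok2 <- yy2 >= 1 & yy2 <= nr & xx2 >= 1 & xx2 <= nc &
      rr <= half + 0.5
    # antialiased inclusion: boundary pixels enter with fractional weight,
    # otherwise pixelation of the mask edge biases the second moments
    edge_w <- pmin(pmax(half + 0.5 - rr[ok2], 0), 1)
    wts <- bp[cbind(yy2[ok2], xx2[ok2])] * edge_w
    m <- sum(wts)
    if (m <= 0) next
    cx <- sum(wts * xx2[ok2]) / m
    cy <- sum(wts * yy2[ok2]) / m
    rg <- sqrt(sum(wts * ((xx2[ok2] - cx)^2 + (yy2[ok2] - cy)^2)) / m)
    ecc <- moment_eccentricity(xx2[ok2] - 1, yy2[ok2] - 1, wts)
    xx <- xx2; yy <- yy2; ok <- ok2
    res[[i]] <- data.frame(x = cx - 1, y = cy - 1, mass = m,
                           size = max(rg, 1e-6), ecc = ecc,
                           peak_intensity = max(frame[cbind(yy[ok],
                                                            xx[ok])]))
  }
  det <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(det) || nrow(det) == 0L) return(empty)
  # merge candidates that converged to the same particle (keep max mass)
  ord <- order(det$mass, decreasing = TRUE)
  det <- det[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      later <- (i + 1L):nrow(det)
      d2 <- (det$x[later] - det$x[i])^2 + (det$y[later] - det$y[i])^2
      keep[later][d2 < (0.5 * diameter)^2] <- FALSE
    }
  }
  det <- det[keep, , drop = FALSE]
  det <- det[det$mass >= min_mass, , drop = FALSE]
  if (!is.null(min_intensity)) {
    det <- det[det$peak_intensity >= min_intensity, , drop = FALSE]
  }
  if (!is.null(max_diameter)) {
    det <- det[2 * det$size <= max_diameter, , drop = FALSE]
  }
  rownames(det) <- NULL
  det
}

#' Detect particles in every frame of a stack
#'
#' @param stack a [frame_stack]; RGB frames are collapsed to grayscale.
#' @param ... passed to [detect_particles()].
#' @return data.frame of detections with a `frame` column (1-based).
#' @export
detect_particles_stack <- function(stack, ...) {
  out <- lapply(seq_len(n_frames(stack)), function(i) {
    d <- detect_particles(gray_frame(stack, i), ...)
    if (nrow(d) > 0L) d$frame <- i
    d
  })
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  if (length(out) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), mass = numeric(0),
                      size = numeric(0), ecc = numeric(0),
                      peak_intensity = numeric(0), frame = integer(0)))
  }
  do.call(rbind, out)
}

# Optimal assignment of active tracks to candidate detections within one
# connected candidate subnetwork: minimize total squared displacement, with
# an unmatched track or detection costing search_range^2. Exhaustive
# branch-and-bound for small subnetworks, greedy fallback for large ones.
assign_subnetwork <- function(cost, max_cost) {
  nt <- nrow(cost); nd <- ncol(cost)
  if (nt * nd > 64L) {
    # greedy: repeatedly take the cheapest remaining feasible pair
    match_t <- rep(NA_integer_, nt)
    used_d <- rep(FALSE, nd)
    ord <- order(cost)
    for (k in ord) {
      if (cost[k] > max_cost) break
      ti <- (k - 1L) %% nt + 1L; di <- (k - 1L) %/% nt + 1L
      if (is.na(match_t[ti]) && !used_d[di]) {
        match_t[ti] <- di; used_d[di] <- TRUE
      }
    }
    return(match_t)
  }
  best <- list(cost = Inf, match = rep(NA_integer_, nt))
  match_t <- rep(NA_integer_, nt)
  used_d <- rep(FALSE, nd)
  recurse <- function(ti, acc) {
    if (acc >= best$cost) return()
    if (ti > nt) {
      # unmatched detections start new tracks: cost max_cost each
      total <- acc + sum(!used_d) * max_cost
      if (total < best$cost) {
        best <<- list(cost = total, match = match_t)
      }
      return()
    }
    for (di in seq_len(nd)) {
      if (!used_d[di] && cost[ti, di] <= max_cost) {
        match_t[ti] <<- di; used_d[di] <<- TRUE
        recurse(ti + 1L, acc + cost[ti, di])
        match_t[ti] <<- NA_integer_; used_d[di] <<- FALSE
      }
    }
    # leave track ti unmatched
    recurse(ti + 1L, acc + max_cost)
  }
  recurse(1L, 0)
  best$match
}

#' Link detections across frames into trajectories and filter for quality
#'
#' Frame-to-frame linking restricted to candidate displacements within
#' `search_range_px`; competing candidates inside a connected subnetwork are
#' resolved by minimizing total squared displacement. Tracks missing from up
#' to `memory_frames` consecutive frames are bridged. Trajectories observed
#' in fewer than `min_frames` frames or traveling less than
#' `min_distance_px` total path distance are discarded.
#'
#' @param detections data.frame from [detect_particles_stack()] (needs
#'   `frame`, `x`, `y`; extra columns are carried along).
#' @param search_range_px maximum per-step displacement, pixels.
#' @param memory_frames frames a vanished particle is remembered.
#' @param min_frames minimum frames a trajectory must span (>= 2).
#' @param min_distance_px minimum total path distance, pixels.
#' @return object of class `trajectory_set`: list with `detections` (input
#'   rows plus `cell_id`) and `trajectories` (one summary row per retained
#'   cell: `cell_id`, `n_frames_present`, `first_frame`, `last_frame`,
#'   `path_distance`, `net_displacement`, `mean_mass`, `mean_size_px`, ...).
#' @export
link_and_filter <- function(detections, search_range_px, memory_frames = 0,
                            min_frames = 2, min_distance_px = 0) {
  stopifnot(search_range_px > 0, min_frames >= 2)
  det <- detections
  if (nrow(det) == 0L) {
    return(structure(list(detections = cbind(det, cell_id = integer(0)),
                          trajectories = empty_traj_summary()),
                     class = "trajectory_set"))
  }
  det <- det[order(det$frame), , drop = FALSE]
  det$cell_id <- NA_integer_
  # iterate every frame in range so tracks age across empty frames too
  frames <- seq(min(det$frame), max(det$frame))
  # active track state
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_missed <- integer(0)
  next_id <- 1L
  max_cost <- search_range_px^2
  for (f in frames) {
    rows <- which(det$frame == f)
    dx <- det$x[rows]; dy <- det$y[rows]
    nd <- length(rows)
    assigned <- rep(NA_integer_, nd)  # index into active tracks
    if (length(act_id) > 0L && nd > 0L) {
      cost <- outer(act_x, dx, function(a, b) (a - b)^2) +
        outer(act_y, dy, function(a, b) (a - b)^2)
      feasible <- cost <= max_cost
      # connected components of the bipartite candidate graph
      nt <- length(act_id)
      comp <- rep(0L, nt + nd)  # tracks then detections
      cid <- 0L
      for (s in seq_len(nt)) {
        if (comp[s] != 0L || !any(feasible[s, ])) next
        cid <- cid + 1L
        queue <- s
        comp[s] <- cid
        while (length(queue) > 0L) {
          u <- queue[1L]; queue <- queue[-1L]
          if (u <= nt) {
            nbr <- nt + which(feasible[u, ] & comp[nt + seq_len(nd)] == 0L)
          } else {
            nbr <- which(feasible[, u - nt] & comp[seq_len(nt)] == 0L)
          }
          comp[nbr] <- cid
          queue <- c(queue, nbr)
        }
      }
      if (cid > 0L) {
        for (cc in seq_len(cid)) {
          ts <- which(comp[seq_len(nt)] == cc)
          ds <- which(comp[nt + seq_len(nd)] == cc)
          if (length(ts) == 0L || length(ds) == 0L) next
          sub <- cost[ts, ds, drop = FALSE]
          sub[sub > max_cost] <- Inf
          m <- assign_subnetwork(sub, max_cost)
          for (k in seq_along(ts)) {
            if (!is.na(m[k])) assigned[ds[m[k]]] <- ts[k]
          }
        }
      }
    }
    # update matched tracks
    matched_tracks <- logical(length(act_id))
    for (j in seq_len(nd)) {
      ti <- assigned[j]
      if (!is.na(ti)) {
        det$cell_id[rows[j]] <- act_id[ti]
        act_x[ti] <- dx[j]; act_y[ti] <- dy[j]; act_missed[ti] <- 0L
        matched_tracks[ti] <- TRUE
      } else {
        det$cell_id[rows[j]] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, dx[j]); act_y <- c(act_y, dy[j])
        act_missed <- c(act_missed, 0L)
        matched_tracks <- c(matched_tracks, TRUE)
        next_id <- next_id + 1L
      }
    }
    # age unmatched tracks; retire those beyond memory
    if (length(act_id) > 0L) {
      act_missed[!matched_tracks] <- act_missed[!matched_tracks] + 1L
      keep <- act_missed <= memory_frames
      act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
      act_missed <- act_missed[keep]
    }
  }
  summ <- summarize_trajectories(det)
  keep_ids <- summ$cell_id[summ$n_frames_present >= min_frames &
                             summ$path_distance >= min_distance_px]
  det <- det[det$cell_id %in% keep_ids, , drop = FALSE]
  summ <- summ[summ$cell_id %in% keep_ids, , drop = FALSE]
  # renumber retained cells 1..n in order of first appearance
  remap <- stats::setNames(seq_along(keep_ids),
                           sort(unique(det$cell_id)))
  det$cell_id <- as.integer(remap[as.character(det$cell_id)])
  summ$cell_id <- as.integer(remap[as.character(summ$cell_id)])
  summ <- summ[order(summ$cell_id), , drop = FALSE]
  rownames(det) <- rownames(summ) <- NULL
  structure(list(detections = det, trajectories = summ),
            class = "trajectory_set")
}

empty_traj_summary <- function() {
  data.frame(cell_id = integer(0), n_frames_present = integer(0),
             first_frame = integer(0), last_frame = integer(0),
             x_first = numeric(0), x_last = numeric(0),
             y_first = numeric(0), y_last = numeric(0),
             path_distance = numeric(0), net_displacement = numeric(0),
             mean_mass = numeric(0), mean_size_px = numeric(0),
             mean_ecc = numeric(0))
}

summarize_trajectories <- function(det) {
  ids <- sort(unique(det$cell_id))
  if (length(ids) == 0L) return(empty_traj_summary())
  rows <- lapply(ids, function(id) {
    d <- det[det$cell_id == id, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    steps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    data.frame(
      cell_id = id,
      n_frames_present = nrow(d),
      first_frame = d$frame[1L], last_frame = d$frame[nrow(d)],
      x_first = d$x[1L], x_last = d$x[nrow(d)],
      y_first = d$y[1L], y_last = d$y[nrow(d)],
      path_distance = sum(steps),
      net_displacement = sqrt((d$x[nrow(d)] - d$x[1L])^2 +
                                (d$y[nrow(d)] - d$y[1L])^2),
      mean_mass = mean(d$mass),
      mean_size_px = mean(d$size),
      mean_ecc = if ("ecc" %in% names(d)) mean(d$ecc) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d trajectories, %d detections\n",
              nrow(x$trajectories), nrow(x$detections)))
  invisible(x)
}

#' Per-cell velocity, size, and approximate area
#'
#' Mean speed uses the trajectory's frame span as elapsed time, so frames
#' bridged by linking memory count toward time. In `"free"` mode speed is
#' total path distance over elapsed time; in `"x_channel_flow"` mode it is
#' the x-displacement over elapsed time (flow along +x), with negative
#' values flagged. Reported area is `pi * size^2` with size the radius of
#' gyration, an approximation valid for compact cells.
#'
#' @param trajset a `trajectory_set` from [link_and_filter()].
#' @param fps,um_per_px calibration (strictly positive, required).
#' @param mode `"free"` (default) or `"x_channel_flow"`.
#' @return data.frame of cell records: `cell_id`, `velocity_um_s`,
#'   `negative_x` flag, `size_um`, `area_um2`, plus trajectory summaries.
#' @export
compute_cell_velocity <- function(trajset, fps, um_per_px,
                                  mode = c("free", "x_channel_flow")) {
  mode <- match.arg(mode)
  if (missing(fps) || is.null(fps) || !is.numeric(fps) || fps <= 0) {
    stop("`fps` must be supplied and strictly positive")
  }
  if (missing(um_per_px) || is.null(um_per_px) || um_per_px <= 0) {
    stop("`um_per_px` must be supplied and strictly positive")
  }
  tr <- trajset$trajectories
  span <- tr$last_frame - tr$first_frame
  if (any(span < 1)) stop("trajectories must span at least 2 frames")
  disp <- switch(mode,
                 free = tr$path_distance,
                 x_channel_flow = tr$x_last - tr$x_first)
  vel <- disp * um_per_px * fps / span
  out <- tr
  out$velocity_um_s <- if (mode == "free") vel else abs(vel)
  out$negative_x <- if (mode == "x_channel_flow") vel < 0 else FALSE
  out$size_um <- tr$mean_size_px * um_per_px
  out$area_um2 <- pi * (tr$mean_size_px * um_per_px)^2
  out
}

#' Mean summed fluorescence of a tracked cell
#'
#' For each frame in which the cell was detected, pixel intensity of the
#' chosen channel is summed over a circular aperture centered on the
#' detection; the mean of those per-frame sums is returned per cell.
#'
#' @param trajset a `trajectory_set`.
#' @param stack the [frame_stack] the detections came from.
#' @param channel plane index, color name, or channel tag.
#' @param aperture_radius_px radius of the summation aperture.
#' @return data.frame `cell_id`, `mean_fluorescence_sum`, `n_frames_used`.
#' @export
measure_cell_fluorescence <- function(trajset, stack, channel,
                                      aperture_radius_px) {
  det <- trajset$detections
  d <- frame_dim(stack)
  r <- aperture_radius_px
  off <- expand.grid(dy = -ceiling(r):ceiling(r),
                     dx = -ceiling(r):ceiling(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  ids <- sort(unique(det$cell_id))
  rows <- lapply(ids, function(id) {
    dd <- det[det$cell_id == id, , drop = FALSE]
    sums <- numeric(0)
    skipped <- 0L
    for (k in seq_len(nrow(dd))) {
      cx <- round(dd$x[k]); cy <- round(dd$y[k])
      xx <- cx + off$dx; yy <- cy + off$dy
      if (any(xx < 0 | xx > d[2] - 1 | yy < 0 | yy > d[1] - 1)) {
        skipped <- skipped + 1L
        next
      }
      plane <- get_plane(stack, dd$frame[k], channel)
      sums <- c(sums, sum(plane[cbind(yy + 1, xx + 1)]))
    }
    if (skipped > 0L) {
      warning("cell ", id, ": aperture off-frame in ", skipped,
              " frame(s); skipped", call. = FALSE)
    }
    if (length(sums) == 0L) {
      stop("cell ", id, ": aperture off-frame in every detected frame")
    }
    data.frame(cell_id = id, mean_fluorescence_sum = mean(sums),
               n_frames_used = length(sums))
  })
  do.call(rbind, rows)
}
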