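# Adhered-cell quantification: brightfield morphology, fluorescence
# morphology/functionality (secondary stain, texture, nuclear lobes),
# filopodia-like protrusion counting, and transient adhesion under flow.

#' Brightfield single-cell morphology
#'
#' Cells are located as Gaussian-like particles (see [detect_particles()]);
#' the radius of gyration Rg of each particle is converted to the radius of
#' the equivalent uniform disk (`R = sqrt(2) * Rg`, exact for a flat-topped
#' spread cell) and the reported area is `pi * R^2`. Circularity is the
#' moment eccentricity, and cells outside the `[min_area_um2, max_area_um2]`
#' window are excluded as noise or aggregates. Field density is retained
#' cells per square millimeter of imaged area.
#'
#' @param image 2-D numeric matrix (single brightfield frame).
#' @param expected_diameter_px odd particle diameter for detection.
#' @param min_area_um2,max_area_um2 retained area window, square micrometers.
#' @param invert `TRUE` for dark-on-light cells.
#' @param um_per_px calibration, strictly positive.
#' @param ... further arguments to [detect_particles()].
#' @return list with `cells` (data.frame: `cell_id`, `x`, `y`, `area_um2`,
#'   `area_px2`, `circularity`, `radius_um`, `mass`) and `field_density`
#'   (cells per mm^2).
#' @export
measure_brightfield_cells <- function(image, expected_diameter_px,
                                      min_area_um2 = 0,
                                      max_area_um2 = Inf,
                                      invert = FALSE, um_per_px = 1, ...) {
  stopifnot(um_per_px > 0)
  det <- detect_particles(image, expected_diameter_px, invert = invert, ...)
  r_eq <- sqrt(2) * det$size        # uniform-disk equivalent radius
  area_um2 <- pi * (r_eq * um_per_px)^2
  keep <- area_um2 >= min_area_um2 & area_um2 <= max_area_um2
  det <- det[keep, , drop = FALSE]
  # stable row-major indexing so annotated indices match table rows
  ord <- order(round(det$y), det$x)
  det <- det[ord, , drop = FALSE]
  r_eq <- sqrt(2) * det$size
  area_um2 <- pi * (r_eq * um_per_px)^2
  cells <- data.frame(
    cell_id = seq_len(nrow(det)),
    x = det$x, y = det$y,
    area_um2 = area_um2,
    area_px2 = pi * r_eq^2,
    circularity = det$ecc,
    radius_um = r_eq * um_per_px,
    mass = det$mass
  )
  field_mm2 <- prod(dim(image)) * (um_per_px / 1000)^2
  list(cells = cells, field_density = nrow(cells) / field_mm2)
}

#' Fluorescent single-cell morphology and functionality
#'
#' The membrane channel is binarized (`pixel > threshold` is signal) and
#' 8-connected regions of signal are treated as cells. Per region the
#' function reports rasterized area, centroid, moment eccentricity
#' (circularity), equivalent-disk radius, membrane texture (s.d. of
#' membrane intensity over region pixels), summed above-threshold secondary
#' stain, and the number of lobe-channel local maxima separated by at least
#' `min_peak_sep_px` (each above the lobe threshold).
#'
#' @param stack a one-frame [frame_stack] with the relevant stain planes.
#' @param membrane_channel,membrane_threshold membrane stain plane and its
#'   binarization threshold (arbitrary units).
#' @param secondary_channel,secondary_threshold optional functional stain.
#' @param lobe_channel,lobe_threshold,min_peak_sep_px optional nuclear-lobe
#'   (or other punctate) stain and peak-separation rule.
#' @param min_area_um2,max_area_um2 retained region area window.
#' @param um_per_px calibration, strictly positive.
#' @return data.frame of cell records ordered row-major by centroid:
#'   `cell_id`, `x`, `y`, `area_px2`, `area_um2`, `circularity`,
#'   `radius_um`, `membrane_texture`, `secondary_sum`, `lobe_count`.
#' @export
measure_fluorescent_cells <- function(stack, membrane_channel,
                                      membrane_threshold,
                                      secondary_channel = NULL,
                                      secondary_threshold = 0,
                                      lobe_channel = NULL,
                                      lobe_threshold = 0,
                                      min_peak_sep_px = 5,
                                      min_area_um2 = 0,
                                      max_area_um2 = Inf,
                                      um_per_px = 1) {
  stopifnot(um_per_px > 0)
  mem <- get_plane(stack, 1L, membrane_channel)
  sec <- if (!is.null(secondary_channel)) {
    get_plane(stack, 1L, secondary_channel)
  }
  lob <- if (!is.null(lobe_channel)) get_plane(stack, 1L, lobe_channel)
  mask <- mem > membrane_threshold
  lab <- label_regions(mask)
  n <- max(lab)
  rows <- list()
  for (i in seq_len(n)) {
    pix <- which(lab == i, arr.ind = TRUE)
    xs <- pix[, 2L] - 1; ys <- pix[, 1L] - 1
    area_px <- nrow(pix)
    area_um2 <- area_px * um_per_px^2
    if (area_um2 < min_area_um2 || area_um2 > max_area_um2) next
    vals <- mem[pix]
    sec_sum <- 0
    if (!is.null(sec)) {
      sv <- sec[pix]
      sec_sum <- sum(sv[sv > secondary_threshold])
    }
    lobe_count <- NA_integer_
    if (!is.null(lob)) {
      region_mask <- lab == i
      pk <- find_peaks(lob, mask = region_mask,
                       threshold = lobe_threshold,
                       min_sep = min_peak_sep_px)
      lobe_count <- nrow(pk)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      x = mean(xs), y = mean(ys),
      area_px2 = area_px, area_um2 = area_um2,
      circularity = moment_eccentricity(xs, ys),
      radius_um = sqrt(area_px / pi) * um_per_px,
      membrane_texture = if (area_px > 1L) stats::sd(vals) else 0,
      secondary_sum = sec_sum,
      lobe_count = lobe_count
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area_px2 = numeric(0), area_um2 = numeric(0),
                      circularity = numeric(0), radius_um = numeric(0),
                      membrane_texture = numeric(0),
                      secondary_sum = numeric(0), lobe_count = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(round(out$y), out$x), , drop = FALSE]
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Harris corner response (det - k * trace^2) of a lightly smoothed image,
# with a fixed 3-px structure-tensor window and k = 0.04.
harris_response <- function(img, smooth_sigma = 1) {
  f <- gauss_blur(img, smooth_sigma)
  nr <- nrow(f); nc <- ncol(f)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (f[, 3:nc] - f[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (f[3:nr, ] - f[1:(nr - 2), ]) / 2
  sxx <- box_blur(gx * gx, 3)
  syy <- box_blur(gy * gy, 3)
  sxy <- box_blur(gx * gy, 3)
  sxx * syy - sxy^2 - 0.04 * (sxx + syy)^2
}

#' Count filopodia-like protrusions of one cell region
#'
#' Harris corner response is computed on the binarized region; candidate
#' corners must reach `corner_sharpness` times the maximum response and lie
#' on the convex-hull circumference of the region (protrusion tips are
#' convex by definition, which excludes the concave notches between
#' protrusions). Candidates closer than `min_separation_px` are merged,
#' keeping the strongest. Tip distances are measured from the region
#' centroid.
#'
#' @param region_mask logical/0-1 matrix of one labeled cell region.
#' @param corner_sharpness fraction of the maximum Harris response a
#'   candidate must reach.
#' @param min_separation_px minimum tip separation; closer tips merge.
#' @param um_per_px calibration for the reported distances.
#' @return list with `protrusion_count`, `dist_min_um`, `dist_mean_um`,
#'   `dist_max_um`, and `tips` (data.frame x, y, response).
#' @export
count_protrusions <- function(region_mask, corner_sharpness = 0.2,
                              min_separation_px = 6, um_per_px = 1) {
  mask <- region_mask != 0
  none <- list(protrusion_count = 0L, dist_min_um = NA_real_,
               dist_mean_um = NA_real_, dist_max_um = NA_real_,
               tips = data.frame(x = numeric(0), y = numeric(0),
                                 response = numeric(0)))
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 5L) return(none)
  xs <- pix[, 2L] - 1; ys <- pix[, 1L] - 1
  cx <- mean(xs); cy <- mean(ys)
  resp <- harris_response(mask * 1)
  mx <- max(resp)
  if (mx <= 0) return(none)
  cand <- which(resp >= corner_sharpness * mx & mask, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(none)
  cand_x <- cand[, 2L] - 1; cand_y <- cand[, 1L] - 1
  cand_r <- resp[cand]
  # snap each candidate to the protrusion end: the region pixel near the
  # corner farthest from the centroid (smoothing shifts the Harris peak a
  # few pixels inside the apex)
  for (i in seq_along(cand_x)) {
    near <- (xs - cand_x[i])^2 + (ys - cand_y[i])^2 <= 4^2
    if (any(near)) {
      dd <- (xs[near] - cx)^2 + (ys[near] - cy)^2
      j <- which.max(dd)
      cand_x[i] <- xs[near][j]; cand_y[i] <- ys[near][j]
    }
  }
  # convex hull circumference of the region pixels
  hull <- grDevices::chull(xs, ys)
  hx <- xs[hull]; hy <- ys[hull]
  nh <- length(hx)
  seg_dist <- function(px, py) {
    d <- Inf
    for (s in seq_len(nh)) {
      x1 <- hx[s]; y1 <- hy[s]
      x2 <- hx[if (s == nh) 1L else s + 1L]
      y2 <- hy[if (s == nh) 1L else s + 1L]
      vx <- x2 - x1; vy <- y2 - y1
      t <- if (vx == 0 && vy == 0) 0 else {
        pmin(pmax(((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2), 0), 1)
      }
      d <- pmin(d, sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2))
    }
    d
  }
  on_hull <- seg_dist(cand_x, cand_y) <= 1.5
  if (!any(on_hull)) return(none)
  cand_x <- cand_x[on_hull]; cand_y <- cand_y[on_hull]
  cand_r <- cand_r[on_hull]
  ord <- order(cand_r, decreasing = TRUE)
  cand_x <- cand_x[ord]; cand_y <- cand_y[ord]; cand_r <- cand_r[ord]
  keep <- logical(length(cand_x))
  for (i in seq_along(cand_x)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep[seq_len(i - 1L)])
    d2 <- (cand_x[sel] - cand_x[i])^2 + (cand_y[sel] - cand_y[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  tx <- cand_x[keep]; ty <- cand_y[keep]
  dist_um <- sqrt((tx - cx)^2 + (ty - cy)^2) * um_per_px
  list(protrusion_count = length(tx),
       dist_min_um = min(dist_um), dist_mean_um = mean(dist_um),
       dist_max_um = max(dist_um),
       tips = data.frame(x = tx, y = ty, response = cand_r[keep]))
}

#' Transient adhesion time of cells under flow
#'
#' Cells are detected and linked as in the tracking module. Detections whose
#' integrated brightness exceeds `max_intensity` are discarded as debris;
#' trajectories observed in fewer than `min_frames` frames are discarded as
#' noise. Adhesion time is the inclusive frame span over the imaging rate,
#' so times are exact multiples of `1/fps`.
#'
#' @param stack a [frame_stack] with `fps` set (or passed explicitly).
#' @param expected_diameter_px odd particle diameter.
#' @param min_mass minimum integrated brightness.
#' @param max_intensity maximum integrated brightness (debris exclusion).
#' @param min_frames minimum frames present.
#' @param fps frames per second; defaults to the stack calibration.
#' @param search_range_px linking search range (adhered cells move little).
#' @param memory_frames linking memory for brief detection dropouts.
#' @return data.frame of cell records with `adhesion_time_s`,
#'   `net_displacement_px`, and trajectory summaries.
#' @export
measure_transient_adhesion <- function(stack, expected_diameter_px,
                                       min_mass = 0, max_intensity = Inf,
                                       min_frames = 3, fps = NULL,
                                       search_range_px = 5,
                                       memory_frames = 1) {
  fps <- if (is.null(fps)) stack$fps else fps
  if (is.null(fps) || fps <= 0) {
    stop("`fps` must be supplied (stack calibration or argument)")
  }
  det <- detect_particles_stack(stack, diameter = expected_diameter_px,
                                min_mass = min_mass)
  det <- det[det$mass <= max_intensity, , drop = FALSE]
  ts <- link_and_filter(det, search_range_px = search_range_px,
                        memory_frames = memory_frames,
                        min_frames = min_frames, min_distance_px = 0)
  tr <- ts$trajectories
  tr$adhesion_time_s <- (tr$last_frame - tr$first_frame + 1L) / fps
  tr$net_displacement_px <- tr$net_displacement
  tr
}
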