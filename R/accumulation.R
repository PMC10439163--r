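# Multiscale occlusion/accumulation quantification: per-plane binarization,
# device-map inference, microchannel detection with wall smoothing, and
# occlusion / accumulation time series including per-x spatial occlusion.

#' Binarize selected color planes of every timepoint
#'
#' A pixel is signal when its intensity is strictly greater than the
#' threshold supplied for its plane.
#'
#' @param stack a [frame_stack]; frames are timepoints.
#' @param thresholds named numeric vector over `red`/`green`/`blue` (or
#'   plane indices as names); only named planes are binarized.
#' @return object of class `mask_series`: list with `masks` (list over
#'   timepoints of named lists of logical matrices) and `channels` (plane
#'   names).
#' @export
binarize_channels <- function(stack, thresholds) {
  if (is.null(names(thresholds)) || any(names(thresholds) == "")) {
    stop("`thresholds` must be a fully named vector (e.g. c(red = 80))")
  }
  for (nm in names(thresholds)) resolve_channel(stack, nm)
  masks <- lapply(seq_len(n_frames(stack)), function(t) {
    out <- lapply(names(thresholds), function(nm) {
      get_plane(stack, t, nm) > thresholds[[nm]]
    })
    names(out) <- names(thresholds)
    out
  })
  structure(list(masks = masks, channels = names(thresholds)),
            class = "mask_series")
}

#' Infer the device map from signal across all planes and timepoints
#'
#' Counts, per pixel, how many plane/timepoint masks contain signal there;
#' pixels reaching `map_threshold` occurrences form the device mask. With
#' the default threshold of 1 the map is the union of all signal ever seen,
#' so a device whose wetted area is progressively covered is recovered in
#' full.
#'
#' @param mask_series a `mask_series` from [binarize_channels()].
#' @param map_threshold minimum number of signal occurrences (>= 1).
#' @return object of class `device_map`: list with `mask` (logical matrix)
#'   and `channels` (empty until [detect_microchannels()]).
#' @export
build_device_map <- function(mask_series, map_threshold = 1) {
  stopifnot(map_threshold >= 1)
  counts <- NULL
  for (t in seq_along(mask_series$masks)) {
    for (nm in mask_series$channels) {
      m <- mask_series$masks[[t]][[nm]]
      counts <- if (is.null(counts)) m + 0 else counts + m
    }
  }
  mask <- counts >= map_threshold
  if (!any(mask)) stop("no device signal found")
  structure(list(mask = mask, channels = list()), class = "device_map")
}

#' @export
print.device_map <- function(x, ...) {
  cat(sprintf("<device_map> %d device px, %d microchannel(s)\n",
              sum(x$mask), length(x$channels)))
  invisible(x)
}

#' Detect straight microchannels and smooth their walls
#'
#' Each 8-connected region of the device mask is treated as one
#' microchannel (flow along x). For every x in a channel's range the wall
#' coordinates are the extreme y of region pixels in that column;
#' single-column gaps are filled by linear interpolation and walls are
#' smoothed with a short running median, which removes +/-1 px raggedness.
#' The channel interior used for occlusion is the area between the smoothed
#' walls.
#'
#' @param map a `device_map`.
#' @param smooth_k odd running-median window for wall smoothing.
#' @return the `device_map` with `channels` populated: per channel `id`,
#'   `x0`, `x1` (0-based inclusive), `y_top`, `y_bottom` (per-x smoothed
#'   wall rows), `area_px` (between-wall area).
#' @export
detect_microchannels <- function(map, smooth_k = 5) {
  lab <- label_regions(map$mask)
  n <- max(lab)
  channels <- vector("list", n)
  for (i in seq_len(n)) {
    pix <- which(lab == i, arr.ind = TRUE)
    xs <- pix[, 2L] - 1; ys <- pix[, 1L] - 1
    x0 <- min(xs); x1 <- max(xs)
    xr <- x0:x1
    ytop <- rep(NA_real_, length(xr)); ybot <- rep(NA_real_, length(xr))
    for (j in seq_along(xr)) {
      sel <- xs == xr[j]
      if (any(sel)) {
        ytop[j] <- min(ys[sel]); ybot[j] <- max(ys[sel])
      }
    }
    # fill column gaps by linear interpolation between neighbours
    if (anyNA(ytop) && sum(!is.na(ytop)) >= 2L) {
      ytop <- stats::approx(xr[!is.na(ytop)], ytop[!is.na(ytop)], xout = xr,
                            rule = 2)$y
      ybot <- stats::approx(xr[!is.na(ybot)], ybot[!is.na(ybot)], xout = xr,
                            rule = 2)$y
    }
    k <- min(smooth_k, if (length(xr) %% 2 == 0) length(xr) - 1 else
      length(xr))
    if (k >= 3) {
      ytop <- as.numeric(stats::runmed(ytop, k))
      ybot <- as.numeric(stats::runmed(ybot, k))
    }
    channels[[i]] <- list(id = i, x0 = x0, x1 = x1,
                          y_top = ytop, y_bottom = ybot,
                          area_px = sum(floor(ybot) - ceiling(ytop) + 1))
  }
  # index channels top-to-bottom, then left-to-right
  ord <- order(vapply(channels, function(ch) mean(ch$y_top), numeric(1)),
               vapply(channels, function(ch) ch$x0, numeric(1)))
  channels <- channels[ord]
  for (i in seq_along(channels)) channels[[i]]$id <- i
  map$channels <- channels
  map
}

# Logical matrix of the pixels between a channel's smoothed walls.
channel_interior <- function(channel, dim_hw) {
  m <- matrix(FALSE, dim_hw[1], dim_hw[2])
  xr <- channel$x0:channel$x1
  for (j in seq_along(xr)) {
    rows <- (ceiling(channel$y_top[j]):floor(channel$y_bottom[j])) + 1
    m[rows, xr[j] + 1] <- TRUE
  }
  m
}

#' Occlusion and accumulation over time
#'
#' For each timepoint and color plane the signal area inside the region of
#' interest (whole device map or one microchannel interior) is measured;
#' percent occlusion is `100 * signal / region area`, accumulation is the
#' between-timepoint change in signal area, and the accumulation rate is
#' the least-squares slope of signal area (square micrometers) against time
#' (minutes).
#'
#' @param mask_series a `mask_series` from [binarize_channels()].
#' @param map a `device_map`; pass `channel` to restrict to one
#'   microchannel.
#' @param timestamps_min strictly increasing acquisition times, minutes.
#' @param um_per_px calibration, strictly positive.
#' @param channel optional microchannel id from [detect_microchannels()].
#' @return object of class `occlusion_series`: list with `series`
#'   (data.frame: `timepoint`, `time_min`, `channel`, `signal_area_px2`,
#'   `signal_area_um2`, `occlusion_pct`, `accumulation_um2`) and `rates`
#'   (per plane least-squares `rate_um2_min`), plus `region_area_px2`.
#' @export
compute_occlusion_accumulation <- function(mask_series, map, timestamps_min,
                                           um_per_px = 1, channel = NULL) {
  stopifnot(um_per_px > 0)
  n_t <- length(mask_series$masks)
  if (length(timestamps_min) != n_t) {
    stop("need one timestamp per timepoint")
  }
  if (any(diff(timestamps_min) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  region <- if (is.null(channel)) {
    map$mask
  } else {
    if (length(map$channels) == 0L) {
      stop("run detect_microchannels() before selecting a channel")
    }
    channel_interior(map$channels[[channel]], dim(map$mask))
  }
  region_area <- sum(region)
  if (region_area == 0L) stop("region of interest has zero area")
  rows <- list()
  for (t in seq_len(n_t)) {
    for (nm in mask_series$channels) {
      sig <- sum(mask_series$masks[[t]][[nm]] & region)
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = t, time_min = timestamps_min[t], channel = nm,
        signal_area_px2 = sig,
        signal_area_um2 = sig * um_per_px^2,
        occlusion_pct = 100 * sig / region_area
      )
    }
  }
  series <- do.call(rbind, rows)
  series$accumulation_um2 <- NA_real_
  rates <- lapply(mask_series$channels, function(nm) {
    d <- series[series$channel == nm, ]
    acc <- c(NA, diff(d$signal_area_um2))
    series$accumulation_um2[series$channel == nm] <<- acc
    x <- d$time_min - mean(d$time_min)
    slope <- if (n_t > 1L) {
      sum(x * (d$signal_area_um2 - mean(d$signal_area_um2))) / sum(x^2)
    } else NA_real_
    data.frame(channel = nm, rate_um2_min = slope)
  })
  structure(
    list(series = series, rates = do.call(rbind, rates),
         region_area_px2 = region_area),
    class = "occlusion_series"
  )
}

#' @export
print.occlusion_series <- function(x, ...) {
  cat(sprintf(
    "<occlusion_series> %d timepoint(s) x %d plane(s), region %d px\n",
    length(unique(x$series$timepoint)),
    length(unique(x$series$channel)), x$region_area_px2))
  invisible(x)
}

#' Spatial occlusion along one microchannel
#'
#' At each x along the channel, the percentage of the wall-to-wall span
#' covered by signal. The x axis is reported relative to the channel inlet
#' (proximal end = smallest x).
#'
#' @param mask logical signal mask (one plane, one timepoint).
#' @param channel one microchannel from [detect_microchannels()].
#' @return data.frame `x_rel` (0-based from the inlet), `x_abs`,
#'   `span_px`, `occlusion_pct`.
#' @export
spatial_occlusion <- function(mask, channel) {
  xr <- channel$x0:channel$x1
  rows <- lapply(seq_along(xr), function(j) {
    ys <- ceiling(channel$y_top[j]):floor(channel$y_bottom[j])
    span <- length(ys)
    sig <- sum(mask[ys + 1, xr[j] + 1])
    data.frame(x_rel = j - 1L, x_abs = xr[j], span_px = span,
               occlusion_pct = 100 * sig / span)
  })
  do.call(rbind, rows)
}
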