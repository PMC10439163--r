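#' Frame stacks: the universal imaging container
#'
#' A `frame_stack` holds an ordered list of pixel frames together with the
#' acquisition calibration needed to convert measurements to physical units.
#' Frames are numeric matrices (grayscale) or height x width x 3 arrays (RGB);
#' pixel intensities are arbitrary units, non-negative, and are never rescaled
#' by the package. All frames in a stack share identical dimensions.
#'
#' @param frames list of numeric matrices or h x w x 3 arrays, all the same
#'   size, finite and >= 0.
#' @param fps frames per second of the acquisition (strictly positive);
#'   required only for time-resolved outputs.
#' @param um_per_px micrometers per pixel (strictly positive); required only
#'   for outputs in physical units.
#' @param channel_tags optional named character vector mapping color plane
#'   index (as character) to a semantic stain label, e.g.
#'   `c("1" = "membrane", "2" = "annexin")`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = NULL, um_per_px = NULL,
                        channel_tags = NULL) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of matrices or h x w x 3 arrays")
  }
  dims <- lapply(frames, function(f) {
    d <- dim(f)
    if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
      stop("each frame must be a 2-D matrix or a 3-D (h x w x planes) array")
    }
    if (length(d) == 3L && !(d[3] %in% c(1L, 3L))) {
      stop("3-D frames must have 1 or 3 planes")
    }
    d
  })
  ref <- dims[[1L]]
  same <- vapply(dims, function(d) {
    length(d) == length(ref) && all(d == ref)
  }, logical(1))
  if (!all(same)) {
    stop("all frames must share identical height/width and plane count; ",
         "frame ", which(!same)[1L], " differs")
  }
  for (i in seq_along(frames)) {
    if (!all(is.finite(frames[[i]]))) {
      stop("frame ", i, " contains non-finite pixel values")
    }
  }
  if (!is.null(fps) && (!is.numeric(fps) || fps <= 0)) {
    stop("`fps` must be strictly positive")
  }
  if (!is.null(um_per_px) && (!is.numeric(um_per_px) || um_per_px <= 0)) {
    stop("`um_per_px` must be strictly positive")
  }
  structure(
    list(frames = frames, fps = fps, um_per_px = um_per_px,
         channel_tags = channel_tags),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf(
    "<frame_stack> %d frame(s), %d x %d px, %d plane(s)\n",
    n_frames(x), d[1], d[2], n_planes(x)
  ))
  if (!is.null(x$fps)) cat("  fps:       ", x$fps, "\n")
  if (!is.null(x$um_per_px)) cat("  um_per_px: ", x$um_per_px, "\n")
  if (!is.null(x$channel_tags)) {
    cat("  channels:  ",
        paste(names(x$channel_tags), x$channel_tags,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname frame_stack
#' @param stack a `frame_stack`.
#' @export
n_frames <- function(stack) length(stack$frames)

#' @rdname frame_stack
#' @export
frame_dim <- function(stack) dim(stack$frames[[1L]])[1:2]

#' @rdname frame_stack
#' @export
n_planes <- function(stack) {
  d <- dim(stack$frames[[1L]])
  if (length(d) == 2L) 1L else d[3L]
}

# Resolve a channel given as plane index, "red"/"green"/"blue", or a
# semantic tag registered in channel_tags. Returns the plane index.
resolve_channel <- function(stack, channel) {
  np <- n_planes(stack)
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
  } else {
    rgb_idx <- c(red = 1L, green = 2L, blue = 3L)
    if (channel %in% names(rgb_idx)) {
      ch <- rgb_idx[[channel]]
    } else if (!is.null(stack$channel_tags) &&
               channel %in% stack$channel_tags) {
      ch <- as.integer(names(stack$channel_tags)[
        match(channel, stack$channel_tags)])
    } else {
      stop("unknown channel: ", channel)
    }
  }
  if (ch < 1L || ch > np) {
    stop("channel ", channel, " not present (stack has ", np, " plane(s))")
  }
  ch
}

# Extract one plane of frame i as a plain matrix.
get_plane <- function(stack, i, channel = NULL) {
  f <- stack$frames[[i]]
  if (length(dim(f)) == 2L) {
    if (!is.null(channel) && resolve_channel(stack, channel) != 1L) {
      stop("grayscale stack has a single plane")
    }
    return(f)
  }
  if (is.null(channel)) {
    # grayscale view of an RGB frame: plane mean
    return((f[, , 1] + f[, , 2] + f[, , 3]) / dim(f)[3])
  }
  f[, , resolve_channel(stack, channel)]
}

# Grayscale view of frame i (mean of planes for RGB input).
gray_frame <- function(stack, i) get_plane(stack, i, channel = NULL)

#' Rectangular region of interest
#'
#' Coordinates are 0-based with x = column and y = row; the region is the
#' half-open pixel range `[x0, x0 + width) x [y0, y0 + height)`.
#'
#' @param x0,y0 top-left pixel (0-based).
#' @param width,height region size in pixels, at least 1.
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) stop("ROI width and height must be >= 1")
  if (x0 < 0 || y0 < 0) stop("ROI origin must be >= 0")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  restore_units <- function(page) {
    # undo readTIFF's [0,1] rescaling using the stored bit depth, so
    # pixel values come back as the original integer arbitrary units
    bits <- attr(page, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    m <- round(unclass(page) * (2^bits - 1))
    attributes(m) <- list(dim = dim(page))
    m
  }
  img <- switch(ext,
    tif = ,
    tiff = tryCatch(
      lapply(tiff::readTIFF(path, all = TRUE, info = TRUE), restore_units),
      error = function(e) {
        stop("cannot decode TIFF file '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }),
    png = tryCatch(list(round(png::readPNG(path) * 255)),
                   error = function(e) {
                     stop("cannot decode PNG file '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   }),
    avi = stop("AVI decoding is not supported; export the video as a ",
               "numbered TIFF/PNG frame sequence or a multi-page TIFF",
               call. = FALSE),
    stop("unsupported image format: '", path, "'", call. = FALSE)
  )
  lapply(img, function(f) {
    d <- dim(f)
    if (length(d) == 3L && d[3] >= 4L) f <- f[, , 1:3, drop = FALSE]
    if (length(d) == 3L && dim(f)[3] == 1L) f <- f[, , 1L]
    storage.mode(f) <- "double"
    f
  })
}

# Numbered-sequence ordering: sort by the numeric part of the filename when
# every file has one, otherwise lexicographically.
order_sequence <- function(files) {
  nums <- suppressWarnings(
    as.numeric(gsub("\\D", "", tools::file_path_sans_ext(basename(files))))
  )
  if (any(is.na(nums))) files[order(basename(files))] else files[order(nums)]
}

#' Load imaging data as a frame stack
#'
#' Reads a single image, a numbered image sequence (directory or explicit
#' file list), or a multi-page TIFF into a [frame_stack]. TIFF pixel values
#' are read as stored; 8-bit PNG values are returned on the 0-255 scale.
#' No rescaling or normalization is applied: intensities are arbitrary units.
#'
#' @param path_or_paths a single image file, a directory of numbered
#'   TIFF/PNG frames, or a character vector of frame files.
#' @param kind `"auto"` (default) infers from the path; `"image"`,
#'   `"sequence"` and `"video"` restrict the interpretation. Video input is
#'   accepted as a multi-page TIFF; AVI containers are not decoded.
#' @param fps,um_per_px optional acquisition calibration, attached to the
#'   returned stack.
#' @param channel_tags optional named character vector of stain labels,
#'   see [frame_stack()].
#' @return A [frame_stack] with frames in acquisition order.
#' @export
load_stack <- function(path_or_paths, kind = c("auto", "image", "sequence",
                                               "video"),
                       fps = NULL, um_per_px = NULL, channel_tags = NULL) {
  kind <- match.arg(kind)
  paths <- path_or_paths
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(paths) == 0L) {
      stop("no TIFF/PNG frames found in directory '", path_or_paths, "'")
    }
    paths <- order_sequence(paths)
  } else if (length(paths) > 1L) {
    paths <- order_sequence(paths)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input file does not exist: '", missing[1L], "'")
  }
  frames <- list()
  for (p in paths) {
    fl <- read_one_image(p)
    if (length(frames) > 0L) {
      ref <- dim(frames[[1L]]); d <- dim(fl[[1L]])
      if (length(ref) != length(d) || !all(ref == d)) {
        stop("frame size mismatch in '", p, "'")
      }
    }
    frames <- c(frames, fl)
  }
  if (kind == "image" && length(frames) != 1L) {
    stop("kind = \"image\" expects exactly one frame, got ", length(frames))
  }
  frame_stack(frames, fps = fps, um_per_px = um_per_px,
              channel_tags = channel_tags)
}

#' Crop every frame of a stack to a region of interest
#'
#' @param stack a [frame_stack].
#' @param region an [roi]; must lie fully inside the frame bounds.
#' @return A [frame_stack] with identically cropped frames and unchanged
#'   calibration metadata.
#' @export
crop_roi <- function(stack, region) {
  stopifnot(inherits(stack, "frame_stack"), inherits(region, "roi"))
  d <- frame_dim(stack)
  if (region$x0 + region$width > d[2] || region$y0 + region$height > d[1]) {
    stop("ROI extends past the frame bounds (frame is ", d[2], " x ", d[1],
         " px)")
  }
  rows <- region$y0 + seq_len(region$height)
  cols <- region$x0 + seq_len(region$width)
  frames <- lapply(stack$frames, function(f) {
    if (length(dim(f)) == 2L) f[rows, cols, drop = FALSE]
    else f[rows, cols, , drop = FALSE]
  })
  frame_stack(frames, fps = stack$fps, um_per_px = stack$um_per_px,
              channel_tags = stack$channel_tags)
}

#' Suppress static background structures such as channel walls
#'
#' `"static-median"` estimates the background once as the per-pixel median
#' over all frames; `"rolling"` uses a per-pixel running median over a
#' centered window of frames, which tolerates slow drift. The background is
#' subtracted from every frame and the result clipped at zero, so static
#' scene content (walls, debris stuck to the surface) is removed while
#' moving objects are preserved.
#'
#' @param stack a [frame_stack] with at least 2 frames.
#' @param method `"static-median"` (default) or `"rolling"`.
#' @param window odd window length (frames) for the rolling method.
#' @return A background-corrected [frame_stack].
#' @export
subtract_background <- function(stack, method = c("static-median", "rolling"),
                                window = 11L) {
  method <- match.arg(method)
  nf <- n_frames(stack)
  if (nf < 2L) stop("background subtraction requires at least 2 frames")
  np <- n_planes(stack)
  d <- frame_dim(stack)
  plane_stack <- function(p) {
    vapply(stack$frames, function(f) {
      if (length(dim(f)) == 2L) f else f[, , p]
    }, matrix(0, d[1], d[2]))
  }
  out <- lapply(seq_len(nf), function(i) {
    if (np == 1L) matrix(0, d[1], d[2]) else array(0, c(d[1], d[2], np))
  })
  for (p in seq_len(np)) {
    ps <- plane_stack(p)                 # h x w x nf
    pm <- matrix(ps, d[1] * d[2], nf)    # pixels x frames
    if (method == "static-median") {
      bg <- matrixStats_rowMedians(pm)
      for (i in seq_len(nf)) {
        res <- pmax(pm[, i] - bg, 0)
        if (np == 1L) out[[i]][] <- res else out[[i]][, , p] <- res
      }
    } else {
      half <- max(1L, (as.integer(window) - 1L) %/% 2L)
      for (i in seq_len(nf)) {
        lo <- max(1L, i - half); hi <- min(nf, i + half)
        bg <- matrixStats_rowMedians(pm[, lo:hi, drop = FALSE])
        res <- pmax(pm[, i] - bg, 0)
        if (np == 1L) out[[i]][] <- res else out[[i]][, , p] <- res
      }
    }
  }
  frame_stack(out, fps = stack$fps, um_per_px = stack$um_per_px,
              channel_tags = stack$channel_tags)
}

# Row medians without a matrixStats dependency.
matrixStats_rowMedians <- function(m) {
  apply(m, 1L, stats::median)
}

#' Write a stack to disk as TIFF
#'
#' Frames are written as one multi-page 16-bit TIFF (default) or as a
#' numbered single-page TIFF sequence. Intensities are stored losslessly for
#' integer-valued data in the 0-65535 range.
#'
#' @param stack a [frame_stack].
#' @param path output file (multi-page) or directory (sequence).
#' @param as_sequence write numbered `frame_0001.tif` files instead of one
#'   multi-page file.
#' @return Invisibly, the path(s) written.
#' @export
write_stack <- function(stack, path, as_sequence = FALSE) {
  to01 <- function(f) f / 65535
  if (as_sequence) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, sprintf("frame_%04d.tif",
                                     seq_len(n_frames(stack))))
    for (i in seq_len(n_frames(stack))) {
      tiff::writeTIFF(to01(stack$frames[[i]]), files[i],
                      bits.per.sample = 16L)
    }
    return(invisible(files))
  }
  tiff::writeTIFF(lapply(stack$frames, to01), path, bits.per.sample = 16L)
  invisible(path)
}
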