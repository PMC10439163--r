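# Reporting: indexed tabular export with descriptive statistics, annotated
# imaging with per-event indices, and standard graph generation.

# 3x5 bitmap font for digits, used to stamp event indices into images.
digit_glyphs <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111")
)

# Stamp an integer label into an RGB array at 0-based (x, y); returns array.
stamp_index <- function(arr, x, y, index, col = c(1, 1, 0)) {
  digits <- strsplit(as.character(index), "")[[1]]
  h <- dim(arr)[1]; w <- dim(arr)[2]
  for (di in seq_along(digits)) {
    glyph <- digit_glyphs[[digits[di]]]
    if (is.null(glyph)) next
    for (gy in 1:5) {
      bits <- strsplit(glyph[gy], "")[[1]]
      for (gx in 1:3) {
        if (bits[gx] == "1") {
          px <- round(x) + (di - 1L) * 4L + gx - 1L
          py <- round(y) + gy - 1L
          if (px >= 0 && px < w && py >= 0 && py < h) {
            arr[py + 1, px + 1, ] <- col
          }
        }
      }
    }
  }
  arr
}

to_rgb01 <- function(frame) {
  mx <- max(frame, 1e-9)
  if (length(dim(frame)) == 2L) {
    f <- frame / mx
    array(rep(f, 3), c(dim(frame), 3))
  } else {
    frame / mx
  }
}

#' Export an indexed event table with descriptive statistics
#'
#' Writes the records as CSV (one row per event, keyed by its index) plus a
#' companion `<stem>_stats.csv` of descriptive statistics (n, mean, s.d.,
#' min, quartiles, max) for every numeric column — pooled, and additionally
#' per sample when a `sample` column is present.
#'
#' @param records non-empty data.frame of event records.
#' @param path output CSV path.
#' @return Invisibly, c(table = path, stats = stats_path).
#' @export
export_tabular <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data.frame")
  }
  if (!("index" %in% names(records))) {
    records <- cbind(index = seq_len(nrow(records)), records)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(records, path, row.names = FALSE)
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  num <- setdiff(num, "index")
  describe <- function(d, label) {
    do.call(rbind, lapply(num, function(cl) {
      v <- d[[cl]][is.finite(d[[cl]])]
      q <- if (length(v)) stats::quantile(v, c(.25, .5, .75)) else
        rep(NA_real_, 3)
      data.frame(sample = label, column = cl, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 min = if (length(v)) min(v) else NA_real_,
                 q25 = q[[1]], median = q[[2]], q75 = q[[3]],
                 max = if (length(v)) max(v) else NA_real_)
    }))
  }
  stats_df <- describe(records, "pooled")
  if ("sample" %in% names(records)) {
    for (s in unique(records$sample)) {
      stats_df <- rbind(stats_df,
                        describe(records[records$sample == s, , drop = FALSE],
                                 s))
    }
  }
  stats_path <- file.path(dir, paste0(
    tools::file_path_sans_ext(basename(path)), "_stats.csv"))
  utils::write.csv(stats_df, stats_path, row.names = FALSE)
  invisible(c(table = path, stats = stats_path))
}

#' Annotate imaging with per-event indices and optional trajectories
#'
#' Each event is marked at its centroid with a colored marker and its index
#' stamped beside it, so image labels match the exported table rows.
#' Trajectory mode additionally draws each cell's path. Output is one PNG
#' per frame (`<stem>_0001.png`, ...), or a single PNG for one-frame
#' stacks.
#'
#' @param stack the [frame_stack] that was analyzed.
#' @param records data.frame with `x`, `y`, and an index column (`cell_id`
#'   or `index`); an optional `frame` column restricts each label to its
#'   frame.
#' @param path output PNG path (stem used for multi-frame stacks).
#' @param trajectories optional detections data.frame (`cell_id`, `frame`,
#'   `x`, `y`) whose paths are drawn.
#' @return Invisibly, the file(s) written.
#' @export
annotate_media <- function(stack, records, path, trajectories = NULL) {
  idx_col <- if ("cell_id" %in% names(records)) "cell_id" else "index"
  d <- frame_dim(stack)
  nf <- n_frames(stack)
  files <- character(0)
  for (f in seq_len(nf)) {
    arr <- to_rgb01(stack$frames[[f]])
    if (!is.null(trajectories)) {
      for (id in unique(trajectories$cell_id)) {
        tr <- trajectories[trajectories$cell_id == id &
                             trajectories$frame <= f, , drop = FALSE]
        tr <- tr[order(tr$frame), , drop = FALSE]
        if (nrow(tr) >= 2L) {
          for (s in seq_len(nrow(tr) - 1L)) {
            pts <- bresenham(tr$x[s], tr$y[s], tr$x[s + 1L], tr$y[s + 1L])
            ok <- pts[, 1] >= 0 & pts[, 1] < d[2] &
              pts[, 2] >= 0 & pts[, 2] < d[1]
            if (any(ok)) {
              arr[cbind(pts[ok, 2] + 1, pts[ok, 1] + 1, 1)] <- 0
              arr[cbind(pts[ok, 2] + 1, pts[ok, 1] + 1, 2)] <- 1
              arr[cbind(pts[ok, 2] + 1, pts[ok, 1] + 1, 3)] <- 1
            }
          }
        }
      }
    }
    recs <- records
    if ("frame" %in% names(records)) {
      recs <- records[records$frame == f, , drop = FALSE]
    }
    for (r in seq_len(nrow(recs))) {
      x <- recs$x[r]; y <- recs$y[r]
      if (is.na(x) || is.na(y) || x < 0 || y < 0 || x > d[2] - 1 ||
          y > d[1] - 1) {
        warning("event ", recs[[idx_col]][r],
                ": coordinate outside frame; skipped", call. = FALSE)
        next
      }
      # red cross marker
      for (o in -2:2) {
        px <- round(x) + o; py <- round(y)
        if (px >= 0 && px < d[2]) arr[py + 1, px + 1, ] <- c(1, 0, 0)
        px <- round(x); py <- round(y) + o
        if (py >= 0 && py < d[1]) arr[py + 1, px + 1, ] <- c(1, 0, 0)
      }
      arr <- stamp_index(arr, x + 4, y - 6, recs[[idx_col]][r])
    }
    out <- if (nf == 1L) path else {
      file.path(dirname(path),
                sprintf("%s_%04d.png",
                        tools::file_path_sans_ext(basename(path)), f))
    }
    if (!dir.exists(dirname(out))) dir.create(dirname(out), recursive = TRUE)
    png::writePNG(pmin(pmax(arr, 0), 1), out)
    files <- c(files, out)
  }
  invisible(files)
}

#' Generate standard graphs from event records
#'
#' @param records data.frame of event records.
#' @param kinds any of `"histogram"`, `"scatter"`, `"pairplot"`,
#'   `"timecourse"`, `"profile"`.
#' @param dir output directory for the PNG files.
#' @param features numeric columns to plot (default: all numeric columns
#'   except indices).
#' @param x,y columns for `"scatter"`; `"timecourse"` expects `time_min` /
#'   `occlusion_pct` / `channel` columns; `"profile"` expects
#'   `bin_center_um` / `mean_velocity_um_s`.
#' @return Invisibly, the figure files written.
#' @export
make_graphs <- function(records, kinds, dir, features = NULL,
                        x = NULL, y = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  num <- setdiff(num, c("index", "cell_id", "frame", "timepoint"))
  if (is.null(features)) features <- num
  bad <- setdiff(features, num)
  if (length(bad) > 0L) {
    stop("requested column is not numeric: '", bad[1L], "'")
  }
  files <- character(0)
  save_fig <- function(p, name) {
    f <- file.path(dir, paste0(name, ".png"))
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 100)
    files <<- c(files, f)
  }
  for (kind in kinds) {
    if (kind == "histogram") {
      for (cl in features) {
        p <- ggplot2::ggplot(records,
                             ggplot2::aes(x = .data[[cl]])) +
          ggplot2::geom_histogram(bins = 30, fill = "grey35") +
          ggplot2::theme_minimal()
        save_fig(p, paste0("hist_", cl))
      }
    } else if (kind == "scatter") {
      xs <- if (is.null(x)) features[1L] else x
      ys <- if (is.null(y)) features[min(2L, length(features))] else y
      p <- ggplot2::ggplot(records,
                           ggplot2::aes(x = .data[[xs]], y = .data[[ys]])) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::theme_minimal()
      save_fig(p, paste0("scatter_", xs, "_", ys))
    } else if (kind == "pairplot") {
      # grid of pairwise scatter plots with histograms on the diagonal
      plots <- list()
      for (a in features) {
        for (b in features) {
          plots[[length(plots) + 1L]] <- if (a == b) {
            ggplot2::ggplot(records, ggplot2::aes(x = .data[[a]])) +
              ggplot2::geom_histogram(bins = 20, fill = "grey35") +
              ggplot2::theme_minimal()
          } else {
            ggplot2::ggplot(records, ggplot2::aes(x = .data[[b]],
                                                  y = .data[[a]])) +
              ggplot2::geom_point(size = 0.5, alpha = 0.5) +
              ggplot2::theme_minimal()
          }
        }
      }
      p <- patchwork::wrap_plots(plots, ncol = length(features))
      save_fig(p, "pairplot")
    } else if (kind == "timecourse") {
      p <- ggplot2::ggplot(records,
                           ggplot2::aes(x = .data[["time_min"]],
                                        y = .data[["occlusion_pct"]],
                                        color = .data[["channel"]])) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::theme_minimal()
      save_fig(p, "timecourse")
    } else if (kind == "profile") {
      p <- ggplot2::ggplot(records,
                           ggplot2::aes(x = .data[["bin_center_um"]],
                                        y = .data[["mean_velocity_um_s"]])) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::theme_minimal()
      save_fig(p, "profile")
    } else {
      stop("unknown graph kind: '", kind, "'")
    }
  }
  invisible(files)
}
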