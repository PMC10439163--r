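# Config-driven workflow orchestration: flat-text run configs, end-to-end
# pipelines that write tables / annotated media / graphs, and a
# parameter-sweep harness for sensitivity analysis.

#' Read and write flat key-value run configs
#'
#' The config dialect is one `key = value` per line; `#` starts a comment.
#' Values are parsed as logical (`true`/`false`), number, comma-separated
#' numeric vector, or string, in that order of preference. Write followed
#' by read is idempotent.
#'
#' @param path config file path.
#' @return named list of parameter values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("malformed config line: '", ln, "'")
    cfg[[trimws(kv[2])]] <- parse_config_value(trimws(kv[3]))
  }
  cfg
}

parse_config_value <- function(v) {
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  if (grepl(",", v)) {
    parts <- trimws(strsplit(v, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    return(if (anyNA(nums)) parts else nums)
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) num else v
}

#' @rdname read_config
#' @param config named list of parameter values.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(tolower(as.character(v)))
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ", ")
  }
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

workflow_names <- c("track", "profile", "adhesion_brightfield",
                    "adhesion_fluorescent", "adhesion_protrusion",
                    "adhesion_transient", "occlusion_surface",
                    "occlusion_device", "occlusion_microchannel",
                    "cluster")

load_workflow_stack <- function(config) {
  stack <- load_stack(config$input,
                      fps = cfg_get(config, "fps"),
                      um_per_px = cfg_get(config, "um_per_px"))
  if (!is.null(config$roi)) {
    r <- config$roi
    stack <- crop_roi(stack, roi(r[1], r[2], r[3], r[4]))
  }
  bg <- cfg_get(config, "background", "none")
  if (bg != "none") stack <- subtract_background(stack, method = bg)
  stack
}

#' Run a named analysis workflow end to end
#'
#' Executes one of the pipelines (`track`, `profile`,
#' `adhesion_brightfield`, `adhesion_fluorescent`, `adhesion_protrusion`,
#' `adhesion_transient`, `occlusion_surface`, `occlusion_device`,
#' `occlusion_microchannel`, `cluster`)
#' with all parameters taken from the config, then writes the indexed event
#' table with descriptive statistics, annotated imaging, standard graphs,
#' and a log of every effective parameter into the output directory.
#'
#' @param config named list (see [read_config()]); required keys: `workflow`,
#'   `input` (path, or comma list for `cluster`), `out_dir`. All remaining
#'   parameters default sensibly and are recorded in the run log.
#' @param write_outputs set `FALSE` to skip file outputs (used by
#'   [parameter_sweep()]).
#' @return list with `records` (main event table), `workflow`, and
#'   workflow-specific extras (`profile`, `series`, `cluster`, ...).
#' @export
run_workflow <- function(config, write_outputs = TRUE) {
  wf <- config$workflow
  if (is.null(wf) || !(wf %in% workflow_names)) {
    stop("unknown workflow: '", if (is.null(wf)) "<missing>" else wf,
         "' (expected one of: ", paste(workflow_names, collapse = ", "), ")")
  }
  if (is.null(config$input)) stop("config key `input` is required")
  seed <- cfg_get(config, "seed", 1)
  out_dir <- cfg_get(config, "out_dir", ".")
  result <- switch(
    wf,
    track = wf_track(config),
    profile = wf_profile(config),
    adhesion_brightfield = wf_adhesion_brightfield(config),
    adhesion_fluorescent = wf_adhesion_fluorescent(config),
    adhesion_protrusion = wf_adhesion_protrusion(config),
    adhesion_transient = wf_adhesion_transient(config),
    occlusion_surface = wf_occlusion(config, kind = "surface"),
    occlusion_device = wf_occlusion(config, kind = "device"),
    occlusion_microchannel = wf_occlusion(config, kind = "microchannel"),
    cluster = wf_cluster(config, seed)
  )
  result$workflow <- wf
  if (write_outputs) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(result$records) && nrow(result$records) > 0L) {
      export_tabular(result$records, file.path(out_dir, "events.csv"))
      num <- names(result$records)[vapply(result$records, is.numeric,
                                          logical(1))]
      feats <- setdiff(num, c("index", "cell_id", "frame", "timepoint"))
      if (length(feats) > 0L) {
        make_graphs(result$records, "histogram", out_dir,
                    features = utils::head(feats, 4))
      }
      if (!is.null(result$stack) &&
          all(c("x", "y") %in% names(result$records))) {
        annotate_media(result$stack, result$records,
                       file.path(out_dir, "annotated.png"),
                       trajectories = result$trajectories)
      }
    }
    if (!is.null(result$profile)) {
      utils::write.csv(result$profile$bins,
                       file.path(out_dir, "profile.csv"), row.names = FALSE)
      make_graphs(result$profile$bins[
        !is.na(result$profile$bins$mean_velocity_um_s), ],
        "profile", out_dir)
    }
    if (!is.null(result$series)) {
      utils::write.csv(result$series, file.path(out_dir, "series.csv"),
                       row.names = FALSE)
      make_graphs(result$series, "timecourse", out_dir)
    }
    if (!is.null(result$spatial)) {
      utils::write.csv(result$spatial,
                       file.path(out_dir, "spatial_occlusion.csv"),
                       row.names = FALSE)
    }
    if (!is.null(result$scree)) {
      utils::write.csv(result$scree$inertia_by_k,
                       file.path(out_dir, "scree.csv"), row.names = FALSE)
    }
    if (!is.null(result$cluster)) {
      utils::write.csv(as.data.frame(result$cluster$frequency_table),
                       file.path(out_dir, "frequency_table.csv"),
                       row.names = FALSE)
    }
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      paste0("workflow = ", wf),
      paste0("timestampless deterministic run, seed = ", seed),
      paste0("package = microflowq ",
             as.character(utils::packageVersion("microflowq"))),
      paste0("R = ", R.version.string),
      "",
      "# effective parameters",
      vapply(names(config), function(k) {
        paste0(k, " = ", paste(format(config[[k]]), collapse = ", "))
      }, character(1))
    ), log_path)
    write_config(config, file.path(out_dir, "config_used.txt"))
  }
  invisible(result)
}

wf_track <- function(config) {
  stack <- load_workflow_stack(config)
  det <- detect_particles_stack(
    stack,
    diameter = cfg_get(config, "diameter", 9),
    min_mass = cfg_get(config, "min_mass", 0),
    max_diameter = cfg_get(config, "max_diameter"),
    min_intensity = cfg_get(config, "min_intensity"),
    invert = cfg_get(config, "invert", FALSE)
  )
  ts <- link_and_filter(det,
                        search_range_px = cfg_get(config, "search_range", 10),
                        memory_frames = cfg_get(config, "memory", 0),
                        min_frames = cfg_get(config, "min_frames", 2),
                        min_distance_px = cfg_get(config, "min_distance", 0))
  rec <- compute_cell_velocity(ts, fps = config$fps,
                               um_per_px = config$um_per_px,
                               mode = cfg_get(config, "mode", "free"))
  ch <- cfg_get(config, "fluorescence_channel")
  if (!is.null(ch)) {
    fl <- measure_cell_fluorescence(
      ts, stack, ch,
      aperture_radius_px = cfg_get(config, "aperture_radius", 5))
    rec <- merge(rec, fl, by = "cell_id")
  }
  rec$x <- rec$x_first; rec$y <- rec$y_first
  list(records = rec, stack = stack, trajectories = ts$detections)
}

wf_profile <- function(config) {
  stack <- load_workflow_stack(config)
  ft <- detect_and_track_flow(
    stack,
    max_features = cfg_get(config, "max_features", 300),
    quality = cfg_get(config, "quality", 0.05),
    min_corner_sep_px = cfg_get(config, "min_corner_sep", 5),
    window_size_px = cfg_get(config, "window", 15),
    reseed_every = cfg_get(config, "reseed_every", 10))
  tc <- summarize_timecourse(ft, fps = config$fps,
                             um_per_px = config$um_per_px,
                             min_step_px = cfg_get(config, "min_step", 0))
  span <- cfg_get(config, "channel_span",
                  c(0, frame_dim(stack)[1] - 1))
  pr <- build_velocity_profile(ft, channel_span = span,
                               bin_width_um = cfg_get(config,
                                                      "bin_width_um", 5),
                               fps = config$fps,
                               um_per_px = config$um_per_px)
  list(records = tc, profile = pr, features = ft, stack = stack)
}

wf_adhesion_brightfield <- function(config) {
  stack <- load_workflow_stack(config)
  res <- measure_brightfield_cells(
    gray_frame(stack, 1L),
    expected_diameter_px = cfg_get(config, "diameter", 15),
    min_area_um2 = cfg_get(config, "min_area_um2", 0),
    max_area_um2 = cfg_get(config, "max_area_um2", Inf),
    invert = cfg_get(config, "invert", FALSE),
    um_per_px = config$um_per_px,
    min_mass = cfg_get(config, "min_mass", 0))
  list(records = res$cells, field_density = res$field_density,
       stack = stack)
}

wf_adhesion_fluorescent <- function(config) {
  stack <- load_workflow_stack(config)
  cells <- measure_fluorescent_cells(
    stack,
    membrane_channel = cfg_get(config, "membrane_channel", "red"),
    membrane_threshold = cfg_get(config, "membrane_threshold", 50),
    secondary_channel = cfg_get(config, "secondary_channel"),
    secondary_threshold = cfg_get(config, "secondary_threshold", 0),
    lobe_channel = cfg_get(config, "lobe_channel"),
    lobe_threshold = cfg_get(config, "lobe_threshold", 0),
    min_peak_sep_px = cfg_get(config, "min_peak_sep", 5),
    min_area_um2 = cfg_get(config, "min_area_um2", 0),
    max_area_um2 = cfg_get(config, "max_area_um2", Inf),
    um_per_px = config$um_per_px)
  list(records = cells, stack = stack)
}

wf_adhesion_protrusion <- function(config) {
  stack <- load_workflow_stack(config)
  thr <- cfg_get(config, "membrane_threshold", 50)
  mem <- get_plane(stack, 1L, cfg_get(config, "membrane_channel", "red"))
  lab <- label_regions(mem > thr)
  um <- config$um_per_px
  min_a <- cfg_get(config, "min_area_um2", 0)
  max_a <- cfg_get(config, "max_area_um2", Inf)
  rows <- list()
  for (i in seq_len(max(lab))) {
    mask <- lab == i
    area_um2 <- sum(mask) * um^2
    if (area_um2 < min_a || area_um2 > max_a) next
    pix <- which(mask, arr.ind = TRUE)
    pr <- count_protrusions(
      mask,
      corner_sharpness = cfg_get(config, "sharpness", 0.2),
      min_separation_px = cfg_get(config, "min_separation", 6),
      um_per_px = um)
    rows[[length(rows) + 1L]] <- data.frame(
      x = mean(pix[, 2L] - 1), y = mean(pix[, 1L] - 1),
      area_um2 = area_um2,
      protrusion_count = pr$protrusion_count,
      protrusion_dist_min_um = pr$dist_min_um,
      protrusion_dist_mean_um = pr$dist_mean_um,
      protrusion_dist_max_um = pr$dist_max_um)
  }
  cells <- do.call(rbind, rows)
  if (!is.null(cells)) {
    cells <- cells[order(round(cells$y), cells$x), , drop = FALSE]
    cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
    rownames(cells) <- NULL
  }
  list(records = cells, stack = stack)
}

wf_adhesion_transient <- function(config) {
  stack <- load_workflow_stack(config)
  rec <- measure_transient_adhesion(
    stack,
    expected_diameter_px = cfg_get(config, "diameter", 9),
    min_mass = cfg_get(config, "min_mass", 0),
    max_intensity = cfg_get(config, "max_intensity", Inf),
    min_frames = cfg_get(config, "min_frames", 3),
    fps = config$fps,
    search_range_px = cfg_get(config, "search_range", 5),
    memory_frames = cfg_get(config, "memory", 1))
  rec$x <- rec$x_first; rec$y <- rec$y_first
  list(records = rec, stack = stack)
}

wf_occlusion <- function(config, kind) {
  stack <- load_workflow_stack(config)
  thr <- unlist(list(red = cfg_get(config, "threshold_red"),
                     green = cfg_get(config, "threshold_green"),
                     blue = cfg_get(config, "threshold_blue")))
  if (length(thr) == 0L) stop("no channel thresholds given")
  masks <- binarize_channels(stack, thr)
  map <- build_device_map(masks,
                          map_threshold = cfg_get(config, "map_threshold",
                                                  1))
  ts <- cfg_get(config, "timestamps_min",
                seq(0, by = cfg_get(config, "dt_min", 1),
                    length.out = n_frames(stack)))
  um <- cfg_get(config, "um_per_px", 1)
  if (kind == "surface") {
    # surface assay: the whole field of view is the region of interest
    map$mask[] <- TRUE
  }
  spatial <- NULL
  if (kind == "microchannel") {
    map <- detect_microchannels(map)
    oc <- compute_occlusion_accumulation(masks, map, ts, um_per_px = um,
                                         channel = 1L)
    last_mask <- masks$masks[[n_frames(stack)]][[masks$channels[1L]]]
    spatial <- do.call(rbind, lapply(seq_along(map$channels), function(i) {
      cbind(channel_id = i,
            spatial_occlusion(last_mask, map$channels[[i]]))
    }))
  } else {
    oc <- compute_occlusion_accumulation(masks, map, ts, um_per_px = um)
  }
  list(records = oc$series, series = oc$series, rates = oc$rates,
       map = map, spatial = spatial, stack = stack)
}

wf_cluster <- function(config, seed) {
  inputs <- config$input
  tables <- as.list(inputs)
  features <- config$features
  if (is.null(features)) stop("config key `features` is required")
  fm <- assemble_feature_matrix(tables, features,
                                standardize = cfg_get(config, "standardize",
                                                      TRUE))
  k_max <- cfg_get(config, "k_max", 8)
  scree <- scree_analysis(fm, k_max = k_max, seed = seed)
  k <- cfg_get(config, "k", scree$suggested_k)
  cr <- cluster_kmeans(fm, n_clusters = k, seed = seed)
  records <- data.frame(sample = fm$sample_labels, cluster = cr$labels)
  records <- cbind(records, as.data.frame(fm$points))
  list(records = records, cluster = cr, scree = scree, fm = fm)
}

#' Parameter sweep for sensitivity analysis
#'
#' Re-runs a workflow once per point of a parameter grid and tabulates
#' summary outputs (event count and per-column means) against the parameter
#' values, in long format. Used to verify that reasonable parameter changes
#' do not change the interpretation of results.
#'
#' @param config base workflow config.
#' @param param_grid named list of parameter value vectors; the grid is
#'   their full crossing.
#' @return long-format data.frame: one row per grid point per summary
#'   metric, with the parameter columns, `metric`, `value`.
#' @export
parameter_sweep <- function(config, param_grid) {
  stopifnot(length(param_grid) > 0L, !is.null(names(param_grid)))
  grid <- expand.grid(param_grid, stringsAsFactors = FALSE)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    for (p in names(param_grid)) cfg[[p]] <- grid[[p]][g]
    res <- run_workflow(cfg, write_outputs = FALSE)
    rec <- res$records
    metrics <- c(n_events = if (is.null(rec)) 0 else nrow(rec))
    if (!is.null(rec) && nrow(rec) > 0L) {
      num <- names(rec)[vapply(rec, is.numeric, logical(1))]
      num <- setdiff(num, c("index", "cell_id", "frame", "timepoint"))
      for (cl in num) {
        metrics[[paste0("mean_", cl)]] <- mean(rec[[cl]], na.rm = TRUE)
      }
    }
    for (m in names(metrics)) {
      row <- grid[g, , drop = FALSE]
      row$metric <- m
      row$value <- metrics[[m]]
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
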