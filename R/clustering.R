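# Unsupervised interpretation of pooled feature tables: k-means with
# scree-based k suggestion, silhouette diagnostics, and per-sample cluster
# frequency tables ready for contingency testing.

#' Assemble a pooled, optionally standardized feature matrix
#'
#' Concatenates one or several per-sample feature tables (CSV files or data
#' frames, e.g. the indexed tables written by [export_tabular()]) into one
#' point-by-feature matrix, remembering the sample label of every point.
#' Rows with missing values in the selected features are dropped (with a
#' message). With `standardize = TRUE` (default) each feature is
#' transformed to zero mean and unit standard deviation over the pooled
#' points, which puts mixed-unit features (square micrometers, micrometers
#' per second, arbitrary intensity units) on a common Euclidean scale.
#'
#' @param tables named list of data.frames and/or CSV file paths; names are
#'   the sample labels (file base names are used when unnamed).
#' @param selected_features character vector of feature column names; must
#'   be present and numeric in every table.
#' @param standardize center and scale each feature over the pooled points.
#' @return object of class `feature_matrix`: list with `points` (n x p
#'   matrix), `feature_names`, `sample_labels` (length n), `center`,
#'   `scale` (per-feature standardization record), `n_dropped`.
#' @export
assemble_feature_matrix <- function(tables, selected_features,
                                    standardize = TRUE) {
  if (!is.list(tables) || length(tables) == 0L) {
    stop("`tables` must be a non-empty list of data frames or file paths")
  }
  labels <- names(tables)
  if (is.null(labels)) labels <- rep("", length(tables))
  parts <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    src <- if (is.character(tb)) tb else sprintf("tables[[%d]]", i)
    if (is.character(tb)) {
      if (!file.exists(tb)) stop("input table does not exist: '", tb, "'")
      lab <- if (labels[i] == "") {
        tools::file_path_sans_ext(basename(tb))
      } else labels[i]
      tb <- utils::read.csv(tb, check.names = FALSE)
    } else {
      lab <- if (labels[i] == "") sprintf("sample_%d", i) else labels[i]
    }
    miss <- setdiff(selected_features, names(tb))
    if (length(miss) > 0L) {
      stop("feature column '", miss[1L], "' is missing from ", src)
    }
    sub <- tb[, selected_features, drop = FALSE]
    for (cl in selected_features) {
      if (!is.numeric(sub[[cl]])) {
        stop("feature column '", cl, "' in ", src, " is not numeric")
      }
    }
    parts[[i]] <- list(points = as.matrix(sub), label = lab)
  }
  points <- do.call(rbind, lapply(parts, `[[`, "points"))
  sample_labels <- rep(vapply(parts, `[[`, "", "label"),
                       vapply(parts, function(p) nrow(p$points),
                              integer(1)))
  complete <- stats::complete.cases(points)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " row(s) with missing feature values")
    points <- points[complete, , drop = FALSE]
    sample_labels <- sample_labels[complete]
  }
  center <- rep(0, ncol(points)); scale <- rep(1, ncol(points))
  if (standardize) {
    center <- colMeans(points)
    scale <- apply(points, 2L, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
    points <- sweep(sweep(points, 2L, center), 2L, scale, "/")
  }
  dimnames(points) <- list(NULL, selected_features)
  structure(
    list(points = points, feature_names = selected_features,
         sample_labels = sample_labels, center = center, scale = scale,
         n_dropped = n_dropped),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d points x %d features, %d sample(s)\n",
              nrow(x$points), ncol(x$points),
              length(unique(x$sample_labels))))
  invisible(x)
}

# Seeded k-means with multiple k-means++-style restarts (via nstart).
seeded_kmeans <- function(points, k, seed, nstart = 10) {
  set.seed(seed)
  if (k == 1L) {
    ctr <- colMeans(points)
    ss <- sum(sweep(points, 2L, ctr)^2)
    return(list(cluster = rep(1L, nrow(points)), tot.withinss = ss,
                centers = matrix(ctr, 1L)))
  }
  stats::kmeans(points, centers = k, nstart = nstart, iter.max = 100L)
}

#' Scree analysis: within-cluster sum of squares over k
#'
#' Runs seeded k-means for `k = 1..k_max` and records the inertia
#' (within-cluster sum of squares). The suggested number of clusters is the
#' elbow of the scree curve, located as the k maximizing the second
#' difference of inertia; it is advisory only.
#'
#' @param fm a `feature_matrix`.
#' @param k_max largest k to evaluate (must be < number of points).
#' @param seed random seed.
#' @return list with `inertia_by_k` (data.frame `k`, `inertia`) and
#'   `suggested_k`.
#' @export
scree_analysis <- function(fm, k_max = 10, seed = 1) {
  n <- nrow(fm$points)
  if (k_max >= n) stop("`k_max` must be smaller than the number of points")
  inertia <- vapply(seq_len(k_max), function(k) {
    seeded_kmeans(fm$points, k, seed = seed + k)$tot.withinss
  }, numeric(1))
  suggested <- if (k_max >= 3L) {
    ks <- 2:(k_max - 1L)
    d2 <- inertia[ks - 1L] - 2 * inertia[ks] + inertia[ks + 1L]
    ks[which.max(d2)]
  } else {
    NA_integer_
  }
  list(inertia_by_k = data.frame(k = seq_len(k_max), inertia = inertia),
       suggested_k = suggested)
}

#' Mean silhouette coefficient
#'
#' Mean over points of `(b - a) / max(a, b)` with `a` the mean distance to
#' the point's own cluster and `b` the smallest mean distance to any other
#' cluster; values near 1 indicate well-separated clusters.
#'
#' @param points n x p numeric matrix.
#' @param labels integer cluster label per point (>= 2 distinct values).
#' @return the mean silhouette coefficient, in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels) {
  labs <- sort(unique(labels))
  if (length(labs) < 2L) return(NA_real_)
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  sil <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) { sil[i] <- 0; next }
    a <- sum(dm[i, labels == own]) / (sizes[[as.character(own)]] - 1L)
    b <- min(vapply(labs[labs != own], function(l) {
      mean(dm[i, labels == l])
    }, numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' K-means clustering with diagnostics and per-sample frequency table
#'
#' Seeded k-means with multiple restarts; cluster ids are renumbered in
#' descending cluster size so labels are stable across runs. Returns labels,
#' the mean silhouette coefficient, and a sample-by-cluster contingency
#' table suitable for downstream Chi-squared analysis.
#'
#' @param fm a `feature_matrix`.
#' @param n_clusters requested number of clusters (`2 <= k < n`; `k = 1` is
#'   allowed but the silhouette is then undefined).
#' @param seed random seed.
#' @return object of class `cluster_result`: list with `labels`,
#'   `centers` (on the standardized scale), `inertia`, `silhouette`,
#'   `frequency_table` (sample label x cluster counts), `sample_labels`.
#' @export
cluster_kmeans <- function(fm, n_clusters, seed = 1) {
  n <- nrow(fm$points)
  if (n_clusters >= n) stop("`n_clusters` must be smaller than n points")
  if (n_clusters < 1L) stop("`n_clusters` must be >= 1")
  km <- seeded_kmeans(fm$points, n_clusters, seed = seed)
  labels <- km$cluster
  # renumber ids in descending cluster size; ties broken by center
  # coordinates so labels are invariant to point order
  sizes <- tabulate(labels, nbins = n_clusters)
  ctr <- km$centers
  ord <- do.call(order, c(list(-sizes),
                          lapply(seq_len(ncol(ctr)),
                                 function(j) ctr[, j])))
  new_id <- integer(n_clusters)
  new_id[ord] <- seq_len(n_clusters)
  labels <- new_id[labels]
  centers <- km$centers[order(new_id), , drop = FALSE]
  sil <- if (n_clusters >= 2L) silhouette_mean(fm$points, labels) else
    NA_real_
  freq <- table(sample = fm$sample_labels, cluster = labels)
  structure(
    list(labels = labels, centers = centers,
         inertia = km$tot.withinss, silhouette = sil,
         frequency_table = freq, sample_labels = fm$sample_labels),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf("<cluster_result> k = %d, inertia = %.3f, silhouette = %s\n",
              k, x$inertia,
              if (is.na(x$silhouette)) "undefined" else
                sprintf("%.3f", x$silhouette)))
  print(x$frequency_table)
  invisible(x)
}
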