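# Shared helpers for building tiny in-code fixtures.

# Rasterized disk image (0-based center), intensity on black background.
disk_image <- function(h, w, cx, cy, r, intensity = 150) {
  dx <- outer(rep(1, h), (0:(w - 1)) - cx)
  dy <- outer((0:(h - 1)) - cy, rep(1, w))
  m <- matrix(0, h, w)
  m[dx^2 + dy^2 <= r^2] <- intensity
  m
}

# Rasterized axis-aligned ellipse image.
ellipse_image <- function(h, w, cx, cy, a, b, intensity = 150) {
  dx <- outer(rep(1, h), (0:(w - 1)) - cx)
  dy <- outer((0:(h - 1)) - cy, rep(1, w))
  m <- matrix(0, h, w)
  m[(dx / a)^2 + (dy / b)^2 <= 1] <- intensity
  m
}

# Independent exhaustive count of strict 8-neighbour local maxima.
count_strict_maxima <- function(m, threshold = 0) {
  nr <- nrow(m); nc <- ncol(m)
  cnt <- 0L
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      v <- m[i, j]
      if (v <= threshold) next
      nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v > max(nb[-5])) cnt <- cnt + 1L
    }
  }
  cnt
}

# Independent intensity-moment eccentricity, computed directly on pixels.
pixel_moment_ecc <- function(img, threshold = 0) {
  pix <- which(img > threshold, arr.ind = TRUE)
  xs <- pix[, 2] - 1; ys <- pix[, 1] - 1
  w <- img[pix]
  m <- sum(w)
  cx <- sum(w * xs) / m; cy <- sum(w * ys) / m
  mu20 <- sum(w * (xs - cx)^2) / m
  mu02 <- sum(w * (ys - cy)^2) / m
  mu11 <- sum(w * (xs - cx) * (ys - cy)) / m
  tr <- mu20 + mu02
  disc <- sqrt(max(tr^2 / 4 - (mu20 * mu02 - mu11^2), 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  sqrt(max(1 - l2 / l1, 0))
}

# Brute-force mean silhouette from first principles (double loop).
brute_silhouette <- function(points, labels) {
  n <- nrow(points)
  dm <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(dm[i, own]) / (sum(own) - 1)
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dm[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Match detections to truth positions within a tolerance; returns a list
# with recall, precision, and rmse of matched centroid errors.
match_detections <- function(det, truth, tol = 2) {
  used <- rep(FALSE, nrow(det))
  errs <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$x - truth$x[i])^2 + (det$y - truth$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) == 1L && d2[j] <= tol^2) {
      used[j] <- TRUE
      errs <- c(errs, sqrt(d2[j]))
    }
  }
  list(recall = length(errs) / nrow(truth),
       precision = length(errs) / nrow(det),
       rmse = if (length(errs)) sqrt(mean(errs^2)) else NA_real_)
}
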