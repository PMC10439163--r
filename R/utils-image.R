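# Internal image primitives shared by all analysis modules.
#
# Convention used across the package: pixel coordinates are 0-based with
# x = column index increasing rightward and y = row index increasing
# downward. R matrices are indexed [row, col] = [y + 1, x + 1].

# Separable convolution with replicate (edge-extend) padding.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  mp <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * mp[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  mp <- out[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * mp[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_blur <- function(m, sigma) conv_sep(m, gauss_kernel(sigma))

# width must be odd
box_blur <- function(m, width) conv_sep(m, rep(1 / width, width))

# Grayscale dilation: running max over a (2*half+1) square window.
dilate_max <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m); r <- half
  mp <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- matrix(-Inf, nr, nc)
  for (i in 0:(2 * r)) {
    out <- pmax(out, mp[i + seq_len(nr), , drop = FALSE])
  }
  mp <- out[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out <- matrix(-Inf, nr, nc)
  for (i in 0:(2 * r)) {
    out <- pmax(out, mp[, i + seq_len(nc), drop = FALSE])
  }
  out
}

# Connected-component labelling with 8-connectivity.
# EBImage::bwlabel is 4-connected; labels touching diagonally are merged
# afterwards with a union-find pass over diagonal adjacencies.
label_regions <- function(mask) {
  mask <- mask != 0
  storage.mode(mask) <- "integer"
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # \ diagonal
  cc <- lab[-1, -nc]; d <- lab[-nr, -1]    # / diagonal
  keep1 <- a > 0L & b > 0L & a != b
  keep2 <- cc > 0L & d > 0L & cc != d
  pairs <- rbind(cbind(a[keep1], b[keep1]), cbind(cc[keep2], d[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1L]); rj <- find(pairs[r, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  compact <- match(root, sort(unique(root)))
  lab[lab > 0L] <- compact[lab[lab > 0L]]
  lab
}

# Local maxima of img (optionally restricted to mask) above threshold,
# with candidates closer than min_sep suppressed keeping the strongest.
# Returns data.frame(x, y, value) in 0-based coordinates.
find_peaks <- function(img, mask = NULL, threshold = -Inf, min_sep = 1) {
  dil <- dilate_max(img, 1L)
  is_peak <- img >= dil & img > threshold
  if (!is.null(mask)) is_peak <- is_peak & (mask != 0)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  }
  val <- img[is_peak]
  ord <- order(val, decreasing = TRUE)
  xs <- idx[ord, 2L] - 1; ys <- idx[ord, 1L] - 1; vals <- val[ord]
  keep <- logical(length(xs))
  for (i in seq_along(xs)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep[seq_len(i - 1L)])
    d2 <- (xs[sel] - xs[i])^2 + (ys[sel] - ys[i])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  data.frame(x = xs[keep], y = ys[keep], value = vals[keep])
}

# Bilinear interpolation at continuous 0-based (x, y); NA outside the frame.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 2 + (fx == 0) & y0 <= nr - 2 + (fy == 0)
  # clamp indices so subscripting stays legal; invalid entries overwritten
  x0c <- pmin(pmax(x0, 0), nc - 1); y0c <- pmin(pmax(y0, 0), nr - 1)
  x1c <- pmin(x0c + 1, nc - 1);     y1c <- pmin(y0c + 1, nr - 1)
  i00 <- cbind(y0c + 1, x0c + 1); i01 <- cbind(y0c + 1, x1c + 1)
  i10 <- cbind(y1c + 1, x0c + 1); i11 <- cbind(y1c + 1, x1c + 1)
  v <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
  v[!ok] <- NA_real_
  v
}

# Intensity-weighted central second moments -> eccentricity in [0, 1).
# xs, ys are 0-based coordinates, w non-negative weights.
moment_eccentricity <- function(xs, ys, w = rep(1, length(xs))) {
  m <- sum(w)
  if (m <= 0 || length(xs) < 2L) return(0)
  cx <- sum(w * xs) / m; cy <- sum(w * ys) / m
  mu20 <- sum(w * (xs - cx)^2) / m
  mu02 <- sum(w * (ys - cy)^2) / m
  mu11 <- sum(w * (xs - cx) * (ys - cy)) / m
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

# Integer pixel coordinates (0-based) on the segment between two points.
bresenham <- function(x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1)
  t <- seq(0, 1, length.out = n + 1)
  cbind(x = round(x0 + t * (x1 - x0)), y = round(y0 + t * (y1 - y0)))
}
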