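# Independent oracles used across the suite: brute-force convolution,
# exhaustive between-class-variance thresholding, explicit neighbor
# counting, and a boundary-walk perimeter.

# O(N^2 k^2) dense convolution with reflective boundary
brute_convolve <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + kernel[di + r + 1L, dj + r + 1L] *
        m[reflect(i + di, nr), reflect(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# exhaustive Otsu on a 256-bin histogram of values in [0, 1]: returns the
# candidate threshold maximizing between-class variance
otsu_oracle <- function(x, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                     levels), nbins = levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  best_t <- 0; best_v <- -Inf
  n <- sum(h)
  for (k in seq_len(levels - 1L)) {
    w0 <- sum(h[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1L):levels] * mids[(k + 1L):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- breaks[k + 1L] }
  }
  best_t
}

# neighbor counting by explicit loop over the 8 offsets
neighbor_count_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cnt <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && m[ii, jj] != 0)
        cnt <- cnt + 1L
    }
    out[i, j] <- cnt
  }
  out
}

# closed-boundary walk length of a (single-object) mask via EBImage
# contour tracing; perimeter / 2 is the defining length contract for
# one-pixel-wide objects
boundary_perimeter <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))[[1L]]
  closed <- rbind(oc, oc[1L, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

# ordered pixel path for a straight segment fixture
path_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("row", "col")
  storage.mode(m) <- "integer"
  m
}

# build a processed_image by hand (for bundling unit tests)
fake_processed <- function(filtered, skeleton, frame_index = 0L, time_s = 0) {
  structure(list(filtered = filtered, normalized = filametrics::normalize_image(filtered),
                 mask = skeleton, skeleton = skeleton,
                 detect_level = 0,
                 pixel_size_um = 0.1, frame_index = as.integer(frame_index),
                 time_s = time_s, config = filametrics::preprocess_config()),
            class = "processed_image")
}
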