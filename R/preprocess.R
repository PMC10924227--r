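# Raw micrograph -> filtered -> normalized -> binary mask -> skeleton.
# Noise filtering and background subtraction use truncated 2D Gaussian
# kernels whose side is kernel_factor * sigma (default 7, which captures
# >99% of the Gaussian mass); background subtraction is the difference of
# the small-sigma and large-sigma smoothed images.

#' Preprocessing configuration
#'
#' @param sigma_noise_px Gaussian SD (pixels) for noise filtering; > 0.
#' @param sigma_background_px Gaussian SD (pixels) for background
#'   estimation; must exceed `sigma_noise_px` since background varies more
#'   slowly than filament signal.
#' @param min_threshold User minimum detection threshold on the normalized
#'   image, in `[0, 1)`. Combined with the automatic threshold by `max()`.
#' @param kernel_factor Kernel side = `kernel_factor * sigma` (rounded,
#'   forced odd); >= 3. The default 7 truncates less than 1% of the
#'   Gaussian mass (see [kernel_coverage]).
#' @param connectivity Pixel connectivity for object/skeleton analysis;
#'   only 8 is supported (diagonal filament steps must stay connected).
#' @param min_object_px Skeletons smaller than this are counted as puncta
#'   and excluded from length statistics.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sigma_noise_px = 1.0,
                              sigma_background_px = 20.0,
                              min_threshold = 0.0,
                              kernel_factor = 7,
                              connectivity = 8L,
                              min_object_px = 3L) {
  if (sigma_noise_px <= 0) stop("sigma_noise_px must be > 0", call. = FALSE)
  if (sigma_background_px <= sigma_noise_px)
    stop("sigma_background_px must exceed sigma_noise_px", call. = FALSE)
  if (min_threshold < 0 || min_threshold >= 1)
    stop("min_threshold must lie in [0, 1)", call. = FALSE)
  if (kernel_factor < 3) stop("kernel_factor must be >= 3", call. = FALSE)
  if (connectivity != 8L) stop("only 8-connectivity is supported", call. = FALSE)
  structure(list(sigma_noise_px = sigma_noise_px,
                 sigma_background_px = sigma_background_px,
                 min_threshold = min_threshold,
                 kernel_factor = kernel_factor,
                 connectivity = 8L,
                 min_object_px = as.integer(min_object_px)),
            class = "preprocess_config")
}

#' Load a preprocessing configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [preprocess_config].
#'
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @return A `preprocess_config`.
#' @export
read_preprocess_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else stop("config must be JSON or YAML", call. = FALSE)
  known <- names(formals(preprocess_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(preprocess_config, vals)
}

gaussian_kernel <- function(sigma, kernel_factor = 7) {
  side <- round(kernel_factor * sigma)
  if (side %% 2 == 0) side <- side + 1  # centered filter needs odd side
  side <- max(side, 3L)
  r <- (side - 1L) / 2L
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Fraction of 2D Gaussian mass inside the truncated kernel
#'
#' A square kernel of side `kernel_factor * sigma` keeps the mass within
#' `kernel_factor / 2` SDs of center along each axis; the default factor 7
#' retains over 99% of the full 2D Gaussian mass.
#'
#' @param kernel_factor Kernel side expressed in SDs.
#' @return Retained mass fraction in `[0, 1]`.
#' @export
kernel_coverage <- function(kernel_factor = 7) {
  half <- kernel_factor / 2
  (stats::pnorm(half) - stats::pnorm(-half))^2
}

pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("padding radius exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  m[ri, ci]
}

# 2D convolution with reflective boundary; kernel side must be odd
convolve2d_reflect <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  padded <- pad_reflect(m, r)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

#' Noise filtering and background subtraction
#'
#' Smooths the micrograph with a small-SD Gaussian (noise filtering) and
#' subtracts the large-SD smoothed image (background estimate); negative
#' differences are clipped to zero so downstream thresholds see
#' nonnegative fluorescence.
#'
#' @param img A [micrograph] or numeric matrix.
#' @param cfg A [preprocess_config].
#' @return Filtered intensity matrix in the input's units.
#' @export
filter_and_subtract <- function(img, cfg = preprocess_config()) {
  m <- if (inherits(img, "micrograph")) img$pixels else img
  kb <- gaussian_kernel(cfg$sigma_background_px, cfg$kernel_factor)
  if (nrow(kb) > min(dim(m)))
    stop("image smaller than the background kernel (",
         nrow(kb), " px); reduce sigma_background_px", call. = FALSE)
  kn <- gaussian_kernel(cfg$sigma_noise_px, cfg$kernel_factor)
  smoothed <- convolve2d_reflect(m, kn)
  background <- convolve2d_reflect(m, kb)
  pmax(smoothed - background, 0)
}

#' Rescale an intensity image to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant image maps to all zeros. The
#' operation is idempotent.
#'
#' @param x Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(array(0, dim = dim(x)))
  (x - lo) / (hi - lo)
}

#' Automatic global histogram threshold (Otsu criterion)
#'
#' Bins the values into a fixed number of levels and returns the class
#' boundary maximizing the between-class variance; ties are resolved by
#' the midpoint of the maximizing range.
#'
#' @param x Numeric values in `[0, 1]`.
#' @param levels Number of histogram bins.
#' @return Threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1L)
  counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                          levels), nbins = levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(counts)
  m1 <- cumsum(counts * mids)
  n <- w1[levels]; mtot <- m1[levels]
  k <- seq_len(levels - 1L)
  w2 <- n - w1[k]
  bcv <- ifelse(w1[k] > 0 & w2 > 0,
                w1[k] * w2 * (m1[k] / w1[k] - (mtot - m1[k]) / w2)^2, NA)
  best <- which(bcv == max(bcv, na.rm = TRUE))
  (breaks[best[1L] + 1L] + breaks[best[length(best)] + 1L]) / 2
}

#' Detect filament pixels in a normalized image
#'
#' Pixels above `max(min_threshold, T_auto)` are detected, where `T_auto`
#' is the automatic global histogram threshold (Otsu criterion, maximizing
#' between-class variance) computed on the normalized image and
#' `min_threshold` is the user floor.
#'
#' @param normalized Matrix with values in `[0, 1]`.
#' @param cfg A [preprocess_config].
#' @return Logical detection mask.
#' @export
detect <- function(normalized, cfg = preprocess_config()) {
  if (min(normalized) < 0 || max(normalized) > 1)
    stop("detect() expects a normalized image in [0, 1]", call. = FALSE)
  if (max(normalized) == min(normalized)) {
    mask <- array(FALSE, dim = dim(normalized))
  } else {
    mask <- normalized > max(cfg$min_threshold, otsu_threshold(normalized))
  }
  if (!any(mask)) warning("empty detection mask", call. = FALSE)
  mask
}

#' Run the full preprocessing chain
#'
#' Filters and background-subtracts, normalizes, thresholds, and
#' skeletonizes a micrograph. By default the detection threshold is
#' computed from the frame itself (`max(min_threshold, Otsu)` on the
#' normalized image); for time series, `detect_level` fixes the absolute
#' detection level (in filtered-intensity units) so that the definition
#' of "filament pixel" does not drift as bright bundles form.
#'
#' @param img A [micrograph].
#' @param cfg A [preprocess_config].
#' @param detect_level Optional absolute detection threshold in the
#'   filtered image's intensity units; `NULL` uses the frame's own
#'   normalized-image threshold.
#' @return A `processed_image` with elements `filtered`, `normalized`,
#'   `mask`, `skeleton`, and `detect_level` (the absolute threshold
#'   used), plus the source `pixel_size_um`, `frame_index` and `time_s`.
#' @export
preprocess <- function(img, cfg = preprocess_config(), detect_level = NULL) {
  stopifnot(inherits(img, "micrograph"))
  filtered <- filter_and_subtract(img, cfg)
  normalized <- normalize_image(filtered)
  if (is.null(detect_level)) {
    rng <- range(filtered)
    if (rng[2L] > rng[1L]) {
      t_auto <- otsu_threshold(normalized)
      detect_level <- rng[1L] + max(cfg$min_threshold, t_auto) *
        (rng[2L] - rng[1L])
    } else {
      detect_level <- Inf  # constant image: nothing detectable
    }
  }
  mask <- filtered > detect_level
  skeleton <- skeletonize_mask(mask)
  structure(list(filtered = filtered, normalized = normalized,
                 mask = mask, skeleton = skeleton,
                 detect_level = detect_level,
                 pixel_size_um = img$pixel_size_um,
                 frame_index = img$frame_index, time_s = img$time_s,
                 config = cfg),
            class = "processed_image")
}

#' @export
print.processed_image <- function(x, ...) {
  cat(sprintf("<processed_image> %d x %d px; %d mask px, %d skeleton px\n",
              nrow(x$filtered), ncol(x$filtered),
              sum(x$mask), sum(x$skeleton)))
  invisible(x)
}
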