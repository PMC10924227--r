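# Synthetic TIRF-like micrographs with ground truth: blurred curvilinear
# filaments on a noisy, optionally unevenly illuminated background, with
# crossings, stepwise bundling events and exponential photobleaching.
# Every pipeline stage is testable against these scenes without real data.

#' Specify a synthetic scene
#'
#' Defaults emulate FITC-phalloidin-labeled actin filaments imaged by TIRF
#' with an EMCCD camera: 0.1 um pixels, filament lengths exponentially
#' distributed with mean 7 um, a PSF of 1.5 px SD, additive Gaussian read
#' noise, and 10 s frame intervals.
#'
#' @param image_shape Integer pair (rows, cols).
#' @param pixel_size_um Micrometers per pixel.
#' @param n_filaments Number of filaments.
#' @param length_distribution One of `list(type = "exponential", mean_um =)`,
#'   `list(type = "fixed", length_um =)`, or `list(type = "list",
#'   lengths_um =)`.
#' @param curvature_px Maximum random perpendicular deviation from the
#'   filament's chord, in pixels; 0 draws straight filaments.
#' @param orientation_deg Optional fixed orientation(s) in degrees
#'   (recycled); `NULL` draws uniformly random orientations.
#' @param filament_intensity Fluorescence amplitude per unit filament
#'   length (AU); a single filament's blurred centerline peaks near
#'   `filament_intensity / (sqrt(2 * pi) * psf_sigma_px)`.
#' @param bundle_events List of `list(time_s =, filament_ids =,
#'   multiplier =)`: from `time_s` onward the named filaments fluoresce at
#'   `multiplier` times the single-filament level (2 for two-filament
#'   bundles). Later events override earlier ones for the same filament.
#' @param psf_sigma_px Gaussian PSF SD in pixels (0 disables blurring).
#' @param noise_sd Additive Gaussian noise SD (AU); EMCCD read-noise proxy.
#' @param illumination `"flat"`, `"gradient"` (smooth multiplicative field
#'   rising left to right across `illumination_range`), or a matrix.
#' @param illumination_range Range of the gradient field, default
#'   `c(0.5, 1)`.
#' @param bleach_rate Photobleaching rate constant (1/s); intensities are
#'   scaled by `exp(-bleach_rate * t)`.
#' @param frame_interval_s Seconds between frames.
#' @param n_frames Number of frames.
#' @param rng_seed Seed; a fixed seed reproduces the stack bit-exactly.
#' @param margin_px Border kept free of filament starts; defaults to
#'   `ceiling(3 * psf_sigma_px) + 2`.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       pixel_size_um = 0.1,
                       n_filaments = 30L,
                       length_distribution = list(type = "exponential",
                                                  mean_um = 7),
                       curvature_px = 2,
                       orientation_deg = NULL,
                       filament_intensity = 100,
                       bundle_events = list(),
                       psf_sigma_px = 1.5,
                       noise_sd = 4,
                       illumination = "flat",
                       illumination_range = c(0.5, 1),
                       bleach_rate = 0,
                       frame_interval_s = 10,
                       n_frames = 1L,
                       rng_seed = 1L,
                       margin_px = NULL) {
  if (any(image_shape < 16L)) stop("image_shape too small", call. = FALSE)
  if (pixel_size_um <= 0 || filament_intensity <= 0)
    stop("sizes and intensities must be positive", call. = FALSE)
  if (noise_sd < 0 || psf_sigma_px < 0 || bleach_rate < 0 || curvature_px < 0)
    stop("noise_sd, psf_sigma_px, bleach_rate, curvature_px must be >= 0",
         call. = FALSE)
  if (frame_interval_s <= 0 || n_frames < 1L)
    stop("need frame_interval_s > 0 and n_frames >= 1", call. = FALSE)
  for (ev in bundle_events) {
    if (is.null(ev$time_s) || is.null(ev$filament_ids) || is.null(ev$multiplier))
      stop("bundle events need time_s, filament_ids, multiplier", call. = FALSE)
    if (ev$time_s < 0) stop("bundle event before t = 0", call. = FALSE)
    if (ev$multiplier < 1) stop("bundle multiplier must be >= 1", call. = FALSE)
  }
  if (is.null(margin_px)) margin_px <- ceiling(3 * psf_sigma_px) + 2
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 n_filaments = as.integer(n_filaments),
                 length_distribution = length_distribution,
                 curvature_px = curvature_px,
                 orientation_deg = orientation_deg,
                 filament_intensity = filament_intensity,
                 bundle_events = bundle_events,
                 psf_sigma_px = psf_sigma_px,
                 noise_sd = noise_sd,
                 illumination = illumination,
                 illumination_range = illumination_range,
                 bleach_rate = bleach_rate,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 rng_seed = as.integer(rng_seed),
                 margin_px = as.integer(margin_px)),
            class = "scene_spec")
}

sample_lengths <- function(dist, n) {
  switch(dist$type,
    exponential = stats::rexp(n, rate = 1 / dist$mean_um),
    fixed = rep(dist$length_um, n),
    list = rep_len(dist$lengths_um, n),
    stop("unknown length distribution type '", dist$type, "'", call. = FALSE))
}

illumination_field <- function(spec) {
  d <- spec$image_shape
  if (is.matrix(spec$illumination)) return(spec$illumination)
  if (identical(spec$illumination, "flat")) return(matrix(1, d[1L], d[2L]))
  if (identical(spec$illumination, "gradient")) {
    rng <- spec$illumination_range
    return(matrix(rep(seq(rng[1L], rng[2L], length.out = d[2L]),
                      each = d[1L]), d[1L], d[2L]))
  }
  stop("illumination must be 'flat', 'gradient', or a matrix", call. = FALSE)
}

# round half away from zero (base round() is round-half-even, which can
# turn a unit-step polyline into 2-px jumps)
rnd_half_up <- function(x) floor(x + 0.5)

# 8-connected Bresenham line between two integer points, inclusive
bresenham <- function(p0, p1) {
  d <- p1 - p0
  n <- max(abs(d))
  if (n == 0L) return(matrix(p0, 1L, 2L))
  cbind(p0[1L] + rnd_half_up(seq(0L, d[1L], length.out = n + 1L)),
        p0[2L] + rnd_half_up(seq(0L, d[2L], length.out = n + 1L)))
}

# digitize a continuous polyline as a minimal 8-connected chain:
# anchor points are taken every ~2 px of arc and joined by Bresenham
# segments (dense rounding would inflate the chain with staircase steps)
rasterize_polyline <- function(pts) {
  n <- nrow(pts)
  anchor_idx <- unique(c(seq(1L, n, by = 4L), n))
  anchors <- rnd_half_up(pts[anchor_idx, , drop = FALSE])
  raster <- if (nrow(anchors) == 1L) anchors else {
    segs <- vector("list", nrow(anchors) - 1L)
    for (i in seq_along(segs))
      segs[[i]] <- bresenham(anchors[i, ], anchors[i + 1L, ])
    do.call(rbind, segs)
  }
  keep <- c(TRUE, rowSums(abs(matrix(diff(raster), ncol = 2L))) > 0)
  raster <- raster[keep, , drop = FALSE]
  storage.mode(raster) <- "integer"
  colnames(raster) <- c("row", "col")
  raster
}

# trace one filament: a gentle smooth bend (sinusoidal perpendicular
# deviation of amplitude <= curvature_px around a straight chord,
# emulating the high persistence length of phalloidin-stabilized
# filaments), placed uniformly at random so the whole path stays inside
# the margins
trace_filament <- function(len_px, d, margin, curvature_px, theta0 = NULL) {
  usable <- d - 2 * margin
  if (len_px > sqrt(sum(usable^2)))
    stop("filament longer than the usable image diagonal", call. = FALSE)
  amp <- if (curvature_px > 0) stats::runif(1, 0, curvature_px) else 0
  lambda <- len_px / stats::runif(1, 0.5, 2)  # 0.5-2 bend periods
  phase <- stats::runif(1, 0, 2 * pi)
  s <- seq(0, len_px, by = 0.5)
  dev <- amp * (sin(2 * pi * s / lambda + phase) - sin(phase))
  for (try in seq_len(200L)) {
    th <- if (is.null(theta0)) stats::runif(1, 0, 2 * pi) else theta0
    u <- c(cos(th), sin(th)); nrm <- c(-sin(th), cos(th))
    rel <- cbind(s * u[1L] + dev * nrm[1L], s * u[2L] + dev * nrm[2L])
    span <- apply(rel, 2L, range)
    ext <- span[2L, ] - span[1L, ]
    if (any(ext > usable)) {
      if (!is.null(theta0))
        stop("filament does not fit in the image at the given orientation",
             call. = FALSE)
      next
    }
    lo <- margin + 1 - span[1L, ]
    hi <- d - margin - span[2L, ]
    start <- c(stats::runif(1, lo[1L], hi[1L]), stats::runif(1, lo[2L], hi[2L]))
    return(rasterize_polyline(cbind(rel[, 1L] + start[1L],
                                    rel[, 2L] + start[2L])))
  }
  stop("could not place filament inside the image", call. = FALSE)
}

# deposited intensity per raster pixel is proportional to the local step
# length (sqrt(2) for diagonal steps), i.e. fluorophore density per unit
# filament length
path_weights <- function(path) {
  n <- nrow(path)
  if (n == 1L) return(1)
  steps <- sqrt(rowSums(diff(path)^2))
  w <- numeric(n)
  w[1L] <- steps[1L] / 2 + 0.5
  w[n] <- steps[n - 1L] / 2 + 0.5
  if (n > 2L) w[2L:(n - 1L)] <- (steps[-length(steps)] + steps[-1L]) / 2
  w
}

bundle_multipliers <- function(spec, t) {
  mult <- rep(1, spec$n_filaments)
  evs <- spec$bundle_events
  if (length(evs)) {
    ord <- order(vapply(evs, `[[`, numeric(1L), "time_s"))
    for (ev in evs[ord])
      if (ev$time_s <= t) mult[ev$filament_ids] <- ev$multiplier
  }
  mult
}

#' Render a synthetic scene with ground truth
#'
#' Filaments are drawn as bounded-curvature random-walk polylines,
#' rasterized one pixel wide with intensity proportional to local
#' filament length, scaled by the illumination field, photobleaching
#' decay and any bundle multipliers, convolved with the Gaussian PSF, and
#' degraded with additive Gaussian noise. Ground truth (pixel paths, true
#' lengths, per-frame bundled masks and the noiseless intensity-weighted
#' fraction bundled) is recorded before blurring and noise.
#'
#' @param spec A [scene_spec].
#' @return List with `stack` (a [micrograph_stack]) and `truth` (list:
#'   `paths`, `lengths_um`, `per_frame` with `bundled_mask` and
#'   `fraction_bundled`, `bleach_curve`, `illumination`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- spec$image_shape
  withr::with_seed(spec$rng_seed, {
    lengths_um <- sample_lengths(spec$length_distribution, spec$n_filaments)
    thetas <- if (is.null(spec$orientation_deg)) rep(list(NULL), spec$n_filaments)
              else as.list(rep_len(spec$orientation_deg * pi / 180,
                                   spec$n_filaments))
    paths <- vector("list", spec$n_filaments)
    for (i in seq_len(spec$n_filaments))
      paths[[i]] <- trace_filament(lengths_um[i] / spec$pixel_size_um, d,
                                   spec$margin_px, spec$curvature_px,
                                   thetas[[i]])
    true_lengths_um <- vapply(paths, measure_path_px, numeric(1L)) *
      spec$pixel_size_um
    illum <- illumination_field(spec)
    weights <- lapply(paths, path_weights)

    frames <- vector("list", spec$n_frames)
    per_frame <- vector("list", spec$n_frames)
    psf <- if (spec$psf_sigma_px > 0)
      gaussian_kernel(spec$psf_sigma_px, 7) else NULL
    times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_s
    for (fi in seq_len(spec$n_frames)) {
      t <- times[fi]
      mult <- bundle_multipliers(spec, t)
      decay <- exp(-spec$bleach_rate * t)
      raster <- matrix(0, d[1L], d[2L])
      bundled_raster <- matrix(0, d[1L], d[2L])
      for (i in seq_len(spec$n_filaments)) {
        lin <- (paths[[i]][, 2L] - 1L) * d[1L] + paths[[i]][, 1L]
        contrib <- spec$filament_intensity * weights[[i]] * mult[i] *
          illum[lin] * decay
        raster[lin] <- raster[lin] + contrib
        if (mult[i] > 1) bundled_raster[lin] <- bundled_raster[lin] + contrib
      }
      total <- sum(raster)
      per_frame[[fi]] <- list(
        bundled_mask = bundled_raster > 0,
        fraction_bundled = if (total > 0) sum(bundled_raster) / total else 0)
      img <- if (is.null(psf)) raster else convolve2d_reflect(raster, psf)
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                            d[1L], d[2L])
      frames[[fi]] <- pmax(img, 0)
    }
    stack <- micrograph_stack(frames, frame_interval_s = spec$frame_interval_s,
                              pixel_size_um = spec$pixel_size_um)
    list(stack = stack,
         truth = list(paths = paths, lengths_um = true_lengths_um,
                      per_frame = per_frame,
                      bleach_curve = exp(-spec$bleach_rate * times),
                      illumination = illum))
  })
}

#' Build a crossing fixture with known segment pairing
#'
#' Straight filaments are drawn through the image center at the given
#' angles so that every pair intersects; the ground truth records each
#' filament's pixel path (the correct pairing of opposite arms at the
#' crossing).
#'
#' @param angles_deg Orientations (degrees), length >= 2, pairwise
#'   distinct modulo 180.
#' @param lengths_um Filament lengths in micrometers (recycled).
#' @param image_shape,pixel_size_um,filament_intensity,psf_sigma_px,noise_sd
#'   Scene parameters as in [scene_spec].
#' @param rng_seed Seed for the noise.
#' @return List with `image` (a [micrograph]) and `truth` (`paths`,
#'   `lengths_um`).
#' @export
make_crossing_fixture <- function(angles_deg, lengths_um,
                                  image_shape = c(256L, 256L),
                                  pixel_size_um = 0.1,
                                  filament_intensity = 100,
                                  psf_sigma_px = 1.5, noise_sd = 2,
                                  rng_seed = 1L) {
  if (length(angles_deg) < 2L)
    stop("need at least 2 filaments to build a crossing", call. = FALSE)
  if (anyDuplicated(angles_deg %% 180))
    stop("parallel filaments never intersect", call. = FALSE)
  lengths_um <- rep_len(lengths_um, length(angles_deg))
  d <- as.integer(image_shape)
  center <- (d + 1) / 2
  paths <- vector("list", length(angles_deg))
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    half <- lengths_um[i] / pixel_size_um / 2
    s <- seq(-half, half, by = 1)
    pts <- cbind(center[1L] + s * sin(th), center[2L] + s * cos(th))
    if (any(pts < 1) || any(pts[, 1L] > d[1L]) || any(pts[, 2L] > d[2L]))
      stop("filament ", i, " does not fit in the image", call. = FALSE)
    paths[[i]] <- rasterize_polyline(pts)
  }
  img <- matrix(0, d[1L], d[2L])
  for (i in seq_along(paths)) {
    lin <- (paths[[i]][, 2L] - 1L) * d[1L] + paths[[i]][, 1L]
    img[lin] <- img[lin] + filament_intensity * path_weights(paths[[i]])
  }
  if (psf_sigma_px > 0)
    img <- convolve2d_reflect(img, gaussian_kernel(psf_sigma_px, 7))
  if (noise_sd > 0)
    img <- withr::with_seed(rng_seed,
      img + matrix(stats::rnorm(length(img), 0, noise_sd), d[1L], d[2L]))
  list(image = micrograph(pmax(img, 0), pixel_size_um = pixel_size_um),
       truth = list(paths = paths,
                    lengths_um = vapply(paths, measure_path_px, numeric(1L)) *
                      pixel_size_um))
}

#' Render a bundling time series with ground truth kinetics
#'
#' Thin wrapper around [render_scene] that checks the first frame
#' precedes all bundle events (so it contains only single filaments) and
#' returns the true fraction-bundled curve alongside the stack.
#'
#' @param spec A [scene_spec] with `n_frames > 1` and `bundle_events`.
#' @return As [render_scene], plus `truth$fraction_curve` (one value per
#'   frame).
#' @export
make_bundling_series <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ev_times <- vapply(spec$bundle_events, `[[`, numeric(1L), "time_s")
  if (length(ev_times) && min(ev_times) <= 0)
    stop("frame 0 must precede all bundle events", call. = FALSE)
  out <- render_scene(spec)
  out$truth$fraction_curve <- vapply(out$truth$per_frame, `[[`,
                                     numeric(1L), "fraction_bundled")
  out
}

#' The standard synthetic bundling series
#'
#' A fixed reference scene used throughout the package's own validation:
#' a dilute field of 8 filaments (limiting filament crossovers, which no
#' intensity threshold can distinguish from bundles), staged bundle
#' events that progressively raise the fluorescence of subsets of
#' filaments between 50 s and 200 s (including one bundle-expansion
#' event), mild photobleaching, and 30 frames at 10 s intervals.
#'
#' @param rng_seed Seed.
#' @return A [scene_spec].
#' @export
standard_bundling_spec <- function(rng_seed = 1L) {
  scene_spec(image_shape = c(320L, 320L),
             n_filaments = 8L,
             length_distribution = list(type = "exponential", mean_um = 4),
             curvature_px = 2,
             bundle_events = list(
               list(time_s = 50, filament_ids = 1:3, multiplier = 2),
               list(time_s = 100, filament_ids = 4:5, multiplier = 2),
               list(time_s = 150, filament_ids = 6L, multiplier = 2),
               list(time_s = 200, filament_ids = 1:3, multiplier = 3)),
             bleach_rate = 0.001,
             noise_sd = 2,
             frame_interval_s = 10,
             n_frames = 30L,
             rng_seed = rng_seed)
}
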