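# Bundling kinetics: grid-local intensity thresholds calibrated on a
# pre-bundling frame (threshold = mean + k_sd * SD of single-filament
# pixel intensities per grid cell), photobleaching correction by linear /
# exponential fits, per-pixel single vs bundled classification, and the
# intensity-weighted fraction-bundled time course.

#' Two-sided normal mass within k SDs of the mean
#'
#' The rationale for the default SD multiplier: pixel intensities of
#' single filaments in a grid cell are approximately normal, and a
#' threshold at mean + 1.8 SD encompasses about 93% of the two-sided
#' normal mass, excluding the bright upper tail contributed by
#' overlapping/bundled filaments.
#'
#' @param k_sd SD multiplier.
#' @return Mass fraction in `[0, 1]`.
#' @export
normal_coverage <- function(k_sd = 1.8) {
  stats::pnorm(k_sd) - stats::pnorm(-k_sd)
}

# grid cell id (1..n_rows*n_cols, row-major) for every pixel of an image;
# cells tile the image as equal rectangles, last row/col absorb remainders
grid_cell_map <- function(d, n_rows, n_cols) {
  ch <- max(1L, d[1L] %/% n_rows)
  cw <- max(1L, d[2L] %/% n_cols)
  ri <- pmin((seq_len(d[1L]) - 1L) %/% ch + 1L, n_rows)
  ci <- pmin((seq_len(d[2L]) - 1L) %/% cw + 1L, n_cols)
  outer(ri, ci, function(r, c) (r - 1L) * n_cols + c)
}

#' Calibrate per-cell bundle intensity thresholds
#'
#' The image is segmented into an `n_rows x n_cols` grid (default 3x3) to
#' cope with uneven illumination. In each cell the threshold is
#' `mean(I) + k_sd * sd(I)` over the filament-mask pixels of the
#' noise-filtered, nonbinary image. Filament pixels are the skeleton
#' (centerline) pixels of the detected filaments, whose intensities are
#' read from the filtered image; this mirrors the processing order
#' (threshold, binarize, skeletonize, then segment into a grid) and keeps
#' per-filament intensities approximately normal. Cells with fewer than
#' `min_cell_px` filament pixels inherit the whole-image threshold.
#'
#' @param frame0 A `processed_image` of the calibration frame (collected
#'   before the onset of bundling, so it contains only single filaments).
#' @param grid Integer pair `(n_rows, n_cols)`.
#' @param k_sd SD multiplier (default 1.8).
#' @param min_cell_px Minimum filament pixels per cell before falling back
#'   to the global threshold.
#' @return A `grid_threshold_map` with a `n_rows x n_cols` threshold
#'   matrix in the filtered image's intensity units.
#' @export
calibrate_thresholds <- function(frame0, grid = c(3L, 3L), k_sd = 1.8,
                                 min_cell_px = 10L) {
  stopifnot(inherits(frame0, "processed_image"))
  if (!any(frame0$skeleton))
    stop("cannot calibrate: no filament pixels detected", call. = FALSE)
  n_rows <- as.integer(grid[1L]); n_cols <- as.integer(grid[2L])
  cells <- grid_cell_map(dim(frame0$filtered), n_rows, n_cols)
  vals <- frame0$filtered[frame0$skeleton]
  cell_of <- cells[frame0$skeleton]
  global_thr <- mean(vals) + k_sd * stats::sd(vals)
  if (!is.finite(global_thr)) global_thr <- mean(vals)  # single-pixel mask
  thr <- matrix(global_thr, n_rows, n_cols, byrow = TRUE)
  for (cell in seq_len(n_rows * n_cols)) {
    v <- vals[cell_of == cell]
    if (length(v) >= min_cell_px)
      thr[matrix(c((cell - 1L) %/% n_cols + 1L,
                   (cell - 1L) %% n_cols + 1L), 1L)] <-
        mean(v) + k_sd * stats::sd(v)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, thresholds = thr,
                 k_sd = k_sd, frame_index = frame0$frame_index),
            class = "grid_threshold_map")
}

#' @export
print.grid_threshold_map <- function(x, ...) {
  cat(sprintf("<grid_threshold_map> %d x %d grid, k_sd = %g (frame %d)\n",
              x$n_rows, x$n_cols, x$k_sd, x$frame_index))
  print(round(x$thresholds, 2))
  invisible(x)
}

#' Fit photobleaching models to a threshold time series
#'
#' Fits both a linear model `T(t) = a + b t` and an exponential model
#' `T(t) = A exp(-k t) + c` by least squares to the per-frame scalar
#' thresholds, keeps the model with the lower sum of squared residuals,
#' and returns a correction factor `correction(t) = T_fit(t) / T_fit(t0)`
#' used to scale the calibration thresholds over time.
#'
#' @param time_s Frame acquisition times (seconds), length >= 3.
#' @param thresholds Per-frame scalar thresholds at those times.
#' @param model `"auto"` (lower SSE wins), `"linear"`, `"exponential"`, or
#'   `"none"` (constant correction of 1).
#' @return A `bleach_model` with `model_type`, `params`, `sse`, and the
#'   `correction(t)` function (`correction(t0) = 1`).
#' @export
fit_bleach_model <- function(time_s, thresholds,
                             model = c("auto", "linear", "exponential", "none")) {
  model <- match.arg(model)
  t0 <- time_s[1L]
  constant <- structure(
    list(model_type = "constant", params = c(level = mean(thresholds)),
         sse = sum((thresholds - mean(thresholds))^2), t0 = t0,
         correction = function(t) rep(1, length(t))),
    class = "bleach_model")
  if (model == "none") return(constant)
  if (length(time_s) < 3L)
    stop("need at least 3 sampled frames to fit bleaching", call. = FALSE)
  if (stats::sd(thresholds) == 0) return(constant)

  lin <- stats::lm(thresholds ~ time_s)
  lin_sse <- sum(stats::residuals(lin)^2)
  lin_par <- c(intercept = unname(stats::coef(lin)[1L]),
               slope = unname(stats::coef(lin)[2L]))
  make_lin <- function() {
    pred0 <- lin_par[["intercept"]] + lin_par[["slope"]] * t0
    structure(list(model_type = "linear", params = lin_par, sse = lin_sse,
                   t0 = t0,
                   correction = function(t)
                     (lin_par[["intercept"]] + lin_par[["slope"]] * t) / pred0),
              class = "bleach_model")
  }

  exp_fit <- tryCatch({
    c0 <- min(thresholds) * 0.5
    a0 <- max(thresholds[1L] - c0, 1e-9)
    span <- max(time_s) - t0
    k0 <- if (thresholds[length(thresholds)] < thresholds[1L])
      log(max(a0, 2e-9) / max(thresholds[length(thresholds)] - c0, 1e-9)) /
        max(span, 1e-9)
      else 1 / max(span, 1e-9)
    k0 <- max(k0, 1e-6)
    minpack.lm::nlsLM(thresholds ~ A * exp(-k * time_s) + c,
                      start = list(A = a0, k = k0, c = c0),
                      lower = c(A = -Inf, k = 0, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)

  if (model == "linear" || is.null(exp_fit)) return(make_lin())
  exp_par <- stats::coef(exp_fit)
  exp_sse <- sum(stats::residuals(exp_fit)^2)
  make_exp <- function() {
    a <- exp_par[["A"]]; k <- exp_par[["k"]]; cc <- exp_par[["c"]]
    pred0 <- a * exp(-k * t0) + cc
    structure(list(model_type = "exponential",
                   params = c(amplitude = a, decay_rate = k, offset = cc),
                   sse = exp_sse, t0 = t0,
                   correction = function(t) (a * exp(-k * t) + cc) / pred0),
              class = "bleach_model")
  }
  if (model == "exponential") return(make_exp())
  if (exp_sse < lin_sse) make_exp() else make_lin()
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf("<bleach_model> %s, SSE = %.4g\n", x$model_type, x$sse))
  print(signif(x$params, 4))
  invisible(x)
}

#' Calibrate photobleaching from a micrograph stack
#'
#' Preprocesses a subset of frames spread evenly across the stack,
#' reduces each to one scalar threshold, and fits the bleach model. So
#' that the fit tracks photobleaching of *single* filaments rather than
#' the progress of bundling, the sampled frames are processed in time
#' order: in each frame the median intensity of the pixels classified
#' single by the running threshold is taken as the single-filament level
#' (the median is insensitive to truncating the bright tail, and bundles
#' fluoresce at twice the single level or more while bleaching between
#' consecutive samples is gradual), and the frame's threshold is the
#' frame-0 threshold scaled by the decay of that level. Per-frame `k_sd`
#' overrides let a user adjust individual sampled frames, the batch
#' analogue of the interactive per-frame threshold tuning.
#'
#' @param stack A [micrograph_stack].
#' @param cfg A [preprocess_config] (must match the one used for
#'   classification).
#' @param n_sample Number of frames sampled for the fit (default 8).
#' @param grid,k_sd As in [calibrate_thresholds].
#' @param model Passed to [fit_bleach_model].
#' @param k_sd_overrides Optional named numeric vector mapping frame index
#'   (as character) to a replacement `k_sd` for that sampled frame.
#' @param detect_level Absolute detection threshold shared by all frames
#'   (see [preprocess]); defaults to the first sampled frame's own level.
#' @return A `bleach_model`; attribute `samples` holds the fitted points.
#' @export
calibrate_bleaching <- function(stack, cfg = preprocess_config(),
                                n_sample = 8L, grid = c(3L, 3L), k_sd = 1.8,
                                model = "auto", k_sd_overrides = NULL,
                                detect_level = NULL) {
  n <- length(stack$frames)
  if (n < 3L) {
    warning("fewer than 3 frames: using constant bleach correction",
            call. = FALSE)
    return(fit_bleach_model(0, 0, model = "none"))
  }
  pick <- unique(round(seq(1L, n, length.out = min(n_sample, n))))
  ts <- vapply(pick, function(i) stack$frames[[i]]$time_s, numeric(1L))
  thr <- rep(NA_real_, length(pick))
  m_trace <- rep(NA_real_, length(pick))
  thr0 <- m0 <- NULL
  for (j in seq_along(pick)) {
    i <- pick[j]
    proc <- preprocess(stack$frames[[i]], cfg, detect_level = detect_level)
    if (j == 1L) detect_level <- proc$detect_level
    ks <- k_sd
    ov <- k_sd_overrides[[as.character(stack$frames[[i]]$frame_index)]]
    if (!is.null(ov)) ks <- ov
    vals <- proc$filtered[proc$skeleton]
    if (j == 1L) {
      thr0 <- mean(vals) + ks * stats::sd(vals)
      singles <- vals[vals <= thr0]
      if (length(singles) < 10L) singles <- vals
      # re-estimate with the tracking separator so frame 0 is measured by
      # the same statistic as the later samples
      singles <- vals[vals <= sqrt(2) * stats::median(singles)]
      if (length(singles) < 10L) singles <- vals
      m0 <- stats::median(singles)
      m_trace[j] <- m0
      thr[j] <- thr0
    } else {
      # separator halfway (geometrically) between the single level and the
      # 2x bundle level, extrapolating the running bleach trend
      trend <- if (j > 2L) m_trace[j - 1L] / m_trace[j - 2L] else 1
      sep <- sqrt(2) * m_trace[j - 1L] * min(trend, 1)
      singles <- vals[vals <= sep]
      if (length(singles) < 10L) singles <- vals
      m_trace[j] <- stats::median(singles)
      thr[j] <- thr0 * m_trace[j] / m0
    }
  }
  fit <- fit_bleach_model(ts, thr, model = model)
  attr(fit, "samples") <- data.frame(frame = pick - 1L, time_s = ts,
                                     threshold = thr)
  fit
}

#' Classify filament pixels of one frame as single or bundled
#'
#' Every detected filament (skeleton) pixel is compared with its grid
#' cell's calibration threshold scaled by the photobleaching correction at
#' the frame's acquisition time: intensities at or below the threshold are
#' registered as single filaments, intensities above it as bundled. The
#' fraction bundled is the intensity-weighted ratio
#' `sum(I[bundled]) / sum(I[filament pixels])`.
#'
#' @param frame A `processed_image` (preprocessed with the calibration
#'   config).
#' @param tmap A `grid_threshold_map` from [calibrate_thresholds].
#' @param bleach Optional `bleach_model`; `NULL` means no correction.
#' @param time_s Acquisition time; defaults to the frame's own.
#' @return A `bundling_frame_result` with `bundled_mask`, `single_mask`,
#'   `fraction_bundled`, and pixel counts.
#' @export
classify_frame <- function(frame, tmap, bleach = NULL, time_s = NULL) {
  stopifnot(inherits(frame, "processed_image"),
            inherits(tmap, "grid_threshold_map"))
  if (is.null(time_s)) time_s <- frame$time_s
  corr <- if (is.null(bleach)) 1 else bleach$correction(time_s)
  fil <- frame$skeleton
  cells <- grid_cell_map(dim(frame$filtered), tmap$n_rows, tmap$n_cols)
  thr_px <- matrix(t(tmap$thresholds)[cells], nrow(cells), ncol(cells)) * corr
  bundled <- fil & frame$filtered > thr_px
  single <- fil & !bundled
  total <- sum(frame$filtered[fil])
  frac <- if (total > 0) sum(frame$filtered[bundled]) / total else 0
  if (!any(fil))
    warning("frame ", frame$frame_index, " has an empty filament mask",
            call. = FALSE)
  structure(list(frame_index = frame$frame_index, time_s = time_s,
                 bundled_mask = bundled, single_mask = single,
                 fraction_bundled = frac,
                 n_filament_pixels = sum(fil),
                 n_bundled_pixels = sum(bundled)),
            class = "bundling_frame_result")
}

#' @export
print.bundling_frame_result <- function(x, ...) {
  cat(sprintf("<bundling_frame_result> frame %d (t = %.6g s): %.3f bundled (%d / %d px)\n",
              x$frame_index, x$time_s, x$fraction_bundled,
              x$n_bundled_pixels, x$n_filament_pixels))
  invisible(x)
}

#' Quantify bundling kinetics over a time series
#'
#' Calibrates grid-local thresholds on the first frame (which must be
#' collected before the onset of bundling), fits the photobleaching
#' correction on a sampled subset of frames, classifies every frame's
#' filament pixels as single or bundled, and reports the fraction-bundled
#' time course. Optionally renders the classification overlay movie.
#'
#' @param stack A [micrograph_stack].
#' @param cfg A [preprocess_config] applied to every frame.
#' @param grid Grid dimensions, default `c(3, 3)`.
#' @param k_sd SD multiplier for the bundle threshold, default 1.8.
#' @param n_calib_frames Frames sampled for the bleach fit, default 8.
#' @param bleach_model `"auto"`, `"linear"`, `"exponential"` or `"none"`.
#' @param report_interval_s Optional reporting granularity; frames are
#'   thinned to (approximately) this spacing in the summary table.
#' @param k_sd_overrides See [calibrate_bleaching].
#' @param movie_path Optional AVI path for the overlay movie.
#' @return List with `results` (summary data frame: `frame_index`,
#'   `time_s`, `fraction_bundled`, `n_filament_pixels`,
#'   `n_bundled_pixels`), `frames` (per-frame `bundling_frame_result`s),
#'   `thresholds` (the `grid_threshold_map`), and `bleach` (the
#'   `bleach_model`).
#' @export
run_kinetics <- function(stack, cfg = preprocess_config(), grid = c(3L, 3L),
                         k_sd = 1.8, n_calib_frames = 8L,
                         bleach_model = "auto", report_interval_s = NULL,
                         k_sd_overrides = NULL, movie_path = NULL) {
  proc0 <- preprocess(stack$frames[[1L]], cfg)
  lvl <- proc0$detect_level
  procs <- c(list(proc0),
             lapply(stack$frames[-1L], preprocess, cfg = cfg,
                    detect_level = lvl))
  tmap <- calibrate_thresholds(proc0, grid = grid, k_sd = k_sd)
  bleach <- if (length(stack$frames) < 3L || bleach_model == "none") {
    if (length(stack$frames) < 3L && bleach_model != "none")
      warning("too few frames for bleach fitting; using constant correction",
              call. = FALSE)
    fit_bleach_model(0, 0, model = "none")
  } else {
    calibrate_bleaching(stack, cfg = cfg, n_sample = n_calib_frames,
                        grid = grid, k_sd = k_sd, model = bleach_model,
                        k_sd_overrides = k_sd_overrides, detect_level = lvl)
  }
  frames <- lapply(procs, classify_frame, tmap = tmap, bleach = bleach)
  res <- data.frame(
    frame_index = vapply(frames, `[[`, integer(1L), "frame_index"),
    time_s = vapply(frames, `[[`, numeric(1L), "time_s"),
    fraction_bundled = vapply(frames, `[[`, numeric(1L), "fraction_bundled"),
    n_filament_pixels = vapply(frames, `[[`, integer(1L), "n_filament_pixels"),
    n_bundled_pixels = vapply(frames, `[[`, integer(1L), "n_bundled_pixels"))
  if (!is.null(report_interval_s)) {
    step <- max(1L, round(report_interval_s / stack$frame_interval_s))
    res <- res[seq(1L, nrow(res), by = step), , drop = FALSE]
    rownames(res) <- NULL
  }
  if (!is.null(movie_path))
    write_overlay_movie(stack, frames, movie_path)
  list(results = res, frames = frames, thresholds = tmap, bleach = bleach)
}
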