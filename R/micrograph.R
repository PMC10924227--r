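#' Calibrated fluorescence micrograph
#'
#' A `micrograph` is the pipeline's raw input: a 2D matrix of nonnegative
#' fluorescence intensities (arbitrary units, kept in the range they were
#' read in) together with the pixel-to-micrometer conversion factor set by
#' the camera and magnification.
#'
#' @param pixels Numeric matrix of nonnegative intensities, at least 2x2.
#' @param pixel_size_um Micrometers per pixel, > 0.
#' @param frame_index Integer frame index (>= 0); 0 for single images.
#' @param time_s Acquisition time in seconds (>= 0); 0 for single images.
#' @return An object of class `micrograph`.
#' @examples
#' m <- micrograph(matrix(1:16, 4, 4), pixel_size_um = 0.1)
#' dim(m$pixels)
#' @export
micrograph <- function(pixels, pixel_size_um, frame_index = 0L, time_s = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("micrograph must have at least 2 rows and 2 columns", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("intensities must be nonnegative and non-missing", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (frame_index < 0 || time_s < 0)
    stop("`frame_index` and `time_s` must be nonnegative", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         frame_index = as.integer(frame_index), time_s = as.numeric(time_s)),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.4g um/px, frame %d, t = %.6g s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$frame_index, x$time_s))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Ordered time series of micrographs
#'
#' Frames must share dimensions and pixel size. Frame indices are assigned
#' 0, 1, 2, ... in order and acquisition times follow
#' `time_s = frame_index * frame_interval_s`.
#'
#' @param frames List of [micrograph] objects (or numeric matrices, which are
#'   promoted using `pixel_size_um`).
#' @param frame_interval_s Seconds between consecutive frames, > 0.
#' @param pixel_size_um Pixel size used to promote bare matrices; ignored for
#'   frames that are already micrographs.
#' @return An object of class `micrograph_stack`.
#' @export
micrograph_stack <- function(frames, frame_interval_s, pixel_size_um = NULL) {
  if (length(frames) < 1L) stop("a stack needs at least one frame", call. = FALSE)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be > 0", call. = FALSE)
  frames <- lapply(frames, function(f) {
    if (inherits(f, "micrograph")) return(f)
    micrograph(f, pixel_size_um = pixel_size_um)
  })
  d <- dim(frames[[1L]]$pixels)
  ps <- frames[[1L]]$pixel_size_um
  for (f in frames) {
    if (!identical(dim(f$pixels), d))
      stop("all frames in a stack must share dimensions", call. = FALSE)
    if (!isTRUE(all.equal(f$pixel_size_um, ps)))
      stop("all frames in a stack must share pixel_size_um", call. = FALSE)
  }
  for (i in seq_along(frames)) {
    frames[[i]]$frame_index <- i - 1L
    frames[[i]]$time_s <- (i - 1L) * frame_interval_s
  }
  structure(list(frames = frames, frame_interval_s = as.numeric(frame_interval_s)),
            class = "micrograph_stack")
}

#' @export
print.micrograph_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]]$pixels)
  cat(sprintf("<micrograph_stack> %d frames of %d x %d px, dt = %.6g s, %.4g um/px\n",
              length(x$frames), d[1L], d[2L], x$frame_interval_s,
              x$frames[[1L]]$pixel_size_um))
  invisible(x)
}

#' @export
length.micrograph_stack <- function(x) length(x$frames)
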