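# Filament length measurement and population summaries.

# geodesic step-sum of an ordered pixel path (1 per orthogonal step,
# sqrt(2) per diagonal step)
measure_path_px <- function(pixel_path) {
  n <- nrow(pixel_path)
  if (is.null(n) || n < 2L) return(0)
  dr <- diff(pixel_path[, 1L]); dc <- diff(pixel_path[, 2L])
  if (any(abs(dr) > 1L | abs(dc) > 1L) || any(dr == 0L & dc == 0L))
    stop("pixel path is not 8-connected", call. = FALSE)
  sum(sqrt(dr^2 + dc^2))
}

#' Measure the length of a filament pixel path
#'
#' Skeletonized filaments are one pixel wide, so their length equals the
#' closed-boundary perimeter divided by two; for a branch-free path this
#' is computed as the geodesic step-sum (orthogonal steps count 1,
#' diagonal steps `sqrt(2)`). The micrometer length applies the user's
#' pixel-to-micrometer conversion factor.
#'
#' @param pixel_path Ordered `n x 2` matrix of (row, col) skeleton
#'   coordinates forming an 8-connected, branch-free path.
#' @param pixel_size_um Micrometers per pixel.
#' @return List with `length_px` and `length_um`.
#' @export
measure_length <- function(pixel_path, pixel_size_um) {
  lpx <- measure_path_px(pixel_path)
  list(length_px = lpx, length_um = lpx * pixel_size_um)
}

#' Summarize a filament population
#'
#' Histogram of lengths (left-closed bins of width `bin_um` starting at
#' 0), filament count, and total polymer (the integral of the length
#' distribution, i.e. the summed filament length in micrometers).
#'
#' @param filaments Data frame of filament records (needs a `length_um`
#'   column) or a numeric vector of lengths in micrometers.
#' @param bin_um Histogram bin width in micrometers (default 3).
#' @return List with `histogram` (data frame: `bin_start_um`,
#'   `bin_end_um`, `count`), `n_filaments`, and `total_polymer_um`.
#' @export
summarize_filaments <- function(filaments, bin_um = 3) {
  lengths <- if (is.data.frame(filaments)) filaments$length_um
             else as.numeric(filaments)
  if (bin_um <= 0) stop("bin_um must be > 0", call. = FALSE)
  if (length(lengths) == 0L) {
    hist <- data.frame(bin_start_um = numeric(0), bin_end_um = numeric(0),
                       count = integer(0))
    return(list(histogram = hist, n_filaments = 0L, total_polymer_um = 0))
  }
  n_bins <- max(1L, ceiling((max(lengths) + 1e-12) / bin_um))
  starts <- (seq_len(n_bins) - 1L) * bin_um
  idx <- pmin(floor(lengths / bin_um) + 1L, n_bins)
  hist <- data.frame(bin_start_um = starts, bin_end_um = starts + bin_um,
                     count = as.integer(tabulate(idx, nbins = n_bins)))
  list(histogram = hist, n_filaments = length(lengths),
       total_polymer_um = sum(lengths))
}

#' Plot a filament length histogram to PNG
#'
#' @param summary Result of [summarize_filaments].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_length_histogram <- function(summary, path) {
  h <- summary$histogram
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  if (nrow(h) == 0L) {
    graphics::plot.new()
    graphics::title(main = "Filament lengths (no filaments)")
  } else {
    graphics::barplot(h$count, names.arg = sprintf("%g-%g", h$bin_start_um,
                                                   h$bin_end_um),
                      xlab = "Length (µm)", ylab = "Filaments",
                      main = sprintf("Filament lengths (n = %d, total = %.1f µm)",
                                     summary$n_filaments,
                                     summary$total_polymer_um),
                      col = "grey60")
  }
  invisible(path)
}
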