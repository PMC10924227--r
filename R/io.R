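# Image, stack, table and movie I/O. Intensities are kept in their native
# integer range on read; normalization happens downstream in preprocessing.

png_bit_depth <- function(path) {
  # IHDR bit-depth byte: 8 signature + 4 length + 4 "IHDR" + 4 width + 4 height
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("truncated PNG: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

to_gray <- function(px) {
  if (is.matrix(px)) return(px)
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3L]
    if (nc == 1L) return(px[, , 1L])
    # alpha (4th) channel dropped; color collapsed by unweighted channel mean
    nch <- min(nc, 3L)
    out <- px[, , 1L]
    for (k in seq_len(nch)[-1L]) out <- out + px[, , k]
    return(out / nch)
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Read a single micrograph from TIFF or PNG
#'
#' Intensities are returned as read, without rescaling: TIFF pixels keep
#' their stored integer values; PNG pixels are mapped back to the file's
#' native integer range (0..255 or 0..65535). Multi-channel images are
#' reduced to one channel by unweighted channel averaging.
#'
#' @param path Path to a single-page TIFF or PNG file.
#' @param pixel_size_um Micrometers per pixel (camera/magnification
#'   conversion factor, supplied by the user).
#' @return A [micrograph].
#' @export
read_image <- function(path, pixel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    "tif" = , "tiff" = {
      img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                      error = function(e) stop("unreadable TIFF: ", path,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
      to_gray(img)
    },
    "png" = {
      img <- tryCatch(png::readPNG(path),
                      error = function(e) stop("unreadable PNG: ", path,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
      depth <- png_bit_depth(path)
      to_gray(img) * (2^depth - 1)
    },
    stop("unsupported image format '", ext, "' (use TIFF or PNG)",
         call. = FALSE))
  if (length(px) == 0L) stop("zero-sized image: ", path, call. = FALSE)
  micrograph(px, pixel_size_um = pixel_size_um)
}

#' Write a single micrograph to TIFF or PNG
#'
#' @param img A [micrograph] or numeric matrix of integers in the target range.
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @param bits_per_sample Bit depth for TIFF output (8 or 16). PNG output is
#'   always 8-bit.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits_per_sample = 16L) {
  px <- if (inherits(img, "micrograph")) img$pixels else img
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    top <- 2^bits_per_sample - 1
    if (max(px) > top) stop("intensities exceed ", bits_per_sample,
                            "-bit range", call. = FALSE)
    tiff::writeTIFF(px / top, path, bits.per.sample = as.integer(bits_per_sample))
  } else if (ext == "png") {
    if (max(px) > 255) stop("PNG output is 8-bit; intensities exceed 255",
                            call. = FALSE)
    png::writePNG(px / 255, path)
  } else {
    stop("unsupported image format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Read a time series of micrographs from multi-page TIFF or AVI
#'
#' Frames are returned in storage order; acquisition times are assigned as
#' `frame_index * frame_interval_s`. AVI input must be an uncompressed
#' 24-bit stream (see [read_avi]); gray frames stored as RGB are collapsed
#' by channel averaging.
#'
#' @param path Multi-page TIFF or AVI file.
#' @param pixel_size_um Micrometers per pixel.
#' @param frame_interval_s Seconds between consecutive frames.
#' @return A [micrograph_stack].
#' @export
read_stack <- function(path, pixel_size_um, frame_interval_s) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mats <- switch(ext,
    "tif" = , "tiff" = {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, to_gray)
    },
    "avi" = lapply(read_avi(path), to_gray),
    stop("unsupported stack format '", ext, "' (use multi-page TIFF or AVI)",
         call. = FALSE))
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1L))))
    stop("mixed frame sizes in ", path, call. = FALSE)
  micrograph_stack(mats, frame_interval_s = frame_interval_s,
                   pixel_size_um = pixel_size_um)
}

#' Write a micrograph stack to multi-page TIFF or AVI
#'
#' @param stack A [micrograph_stack].
#' @param path Output path (`.tif`/`.tiff` or `.avi`). AVI frames are
#'   clipped/rounded to the 8-bit range 0..255 and written with the raw
#'   codec.
#' @param bits_per_sample TIFF bit depth (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16L) {
  ext <- tolower(tools::file_ext(path))
  mats <- lapply(stack$frames, `[[`, "pixels")
  if (ext %in% c("tif", "tiff")) {
    top <- 2^bits_per_sample - 1
    if (max(vapply(mats, max, numeric(1L))) > top)
      stop("intensities exceed ", bits_per_sample, "-bit range", call. = FALSE)
    tiff::writeTIFF(lapply(mats, function(m) m / top), path,
                    bits.per.sample = as.integer(bits_per_sample))
  } else if (ext == "avi") {
    write_avi(mats, path, fps = 1 / stack$frame_interval_s)
  } else {
    stop("unsupported stack format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write a results table to CSV
#'
#' One row per record. Filament tables carry `filament_id`, `object_id`,
#' `n_pixels`, `length_px`, `length_um`, `frame_index`; bundling tables
#' carry `frame_index`, `time_s`, `fraction_bundled`, `n_filament_pixels`,
#' `n_bundled_pixels`. An empty record set yields a header-only file.
#'
#' @param records A data frame of filament or bundling results (list columns
#'   such as pixel paths are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  df <- as.data.frame(records)
  keep <- !vapply(df, is.list, logical(1L))
  df <- df[, keep, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results table to ", path, call. = FALSE)
  invisible(path)
}

#' Render an overlay movie of single vs bundled pixels
#'
#' Each movie frame shows the micrograph in grayscale with classified
#' pixels painted in two fixed contrasting colors (defaults: magenta for
#' single filaments, yellow for bundles), for visual verification that
#' color changes track the coalescence of filaments into bundles.
#'
#' @param stack A [micrograph_stack].
#' @param masks One classification per frame: either a list of
#'   `bundling_frame_result` objects or a list of integer matrices with
#'   0 = background, 1 = single, 2 = bundled.
#' @param path Output AVI path (raw codec, pixel-exact).
#' @param col_single,col_bundled RGB triples in 0..255.
#' @return `path`, invisibly.
#' @export
write_overlay_movie <- function(stack, masks, path,
                                col_single = c(255, 0, 255),
                                col_bundled = c(255, 255, 0)) {
  if (length(masks) != length(stack$frames))
    stop("need exactly one mask per frame", call. = FALSE)
  masks <- lapply(masks, function(m) {
    if (inherits(m, "bundling_frame_result"))
      m <- m$single_mask + 2L * m$bundled_mask
    m
  })
  d <- dim(stack$frames[[1L]]$pixels)
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1L))))
    stop("mask/frame shape mismatch", call. = FALSE)
  top <- max(vapply(stack$frames, function(f) max(f$pixels), numeric(1L)), 1)
  frames <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    g <- pmin(stack$frames[[i]]$pixels / top, 1) * 255
    fr <- array(rep(g, 3L), dim = c(d, 3L))
    m <- masks[[i]]
    for (k in 1:3) {
      ch <- fr[, , k]
      ch[m == 1L] <- col_single[k]
      ch[m == 2L] <- col_bundled[k]
      fr[, , k] <- ch
    }
    frames[[i]] <- fr
  }
  write_avi(frames, path, fps = 1 / stack$frame_interval_s)
  invisible(path)
}
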