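# Minimal AVI (RIFF) container support: uncompressed 24-bit RGB ('DIB ')
# video only, the raw codec used for pixel-testable overlay movies.

fourcc <- function(s) charToRaw(s)

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

riff_chunk <- function(id, data) {
  out <- c(fourcc(id), u32(length(data)), data)
  if (length(data) %% 2L == 1L) out <- c(out, as.raw(0L))  # chunks are word-aligned
  out
}

riff_list <- function(type, data) riff_chunk("LIST", c(fourcc(type), data))

# rows of an h x w x 3 array (values 0..255) -> bottom-up BGR DIB bytes
frame_to_dib <- function(fr) {
  h <- dim(fr)[1L]; w <- dim(fr)[2L]
  pad <- (4L - (3L * w) %% 4L) %% 4L
  v <- pmin(pmax(round(fr), 0), 255)
  rows <- vector("list", h)
  for (r in seq_len(h)) {
    # bottom row first; per pixel B, G, R
    rr <- h - r + 1L
    px <- rbind(v[rr, , 3L], v[rr, , 2L], v[rr, , 1L])
    rows[[r]] <- c(as.raw(as.integer(px)), as.raw(integer(pad)))
  }
  do.call(c, rows)
}

dib_to_frame <- function(bytes, w, h) {
  pad <- (4L - (3L * w) %% 4L) %% 4L
  stride <- 3L * w + pad
  fr <- array(0, dim = c(h, w, 3L))
  b <- as.integer(bytes)
  for (r in seq_len(h)) {
    off <- (r - 1L) * stride
    row <- b[(off + 1L):(off + 3L * w)]
    rr <- h - r + 1L
    fr[rr, , 3L] <- row[seq(1L, by = 3L, length.out = w)]
    fr[rr, , 2L] <- row[seq(2L, by = 3L, length.out = w)]
    fr[rr, , 1L] <- row[seq(3L, by = 3L, length.out = w)]
  }
  fr
}

#' Write an uncompressed RGB AVI movie
#'
#' Frames are stored as raw 24-bit DIB bitmaps (no compression), so a
#' written movie decodes bit-exactly; lossy codecs are out of scope.
#'
#' @param frames List of `h x w x 3` numeric arrays with values in 0..255
#'   (grayscale `h x w` matrices are replicated across channels).
#' @param path Output file path.
#' @param fps Frames per second (may be fractional).
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, fps = 10) {
  if (length(frames) < 1L) stop("no frames to write", call. = FALSE)
  frames <- lapply(frames, function(f) {
    if (is.matrix(f)) f <- array(rep(f, 3L), dim = c(dim(f), 3L))
    if (length(dim(f)) != 3L || dim(f)[3L] != 3L)
      stop("frames must be h x w x 3 arrays or matrices", call. = FALSE)
    f
  })
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1L))))
    stop("all frames must share dimensions", call. = FALSE)
  h <- d[1L]; w <- d[2L]; n <- length(frames)
  pad <- (4L - (3L * w) %% 4L) %% 4L
  frame_bytes <- (3L * w + pad) * h

  scale <- 1000L
  rate <- as.integer(round(fps * scale))
  avih <- c(u32(round(1e6 / fps)), u32(frame_bytes * fps), u32(0L),
            u32(0x10), u32(n), u32(0L), u32(1L), u32(frame_bytes),
            u32(w), u32(h), u32(0L), u32(0L), u32(0L), u32(0L))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0L), u16(0L), u16(0L),
            u32(0L), u32(scale), u32(rate), u32(0L), u32(n),
            u32(frame_bytes), u32(-1L), u32(0L),
            u16(0L), u16(0L), u16(w), u16(h))
  strf <- c(u32(40L), u32(w), u32(h), u16(1L), u16(24L), u32(0L),
            u32(frame_bytes), u32(0L), u32(0L), u32(0L), u32(0L))
  hdrl <- riff_list("hdrl", c(
    riff_chunk("avih", avih),
    riff_list("strl", c(riff_chunk("strh", strh), riff_chunk("strf", strf)))))

  dibs <- lapply(frames, frame_to_dib)
  movi_body <- do.call(c, lapply(dibs, function(d) riff_chunk("00db", d)))
  movi <- riff_list("movi", movi_body)

  # idx1: offsets relative to the 'movi' fourcc
  chunk_len <- frame_bytes + 8L + (frame_bytes %% 2L)
  offsets <- 4L + (seq_len(n) - 1L) * chunk_len
  idx <- do.call(c, lapply(seq_len(n), function(i)
    c(fourcc("00db"), u32(0x10), u32(offsets[i]), u32(frame_bytes))))
  idx1 <- riff_chunk("idx1", idx)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

rd_u32 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 3L)], "integer", size = 4, endian = "little")
}
rd_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
rd_cc <- function(bytes, pos) rawToChar(bytes[pos:(pos + 3L)])

#' Read an uncompressed RGB AVI movie
#'
#' Only raw 24-bit DIB streams (as written by [write_avi]) are supported;
#' compressed codecs raise a format error.
#'
#' @param path AVI file path.
#' @return List of `h x w x 3` arrays with values in 0..255.
#' @export
read_avi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 24L || rd_cc(bytes, 1L) != "RIFF" || rd_cc(bytes, 9L) != "AVI ")
    stop("not an AVI (RIFF) file: ", path, call. = FALSE)

  w <- h <- bpp <- compression <- NULL
  frames <- list()

  walk <- function(pos, end) {
    while (pos + 8L <= end) {
      id <- rd_cc(bytes, pos); sz <- rd_u32(bytes, pos + 4L)
      body <- pos + 8L
      if (id == "LIST") {
        walk(body + 4L, body + sz)
      } else if (id == "strf" && sz >= 40L) {
        if (is.null(w)) {
          w <<- rd_u32(bytes, body + 4L); h <<- rd_u32(bytes, body + 8L)
          bpp <<- rd_u16(bytes, body + 14L)
          compression <<- rd_u32(bytes, body + 16L)
        }
      } else if (id %in% c("00db", "00dc") && sz > 0L) {
        frames[[length(frames) + 1L]] <<- bytes[body:(body + sz - 1L)]
      }
      pos <- body + sz + (sz %% 2L)
    }
  }
  walk(13L, 8L + rd_u32(bytes, 5L))

  if (is.null(w)) stop("no video stream header found in ", path, call. = FALSE)
  if (compression != 0L || bpp != 24L)
    stop("only uncompressed 24-bit AVI streams are supported", call. = FALSE)
  if (length(frames) == 0L) stop("no frames found in ", path, call. = FALSE)
  lapply(frames, dib_to_frame, w = w, h = h)
}
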