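# Topology-preserving morphological thinning: the two-subiteration
# parallel scheme of Zhang-Suen as refined by Lam, Lee and Suen
# (conditions G1-G3/G3'), vectorized over the whole image, with a
# one-pixel-width cleanup pass that removes redundant simple points so no
# 2x2 block of skeleton pixels survives.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# neighbor offsets used for neighbor counting, clockwise from north
.zs_offsets <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                    c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

# x1..x8: E, NE, N, NW, W, SW, S, SE (counterclockwise from east, with
# image rows growing downward)
.thin_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                      c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

zs_pass <- function(m, subiter) {
  x <- lapply(.thin_offsets, function(o) shift_mat(m, o[1L], o[2L]))
  xi <- function(i) x[[((i - 1L) %% 8L) + 1L]]
  # G1: crossing number X_H(p) = 1
  xh <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:4)
    xh <- xh + (xi(2L * i - 1L) == 0L &
                (xi(2L * i) == 1L | xi(2L * i + 1L) == 1L))
  g1 <- xh == 1L
  # G2: 2 <= min(n1, n2) <= 3
  n1 <- n2 <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:4) {
    n1 <- n1 + pmax(xi(2L * k - 1L), xi(2L * k))
    n2 <- n2 + pmax(xi(2L * k), xi(2L * k + 1L))
  }
  nmin <- pmin(n1, n2)
  g2 <- nmin >= 2L & nmin <= 3L
  # G3 (subiteration 1) / G3' (subiteration 2)
  g3 <- if (subiter == 1L)
    (pmax(xi(2L), xi(3L), 1L - xi(8L)) * xi(1L)) == 0L
  else
    (pmax(xi(6L), xi(7L), 1L - xi(4L)) * xi(5L)) == 0L
  del <- m == 1L & g1 & g2 & g3
  m[del] <- 0L
  list(m = m, changed = any(del))
}

prune_2x2 <- function(m) {
  repeat {
    blocks <- m == 1L &
      shift_mat(m, 0L, 1L) == 1L &
      shift_mat(m, 1L, 0L) == 1L &
      shift_mat(m, 1L, 1L) == 1L
    if (!any(blocks)) break
    idx <- which(blocks, arr.ind = TRUE)
    removed <- FALSE
    for (k in seq_len(nrow(idx))) {
      # try each pixel of the offending block; delete the first simple point
      for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- idx[k, 1L] + off[1L]; c <- idx[k, 2L] + off[2L]
        if (m[r, c] != 1L) next
        if (r < 2L || c < 2L || r > nrow(m) - 1L || c > ncol(m) - 1L) next
        nb <- m[(r - 1L):(r + 1L), (c - 1L):(c + 1L)] == 1L
        nb[2L, 2L] <- FALSE
        set <- as.vector(t(nb))[-5L]  # row-major ring, center dropped
        if (sum(set) >= 2L && n_components_3x3_rowmajor(set) == 1L) {
          m[r, c] <- 0L
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break  # no deletable pixel; accept remaining block
  }
  m
}

# same as n_components_3x3 but on the 8 ring cells in row-major order
# (NW, N, NE, W, E, SW, S, SE)
n_components_3x3_rowmajor <- function(set) {
  pos <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
               c(1, -1), c(1, 0), c(1, 1))
  cells <- which(set)
  if (length(cells) == 0L) return(0L)
  comp <- seq_along(cells)
  repeat {
    changed <- FALSE
    for (i in seq_along(cells)) for (j in seq_along(cells)) {
      if (comp[i] != comp[j] &&
          max(abs(pos[cells[i], ] - pos[cells[j], ])) <= 1) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# Parallel thinning erodes line ends by a few pixels. Reclaim them by
# walking from each skeleton endpoint through the mask along the local
# direction until the mask runs out (capped to avoid runaway growth
# along wide blobs).
extend_tips <- function(skel, mask, max_steps = 12L) {
  d <- dim(skel)
  nbr_off <- do.call(rbind, .zs_offsets)
  repeat {
    counts <- neighbor_count_mat(skel)
    ends <- which(skel & counts == 1L, arr.ind = TRUE)
    grown <- FALSE
    for (e in seq_len(nrow(ends))) {
      p <- ends[e, ]
      # local direction: endpoint minus the pixel a few steps back
      back <- p
      prev <- p
      for (k in seq_len(3L)) {
        nb <- t(t(nbr_off) + back)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= d[2L]
        nb <- nb[ok, , drop = FALSE]
        inskel <- skel[nb] & !(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L])
        if (!any(inskel)) break
        prev <- back
        back <- nb[which(inskel)[1L], ]
      }
      dir <- p - back
      if (all(dir == 0)) next
      dir <- dir / sqrt(sum(dir^2))
      cur <- p
      for (step in seq_len(max_steps)) {
        nb <- t(t(nbr_off) + cur)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= d[2L]
        nb <- nb[ok, , drop = FALSE]
        free <- mask[nb] & !skel[nb]
        if (!any(free)) break
        cand <- nb[free, , drop = FALSE]
        align <- (cand[, 1L] - cur[1L]) * dir[1L] +
                 (cand[, 2L] - cur[2L]) * dir[2L]
        best <- which.max(align)
        if (align[best] < 0.7) break  # only continue forward
        cur <- cand[best, ]
        skel[cur[1L], cur[2L]] <- TRUE
        grown <- TRUE
      }
    }
    if (!grown) break
  }
  skel
}

#' Skeletonize a binary mask
#'
#' Reduces each detected object to a one-pixel-wide, 8-connected centerline
#' by topology-preserving morphological thinning. Every skeleton pixel is a
#' mask pixel, each connected mask component yields connected skeleton
#' pixels, and no 2x2 block of skeleton pixels remains. Because parallel
#' thinning is known to erode line ends by a few pixels, skeleton
#' endpoints are then extended through the mask along their local
#' direction (`reclaim_tips = TRUE`).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param reclaim_tips Extend eroded line ends back through the mask?
#' @return Logical skeleton matrix of the same dimensions.
#' @export
skeletonize_mask <- function(mask, reclaim_tips = TRUE) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    s1 <- zs_pass(m, 1L)
    s2 <- zs_pass(s1$m, 2L)
    m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  m <- prune_2x2(m)
  skel <- m == 1L
  if (reclaim_tips) {
    skel <- extend_tips(skel, mask != 0)
    skel <- prune_2x2(matrix(as.integer(skel), nrow(skel), ncol(skel))) == 1L
  }
  skel
}
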