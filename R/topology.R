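# Skeleton topology: 8-connected component labeling, endpoint/branch-point
# classification by neighbor counting, branch decomposition, and wire
# length (= closed-boundary perimeter / 2 for one-pixel-wide objects).

# edges between 8-adjacent TRUE pixels, as ranks into which(mask)
adjacency_edges <- function(mask, weights = FALSE) {
  nr <- nrow(mask)
  idx <- which(mask)
  rank <- integer(length(mask))
  rank[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in dirs) {
    r2 <- rows + d[1L]; c2 <- cols + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    lin2 <- (c2 - 1L) * nr + r2
    ok[ok] <- mask[lin2[ok]]
    from <- c(from, rank[idx[ok]])
    to <- c(to, rank[lin2[ok]])
    if (weights) w <- c(w, rep(sqrt(sum(d^2)), sum(ok)))
  }
  list(n = length(idx), from = from, to = to, w = w,
       coords = cbind(row = rows, col = cols))
}

# 8-connected component labeling of a logical mask; returns a list of
# n x 2 (row, col) coordinate matrices
label_components8 <- function(mask) {
  e <- adjacency_edges(mask)
  if (e$n == 0L) return(list())
  g <- igraph::make_empty_graph(n = e$n, directed = FALSE)
  if (length(e$from))
    g <- igraph::add_edges(g, rbind(e$from, e$to))
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(e$n), memb), function(i) e$coords[i, , drop = FALSE])
}

# count of set 8-neighbors for every pixel
neighbor_count_mat <- function(skel) {
  m <- matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  Reduce(`+`, lapply(.zs_offsets, function(o) shift_mat(m, o[1L], o[2L])))
}

#' Label skeleton objects and flag topological errors
#'
#' Each 8-connected skeleton component becomes one object. Endpoints are
#' skeleton pixels with exactly one skeleton neighbor; branch points have
#' three or more. An object is flagged as a detection error when it has
#' more than two endpoints or at least one branch point (overlapping
#' filaments). Objects smaller than `min_object_px` are counted as puncta
#' and excluded from length statistics.
#'
#' @param skeleton Logical skeleton matrix (see [skeletonize_mask]).
#' @param min_object_px Minimum skeleton pixel count for a measurable
#'   object.
#' @return List of `skeleton_object`s, each with pixel coordinates,
#'   endpoints, branch points, branch-free segments with their
#'   branch-cluster adjacency, and `is_error` / `is_punctum` flags.
#' @export
label_objects <- function(skeleton, min_object_px = 3L) {
  skel <- skeleton != 0
  nbr <- neighbor_count_mat(skel)
  comps <- label_components8(skel)
  objs <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    px <- comps[[i]]
    counts <- nbr[px]
    endpoints <- px[counts == 1L, , drop = FALSE]
    branch_points <- px[counts >= 3L, , drop = FALSE]
    is_error <- nrow(endpoints) > 2L || nrow(branch_points) >= 1L
    obj <- structure(
      list(object_id = i, pixels = px, dim = dim(skel),
           endpoints = endpoints, branch_points = branch_points,
           is_error = is_error,
           is_punctum = nrow(px) < min_object_px,
           segments = NULL, clusters = NULL, adjacency = NULL),
      class = "skeleton_object")
    dec <- decompose_branches(obj)
    obj$segments <- dec$segments
    obj$clusters <- dec$clusters
    obj$adjacency <- dec$adjacency
    obj$unresolvable <- dec$unresolvable
    objs[[i]] <- obj
  }
  objs
}

#' @export
print.skeleton_object <- function(x, ...) {
  cat(sprintf("<skeleton_object #%d> %d px, %d endpoints, %d branch px, %s\n",
              x$object_id, nrow(x$pixels), nrow(x$endpoints),
              nrow(x$branch_points),
              if (x$is_error) "ERROR" else if (x$is_punctum) "punctum" else "clean"))
  invisible(x)
}

coords_to_mask <- function(coords, d) {
  m <- matrix(FALSE, d[1L], d[2L])
  m[coords] <- TRUE
  m
}

chebyshev_adjacent <- function(p, q) {
  max(abs(p[1L] - q[1L]), abs(p[2L] - q[2L])) == 1L
}

# order the pixels of a branch-free 8-connected set into a path, walking
# from an end and preferring orthogonal over diagonal steps
order_path <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(px)
  # exact integer squared distances (dist()^2 suffers rounding at 2)
  d2 <- outer(px[, 1L], px[, 1L], `-`)^2 + outer(px[, 2L], px[, 2L], `-`)^2
  adj <- d2 > 0L & d2 <= 2L
  deg <- rowSums(adj)
  start <- which(deg == min(deg))[1L]
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    path[k] <- cur
    visited[cur] <- TRUE
    nxt <- which(adj[cur, ] & !visited)
    if (length(nxt) == 0L) break
    if (length(nxt) > 1L) nxt <- nxt[order(d2[cur, nxt])]  # orthogonal first
    cur <- nxt[1L]
  }
  if (any(!visited))  # not a simple path; keep deterministic raster order
    return(px[order(px[, 1L], px[, 2L]), , drop = FALSE])
  px[path, , drop = FALSE]
}

#' Decompose an error object into branch-free segments
#'
#' Removing the branch-point pixels splits the skeleton into branch-free
#' 8-connected paths (the colored "branches" a user would choose among).
#' Branch points are grouped into 8-connected clusters and the adjacency
#' map records which segment ends meet at which cluster.
#'
#' @param obj A `skeleton_object` from [label_objects].
#' @return List with `segments` (each: `segment_id`, ordered `pixels`),
#'   `clusters` (list of branch-pixel coordinate matrices), `adjacency`
#'   (data frame: `segment_id`, `cluster_id`, `end` = "start"/"end"), and
#'   `unresolvable` (TRUE when nothing but branch points remains).
#' @export
decompose_branches <- function(obj) {
  px <- obj$pixels
  bp <- obj$branch_points
  if (nrow(bp) == 0L) {
    segs <- list(list(segment_id = 1L, pixels = order_path(px)))
    return(list(segments = segs, clusters = list(),
                adjacency = data.frame(segment_id = integer(0),
                                       cluster_id = integer(0),
                                       end = character(0)),
                unresolvable = FALSE))
  }
  d <- obj$dim
  bp_mask <- coords_to_mask(bp, d)
  seg_mask <- coords_to_mask(px, d) & !bp_mask
  if (!any(seg_mask))
    return(list(segments = list(), clusters = label_components8(bp_mask),
                adjacency = data.frame(segment_id = integer(0),
                                       cluster_id = integer(0),
                                       end = character(0)),
                unresolvable = TRUE))
  seg_coords <- label_components8(seg_mask)
  segments <- vector("list", length(seg_coords))
  for (i in seq_along(seg_coords))
    segments[[i]] <- list(segment_id = i, pixels = order_path(seg_coords[[i]]))
  clusters <- label_components8(bp_mask)
  adj <- list()
  for (s in segments) {
    p <- s$pixels
    ends <- list(start = p[1L, ], end = p[nrow(p), ])
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      for (endname in names(ends)) {
        e <- ends[[endname]]
        touch <- any(abs(cl[, 1L] - e[1L]) <= 1L & abs(cl[, 2L] - e[2L]) <= 1L)
        if (touch)
          adj[[length(adj) + 1L]] <- data.frame(
            segment_id = s$segment_id, cluster_id = ci, end = endname)
      }
    }
  }
  adj <- if (length(adj)) do.call(rbind, adj)
         else data.frame(segment_id = integer(0), cluster_id = integer(0),
                         end = character(0))
  list(segments = segments, clusters = clusters, adjacency = adj,
       unresolvable = FALSE)
}

#' Total wire length of a skeleton object
#'
#' The length of the object's one-pixel-wide trace: the minimum spanning
#' tree of the pixel adjacency graph with orthogonal steps weighing 1 and
#' diagonal steps `sqrt(2)`. For a branch-free path this equals the
#' geodesic step-sum, and for any one-pixel-wide object it equals the
#' closed-boundary perimeter divided by two.
#'
#' @param obj A `skeleton_object`, or a logical mask of one object.
#' @return Length in pixels.
#' @export
wire_length <- function(obj) {
  mask <- if (inherits(obj, "skeleton_object"))
    coords_to_mask(obj$pixels, obj$dim) else obj != 0
  e <- adjacency_edges(mask, weights = TRUE)
  if (e$n <= 1L) return(0)
  g <- igraph::make_empty_graph(n = e$n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(e$from, e$to))
  igraph::E(g)$weight <- e$w
  sum(igraph::E(igraph::mst(g))$weight)
}
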