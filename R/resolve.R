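# Overlap resolution: recorded segment-level decisions replace the
# original interactive point-and-click workflow. A decision assigns every
# segment of an error object to exactly one action: keep() concatenates
# segments into one continuous filament (bridged through the shared
# branch-point pixels), discard() removes them as noise.

#' Record a resolution decision for one error object
#'
#' @param object_id Id of the `skeleton_object` the decision applies to.
#' @param actions List of actions, each `list(op = "keep"|"discard",
#'   segments = <integer segment ids>)`. Every segment of the object must
#'   appear in exactly one action.
#' @return A `resolution_decision`.
#' @export
resolution_decision <- function(object_id, actions) {
  for (a in actions) {
    if (!is.list(a) || !a$op %in% c("keep", "discard"))
      stop("each action needs op 'keep' or 'discard'", call. = FALSE)
    if (length(a$segments) < 1L)
      stop("each action must name at least one segment", call. = FALSE)
  }
  structure(list(object_id = as.integer(object_id), actions = actions),
            class = "resolution_decision")
}

#' Read / write decision files
#'
#' Decisions are stored as a JSON list of
#' `{"object_id": i, "actions": [{"op": "keep", "segments": [..]}, ...]}`,
#' enabling batch replay of a manual resolution session.
#'
#' @param path JSON file path.
#' @return `read_decisions`: a list of `resolution_decision` objects named
#'   by object id.
#' @export
read_decisions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(d) {
    actions <- lapply(d$actions, function(a)
      list(op = a$op, segments = as.integer(unlist(a$segments))))
    resolution_decision(d$object_id, actions)
  })
  stats::setNames(out, vapply(out, function(d) as.character(d$object_id), ""))
}

#' @rdname read_decisions
#' @param decisions List of `resolution_decision` objects.
#' @export
write_decisions <- function(decisions, path) {
  payload <- lapply(decisions, function(d)
    list(object_id = d$object_id,
         actions = lapply(d$actions, function(a)
           list(op = a$op, segments = as.integer(a$segments)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

seg_end_clusters <- function(adjacency, seg_id) {
  rows <- adjacency[adjacency$segment_id == seg_id, , drop = FALSE]
  list(start = rows$cluster_id[rows$end == "start"],
       end = rows$cluster_id[rows$end == "end"])
}

# find an ordering + orientation of the kept segments such that
# consecutive segments share a branch cluster at their facing ends
chain_segments <- function(obj, seg_ids) {
  if (length(seg_ids) == 1L) return(list(list(id = seg_ids, flip = FALSE)))
  if (length(seg_ids) > 8L)
    stop("keep() of more than 8 segments is not supported", call. = FALSE)
  ends <- lapply(seg_ids, function(s) seg_end_clusters(obj$adjacency, s))
  names(ends) <- as.character(seg_ids)
  for (ord in perms(seq_along(seg_ids))) {
    for (first_flip in c(FALSE, TRUE)) {
      flips <- logical(length(ord))
      flips[1L] <- first_flip
      ok <- TRUE
      shared <- integer(length(ord) - 1L)
      for (k in seq_len(length(ord) - 1L)) {
        a <- ends[[ord[k]]]; b <- ends[[ord[k + 1L]]]
        a_exit <- if (flips[k]) a$start else a$end
        # next segment must begin at a cluster the previous one exits into
        if (length(intersect(a_exit, b$start))) {
          flips[k + 1L] <- FALSE
          shared[k] <- intersect(a_exit, b$start)[1L]
        } else if (length(intersect(a_exit, b$end))) {
          flips[k + 1L] <- TRUE
          shared[k] <- intersect(a_exit, b$end)[1L]
        } else {
          ok <- FALSE
          break
        }
      }
      if (ok)
        return(lapply(seq_along(ord), function(k)
          list(id = seg_ids[ord[k]], flip = flips[k],
               cluster_after = if (k < length(ord)) shared[k] else NA_integer_)))
    }
  }
  stop("segments ", paste(seg_ids, collapse = ", "),
       " cannot be joined into one continuous filament", call. = FALSE)
}

# shortest pixel bridge through a branch cluster from path end p to next
# segment start q (either may be directly adjacent to the other)
bridge_through_cluster <- function(cluster_px, p, q) {
  if (chebyshev_adjacent(p, q)) return(NULL)
  n <- nrow(cluster_px)
  touch_p <- which(abs(cluster_px[, 1L] - p[1L]) <= 1L &
                   abs(cluster_px[, 2L] - p[2L]) <= 1L)
  touch_q <- which(abs(cluster_px[, 1L] - q[1L]) <= 1L &
                   abs(cluster_px[, 2L] - q[2L]) <= 1L)
  if (!length(touch_p) || !length(touch_q))
    stop("segments do not meet at the shared branch cluster", call. = FALSE)
  # BFS over cluster pixels
  prev <- rep(NA_integer_, n)
  dist <- rep(Inf, n)
  queue <- touch_p
  dist[touch_p] <- 0
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur %in% touch_q) {
      path <- cur
      while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
      return(cluster_px[path, , drop = FALSE])
    }
    nb <- which(is.infinite(dist) &
                abs(cluster_px[, 1L] - cluster_px[cur, 1L]) <= 1L &
                abs(cluster_px[, 2L] - cluster_px[cur, 2L]) <= 1L)
    for (v in nb) {
      dist[v] <- dist[cur] + 1
      prev[v] <- cur
      queue <- c(queue, v)
    }
  }
  stop("no bridging path through the branch cluster", call. = FALSE)
}

#' Apply a resolution decision to an error object
#'
#' Each keep() action yields one filament whose pixel path is the ordered
#' concatenation of its segments, bridged through the shared branch-point
#' pixels; branch-point pixels belong to every filament that traverses
#' them. discard() actions remove their segments as noise.
#'
#' @param obj A `skeleton_object`.
#' @param decision A [resolution_decision] covering all its segments.
#' @param pixel_size_um Micrometers per pixel.
#' @return Data frame of filament records (one row per keep action) with a
#'   `path` list column of ordered pixel coordinates.
#' @export
apply_resolution <- function(obj, decision, pixel_size_um) {
  seg_ids <- vapply(obj$segments, `[[`, integer(1L), "segment_id")
  mentioned <- unlist(lapply(decision$actions, `[[`, "segments"))
  if (anyDuplicated(mentioned))
    stop("segments assigned to more than one action: ",
         paste(unique(mentioned[duplicated(mentioned)]), collapse = ", "),
         call. = FALSE)
  uncovered <- setdiff(seg_ids, mentioned)
  if (length(uncovered))
    stop("decision for object ", obj$object_id,
         " leaves segments uncovered: ", paste(uncovered, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(mentioned, seg_ids)
  if (length(unknown))
    stop("decision names unknown segments: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  seg_by_id <- stats::setNames(obj$segments, as.character(seg_ids))
  paths <- list()
  for (a in decision$actions) {
    if (a$op == "discard") next
    chain <- chain_segments(obj, as.integer(a$segments))
    path <- NULL
    for (k in seq_along(chain)) {
      sp <- seg_by_id[[as.character(chain[[k]]$id)]]$pixels
      if (chain[[k]]$flip) sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
      if (!is.null(path)) {
        cl <- obj$clusters[[chain[[k - 1L]]$cluster_after]]
        br <- bridge_through_cluster(cl, path[nrow(path), ], sp[1L, ])
        if (!is.null(br)) path <- rbind(path, br)
      }
      path <- rbind(path, sp)
    }
    paths[[length(paths) + 1L]] <- path
  }
  filament_records(paths, object_id = obj$object_id,
                   pixel_size_um = pixel_size_um)
}

filament_records <- function(paths, object_id, pixel_size_um,
                             frame_index = 0L, lengths_px = NULL) {
  n <- max(length(paths), length(lengths_px))
  if (n == 0L) {
    df <- data.frame(filament_id = integer(0), object_id = integer(0),
                     n_pixels = integer(0), length_px = numeric(0),
                     length_um = numeric(0), frame_index = integer(0))
    df$path <- list()
    return(df)
  }
  if (is.null(lengths_px))
    lengths_px <- vapply(paths, measure_path_px, numeric(1L))
  df <- data.frame(filament_id = seq_len(n),
                   object_id = rep_len(object_id, n),
                   n_pixels = if (length(paths))
                     vapply(paths, nrow, integer(1L)) else NA_integer_,
                   length_px = lengths_px,
                   length_um = lengths_px * pixel_size_um,
                   frame_index = rep_len(as.integer(frame_index), n))
  df$path <- if (length(paths)) paths else rep(list(NULL), n)
  df
}

#' Resolve all skeleton objects under a correction policy
#'
#' Policies mirror the three ways overlap errors can be handled:
#' `"none"` (no correction: every object, including overlaps, becomes one
#' filament whose length is its full perimeter / 2), `"remove_errors"`
#' (overlapping objects are dropped from the analysis), and `"decisions"`
#' (recorded segment-level decisions resolve each error object).
#' Puncta (objects below the minimum size) are excluded from all policies
#' and reported in the `n_puncta` attribute.
#'
#' @param objects List of `skeleton_object`s from [label_objects].
#' @param policy `"none"`, `"remove_errors"` or `"decisions"`.
#' @param pixel_size_um Micrometers per pixel.
#' @param decisions Named list of [resolution_decision]s (names = object
#'   ids), required for `policy = "decisions"`.
#' @param frame_index Frame index stamped on the records.
#' @return Data frame of filament records; attribute `n_puncta` counts the
#'   excluded sub-threshold objects.
#' @export
resolve_all <- function(objects, policy = c("decisions", "none", "remove_errors"),
                        pixel_size_um, decisions = NULL, frame_index = 0L) {
  policy <- match.arg(policy)
  n_puncta <- sum(vapply(objects, `[[`, logical(1L), "is_punctum"))
  objects_m <- Filter(function(o) !o$is_punctum, objects)
  recs <- list()
  if (policy == "decisions") {
    err_ids <- vapply(Filter(function(o) o$is_error, objects_m),
                      `[[`, integer(1L), "object_id")
    have <- as.integer(names(decisions))
    missing <- setdiff(err_ids, have)
    if (length(missing))
      stop("unresolved error objects: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  for (obj in objects_m) {
    dec <- decisions[[as.character(obj$object_id)]]
    if (policy == "remove_errors" && obj$is_error) next
    if (policy == "decisions" && (obj$is_error || !is.null(dec))) {
      recs[[length(recs) + 1L]] <- apply_resolution(obj, dec, pixel_size_um)
    } else if (obj$is_error) {  # policy "none": full perimeter / 2
      recs[[length(recs) + 1L]] <- filament_records(
        list(), object_id = obj$object_id, pixel_size_um = pixel_size_um,
        lengths_px = wire_length(obj))
    } else {
      recs[[length(recs) + 1L]] <- filament_records(
        list(obj$segments[[1L]]$pixels), object_id = obj$object_id,
        pixel_size_um = pixel_size_um)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else filament_records(list(), 0L, 1)
  out$filament_id <- seq_len(nrow(out))
  out$frame_index <- rep(as.integer(frame_index), nrow(out))
  attr(out, "n_puncta") <- n_puncta
  out
}

#' Propose segment pairings by collinearity
#'
#' An automatic helper that imitates the choice a user typically makes at
#' a crossing: at each branch cluster, segment ends are paired with the
#' most nearly opposite incoming directions, and paired segments are
#' chained into keep() actions. The result is an ordinary
#' [resolution_decision] which can be reviewed, edited and replayed.
#'
#' @param obj An error `skeleton_object`.
#' @param min_opposition Minimum opposition (`-cos` of the angle between
#'   incoming directions) for two ends to be paired; default 0.3.
#' @return A [resolution_decision].
#' @export
propose_decisions <- function(obj, min_opposition = 0.3) {
  segs <- obj$segments
  adj <- obj$adjacency
  seg_dir <- function(seg_id, end) {
    p <- segs[[seg_id]]$pixels
    n <- nrow(p)
    k <- min(5L, n)
    v <- if (end == "end") p[n, ] - p[n - k + 1L, ] else p[1L, ] - p[k, ]
    if (all(v == 0)) v <- c(1, 0)
    v / sqrt(sum(v^2))
  }
  # union-find over segments via paired ends
  parent <- seq_along(segs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) parent[find(i)] <<- find(j)
  for (ci in seq_along(obj$clusters)) {
    ends <- adj[adj$cluster_id == ci, , drop = FALSE]
    if (nrow(ends) < 2L) next
    dirs <- t(vapply(seq_len(nrow(ends)), function(k)
      seg_dir(ends$segment_id[k], ends$end[k]), numeric(2L)))
    free <- rep(TRUE, nrow(ends))
    repeat {
      best <- NULL; best_val <- min_opposition
      for (i in which(free)) for (j in which(free)) {
        if (j <= i || ends$segment_id[i] == ends$segment_id[j]) next
        opp <- -sum(dirs[i, ] * dirs[j, ])
        if (opp >= best_val) {
          best <- c(i, j); best_val <- opp
        }
      }
      if (is.null(best)) break
      union(ends$segment_id[best[1L]], ends$segment_id[best[2L]])
      free[best] <- FALSE
    }
  }
  groups <- split(seq_along(segs), vapply(seq_along(segs), find, integer(1L)))
  actions <- lapply(groups, function(g) list(op = "keep", segments = as.integer(g)))
  resolution_decision(obj$object_id, unname(actions))
}
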