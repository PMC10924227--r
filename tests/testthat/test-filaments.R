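make_line_skel <- function(d, px) {
  m <- matrix(FALSE, d[1], d[2])
  m[px] <- TRUE
  m
}

test_that("label_objects classifies canonical shapes", {
  line <- matrix(FALSE, 12, 12); line[6, 2:11] <- TRUE
  objs <- label_objects(line)
  expect_length(objs, 1L)
  expect_equal(nrow(objs[[1]]$endpoints), 2L)
  expect_equal(nrow(objs[[1]]$branch_points), 0L)
  expect_false(objs[[1]]$is_error)

  x <- matrix(FALSE, 15, 15)
  for (i in 2:14) { x[i, i] <- TRUE; x[i, 16 - i] <- TRUE }
  objs <- label_objects(x)
  expect_length(objs, 1L)
  expect_equal(nrow(objs[[1]]$endpoints), 4L)
  expect_gte(nrow(objs[[1]]$branch_points), 1L)
  expect_true(objs[[1]]$is_error)

  three <- matrix(FALSE, 20, 20)
  three[3, 2:10] <- TRUE; three[9, 2:10] <- TRUE; three[15, 2:10] <- TRUE
  expect_length(label_objects(three), 3L)
})

test_that("puncta below the size threshold are flagged and excluded", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE                 # 1-px punctum
  m[6, 2:8] <- TRUE               # real filament
  objs <- label_objects(m, min_object_px = 3L)
  expect_equal(sum(vapply(objs, `[[`, logical(1), "is_punctum")), 1L)
  recs <- resolve_all(objs, "none", pixel_size_um = 0.1)
  expect_equal(nrow(recs), 1L)
  expect_equal(attr(recs, "n_puncta"), 1L)
})

test_that("branch decomposition produces the expected segments", {
  x <- matrix(FALSE, 15, 15)
  for (i in 2:14) { x[i, i] <- TRUE; x[i, 16 - i] <- TRUE }
  obj <- label_objects(x)[[1]]
  expect_length(obj$segments, 4L)
  expect_length(obj$clusters, 1L)
  expect_equal(sort(unique(obj$adjacency$segment_id)), 1:4)

  tee <- matrix(FALSE, 15, 15)
  tee[3:13, 7] <- TRUE; tee[8, 8:13] <- TRUE
  obj_t <- label_objects(tee)[[1]]
  expect_true(obj_t$is_error)
  expect_length(obj_t$segments, 3L)

  line <- matrix(FALSE, 10, 10); line[4, 2:9] <- TRUE
  obj_l <- label_objects(line)[[1]]
  expect_length(obj_l$segments, 1L)
  expect_equal(nrow(obj_l$segments[[1]]$pixels), 8L)
})

test_that("apply_resolution joins collinear arms and validates coverage", {
  x <- matrix(FALSE, 15, 15)
  for (i in 2:14) { x[i, i] <- TRUE; x[i, 16 - i] <- TRUE }
  obj <- label_objects(x)[[1]]
  dec <- propose_decisions(obj)
  recs <- apply_resolution(obj, dec, pixel_size_um = 0.1)
  expect_equal(nrow(recs), 2L)
  # each recovered filament spans close to the full 13-px diagonal
  expect_true(all(recs$length_px > 0.85 * 12 * sqrt(2)))

  # uncovered segment
  bad <- resolution_decision(obj$object_id,
                             list(list(op = "keep", segments = c(1L, 2L))))
  expect_error(apply_resolution(obj, bad, 0.1), "uncovered")
  # unknown segment
  bad2 <- resolution_decision(obj$object_id,
                              list(list(op = "keep", segments = 1:5)))
  expect_error(apply_resolution(obj, bad2, 0.1), "unknown")
})

test_that("discard actions drop segments as noise", {
  tee <- matrix(FALSE, 15, 15)
  tee[3:13, 7] <- TRUE; tee[8, 8:13] <- TRUE
  obj <- label_objects(tee)[[1]]
  # identify the long stem segments vs the short arm
  sizes <- vapply(obj$segments, function(s) nrow(s$pixels), integer(1))
  arm <- which.min(sizes)
  keep_ids <- setdiff(seq_along(sizes), arm)
  dec <- resolution_decision(obj$object_id, list(
    list(op = "keep", segments = keep_ids),
    list(op = "discard", segments = arm)))
  recs <- apply_resolution(obj, dec, pixel_size_um = 0.1)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$length_px, 10, tolerance = 0.25)  # 11-px stem
})

test_that("pixel accounting: kept + discarded + branch pixels cover the object", {
  fx <- make_crossing_fixture(c(30, 120), c(8, 9), rng_seed = 3)
  proc <- preprocess(fx$image)
  obj <- Filter(function(o) o$is_error, label_objects(proc$skeleton))[[1]]
  dec <- propose_decisions(obj)
  recs <- apply_resolution(obj, dec, 0.1)
  kept <- unique(do.call(rbind, recs$path))
  seg_px <- do.call(rbind, lapply(obj$segments, `[[`, "pixels"))
  branch_px <- obj$branch_points
  covered <- unique(rbind(kept, seg_px, branch_px))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(covered), key(obj$pixels))
  # kept paths only use object pixels
  expect_true(all(key(kept) %in% key(obj$pixels)))
})

test_that("resolve_all implements the three correction policies", {
  img <- matrix(FALSE, 40, 40)
  img[5, 2:21] <- TRUE           # clean 20 px
  img[10, 2:21] <- TRUE
  img[15, 2:21] <- TRUE
  for (r in 22:34) { img[r, r] <- TRUE; img[r, 56 - r] <- TRUE }  # X at (28, 28)
  objs <- label_objects(img)
  expect_equal(sum(vapply(objs, `[[`, logical(1), "is_error")), 1L)

  r_rm <- resolve_all(objs, "remove_errors", 0.1)
  expect_equal(nrow(r_rm), 3L)
  r_none <- resolve_all(objs, "none", 0.1)
  expect_equal(nrow(r_none), 4L)

  err_obj <- Filter(function(o) o$is_error, objs)[[1]]
  decs <- stats::setNames(list(propose_decisions(err_obj)),
                          err_obj$object_id)
  r_dec <- resolve_all(objs, "decisions", 0.1, decisions = decs)
  expect_equal(nrow(r_dec), 5L)
  expect_gt(mean(r_none$length_um), mean(r_dec$length_um))

  expect_error(resolve_all(objs, "decisions", 0.1), "unresolved")
})

test_that("length measurement follows the perimeter/2 = step-sum contract", {
  horiz <- path_matrix(cbind(5L, 2:12))
  res <- measure_length(horiz, pixel_size_um = 0.1)
  expect_equal(res$length_px, 10)
  expect_equal(res$length_um, 1.0)

  diag <- path_matrix(cbind(2:12, 2:12))
  expect_equal(measure_length(diag, 0.1)$length_px, 10 * sqrt(2))

  # boundary-walk oracle: closed contour perimeter / 2 equals the step-sum
  for (p in list(horiz, diag)) {
    m <- matrix(FALSE, 15, 15); m[p] <- TRUE
    expect_equal(boundary_perimeter(m) / 2, measure_length(p, 1)$length_px,
                 tolerance = 1e-9)
  }

  # wire length of a branched object equals its boundary perimeter / 2
  x <- matrix(FALSE, 15, 15)
  for (i in 2:14) { x[i, i] <- TRUE; x[i, 16 - i] <- TRUE }
  obj <- label_objects(x)[[1]]
  expect_equal(wire_length(obj), boundary_perimeter(x) / 2, tolerance = 0.08)

  expect_error(measure_length(path_matrix(cbind(c(1L, 5L), c(1L, 1L))), 1),
               "not 8-connected")
})

test_that("summaries bin lengths, count filaments, and integrate polymer", {
  s <- summarize_filaments(c(1.0, 2.0, 3.5), bin_um = 3)
  expect_equal(s$histogram$count, c(2L, 1L))
  expect_equal(s$histogram$bin_start_um, c(0, 3))
  expect_equal(s$n_filaments, 3L)
  expect_equal(s$total_polymer_um, 6.5)

  e <- summarize_filaments(numeric(0))
  expect_equal(e$n_filaments, 0L)
  expect_equal(e$total_polymer_um, 0)
  expect_equal(nrow(e$histogram), 0L)

  # boundary value lands in the left-closed bin to its right
  b <- summarize_filaments(c(3.0), bin_um = 3)
  expect_equal(b$histogram$count, c(0L, 1L))
})
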