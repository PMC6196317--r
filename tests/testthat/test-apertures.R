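# Stimulus aperture movies: design arithmetic, geometry, masking, I/O.

test_that("wedge design reproduces the printed cycle and run arithmetic", {
  w <- make_wedge_movie(width_deg = 36, step_deg = 18, n_cycles = 8,
                        fov_radius_deg = 37.5, grid_n = 41, tr_s = 3)
  expect_equal(w$meta$frames_per_cycle, 20)
  expect_equal(w$meta$frames_per_cycle * w$tr_s, 60)   # 60 s per cycle
  expect_equal(n_frames(w), 160)
  run <- finalize_run(w, blank_volumes = 20, dummy_volumes = 3)
  expect_equal(n_frames(run), 183)
  expect_equal(run_duration_s(run), 549)
  expect_equal(sum(run$labels == "dummy"), 3)
  expect_equal(sum(run$labels == "blank"), 20)
})

test_that("single-step wedge (step 360) is the identity cycle", {
  w <- make_wedge_movie(width_deg = 36, step_deg = 360, n_cycles = 2,
                        fov_radius_deg = 10, grid_n = 21)
  expect_equal(n_frames(w), 2)
  expect_equal(w$frames[, , 1], w$frames[, , 2])
})

test_that("one wedge cycle covers every in-field cell with ~width/step hits", {
  w <- make_wedge_movie(width_deg = 36, step_deg = 18, n_cycles = 1,
                        fov_radius_deg = 10, grid_n = 31)
  g <- prfmapr:::grid_centers(31, 10)
  counts <- rowSums(matrix(w$frames, ncol = n_frames(w)))
  expect_true(all(counts[g$in_field] >= 1))       # full coverage
  expect_true(all(abs(counts[g$in_field] - 2) <= 1))  # 36/18 = 2 +/- 1
  expect_true(all(counts[!g$in_field] == 0))
})

test_that("anticlockwise wedge is the reversed clockwise cycle up to shift", {
  cw <- make_wedge_movie(n_cycles = 1, fov_radius_deg = 10, grid_n = 21,
                         direction = "clockwise")
  acw <- make_wedge_movie(n_cycles = 1, fov_radius_deg = 10, grid_n = 21,
                          direction = "anticlockwise")
  n <- n_frames(cw)
  # width = 2 * step here, so cw frame k equals acw frame (-k - 2) mod n
  for (k in 0:(n - 1)) {
    j <- (-k - 2) %% n
    expect_equal(cw$frames[, , k + 1], acw$frames[, , j + 1])
  }
})

test_that("ring designs give the printed frame counts and log spacing", {
  r1 <- make_ring_movie(n_steps = 16, n_reps = 10, fov_radius_deg = 37.5,
                        grid_n = 41)
  expect_equal(n_frames(r1), 160)
  run1 <- finalize_run(r1, blank_volumes = 20)
  expect_equal(n_frames(run1), 183)
  expect_equal(run_duration_s(run1), 549)
  run2 <- finalize_run(make_ring_movie(n_steps = 12, n_reps = 5,
                                       fov_radius_deg = 9, grid_n = 41),
                       blank_volumes = 15)
  expect_equal(n_frames(run2), 78)
  expect_equal(run_duration_s(run2), 234)
  # consecutive mid-radii have a constant ratio
  mids <- r1$meta$mid_radii
  ratios <- mids[-1] / mids[-length(mids)]
  expect_true(all(abs(ratios - ratios[1]) < 1e-9))
})

test_that("two-step ring has exactly two distinct repeated frames", {
  r <- make_ring_movie(n_steps = 2, n_reps = 3, fov_radius_deg = 10,
                       grid_n = 21)
  expect_equal(n_frames(r), 6)
  expect_equal(r$frames[, , 1], r$frames[, , 3])
  expect_equal(r$frames[, , 2], r$frames[, , 4])
  expect_false(isTRUE(all.equal(r$frames[, , 1], r$frames[, , 2])))
})

test_that("contracting ring reverses the within-cycle order", {
  ex <- make_ring_movie(n_steps = 4, n_reps = 2, fov_radius_deg = 10,
                        grid_n = 21, direction = "expanding")
  co <- make_ring_movie(n_steps = 4, n_reps = 2, fov_radius_deg = 10,
                        grid_n = 21, direction = "contracting")
  for (i in 1:4)
    expect_equal(ex$frames[, , i], co$frames[, , 5 - i])
})

test_that("full-field design: trial structure and on-fraction", {
  m <- make_fullfield_movie(n_trials = 10, on_volumes = 1, off_volumes = 9,
                            fov_radius_deg = 10, grid_n = 21)
  expect_equal(n_frames(m), 100)
  expect_equal(sum(m$labels == "fullfield") / n_frames(m), 1 / 10)
  one <- make_fullfield_movie(n_trials = 1, on_volumes = 1, off_volumes = 0,
                              fov_radius_deg = 10, grid_n = 21)
  expect_equal(n_frames(one), 1)
  g <- prfmapr:::grid_centers(21, 10)
  expect_equal(as.vector(one$frames[, , 1]), as.numeric(g$in_field))
})

test_that("finalize_run frame arithmetic is exact and zero-padding a no-op", {
  m <- make_fullfield_movie(n_trials = 2, fov_radius_deg = 10, grid_n = 21)
  for (b in c(0, 5, 20)) for (d in c(0, 3)) {
    r <- finalize_run(m, blank_volumes = b, dummy_volumes = d)
    expect_equal(n_frames(r), n_frames(m) + b + d)
  }
  same <- finalize_run(m, blank_volumes = 0, dummy_volumes = 0)
  expect_equal(same$frames, m$frames)
  expect_equal(same$labels, m$labels)
})

test_that("mask_region keeps only the requested quadrant and is idempotent", {
  m <- make_wedge_movie(n_cycles = 1, fov_radius_deg = 10, grid_n = 21)
  km <- mask_region(m, keep_quadrant("upper-right"))
  g <- prfmapr:::grid_centers(21, 10)
  flat <- matrix(km$frames, ncol = n_frames(km))
  expect_true(all(flat[g$cx <= 0 | g$cy <= 0, ] == 0))
  # frame-wise pixel counts never increase
  s0 <- apply(matrix(m$frames, ncol = n_frames(m)), 2, sum)
  s1 <- apply(flat, 2, sum)
  expect_true(all(s1 <= s0))
  # idempotent
  km2 <- mask_region(km, keep_quadrant("upper-right"))
  expect_equal(km2$frames, km$frames)
  # keep-everything is the identity
  ki <- mask_region(m, function(x, y) rep(TRUE, length(x)))
  expect_equal(ki$frames, m$frames)
  # removing everything warns but is legal
  expect_warning(mask_region(m, function(x, y) rep(FALSE, length(x))),
                 "blank")
})

test_that("design validation errors fire", {
  expect_error(make_wedge_movie(step_deg = 17), "design error")
  expect_error(make_wedge_movie(grid_n = 8), "resolution")
  expect_error(make_ring_movie(inner_radius_deg = 12, fov_radius_deg = 10),
               "design error")
  expect_error(make_ring_movie(n_steps = 1), "design error")
})

test_that("run_duration_s is frames times TR", {
  m <- make_fullfield_movie(n_trials = 1, off_volumes = 0,
                            fov_radius_deg = 10, grid_n = 21, tr_s = 2.5)
  expect_equal(run_duration_s(m), 2.5)
})

test_that("aperture movies round-trip through NIfTI + JSON sidecar", {
  m <- finalize_run(make_ring_movie(n_steps = 4, n_reps = 2,
                                    fov_radius_deg = 10, grid_n = 21),
                    blank_volumes = 2)
  path <- file.path(tempdir(), "movie_rt")
  write_aperture_movie(m, path)
  m2 <- read_aperture_movie(path)
  expect_equal(m2$frames, m$frames)
  expect_equal(m2$labels, m$labels)
  expect_equal(m2$fov_radius_deg, m$fov_radius_deg)
  expect_equal(m2$tr_s, m$tr_s)
  unlink(paste0(path, c(".nii.gz", ".json")))
})
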