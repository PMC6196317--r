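# Binary stimulus-aperture movies: the stimulus model for pRF fitting.
#
# Coordinate conventions used throughout the package:
#   * degrees of visual angle, fixation at the origin, x rightward, y upward
#   * polar angle measured counter-clockwise from the 3-o'clock direction
#   * the aperture grid spans [-fov, +fov] on both axes; a cell belongs to a
#     shape iff its *center* does

#' Construct an aperture movie
#'
#' An aperture movie is the per-acquisition-volume binary mask of stimulated
#' visual-field locations. Frames are stored as a `grid_n x grid_n x n_frames`
#' 0/1 array; `frames[i, j, k]` is the cell centered at `x = xs[i]`,
#' `y = ys[j]` during volume `k`, where `xs`/`ys` run from `-fov_radius_deg`
#' to `+fov_radius_deg`. Cells whose center lies beyond `fov_radius_deg` are
#' forced to 0 in every frame.
#'
#' @param frames numeric 0/1 array, `grid_n x grid_n x n_frames`.
#' @param fov_radius_deg radius of the represented field of view (degrees).
#' @param tr_s repetition time: seconds per frame/volume.
#' @param labels per-frame tag, one of `"wedge"`, `"ring"`, `"fullfield"`,
#'   `"blank"`, `"dummy"`.
#' @param meta free-form design metadata (kept through masking/concatenation).
#' @return An object of class `aperture_movie`.
#' @export
aperture_movie <- function(frames, fov_radius_deg, tr_s, labels,
                           meta = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[1] == dim(frames)[2])
  n <- dim(frames)[3]
  if (length(labels) != n)
    stop("labels must have one entry per frame")
  if (!all(frames %in% c(0, 1)))
    stop("aperture frames must be binary (0/1)")
  if (fov_radius_deg <= 0 || tr_s <= 0)
    stop("fov_radius_deg and tr_s must be positive")
  g <- grid_centers(dim(frames)[1], fov_radius_deg)
  # enforce the out-of-field invariant
  out <- !g$in_field
  if (any(out)) {
    flat <- matrix(frames, ncol = n)
    flat[out, ] <- 0
    frames <- array(flat, dim = dim(frames))
  }
  if (is.null(meta$runs)) meta$runs <- list(seq_len(n))
  structure(list(frames = frames, fov_radius_deg = fov_radius_deg,
                 tr_s = tr_s, labels = labels, meta = meta),
            class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf("<aperture_movie> %d x %d grid, %d frames, fov %.3g deg, TR %g s\n",
              dim(x$frames)[1], dim(x$frames)[2], n_frames(x),
              x$fov_radius_deg, x$tr_s))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames (volumes) in a movie
#' @param movie an `aperture_movie`.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

# cell-center coordinates for a grid_n x grid_n aperture grid
grid_centers <- function(grid_n, fov_radius_deg) {
  xs <- seq(-fov_radius_deg, fov_radius_deg, length.out = grid_n)
  cx <- rep(xs, times = grid_n)        # column-major flattening: x fastest
  cy <- rep(xs, each = grid_n)
  ecc <- sqrt(cx^2 + cy^2)
  list(xs = xs, cx = cx, cy = cy, ecc = ecc,
       in_field = ecc <= fov_radius_deg + 1e-9)
}

check_grid <- function(grid_n) {
  if (grid_n < 16) stop("resolution error: grid_n must be at least 16")
}

#' Rotating-wedge aperture movie
#'
#' One frame per acquisition volume; on frame `k` (0-based within a cycle)
#' the wedge's leading edge sits at `start_deg + k * step_deg`
#' (anticlockwise) or `start_deg - k * step_deg` (clockwise) and the wedge
#' spans `width_deg` of polar angle behind it, restricted to
#' `ecc <= fov_radius_deg`. A cycle contains `360 / step_deg` frames.
#'
#' Defaults reproduce the wide-field mapping design: a 36 deg wedge stepping
#' 18 deg per 3-s volume, so a full rotation takes 20 volumes = 60 s, with
#' 8 cycles per run.
#'
#' @param width_deg wedge angular width, in (0, 360].
#' @param step_deg rotation per volume; must divide 360.
#' @param n_cycles number of full rotations.
#' @param fov_radius_deg stimulated field-of-view radius (degrees).
#' @param grid_n grid cells per side (odd values put a cell at fixation).
#' @param tr_s repetition time (seconds).
#' @param direction `"clockwise"` or `"anticlockwise"`.
#' @param start_deg polar angle of the leading edge on the first frame
#'   (default 90, i.e. 12 o'clock).
#' @return An `aperture_movie` with all frames labeled `"wedge"`.
#' @export
make_wedge_movie <- function(width_deg = 36, step_deg = 18, n_cycles = 8,
                             fov_radius_deg = 37.5, grid_n = 101, tr_s = 3,
                             direction = c("clockwise", "anticlockwise"),
                             start_deg = 90) {
  direction <- match.arg(direction)
  check_grid(grid_n)
  if (width_deg <= 0 || width_deg > 360)
    stop("design error: width_deg must be in (0, 360]")
  if (step_deg <= 0 || abs(360 / step_deg - round(360 / step_deg)) > 1e-9)
    stop("design error: 360 must be an integer multiple of step_deg")
  if (n_cycles < 1) stop("design error: n_cycles must be positive")
  per_cycle <- round(360 / step_deg)
  g <- grid_centers(grid_n, fov_radius_deg)
  theta <- (atan2(g$cy, g$cx) * 180 / pi) %% 360
  frames <- array(0, dim = c(grid_n, grid_n, per_cycle * n_cycles))
  for (k in seq_len(per_cycle)) {
    off <- (k - 1) * step_deg
    rel <- if (direction == "anticlockwise")
      (theta - start_deg - off) %% 360
    else                       # leading edge at start - off, wedge behind it
      (theta - (start_deg - off - width_deg)) %% 360
    cell <- as.numeric(rel < width_deg & g$in_field)
    for (c_ in seq_len(n_cycles))
      frames[, , (c_ - 1) * per_cycle + k] <- cell
  }
  aperture_movie(frames, fov_radius_deg, tr_s,
                 labels = rep("wedge", per_cycle * n_cycles),
                 meta = list(kind = "wedge", width_deg = width_deg,
                             step_deg = step_deg, n_cycles = n_cycles,
                             frames_per_cycle = per_cycle,
                             direction = direction, start_deg = start_deg))
}

#' Expanding/contracting ring aperture movie
#'
#' Ring mid-radii are logarithmically spaced between `inner_radius_deg` and
#' `fov_radius_deg`; ring `i` occupies the annulus between the geometric
#' means of neighboring mid-radii (so consecutive mid-radii have a constant
#' ratio and the rings tile the mapped annulus). One frame per step,
#' repeated `n_reps` times; `"contracting"` reverses the within-cycle order.
#'
#' @param n_steps radii per cycle (>= 2).
#' @param n_reps cycles per run.
#' @param inner_radius_deg smallest mid-radius (> 0).
#' @param direction `"expanding"` or `"contracting"`.
#' @inheritParams make_wedge_movie
#' @return An `aperture_movie` with all frames labeled `"ring"`; the
#'   mid-radius schedule is kept in `meta$mid_radii`.
#' @export
make_ring_movie <- function(n_steps = 16, n_reps = 10, fov_radius_deg = 37.5,
                            inner_radius_deg = 0.28, grid_n = 101, tr_s = 3,
                            direction = c("expanding", "contracting")) {
  direction <- match.arg(direction)
  check_grid(grid_n)
  if (n_steps < 2) stop("design error: n_steps must be at least 2")
  if (n_reps < 1) stop("design error: n_reps must be positive")
  if (inner_radius_deg <= 0) stop("design error: inner_radius_deg must be > 0")
  if (inner_radius_deg >= fov_radius_deg)
    stop("design error: inner_radius_deg must be smaller than fov_radius_deg")
  mid <- exp(seq(log(inner_radius_deg), log(fov_radius_deg),
                 length.out = n_steps))
  q <- sqrt(mid[2] / mid[1])          # constant half-step ratio
  lo <- mid / q
  hi <- pmin(mid * q, fov_radius_deg)
  g <- grid_centers(grid_n, fov_radius_deg)
  cycle <- array(0, dim = c(grid_n, grid_n, n_steps))
  for (i in seq_len(n_steps))
    cycle[, , i] <- as.numeric(g$ecc >= lo[i] & g$ecc < hi[i] + 1e-9 &
                                 g$in_field)
  order_ <- if (direction == "expanding") seq_len(n_steps) else rev(seq_len(n_steps))
  frames <- array(0, dim = c(grid_n, grid_n, n_steps * n_reps))
  for (r in seq_len(n_reps))
    frames[, , (r - 1) * n_steps + seq_len(n_steps)] <- cycle[, , order_]
  aperture_movie(frames, fov_radius_deg, tr_s,
                 labels = rep("ring", n_steps * n_reps),
                 meta = list(kind = "ring", n_steps = n_steps,
                             n_reps = n_reps, mid_radii = mid,
                             inner_radius_deg = inner_radius_deg,
                             direction = direction))
}

#' Full-field on/off aperture movie (HRF estimation design)
#'
#' Each trial shows the full stimulated disk for `on_volumes` frames followed
#' by `off_volumes` blank frames. The default (10 trials of 1 volume on +
#' 9 volumes off at TR 3 s) is the 3 s on / 27 s off event design used for
#' per-subject HRF measurement.
#'
#' @param n_trials,on_volumes,off_volumes positive counts (off_volumes may be 0).
#' @inheritParams make_wedge_movie
#' @return An `aperture_movie` with frames labeled `"fullfield"`/`"blank"`;
#'   1-based trial-onset frame indices are kept in `meta$trial_onsets`.
#' @export
make_fullfield_movie <- function(n_trials = 10, on_volumes = 1,
                                 off_volumes = 9, fov_radius_deg = 37.5,
                                 grid_n = 101, tr_s = 3) {
  check_grid(grid_n)
  if (n_trials < 1 || on_volumes < 1 || off_volumes < 0)
    stop("design error: counts must be positive (off_volumes may be 0)")
  g <- grid_centers(grid_n, fov_radius_deg)
  disk <- matrix(as.numeric(g$in_field), grid_n, grid_n)
  per_trial <- on_volumes + off_volumes
  frames <- array(0, dim = c(grid_n, grid_n, n_trials * per_trial))
  labels <- rep(rep(c("fullfield", "blank"), c(on_volumes, off_volumes)),
                n_trials)
  for (t_ in seq_len(n_trials))
    for (k in seq_len(on_volumes))
      frames[, , (t_ - 1) * per_trial + k] <- disk
  aperture_movie(frames, fov_radius_deg, tr_s, labels,
                 meta = list(kind = "fullfield", n_trials = n_trials,
                             on_volumes = on_volumes,
                             off_volumes = off_volumes,
                             trial_len = per_trial,
                             trial_onsets = (seq_len(n_trials) - 1) *
                               per_trial + 1))
}

#' Add end-of-run blanks and initial dummy volumes
#'
#' Prepends `dummy_volumes` blank frames labeled `"dummy"` (discarded
#' volumes acquired while the signal reaches equilibrium) and appends
#' `blank_volumes` frames labeled `"blank"`. Analysis-side loaders drop the
#' dummy frames.
#'
#' @param movie an `aperture_movie`.
#' @param blank_volumes blank frames appended at the end of the run.
#' @param dummy_volumes discarded frames prepended (default 3).
#' @export
finalize_run <- function(movie, blank_volumes, dummy_volumes = 3) {
  stopifnot(inherits(movie, "aperture_movie"),
            blank_volumes >= 0, dummy_volumes >= 0)
  if (n_frames(movie) == 0) stop("movie must be nonempty")
  gn <- dim(movie$frames)[1]
  n <- n_frames(movie)
  total <- dummy_volumes + n + blank_volumes
  frames <- array(0, dim = c(gn, gn, total))
  frames[, , dummy_volumes + seq_len(n)] <- movie$frames
  labels <- c(rep("dummy", dummy_volumes), movie$labels,
              rep("blank", blank_volumes))
  meta <- movie$meta
  meta$dummy_volumes <- dummy_volumes
  meta$blank_volumes <- blank_volumes
  meta$runs <- list(seq_len(total))
  aperture_movie(frames, movie$fov_radius_deg, movie$tr_s, labels, meta)
}

#' Mask visual-field locations out of a stimulus model
#'
#' Multiplies every frame by a keep-mask derived from `keep`, a predicate on
#' cell-center coordinates. Used to build the scotoma-control stimulus model
#' that retains only part of the visual field (e.g. the upper-right
#' quadrant). Idempotent; a predicate that removes every in-field cell
#' yields a fully blank (degenerate but legal) movie with a warning.
#'
#' @param movie an `aperture_movie`.
#' @param keep `function(x, y)` returning a logical vector: TRUE = retain.
#' @seealso [keep_quadrant()]
#' @export
mask_region <- function(movie, keep) {
  stopifnot(inherits(movie, "aperture_movie"), is.function(keep))
  gn <- dim(movie$frames)[1]
  g <- grid_centers(gn, movie$fov_radius_deg)
  km <- as.logical(keep(g$cx, g$cy))
  if (length(km) != length(g$cx))
    stop("keep predicate must return one value per grid cell")
  if (!any(km & g$in_field))
    warning("mask removes every in-field cell; stimulus model is fully blank")
  flat <- matrix(movie$frames, ncol = n_frames(movie))
  flat[!km, ] <- 0
  meta <- movie$meta
  meta$masked <- TRUE
  aperture_movie(array(flat, dim = dim(movie$frames)), movie$fov_radius_deg,
                 movie$tr_s, movie$labels, meta)
}

#' Quadrant keep-predicates for [mask_region()]
#'
#' @param which one of `"upper-right"`, `"upper-left"`, `"lower-left"`,
#'   `"lower-right"`. Upper-right means `x > 0 & y > 0`.
#' @return A `function(x, y)` predicate.
#' @export
keep_quadrant <- function(which = c("upper-right", "upper-left",
                                    "lower-left", "lower-right")) {
  which <- match.arg(which)
  switch(which,
         "upper-right" = function(x, y) x > 0 & y > 0,
         "upper-left"  = function(x, y) x < 0 & y > 0,
         "lower-left"  = function(x, y) x < 0 & y < 0,
         "lower-right" = function(x, y) x > 0 & y < 0)
}

#' Total run duration in seconds
#' @param movie an `aperture_movie`.
#' @return `n_frames * tr_s`.
#' @export
run_duration_s <- function(movie) n_frames(movie) * movie$tr_s

#' Concatenate aperture movies as successive runs
#'
#' Frames and labels are concatenated; run boundaries are recorded in
#' `meta$runs` so that preprocessing, prediction and convolution are applied
#' per run (runs are independent acquisitions).
#'
#' @param ... `aperture_movie` objects sharing grid, fov and TR.
#' @export
concat_movies <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1, all(vapply(ms, inherits, TRUE, "aperture_movie")))
  gn <- dim(ms[[1]]$frames)[1]
  for (m in ms)
    if (dim(m$frames)[1] != gn ||
        abs(m$fov_radius_deg - ms[[1]]$fov_radius_deg) > 1e-9 ||
        abs(m$tr_s - ms[[1]]$tr_s) > 1e-9)
      stop("movies must share grid size, fov and TR")
  ns <- vapply(ms, n_frames, 1L)
  frames <- array(0, dim = c(gn, gn, sum(ns)))
  at <- 0L
  runs <- list()
  for (i in seq_along(ms)) {
    frames[, , at + seq_len(ns[i])] <- ms[[i]]$frames
    runs[[i]] <- at + seq_len(ns[i])
    at <- at + ns[i]
  }
  aperture_movie(frames, ms[[1]]$fov_radius_deg, ms[[1]]$tr_s,
                 labels = unlist(lapply(ms, `[[`, "labels")),
                 meta = list(kind = "concat", runs = runs))
}

# movie restricted to analysis frames (dummies dropped), per run
analysis_movie <- function(movie) {
  keep <- movie$labels != "dummy"
  idx <- which(keep)
  runs <- lapply(movie$meta$runs, function(r) {
    kept <- r[keep[r]]
    match(kept, idx)
  })
  meta <- movie$meta
  meta$runs <- runs
  aperture_movie(movie$frames[, , idx, drop = FALSE], movie$fov_radius_deg,
                 movie$tr_s, movie$labels[idx], meta)
}

#' Preset mapping/HRF designs for the two scanning sessions
#'
#' Session 1 (wide field, fov radius 37.5 deg): wedge run of 8 x 20 frames
#' and ring run of 16 steps x 10 reps, each finalized with 20 blank + 3
#' dummy volumes (183 volumes, 549 s at TR 3 s). Session 2 (narrow field,
#' fov radius 9 deg): wedge 3 x 20 frames, ring 12 steps x 5 reps, 15 blank
#' + 3 dummy volumes (78 volumes, 234 s). The full-field HRF run has 10
#' trials of 1 volume on + 9 off.
#'
#' @param session 1 or 2.
#' @param grid_n aperture grid resolution.
#' @return list with elements `wedge`, `ring`, `fullfield` (finalized runs)
#'   and `mapping` (wedge and ring runs concatenated, the fit input).
#' @export
session_movies <- function(session = 1, grid_n = 101) {
  stopifnot(session %in% c(1, 2))
  if (session == 1) {
    fov <- 37.5; blanks <- 20; cycles <- 8; steps <- 16; reps <- 10
  } else {
    fov <- 9; blanks <- 15; cycles <- 3; steps <- 12; reps <- 5
  }
  wedge <- finalize_run(make_wedge_movie(n_cycles = cycles,
                                         fov_radius_deg = fov,
                                         grid_n = grid_n),
                        blank_volumes = blanks)
  ring <- finalize_run(make_ring_movie(n_steps = steps, n_reps = reps,
                                       fov_radius_deg = fov,
                                       grid_n = grid_n),
                       blank_volumes = blanks)
  ff <- finalize_run(make_fullfield_movie(fov_radius_deg = fov,
                                          grid_n = grid_n),
                     blank_volumes = 0)
  list(wedge = wedge, ring = ring, fullfield = ff,
       mapping = concat_movies(wedge, ring))
}

#' Write / read an aperture movie as NIfTI plus a JSON sidecar
#'
#' The movie is stored as a `grid_n x grid_n x 1 x n_frames` binary NIfTI
#' volume at `<path>.nii.gz`; field-of-view radius, TR, labels and run
#' boundaries go to `<path>.json`.
#'
#' @param movie an `aperture_movie`.
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_aperture_movie <- function(movie, path) {
  gn <- dim(movie$frames)[1]
  arr <- array(movie$frames, dim = c(gn, gn, 1, n_frames(movie)))
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(path, ".nii.gz"))
  side <- list(fov_radius_deg = movie$fov_radius_deg, tr_s = movie$tr_s,
               labels = movie$labels,
               runs = lapply(movie$meta$runs, range),
               meta = movie$meta[setdiff(names(movie$meta), "runs")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_aperture_movie
#' @export
read_aperture_movie <- function(path) {
  arr <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dm <- dim(arr)
  frames <- array(as.numeric(arr), dim = c(dm[1], dm[2], dm[4]))
  frames <- round(frames)               # guard against storage rounding
  runs <- lapply(seq_len(nrow(side$runs)), function(i)
    side$runs[i, 1]:side$runs[i, 2])
  meta <- as.list(side$meta)
  meta$runs <- runs
  aperture_movie(frames, side$fov_radius_deg, side$tr_s, side$labels, meta)
}
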