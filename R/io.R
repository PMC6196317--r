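# Shared readers/writers and the end-to-end pipeline driver.
#
# Conventions: delimited tables are tab-separated with a header line;
# `vertex` is the join key across truth/fits/ROI tables; HRFs and run
# manifests are JSON; configs are YAML or plain lists.

#' Write / load a vertices x volumes time-series matrix
#'
#' TSV layout: first column `vertex`, remaining columns `v1..vN` (one per
#' volume). `load_timeseries` also accepts a 4-D NIfTI volume whose last
#' dimension is time (voxels are flattened to rows). When `movie` is
#' given, frames labeled `dummy` are dropped and the volume count and TR
#' are validated against the movie.
#'
#' @param ts vertices x volumes matrix.
#' @param path file path (`.tsv` or `.nii`/`.nii.gz` for loading).
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(vertex = seq_len(nrow(ts)), ts)
  names(df) <- c("vertex", paste0("v", seq_len(ncol(ts))))
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param movie optional `aperture_movie` used to drop dummy volumes and
#'   validate volume count and TR.
#' @param tr_s optional TR of the stored data, checked against the movie
#'   (hard error on mismatch; NIfTI files carry their own TR).
#' @return `load_timeseries`: list with `series` (dummy-stripped matrix)
#'   and `unfittable` (rows containing NaN/NA, flagged not dropped).
#' @export
load_timeseries <- function(path, movie = NULL, tr_s = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    dm <- dim(img)
    if (length(dm) < 2) stop("format error: need a time dimension")
    nt <- dm[length(dm)]
    m <- matrix(as.numeric(img), ncol = nt)
    px <- RNifti::pixdim(img)
    if (length(px) >= 4 && px[4] > 0) tr_s <- px[4]
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    if (nrow(df) == 0) stop("format error: empty time-series file")
    m <- as.matrix(df[, setdiff(names(df), "vertex"), drop = FALSE])
  }
  dimnames(m) <- NULL
  if (!is.null(movie)) {
    if (!is.null(tr_s) && abs(tr_s - movie$tr_s) > 1e-6)
      stop(sprintf("TR mismatch: data %g s vs movie %g s", tr_s, movie$tr_s))
    if (ncol(m) != n_frames(movie))
      stop(sprintf("volume count mismatch: data %d vs movie %d frames",
                   ncol(m), n_frames(movie)))
    m <- m[, movie$labels != "dummy", drop = FALSE]
  }
  bad <- apply(m, 1, function(r) any(!is.finite(r)))
  list(series = m, unfittable = bad)
}

#' Write / read a pRF fits (or ground-truth) table
#'
#' Tab-separated with a header; numeric columns written at full precision
#' so that rewrites are bit-identical.
#'
#' @param fits data.frame keyed by `vertex`.
#' @param path file path.
#' @export
write_fits <- function(fits, path) {
  utils::write.table(format(fits, digits = 12, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a fitted HRF as JSON
#'
#' Records the four two-gamma parameters plus the residual norm and number
#' of responsive vertices when present.
#'
#' @param hrf a [two_gamma_hrf()].
#' @param path file path.
#' @export
write_hrf_json <- function(hrf, path) {
  rec <- list(amplitude = hrf$amplitude,
              peak_latency_s = hrf$peak_latency_s,
              undershoot_latency_s = hrf$undershoot_latency_s,
              ratio = hrf$ratio,
              residual_norm = attr(hrf, "residual_norm"),
              n_responsive = attr(hrf, "n_responsive"))
  jsonlite::write_json(rec[!vapply(rec, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hrf_json
#' @export
read_hrf_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- two_gamma_hrf(rec$amplitude, rec$peak_latency_s,
                       rec$undershoot_latency_s, rec$ratio)
  attr(out, "residual_norm") <- rec$residual_norm
  attr(out, "n_responsive") <- rec$n_responsive
  out
}

#' Default pipeline configuration
#'
#' @param session scanning-session preset: 1 (wide field, fov radius
#'   37.5 deg) or 2 (narrow field, 9 deg).
#' @param n_vertices synthetic-cortex size.
#' @param noise_sd simulation noise (z units).
#' @param seed master seed; stage seeds are derived from it.
#' @param threshold R-squared map threshold.
#' @param grid_n aperture grid resolution.
#' @param lesion_quadrant optional quadrant name to lesion (e.g.
#'   `"lower-left"`), or NULL.
#' @param mask_keep optional quadrant kept in a control (masked) stimulus
#'   model rerun, or NULL.
#' @param out_dir artifact directory.
#' @export
pipeline_config <- function(session = 1, n_vertices = 60, noise_sd = 0.5,
                            seed = 1, threshold = 0.05, grid_n = 61,
                            lesion_quadrant = NULL, mask_keep = NULL,
                            out_dir = tempfile("prf_run_")) {
  list(session = session, n_vertices = n_vertices, noise_sd = noise_sd,
       seed = seed, threshold = threshold, grid_n = grid_n,
       lesion_quadrant = lesion_quadrant, mask_keep = mask_keep,
       out_dir = out_dir)
}

#' Run the full synthetic pipeline
#'
#' Stage order mirrors the experimental analysis: build the session's
#' aperture movies; generate a ground-truth synthetic cortex and simulate
#' the full-field (HRF) and mapping runs; estimate the subject HRF from
#' the full-field run; fit pRFs coarse-to-fine (optionally rerunning with
#' a quadrant-masked control stimulus model); derive map tables, coverage
#' and eccentricity-band summaries; and score recovery against the ground
#' truth. All artifacts are plain text (TSV/JSON) plus NIfTI movies; a
#' manifest records the configuration so a rerun with the same config is
#' bit-identical.
#'
#' @param config a [pipeline_config()] list, or the path to a YAML file
#'   with the same fields.
#' @return (invisibly) list with the in-memory stage products: `truth`,
#'   `hrf`, `fits`, `map`, `coverage`, `bands`, `recovery`, and
#'   `fits_masked` when a control rerun was requested; `out_dir` names the
#'   artifact directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  config <- utils::modifyList(defaults, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))

  msg("apertures", "session %d movies at grid %d", config$session,
      config$grid_n)
  mv <- session_movies(config$session, grid_n = config$grid_n)
  write_aperture_movie(mv$mapping, file.path(config$out_dir, "mapping"))
  write_aperture_movie(mv$fullfield, file.path(config$out_dir, "fullfield"))

  fov <- mv$mapping$fov_radius_deg
  lesion <- if (!is.null(config$lesion_quadrant))
    keep_quadrant(config$lesion_quadrant) else NULL
  truth <- make_ground_truth(config$n_vertices, max_ecc_deg = fov,
                             lesion = lesion)
  write_fits(truth, file.path(config$out_dir, "truth.tsv"))

  msg("simulate", "%d vertices, noise sd %g, seed %d", nrow(truth),
      config$noise_sd, config$seed)
  true_hrf <- two_gamma_hrf()
  ts_ff <- simulate_timeseries(truth, mv$fullfield, true_hrf,
                               noise_sd = config$noise_sd,
                               seed = config$seed)
  ts_map <- simulate_timeseries(truth, mv$mapping, true_hrf,
                                noise_sd = config$noise_sd,
                                seed = config$seed + 1)
  write_timeseries(ts_map, file.path(config$out_dir, "mapping_ts.tsv"))

  msg("fit-hrf", "event-averaging %d trials", mv$fullfield$meta$n_trials)
  ts_ff_a <- ts_ff[, mv$fullfield$labels != "dummy", drop = FALSE]
  hrf <- tryCatch(estimate_hrf(ts_ff_a, mv$fullfield),
                  error = function(e) {
                    msg("fit-hrf", "falling back to canonical HRF: %s",
                        conditionMessage(e))
                    two_gamma_hrf()
                  })
  write_hrf_json(hrf, file.path(config$out_dir, "hrf.json"))

  msg("fit-prf", "coarse-to-fine over %d vertices", nrow(truth))
  pre <- preprocess_timeseries(list(
    ts_map[, mv$mapping$meta$runs[[1]], drop = FALSE],
    ts_map[, mv$mapping$meta$runs[[2]], drop = FALSE]))
  fits <- fit_prf(pre$series, mv$mapping, hrf, unfittable = pre$unfittable)
  write_fits(fits, file.path(config$out_dir, "fits.tsv"))

  fits_masked <- NULL
  if (!is.null(config$mask_keep)) {
    msg("fit-prf", "control rerun with %s-only stimulus model",
        config$mask_keep)
    masked <- mask_region(mv$mapping, keep_quadrant(config$mask_keep))
    fits_masked <- fit_prf(pre$series, masked, hrf,
                           unfittable = pre$unfittable)
    write_fits(fits_masked, file.path(config$out_dir, "fits_masked.tsv"))
  }

  msg("maps", "threshold %g", config$threshold)
  roi <- truth[, c("vertex", "area")]
  map <- retinotopic_map(fits, threshold = config$threshold, roi = roi)
  write_fits(as.data.frame(map), file.path(config$out_dir, "map.tsv"))
  above <- threshold_map(map)
  cart <- to_cartesian(above$polar_angle_deg, above$eccentricity_deg)
  cov <- field_coverage(data.frame(x = cart$x_deg, y = cart$y_deg,
                                   sigma = above$sigma_deg),
                        fov_radius_deg = fov, grid_n = config$grid_n)
  utils::write.table(format(as.data.frame(cov$values), digits = 8,
                            trim = TRUE),
                     file.path(config$out_dir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bands <- bin_by_eccentricity(above, "sigma_deg", max_ecc_deg = fov)
  write_fits(bands, file.path(config$out_dir, "bands_sigma.tsv"))

  recovery <- recovery_report(truth, fits, threshold = config$threshold)
  manifest <- config
  manifest$package_version <- as.character(utils::packageVersion("prfmapr"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(position_rmse = recovery$position_rmse,
                            n_scored = recovery$n_scored,
                            lesion_sensitivity = recovery$lesion_sensitivity,
                            lesion_specificity = recovery$lesion_specificity),
                       file.path(config$out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(truth = truth, hrf = hrf, fits = fits,
                 fits_masked = fits_masked, map = map, coverage = cov,
                 bands = bands, recovery = recovery,
                 out_dir = config$out_dir))
}
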