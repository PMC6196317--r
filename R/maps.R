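# Retinotopic map quantities: polar conversion, thresholding, visual-field
# coverage and eccentricity-binned summaries.

#' Cartesian <-> polar visual-field coordinates
#'
#' Polar angle is measured counter-clockwise from the 3-o'clock direction,
#' in `[0, 360)`; eccentricity is the distance from fixation in degrees of
#' visual angle.
#'
#' @param x_deg,y_deg Cartesian coordinates (degrees).
#' @return `to_polar`: data.frame with `polar_angle_deg`, `eccentricity_deg`.
#' @export
to_polar <- function(x_deg, y_deg) {
  data.frame(polar_angle_deg = (atan2(y_deg, x_deg) * 180 / pi) %% 360,
             eccentricity_deg = sqrt(x_deg^2 + y_deg^2))
}

#' @rdname to_polar
#' @param polar_angle_deg,eccentricity_deg polar coordinates.
#' @return `to_cartesian`: data.frame with `x_deg`, `y_deg`.
#' @export
to_cartesian <- function(polar_angle_deg, eccentricity_deg) {
  data.frame(x_deg = eccentricity_deg * cos(polar_angle_deg * pi / 180),
             y_deg = eccentricity_deg * sin(polar_angle_deg * pi / 180))
}

#' Build a retinotopic map table from pRF fits
#'
#' Converts a [fit_prf()] table to per-vertex polar angle, eccentricity,
#' sigma, beta and R-squared, attaches optional area labels, and records
#' the R-squared threshold (default 0.05, the map display threshold).
#'
#' @param fits data.frame from [fit_prf()] (columns `vertex`, `x`, `y`,
#'   `sigma`, `beta`, `r_squared`).
#' @param threshold R-squared cutoff for the thresholded view.
#' @param roi optional data.frame `vertex` -> `area` with region labels
#'   (e.g. V1v, V1d, ...).
#' @return data.frame of class `retinotopic_map` with an `above_threshold`
#'   column; attribute `threshold` records the cutoff.
#' @export
retinotopic_map <- function(fits, threshold = 0.05, roi = NULL) {
  pol <- to_polar(fits$x, fits$y)
  out <- data.frame(vertex = fits$vertex,
                    polar_angle_deg = pol$polar_angle_deg,
                    eccentricity_deg = pol$eccentricity_deg,
                    sigma_deg = fits$sigma, beta = fits$beta,
                    r_squared = fits$r_squared,
                    above_threshold = fits$r_squared >= threshold)
  if (!is.null(roi))
    out$area <- roi$area[match(out$vertex, roi$vertex)]
  attr(out, "threshold") <- threshold
  class(out) <- c("retinotopic_map", "data.frame")
  out
}

#' Thresholded view of a retinotopic map
#'
#' Retains only vertices with `r_squared >= threshold`. Raising the
#' threshold never increases the retained vertex count.
#'
#' @param map a [retinotopic_map()].
#' @param threshold new cutoff; default the map's stored threshold.
#' @export
threshold_map <- function(map, threshold = attr(map, "threshold")) {
  out <- map[!is.na(map$r_squared) & map$r_squared >= threshold, ,
             drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Visual-field coverage: the sum of all pRFs in an area
#'
#' At each grid location the coverage is the sum over pRFs of the unit-peak
#' Gaussian profile (amplitude excluded by default, so the measure is
#' scale-free; set `beta_weighted = TRUE` to weight each pRF by its fitted
#' beta). Normalizing by the pRF count (`normalize = TRUE`) gives the mean
#' profile instead of the sum.
#'
#' @param prfs data.frame with columns `x`, `y`, `sigma` (and `beta` if
#'   weighting); typically an above-threshold subset of a fits table.
#' @param fov_radius_deg half-width of the coverage grid (degrees).
#' @param grid_n grid cells per side (default 101).
#' @param beta_weighted weight profiles by `beta`.
#' @param normalize divide by the number of pRFs.
#' @return list of class `coverage_map`: `values` (`grid_n x grid_n`,
#'   x-by-y), `xs` (axis coordinates), `n_prfs`.
#' @export
field_coverage <- function(prfs, fov_radius_deg, grid_n = 101,
                           beta_weighted = FALSE, normalize = FALSE) {
  g <- grid_centers(grid_n, fov_radius_deg)
  vals <- numeric(grid_n * grid_n)
  if (nrow(prfs) == 0) {
    warning("empty pRF set: coverage map is all zero")
  } else {
    stopifnot(all(prfs$sigma > 0))
    for (i in seq_len(nrow(prfs))) {
      prof <- exp(-((g$cx - prfs$x[i])^2 + (g$cy - prfs$y[i])^2) /
                    (2 * prfs$sigma[i]^2))
      if (beta_weighted) prof <- prof * prfs$beta[i]
      vals <- vals + prof
    }
    if (normalize) vals <- vals / nrow(prfs)
  }
  structure(list(values = matrix(vals, grid_n, grid_n), xs = g$xs,
                 n_prfs = nrow(prfs)), class = "coverage_map")
}

#' Eccentricity-binned mean and SEM of a map quantity
#'
#' Vertices are assigned to half-open eccentricity bands
#' `[e_i, e_{i+1})`; the mean and standard error of the chosen quantity are
#' reported per band. Empty bands are reported as missing (NA), not zero;
#' a band holding a single vertex has an undefined (NA) SEM.
#'
#' @param map a [retinotopic_map()] (or any data.frame with an
#'   `eccentricity_deg` column), normally already thresholded.
#' @param quantity column to summarize: `"sigma_deg"`, `"beta"` or
#'   `"r_squared"`.
#' @param band_edges increasing numeric vector of band edges; default 9
#'   equal-width bands from 0 to `max_ecc_deg`.
#' @param max_ecc_deg outer edge used for the default bands.
#' @return data.frame: `band`, `ecc_lo`, `ecc_hi`, `ecc_mid`, `n`, `mean`,
#'   `sem`.
#' @export
bin_by_eccentricity <- function(map, quantity = "sigma_deg",
                                band_edges = NULL, max_ecc_deg = NULL) {
  if (is.null(band_edges)) {
    if (is.null(max_ecc_deg)) max_ecc_deg <- max(map$eccentricity_deg)
    band_edges <- seq(0, max_ecc_deg, length.out = 10)
  }
  if (any(diff(band_edges) <= 0)) stop("band edges must be increasing")
  stopifnot(quantity %in% names(map))
  nb <- length(band_edges) - 1
  idx <- findInterval(map$eccentricity_deg, band_edges,
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > nb] <- NA
  v <- map[[quantity]]
  out <- data.frame(band = seq_len(nb),
                    ecc_lo = band_edges[-length(band_edges)],
                    ecc_hi = band_edges[-1])
  out$ecc_mid <- (out$ecc_lo + out$ecc_hi) / 2
  out$n <- vapply(seq_len(nb), function(b) sum(idx == b, na.rm = TRUE), 1L)
  out$mean <- vapply(seq_len(nb), function(b)
    if (out$n[b] > 0) mean(v[which(idx == b)]) else NA_real_, 1)
  out$sem <- vapply(seq_len(nb), function(b)
    if (out$n[b] > 1) stats::sd(v[which(idx == b)]) / sqrt(out$n[b])
    else NA_real_, 1)
  out
}

#' Export observed and predicted series for example vertices
#'
#' Rebuilds the best-fitting model prediction for each requested vertex and
#' pairs it with the observed (preprocessed) series, in long format for
#' plotting.
#'
#' @param fits a [fit_prf()] table.
#' @param series the preprocessed vertices x volumes matrix the fits were
#'   computed from.
#' @param movie,hrf the stimulus model and HRF used for fitting.
#' @param vertex_ids vertices to export (must exist in `fits$vertex`).
#' @return data.frame: `vertex`, `volume`, `time_s`, `observed`,
#'   `predicted`, plus per-vertex `r_squared` recomputed from the exported
#'   traces.
#' @export
sample_timeseries <- function(fits, series, movie, hrf, vertex_ids) {
  if (length(vertex_ids) == 0)
    return(data.frame(vertex = integer(0), volume = integer(0),
                      time_s = numeric(0), observed = numeric(0),
                      predicted = numeric(0), r_squared = numeric(0)))
  miss <- setdiff(vertex_ids, fits$vertex)
  if (length(miss) > 0)
    stop("unknown vertex id(s): ", paste(miss, collapse = ", "))
  ctx <- prf_context(movie, hrf)
  out <- vector("list", length(vertex_ids))
  for (k in seq_along(vertex_ids)) {
    v <- vertex_ids[k]
    row <- fits[fits$vertex == v, ]
    obs <- series[v, ]
    pr <- ctx_predict(ctx, row$x, row$y, row$sigma, standardize = TRUE)
    pred <- row$beta * pr$p
    d <- obs - mean(obs)
    r2 <- 1 - sum((d - pred)^2) / sum(d^2)
    out[[k]] <- data.frame(vertex = v, volume = seq_along(obs),
                           time_s = (seq_along(obs) - 1) * ctx$tr_s,
                           observed = obs, predicted = pred,
                           r_squared = min(max(r2, 0), 1))
  }
  do.call(rbind, out)
}
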