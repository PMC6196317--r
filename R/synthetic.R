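# Synthetic retinotopic cortex: ground-truth vertex populations, forward
# simulated BOLD series with controllable noise, simulated cortical
# scotomas, and recovery scoring. This is what makes the whole pipeline
# testable without scanner data.

#' Generate a ground-truth retinotopic vertex population
#'
#' Vertices are split across visual areas (V1-V3, ventral/dorsal) and
#' hemispheres, and their pRF centers tile the corresponding visual-field
#' quadrant quasi-uniformly (a deterministic golden-angle spiral, uniform
#' in area): the left hemisphere represents the right hemifield (x > 0) and
#' vice versa; dorsal areas represent the lower quadrant (y < 0), ventral
#' the upper. pRF size grows linearly with eccentricity,
#' `sigma = multiplier * (intercept + slope * ecc)`, with area multipliers
#' increasing up the hierarchy (V1 < V2 < V3).
#'
#' An optional lesion predicate marks a "cortical scotoma": lesioned
#' vertices keep their ground-truth parameters (for scoring) but emit no
#' stimulus-driven signal when simulated.
#'
#' @param n_vertices total vertices (>= 1), distributed round-robin across
#'   the area x hemisphere groups.
#' @param max_ecc_deg outermost pRF eccentricity (normally the stimulus
#'   radius).
#' @param areas visual-area labels to populate.
#' @param hemispheres `"left"`, `"right"` or both.
#' @param sigma_intercept,sigma_slope the V1 sigma-vs-eccentricity line
#'   (degrees; defaults 0.5 and 0.1).
#' @param area_multipliers named multipliers per area base name.
#' @param lesion optional `function(x, y)` returning TRUE where vertices
#'   are lesioned (visual-field coordinates).
#' @param min_ecc_deg innermost pRF eccentricity (keeps sigma bounded away
#'   from zero).
#' @return data.frame of class `ground_truth_map`: `vertex`, `hemisphere`,
#'   `area` (e.g. `"V1d"`), `x`, `y`, `sigma`, `beta`, `lesioned`.
#' @export
make_ground_truth <- function(n_vertices, max_ecc_deg = 37.5,
                              areas = c("V1v", "V1d", "V2v", "V2d",
                                        "V3v", "V3d"),
                              hemispheres = c("left", "right"),
                              sigma_intercept = 0.5, sigma_slope = 0.1,
                              area_multipliers = c(V1 = 1, V2 = 1.5, V3 = 2),
                              lesion = NULL, min_ecc_deg = 0.25) {
  stopifnot(n_vertices >= 1, max_ecc_deg > min_ecc_deg)
  groups <- expand.grid(hemisphere = hemispheres, area = areas,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ng <- nrow(groups)
  counts <- rep(n_vertices %/% ng, ng)
  extra <- n_vertices %% ng
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  phi <- (sqrt(5) - 1) / 2                   # golden-ratio angle increment
  rows <- vector("list", ng)
  for (gi in seq_len(ng)) {
    m <- counts[gi]
    if (m == 0) next
    hemi <- groups$hemisphere[gi]
    area <- groups$area[gi]
    ventral <- grepl("v$", area)
    base <- sub("[vd]$", "", area)
    mult <- area_multipliers[[base]]
    if (is.null(mult)) mult <- 1
    i <- seq_len(m)
    ecc <- min_ecc_deg + (max_ecc_deg - min_ecc_deg) * sqrt((i - 0.5) / m)
    # angle within the open quadrant (2 deg margin off the meridians)
    frac <- 0.02 + 0.96 * ((i * phi) %% 1)
    qstart <- if (hemi == "left") {
      if (ventral) 0 else 270                # right hemifield
    } else {
      if (ventral) 90 else 180               # left hemifield
    }
    ang <- (qstart + 90 * frac) * pi / 180
    x <- ecc * cos(ang)
    y <- ecc * sin(ang)
    rows[[gi]] <- data.frame(hemisphere = hemi, area = area, x = x, y = y,
                             sigma = mult * (sigma_intercept +
                                               sigma_slope * ecc),
                             beta = 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(vertex = seq_len(nrow(out)), out)
  out$lesioned <- if (is.null(lesion)) rep(FALSE, nrow(out))
                  else as.logical(lesion(out$x, out$y))
  class(out) <- c("ground_truth_map", "data.frame")
  out
}

#' Simulate BOLD time series from a ground-truth map
#'
#' Per vertex the noiseless signal is the Gaussian-pRF forward prediction
#' (overlap with the aperture movie, convolved with the HRF), covering
#' every frame of `movie` including dummy and blank volumes, scaled so the
#' per-run signal has unit standard deviation (z units). Additive iid
#' Gaussian noise with `noise_sd` (optionally AR(1)-correlated with
#' coefficient `ar_rho`) is then added. Lesioned vertices emit pure noise:
#' the stimulus-driven signal is silenced but the noise variance is kept.
#' Output is bit-reproducible given (`truth`, `movie`, `hrf`, `noise_sd`,
#' `seed`).
#'
#' @param truth a [make_ground_truth()] table.
#' @param movie the full (finalized) stimulus `aperture_movie`.
#' @param hrf a [two_gamma_hrf()].
#' @param noise_sd noise standard deviation in z units (>= 0).
#' @param seed integer seed; required.
#' @param ar_rho AR(1) coefficient for temporally correlated noise
#'   (default 0 = white).
#' @return vertices x volumes matrix spanning all frames of `movie`
#'   (feed through [preprocess_timeseries()] before fitting).
#' @export
simulate_timeseries <- function(truth, movie, hrf, noise_sd = 0.5, seed,
                                ar_rho = 0) {
  stopifnot(noise_sd >= 0, !missing(seed))
  nv <- nrow(truth)
  nf <- n_frames(movie)
  gn <- dim(movie$frames)[1]
  g <- grid_centers(gn, movie$fov_radius_deg)
  flat <- matrix(movie$frames, ncol = nf)
  keep <- g$in_field & rowSums(flat) > 0
  A <- flat[keep, , drop = FALSE]
  cx <- g$cx[keep]; cy <- g$cy[keep]
  kern <- hrf_kernel(hrf, movie$tr_s)
  runs <- movie$meta$runs
  analysis <- movie$labels != "dummy"

  sig <- matrix(0, nv, nf)
  active <- which(!truth$lesioned)
  for (i in active) {
    gvec <- exp(-((cx - truth$x[i])^2 + (cy - truth$y[i])^2) /
                  (2 * truth$sigma[i]^2))
    o <- as.numeric(crossprod(A, gvec))
    for (r in runs) {
      seg <- conv_trim(o[r], kern)
      s <- stats::sd(seg[analysis[r]])
      sig[i, r] <- if (is.finite(s) && s > 1e-9) seg / s else 0
    }
  }
  set.seed(seed)
  noise <- matrix(stats::rnorm(nv * nf, sd = noise_sd), nv, nf)
  if (ar_rho != 0 && noise_sd > 0) {
    for (k in 2:nf)
      noise[, k] <- ar_rho * noise[, k - 1] +
        sqrt(1 - ar_rho^2) * noise[, k]
  }
  out <- sig + noise
  attr(out, "seed") <- seed
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Score fitted pRFs against ground truth
#'
#' Recovery metrics over non-lesioned, above-threshold vertices:
#' per-parameter bias, RMSE and truth-fit correlation for x, y and sigma,
#' plus the joint position RMSE `sqrt(mean(dx^2 + dy^2))`. Simulated
#' scotoma detection treats sub-threshold R-squared as "lesion detected":
#' sensitivity is the detected fraction of lesioned vertices, specificity
#' the above-threshold fraction of intact ones.
#'
#' @param truth a [make_ground_truth()] table.
#' @param fits a [fit_prf()] table with matching vertex ids.
#' @param threshold R-squared map threshold (default 0.05).
#' @return list of class `recovery_report`: `params` (data.frame per
#'   parameter), `position_rmse`, `n_scored`, `lesion_sensitivity`,
#'   `lesion_specificity` (NA when no lesion was simulated).
#' @export
recovery_report <- function(truth, fits, threshold = 0.05) {
  ids <- intersect(truth$vertex, fits$vertex)
  if (length(ids) == 0) stop("truth and fits share no vertex ids")
  tr <- truth[match(ids, truth$vertex), ]
  ft <- fits[match(ids, fits$vertex), ]
  ok <- !tr$lesioned & !is.na(ft$r_squared) & ft$r_squared >= threshold &
    !is.na(ft$x)
  param_stats <- function(t_, f_) {
    d <- f_ - t_
    c(bias = mean(d), rmse = sqrt(mean(d^2)),
      correlation = if (length(t_) > 2 && stats::sd(t_) > 0 &&
                          stats::sd(f_) > 0) stats::cor(t_, f_) else NA_real_)
  }
  params <- rbind(x = param_stats(tr$x[ok], ft$x[ok]),
                  y = param_stats(tr$y[ok], ft$y[ok]),
                  sigma = param_stats(tr$sigma[ok], ft$sigma[ok]))
  params <- data.frame(parameter = rownames(params), params,
                       row.names = NULL)
  pos_rmse <- sqrt(mean((ft$x[ok] - tr$x[ok])^2 + (ft$y[ok] - tr$y[ok])^2))
  detected <- is.na(ft$r_squared) | ft$r_squared < threshold
  sens <- if (any(tr$lesioned)) mean(detected[tr$lesioned]) else NA_real_
  spec <- if (any(!tr$lesioned)) mean(!detected[!tr$lesioned]) else NA_real_
  structure(list(params = params, position_rmse = pos_rmse,
                 n_scored = sum(ok), lesion_sensitivity = sens,
                 lesion_specificity = spec, threshold = threshold),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d vertices scored (R2 >= %g)\n",
              x$n_scored, x$threshold))
  print(x$params, digits = 4)
  cat(sprintf("  position RMSE: %.4g deg\n", x$position_rmse))
  if (!is.na(x$lesion_sensitivity))
    cat(sprintf("  lesion detection: sensitivity %.3f, specificity %.3f\n",
                x$lesion_sensitivity, x$lesion_specificity))
  invisible(x)
}
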