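# Gaussian pRF forward model and coarse-to-fine parameter estimation.
#
# The forward model: the response of a cortical vertex to one acquisition
# volume is the overlap between its Gaussian receptive field (unit peak at
# the center) and the binary stimulus aperture of that volume; the overlap
# series is convolved with the subject's HRF sampled at TR. Model and data
# go through the same per-run linear detrend + z-standardization before
# comparison, so a noiseless series generated by the model is an exact
# fixed point of the fit.

#' Gaussian population receptive field
#'
#' @param x_deg,y_deg center in Cartesian visual-field coordinates relative
#'   to fixation (degrees; x rightward, y upward).
#' @param sigma_deg Gaussian spread (> 0, degrees).
#' @param beta response amplitude (z units of the standardized prediction).
#' @export
gaussian_prf <- function(x_deg, y_deg, sigma_deg, beta = 1) {
  stopifnot(is.finite(x_deg), is.finite(y_deg), is.finite(sigma_deg),
            sigma_deg > 0, is.finite(beta))
  structure(list(x_deg = x_deg, y_deg = y_deg, sigma_deg = sigma_deg,
                 beta = beta), class = "gaussian_prf")
}

#' Coarse-stage search grid
#'
#' Candidate pRF centers are placed at `n_angles` polar angles crossed with
#' `n_ecc` log-spaced eccentricities between `min_ecc_deg` and
#' `max_ecc_deg`; sigma candidates are log-spaced over `sigma_range`. The
#' maximal candidate eccentricity defaults to 1.5 times the outer stimulus
#' eccentricity. Candidates are enumerated x-major (angle fastest, then
#' eccentricity, then sigma); ties in the coarse stage are broken by this
#' enumeration order.
#'
#' @param stim_ecc_deg outer eccentricity of the stimulus (degrees).
#' @param max_ecc_deg outermost allowed pRF eccentricity; default
#'   `1.5 * stim_ecc_deg`.
#' @param n_angles,n_ecc,n_sigma grid resolution (defaults 15 x 12 x 8).
#' @param min_ecc_deg innermost candidate eccentricity.
#' @param sigma_range range of sigma candidates; default
#'   `c(0.25, 0.5 * max_ecc_deg)`.
#' @return data.frame with columns `x`, `y`, `sigma` and attribute
#'   `max_ecc_deg`.
#' @export
prf_search_grid <- function(stim_ecc_deg, max_ecc_deg = 1.5 * stim_ecc_deg,
                            n_angles = 15, n_ecc = 12, n_sigma = 8,
                            min_ecc_deg = 0.1,
                            sigma_range = c(0.25, 0.5 * max_ecc_deg)) {
  stopifnot(max_ecc_deg > min_ecc_deg, all(sigma_range > 0))
  ang <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  ecc <- exp(seq(log(min_ecc_deg), log(max_ecc_deg), length.out = n_ecc))
  sig <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                 length.out = n_sigma))
  cand <- expand.grid(angle = ang, ecc = ecc, sigma = sig,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(x = cand$ecc * cos(cand$angle * pi / 180),
                    y = cand$ecc * sin(cand$angle * pi / 180),
                    sigma = cand$sigma)
  attr(out, "max_ecc_deg") <- max_ecc_deg
  out
}

# -- preprocessing -----------------------------------------------------------

# remove the least-squares linear trend from the columns-as-time of a
# vertices x volumes matrix (rows are series)
detrend_rows <- function(m) {
  n <- ncol(m)
  t_ <- seq_len(n) - (n + 1) / 2               # centered regressor
  slope <- as.vector(m %*% t_) / sum(t_^2)
  m - outer(slope, t_) - rowMeans(m)
}

zscore_rows <- function(m, eps = 1e-12) {
  s <- sqrt(rowSums(m^2) / (ncol(m) - 1))
  bad <- s < eps
  s[bad] <- 1
  list(z = m / s, flat = bad)
}

#' Preprocess raw BOLD runs for pRF fitting
#'
#' Per run: the first `n_dummy` volumes are discarded, each vertex series is
#' linearly detrended, then z-standardized (mean 0, sd 1); runs are then
#' concatenated in order. Zero-variance vertices are flagged as unfittable
#' rather than raising an error.
#'
#' @param raw_runs a vertices x volumes matrix, or a list of such matrices
#'   (one per run, identical vertex order).
#' @param n_dummy dummy volumes to discard at the start of each run
#'   (default 3).
#' @return list with `series` (vertices x total analysis volumes),
#'   `unfittable` (logical per vertex) and `run_cols` (list of column
#'   indices per run).
#' @export
preprocess_timeseries <- function(raw_runs, n_dummy = 3) {
  if (is.matrix(raw_runs)) raw_runs <- list(raw_runs)
  stopifnot(all(vapply(raw_runs, is.matrix, TRUE)))
  pieces <- list()
  flat <- NULL
  run_cols <- list()
  at <- 0L
  for (i in seq_along(raw_runs)) {
    m <- raw_runs[[i]]
    if (ncol(m) <= n_dummy + 2)
      stop("each run needs at least 3 volumes after dummy removal")
    m <- m[, (n_dummy + 1):ncol(m), drop = FALSE]
    z <- zscore_rows(detrend_rows(m))
    pieces[[i]] <- z$z
    flat <- if (is.null(flat)) z$flat else flat | z$flat
    run_cols[[i]] <- at + seq_len(ncol(m))
    at <- at + ncol(m)
  }
  list(series = do.call(cbind, pieces), unfittable = flat,
       run_cols = run_cols)
}

# -- prediction machinery ----------------------------------------------------

# Precompute everything reusable across vertices/candidates for one
# (movie, hrf) pair: in-field cell coordinates, the cells x frames aperture
# matrix over analysis frames, per-run kernels. Cached on the movie via an
# environment keyed by a lightweight signature.
prf_context <- function(movie, hrf) {
  am <- analysis_movie(movie)
  gn <- dim(am$frames)[1]
  g <- grid_centers(gn, am$fov_radius_deg)
  flat <- matrix(am$frames, ncol = n_frames(am))
  keep <- g$in_field & rowSums(flat) > 0     # cells ever stimulated
  A <- flat[keep, , drop = FALSE]            # cells x frames
  kern <- hrf_kernel(hrf, am$tr_s)
  # mapping designs repeat a small set of distinct apertures (wedge
  # positions, ring steps, blank); computing overlaps per distinct frame
  # and expanding is an order of magnitude cheaper than per volume
  key <- vapply(seq_len(ncol(A)), function(j)
    paste(which(A[, j] > 0), collapse = ","), "")
  uniq <- !duplicated(key)
  frame_map <- match(key, key[uniq])
  Au <- A[, uniq, drop = FALSE]
  list(A = A, Au = Au, Atu = t(Au), frame_map = frame_map,
       cx = g$cx[keep], cy = g$cy[keep],
       runs = am$meta$runs, kernel = kern,
       n_frames = n_frames(am), tr_s = am$tr_s,
       fov = am$fov_radius_deg)
}

conv_trim <- function(x, kern) {
  n <- length(x)
  if (length(kern) == 1) return(x * kern)
  stats::convolve(c(x, numeric(length(kern) - 1)), rev(kern),
                  type = "open")[seq_len(n)]
}

# overlap series -> per-run conv + detrend (+ optional z); returns the
# standardized prediction and a degenerate flag
ctx_predict <- function(ctx, x, y, sigma, standardize = TRUE) {
  # cells beyond 4 sigma contribute < 3e-4 of the unit peak; restricting
  # the evaluation window there buys a large constant factor for small
  # receptive fields without visibly moving the optimum
  idx <- which(abs(ctx$cx - x) <= 4 * sigma & abs(ctx$cy - y) <= 4 * sigma)
  if (length(idx) == 0) {
    o <- numeric(ctx$n_frames)
  } else {
    if (length(idx) > 0.6 * length(ctx$cx)) {
      gvec <- exp(-((ctx$cx - x)^2 + (ctx$cy - y)^2) / (2 * sigma^2))
      ou <- as.numeric(ctx$Atu %*% gvec)
    } else {
      gvec <- exp(-((ctx$cx[idx] - x)^2 + (ctx$cy[idx] - y)^2) /
                    (2 * sigma^2))
      ou <- as.numeric(ctx$Atu[, idx, drop = FALSE] %*% gvec)
    }
    o <- ou[ctx$frame_map]
  }
  p <- numeric(ctx$n_frames)
  degen <- TRUE
  for (r in ctx$runs) {
    seg <- conv_trim(o[r], ctx$kernel)
    seg <- as.numeric(detrend_rows(matrix(seg, nrow = 1)))
    s <- stats::sd(seg)
    if (is.finite(s) && s > 1e-9) {
      degen <- FALSE
      if (standardize) seg <- seg / s
    } else seg <- numeric(length(seg))
    p[r] <- seg
  }
  list(p = p, degenerate = degen)
}

#' Predict a vertex time series from a pRF and an aperture movie
#'
#' Per frame the overlap is the sum over grid cells of aperture times the
#' unit-peak Gaussian receptive-field profile; the overlap series is
#' convolved with the HRF sampled at TR (kernel truncated at 32 s, output
#' trimmed to the run length), then linearly detrended and z-standardized
#' per run — the same filtering the data receive — and scaled by `beta`.
#' Dummy frames in `movie` are excluded, matching preprocessed data.
#'
#' @param prf a [gaussian_prf()].
#' @param movie an `aperture_movie`.
#' @param hrf a [two_gamma_hrf()].
#' @param standardize z-standardize per run (default TRUE); when FALSE the
#'   detrended convolved overlap is returned unscaled (no `beta` applied).
#' @return numeric vector over analysis frames; attribute `degenerate` is
#'   TRUE when the prediction has (near-)zero variance in every run, e.g.
#'   for a pRF far outside all apertures.
#' @export
predict_timeseries <- function(prf, movie, hrf, standardize = TRUE) {
  stopifnot(inherits(prf, "gaussian_prf"))
  ctx <- prf_context(movie, hrf)
  pr <- ctx_predict(ctx, prf$x_deg, prf$y_deg, prf$sigma_deg, standardize)
  out <- if (standardize) prf$beta * pr$p else pr$p
  attr(out, "degenerate") <- pr$degenerate
  out
}

# standardized candidate predictions for the whole grid, chunked to bound
# memory; returns frames x candidates matrix (degenerate columns all-zero)
grid_predictions <- function(ctx, grid, chunk = 256L) {
  n_cand <- nrow(grid)
  P <- matrix(0, ctx$n_frames, n_cand)
  degen <- logical(n_cand)
  for (lo in seq(1, n_cand, by = chunk)) {
    idx <- lo:min(lo + chunk - 1, n_cand)
    G <- exp(-(outer(ctx$cx, grid$x[idx], "-")^2 +
                 outer(ctx$cy, grid$y[idx], "-")^2) /
               (2 * rep(grid$sigma[idx]^2, each = length(ctx$cx))))
    O <- crossprod(ctx$Au, G)[ctx$frame_map, , drop = FALSE]  # frames x chunk
    for (j in seq_along(idx)) {
      o <- O[, j]
      p <- numeric(ctx$n_frames)
      dg <- TRUE
      for (r in ctx$runs) {
        seg <- conv_trim(o[r], ctx$kernel)
        seg <- as.numeric(detrend_rows(matrix(seg, nrow = 1)))
        s <- stats::sd(seg)
        if (is.finite(s) && s > 1e-9) { dg <- FALSE; seg <- seg / s }
        else seg <- numeric(length(seg))
        p[r] <- seg
      }
      P[, idx[j]] <- p
      degen[idx[j]] <- dg
    }
  }
  attr(P, "degenerate") <- degen
  P
}

# -- coarse and fine stages --------------------------------------------------

fit_result <- function(prf, r_squared, stage, flags = character(0)) {
  structure(list(prf = prf, r_squared = r_squared, stage = stage,
                 flags = flags), class = "prf_fit")
}

#' Coarse grid-search stage
#'
#' Returns the grid candidate maximizing the Pearson correlation between its
#' standardized prediction and the (typically smoothed) vertex series. The
#' amplitude is not estimated at this stage (`beta = 1`). Candidates with a
#' degenerate (constant) prediction score `-Inf`; ties are broken by grid
#' enumeration order.
#'
#' @param series numeric vector (one vertex, analysis volumes).
#' @param movie the mapping `aperture_movie` (runs concatenated).
#' @param hrf a [two_gamma_hrf()].
#' @param grid a [prf_search_grid()] data.frame.
#' @return A `prf_fit` with `stage = "coarse"` and `r_squared` the squared
#'   (signed-max) correlation.
#' @export
coarse_fit <- function(series, movie, hrf, grid) {
  stopifnot(nrow(grid) >= 1)
  ctx <- prf_context(movie, hrf)
  P <- grid_predictions(ctx, grid)
  coarse_from_predictions(series, P, grid)
}

# Pearson correlation of one series against every prediction column;
# degenerate candidates score -Inf
coarse_scores <- function(series, P) {
  n <- length(series)
  d <- series - mean(series)
  sd_d <- sqrt(sum(d^2) / (n - 1))
  if (sd_d < 1e-12) return(NULL)
  degen <- attr(P, "degenerate")
  if (all(degen)) return(NULL)
  sd_p <- sqrt(colSums(P^2) / (n - 1))        # columns are mean-0 per run
  sd_p[sd_p < 1e-12] <- Inf                   # constant prediction -> cor 0
  cors <- as.numeric(crossprod(P, d)) / ((n - 1) * sd_d * sd_p)
  cors[degen] <- -Inf
  cors
}

# vectorized inner step shared with fit_prf
coarse_from_predictions <- function(series, P, grid) {
  cors <- coarse_scores(series, P)
  if (is.null(cors))
    return(fit_result(gaussian_prf(grid$x[1], grid$y[1], grid$sigma[1]),
                      0, "coarse", "unfittable"))
  best <- which.max(cors)                     # which.max takes the first tie
  fit_result(gaussian_prf(grid$x[best], grid$y[best], grid$sigma[best]),
             max(cors[best], 0)^2, "coarse")
}

#' Fine optimization stage
#'
#' Derivative-free (Nelder-Mead) minimization of the summed squared
#' residuals between the standardized prediction and the unsmoothed series,
#' started from the coarse-stage estimate. The search runs over
#' `(x, y, log sigma)` with the amplitude `beta` solved in closed form
#' (least-squares scale of the standardized prediction) at every
#' evaluation; candidate centers beyond `max_ecc_deg` are penalized.
#'
#' @inheritParams coarse_fit
#' @param init a `prf_fit` (or `gaussian_prf`) to start from, normally the
#'   coarse-stage result.
#' @param max_ecc_deg outermost allowed pRF eccentricity (default 1.5 times
#'   the movie's field-of-view radius).
#' @param control passed to [stats::optim()]; defaults
#'   `list(maxit = 400, reltol = 1e-9)`.
#' @return A `prf_fit` with `stage = "fine"`, `r_squared` in \[0, 1\], and
#'   flags `"unfittable"`, `"degenerate"`, `"no_convergence"` or
#'   `"negative_beta"` where applicable.
#' @export
fine_fit <- function(series, movie, hrf, init,
                     max_ecc_deg = 1.5 * movie$fov_radius_deg,
                     control = list()) {
  ctx <- prf_context(movie, hrf)
  fine_with_ctx(series, ctx, init, max_ecc_deg, control)
}

fine_with_ctx <- function(series, ctx, init, max_ecc_deg, control = list()) {
  inits <- if (is.list(init) && !inherits(init, c("prf_fit", "gaussian_prf")))
    init else list(init)
  inits <- lapply(inits, function(z) if (inherits(z, "prf_fit")) z$prf else z)
  control <- utils::modifyList(list(maxit = 400, reltol = 1e-9), control)
  d <- series - mean(series)
  ss_tot <- sum(d^2)
  if (ss_tot < 1e-12)
    return(fit_result(inits[[1]], 0, "fine", "unfittable"))

  eval_par <- function(th) {
    x <- th[1]; y <- th[2]; sigma <- exp(th[3])
    pr <- ctx_predict(ctx, x, y, sigma, standardize = TRUE)
    if (pr$degenerate) return(list(ss = ss_tot, beta = 0, degen = TRUE))
    beta <- sum(d * pr$p) / sum(pr$p^2)
    ss <- sum((d - beta * pr$p)^2)
    ecc <- sqrt(x^2 + y^2)
    if (ecc > max_ecc_deg) ss <- ss + ss_tot * (ecc - max_ecc_deg)^2
    list(ss = ss, beta = beta, degen = FALSE)
  }
  obj <- function(th) eval_par(th)$ss
  # A joint 3-parameter descent from a grid init is fragile here: near
  # (but off) the true center, shrinking sigma improves the fit faster
  # than moving the center does, and the search ends in a deep
  # small-sigma local basin. The center profile at any fixed reasonable
  # sigma is far better behaved, as is the sigma profile at a good
  # center - so refine coordinate-wise first (center, then a global 1-D
  # sigma search, then center again) and only then release all three
  # parameters to Nelder-Mead.
  short <- utils::modifyList(control, list(maxit = 150, reltol = 1e-6))
  xy_stage <- function(th) {
    o <- stats::optim(th[1:2], function(txy) obj(c(txy, th[3])),
                      method = "Nelder-Mead", control = short)
    c(o$par, th[3])
  }
  sigma_stage <- function(th) {
    ls <- seq(log(0.05), log(0.75 * max_ecc_deg), length.out = 12)
    prof <- vapply(ls, function(s) obj(c(th[1:2], s)), 0)
    k <- which.min(prof)
    lo <- ls[max(1, k - 1)]
    hi <- ls[min(length(ls), k + 1)]
    o <- stats::optimize(function(s) obj(c(th[1:2], s)), c(lo, hi),
                         tol = 1e-4)
    c(th[1:2], o$minimum)
  }
  best_th <- NULL
  best_ss <- Inf
  for (ini in inits) {
    th <- c(ini$x_deg, ini$y_deg, log(ini$sigma_deg))
    th <- xy_stage(th)
    th <- sigma_stage(th)
    th <- xy_stage(th)
    ssv <- obj(th)
    if (ssv < best_ss) { best_ss <- ssv; best_th <- th }
  }
  opt <- stats::optim(best_th, obj, method = "Nelder-Mead",
                      control = control)
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = utils::modifyList(control,
                                                  list(maxit = 200)))
  at <- eval_par(opt$par)
  flags <- character(0)
  if (at$degen) flags <- c(flags, "degenerate")
  if (opt$convergence != 0) flags <- c(flags, "no_convergence")
  if (at$beta < 0) flags <- c(flags, "negative_beta")
  r2 <- 1 - at$ss / ss_tot
  fit_result(gaussian_prf(opt$par[1], opt$par[2], exp(opt$par[3]),
                          beta = at$beta),
             min(max(r2, 0), 1), "fine", flags)
}

# -- smoothing for the coarse stage ------------------------------------------

#' Smooth vertex series for the coarse stage
#'
#' The coarse grid search runs on heavily smoothed data. With a vertex
#' adjacency list, smoothing averages each vertex with its neighbors
#' (surface-like smoothing); without geometry a temporal moving average of
#' width 3 TR is the stand-in.
#'
#' @param series vertices x volumes matrix.
#' @param method `"temporal"`, `"graph"` or `"none"`.
#' @param adjacency list (per vertex) of neighbor indices, for
#'   `method = "graph"`.
#' @param width moving-average width in volumes (odd, default 3).
#' @export
smooth_timeseries <- function(series, method = c("temporal", "graph", "none"),
                              adjacency = NULL, width = 3) {
  method <- match.arg(method)
  if (method == "none") return(series)
  if (method == "graph") {
    if (is.null(adjacency)) stop("graph smoothing needs an adjacency list")
    out <- series
    for (i in seq_len(nrow(series))) {
      nb <- c(i, adjacency[[i]])
      out[i, ] <- colMeans(series[nb, , drop = FALSE])
    }
    return(out)
  }
  half <- (width - 1) / 2
  n <- ncol(series)
  out <- series
  for (k in seq_len(n)) {
    idx <- max(1, k - half):min(n, k + half)
    out[, k] <- rowMeans(series[, idx, drop = FALSE])
  }
  out
}

# -- full-surface driver -----------------------------------------------------

#' Fit pRFs for every vertex of a (synthetic or sampled) cortical surface
#'
#' Runs the coarse grid stage on smoothed data and the fine optimization on
#' the unsmoothed data, per vertex. Deterministic given its inputs.
#'
#' @param series preprocessed vertices x volumes matrix (see
#'   [preprocess_timeseries()]); column count must equal the movie's
#'   analysis frames.
#' @param movie mapping `aperture_movie` (dummy frames are excluded
#'   internally).
#' @param hrf a [two_gamma_hrf()].
#' @param grid a [prf_search_grid()]; default grid at 1.5 x the movie fov.
#' @param smoothing `"temporal"`, `"graph"` or `"none"` (see
#'   [smooth_timeseries()]).
#' @param adjacency neighbor list for graph smoothing.
#' @param unfittable optional logical flags from preprocessing; flagged
#'   vertices are skipped (returned with `r_squared` 0).
#' @param control fine-stage optimizer control.
#' @param progress print a progress line every 50 vertices.
#' @return data.frame with one row per vertex: `vertex`, `x`, `y`, `sigma`,
#'   `beta`, `r_squared`, `stage`, `flags` (semicolon-joined).
#' @export
fit_prf <- function(series, movie, hrf, grid = NULL,
                    smoothing = c("temporal", "graph", "none"),
                    adjacency = NULL, unfittable = NULL,
                    control = list(), progress = FALSE) {
  smoothing <- match.arg(smoothing)
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  ctx <- prf_context(movie, hrf)
  if (ncol(series) != ctx$n_frames)
    stop(sprintf("series has %d volumes but the movie has %d analysis frames",
                 ncol(series), ctx$n_frames))
  if (is.null(grid)) grid <- prf_search_grid(movie$fov_radius_deg)
  max_ecc <- attr(grid, "max_ecc_deg")
  if (is.null(max_ecc)) max_ecc <- 1.5 * movie$fov_radius_deg
  if (is.null(unfittable)) unfittable <- rep(FALSE, nrow(series))

  P <- grid_predictions(ctx, grid)
  sm <- smooth_timeseries(series, smoothing, adjacency)
  # temporal smoothing alters the temporal profile, so the coarse stage
  # must compare like with like: filter the candidate predictions the
  # same way (graph smoothing leaves the temporal profile untouched)
  Pc <- if (smoothing == "temporal") {
    tmp <- t(smooth_timeseries(t(P), "temporal"))
    attr(tmp, "degenerate") <- attr(P, "degenerate")
    tmp
  } else P
  ss_p <- colSums(P^2)                        # for the init refinement
  ss_p[ss_p < 1e-12] <- Inf

  nv <- nrow(series)
  out <- data.frame(vertex = seq_len(nv), x = NA_real_, y = NA_real_,
                    sigma = NA_real_, beta = NA_real_, r_squared = 0,
                    stage = "fine", flags = "", stringsAsFactors = FALSE)
  for (i in seq_len(nv)) {
    if (unfittable[i]) {
      out$flags[i] <- "unfittable"
      next
    }
    cors <- coarse_scores(sm[i, ], Pc)
    if (is.null(cors)) {
      out$flags[i] <- "unfittable"
      next
    }
    if (smoothing == "none") {
      init_idx <- which.max(cors)
      init <- gaussian_prf(grid$x[init_idx], grid$y[init_idx],
                           grid$sigma[init_idx])
      fi <- fine_with_ctx(series[i, ], ctx, init, max_ecc, control)
    } else {
      # The correlation surface on smoothed data can rank a neighboring
      # basin first, so re-rank every grid candidate by the fine
      # objective itself (profiled-beta explained sum of squares on the
      # unsmoothed series - one matrix product). Near (but off) the true
      # center a small sigma can mimic the series almost perfectly, a
      # deep local basin adjacent to the true one; a second start at the
      # same center with a mid-range sigma escapes it, and the better
      # final fit wins.
      d_i <- series[i, ] - mean(series[i, ])
      expl <- as.numeric(crossprod(P, d_i))^2 / ss_p
      best <- which.max(expl)
      sig_mid <- grid$sigma[which.min(abs(log(grid$sigma) -
                                            mean(log(range(grid$sigma)))))]
      inits <- lapply(unique(c(grid$sigma[best], sig_mid)), function(s)
        gaussian_prf(grid$x[best], grid$y[best], s))
      fi <- fine_with_ctx(series[i, ], ctx, inits, max_ecc, control)
    }
    out$x[i] <- fi$prf$x_deg
    out$y[i] <- fi$prf$y_deg
    out$sigma[i] <- fi$prf$sigma_deg
    out$beta[i] <- fi$prf$beta
    out$r_squared[i] <- fi$r_squared
    out$flags[i] <- paste(fi$flags, collapse = ";")
    if (progress && i %% 50 == 0)
      message(sprintf("fit_prf: %d / %d vertices", i, nv))
  }
  out
}
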