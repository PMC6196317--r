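# Shared fixtures, built once per test run. Everything is generated in
# code; the small grids keep the unit tests fast while the acceptance
# tests use the full session designs.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small mapping design: fov 10 deg, coarse grid, wedge + ring runs
small_mapping <- function() fx("small_mapping", function() {
  wedge <- finalize_run(make_wedge_movie(n_cycles = 4, fov_radius_deg = 10,
                                         grid_n = 31),
                        blank_volumes = 5)
  ring <- finalize_run(make_ring_movie(n_steps = 8, n_reps = 5,
                                       fov_radius_deg = 10, grid_n = 31),
                       blank_volumes = 5)
  concat_movies(wedge, ring)
})

small_grid <- function() fx("small_grid", function()
  prf_search_grid(10, n_angles = 10, n_ecc = 8, n_sigma = 5))

canonical_hrf <- function() two_gamma_hrf()

# session-1 movies at full resolution, for the acceptance suite
session1 <- function() fx("session1", function() session_movies(1))

# preprocess a simulated matrix against its movie's runs
preprocess_sim <- function(ts, movie) {
  runs <- movie$meta$runs
  preprocess_timeseries(lapply(runs, function(r) ts[, r, drop = FALSE]))
}

# independent naive reimplementation of the coarse objective (explicit
# loops, lm() detrending, stats::cor) used as the brute-force oracle
naive_predictions <- function(movie, hrf, grid) {
  gn <- dim(movie$frames)[1]
  xs <- seq(-movie$fov_radius_deg, movie$fov_radius_deg, length.out = gn)
  Tn <- dim(movie$frames)[3]
  k <- two_gamma(seq(0, 32, by = movie$tr_s), hrf)
  preds <- matrix(NA_real_, Tn, nrow(grid))
  for (c_ in seq_len(nrow(grid))) {
    o <- numeric(Tn)
    for (t_ in seq_len(Tn)) {
      acc <- 0
      for (i in seq_len(gn)) for (j in seq_len(gn)) {
        if (movie$frames[i, j, t_] > 0 &&
            sqrt(xs[i]^2 + xs[j]^2) <= movie$fov_radius_deg + 1e-9)
          acc <- acc + exp(-((xs[i] - grid$x[c_])^2 +
                               (xs[j] - grid$y[c_])^2) /
                             (2 * grid$sigma[c_]^2))
      }
      o[t_] <- acc
    }
    conv <- numeric(Tn)
    for (t_ in seq_len(Tn)) for (u in 0:(length(k) - 1))
      if (t_ - u >= 1) conv[t_] <- conv[t_] + o[t_ - u] * k[u + 1]
    preds[, c_] <- stats::residuals(stats::lm(conv ~ seq_len(Tn)))
  }
  preds
}

naive_coarse_index <- function(series, preds) {
  best <- -Inf
  bi <- NA_integer_
  for (c_ in seq_len(ncol(preds))) {
    p <- preds[, c_]
    if (stats::sd(p) < 1e-9) next
    r <- stats::cor(series, p)
    if (r > best + 1e-12) { best <- r; bi <- c_ }
  }
  bi
}
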