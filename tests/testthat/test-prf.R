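# Gaussian pRF forward model and coarse-to-fine fitting.

test_that("preprocessing detrends, standardizes and flags flat series", {
  set.seed(2)
  n <- 60
  run <- rbind(2 * seq_len(n + 3) + rnorm(n + 3, sd = 0.1),   # trended
               rep(5, n + 3),                                  # constant
               rnorm(n + 3))
  pre <- preprocess_timeseries(run, n_dummy = 3)
  expect_equal(ncol(pre$series), n)
  expect_equal(pre$unfittable, c(FALSE, TRUE, FALSE))
  s1 <- pre$series[1, ]
  expect_equal(mean(s1), 0, tolerance = 1e-10)
  expect_equal(sd(s1), 1, tolerance = 1e-10)
  expect_equal(unname(coef(lm(s1 ~ seq_len(n)))[2]), 0, tolerance = 1e-10)
  # two identical runs: each half standardized independently
  pre2 <- preprocess_timeseries(list(run, run), n_dummy = 3)
  expect_equal(ncol(pre2$series), 2 * n)
  expect_equal(pre2$series[, 1:n], pre2$series[, (n + 1):(2 * n)])
})

test_that("predictions are degenerate for pRFs that never see the stimulus", {
  mv <- small_mapping()
  h <- canonical_hrf()
  far <- gaussian_prf(25, 25, 0.5)       # >= 5 sigma outside the 10-deg fov
  p <- predict_timeseries(far, mv, h)
  expect_true(attr(p, "degenerate"))
  expect_equal(as.numeric(p), rep(0, length(p)))
})

test_that("ring overlap peaks at the frame whose mid-radius is nearest", {
  ring <- make_ring_movie(n_steps = 8, n_reps = 1, fov_radius_deg = 10,
                          grid_n = 41)
  h <- canonical_hrf()
  mids <- ring$meta$mid_radii
  ctx <- prfmapr:::prf_context(ring, h)
  for (e in c(1.3, 2.2, 3.6, 7.0)) {
    gvec <- exp(-((ctx$cx - e)^2 + ctx$cy^2) / (2 * 0.4^2))
    o <- as.numeric(crossprod(ctx$A, gvec))
    expect_equal(which.max(o), which.min(abs(mids - e)))
  }
})

test_that("coarse_fit agrees with the exhaustive brute-force oracle", {
  movie <- make_wedge_movie(width_deg = 72, step_deg = 18, n_cycles = 1,
                            fov_radius_deg = 8, grid_n = 21)
  h <- canonical_hrf()
  pos <- expand.grid(x = seq(-6, 6, length.out = 5),
                     y = seq(-6, 6, length.out = 5))
  grid <- data.frame(x = rep(pos$x, 3), y = rep(pos$y, 3),
                     sigma = rep(c(0.8, 1.6, 3.2), each = 25))
  preds <- naive_predictions(movie, h, grid)
  set.seed(99)
  n_match <- 0
  for (i in 1:100) {
    series <- rnorm(n_frames(movie))
    fit <- coarse_fit(series, movie, h, grid)
    oracle <- naive_coarse_index(series, preds)
    got <- which(abs(grid$x - fit$prf$x_deg) < 1e-12 &
                   abs(grid$y - fit$prf$y_deg) < 1e-12 &
                   abs(grid$sigma - fit$prf$sigma_deg) < 1e-12)[1]
    n_match <- n_match + (got == oracle)
  }
  expect_equal(n_match, 100)
})

test_that("coarse_fit breaks exact ties by enumeration order", {
  movie <- make_wedge_movie(width_deg = 72, step_deg = 18, n_cycles = 1,
                            fov_radius_deg = 8, grid_n = 21)
  h <- canonical_hrf()
  # duplicate candidates: identical predictions, exact tie
  grid <- data.frame(x = c(2, 2, -2), y = c(2, 2, -2),
                     sigma = c(1, 1, 1))
  p <- predict_timeseries(gaussian_prf(2, 2, 1), movie, h)
  fit <- coarse_fit(as.numeric(p), movie, h, grid)
  expect_equal(c(fit$prf$x_deg, fit$prf$y_deg), c(2, 2))
})

test_that("anti-correlated series still selects by signed correlation", {
  movie <- small_mapping()
  h <- canonical_hrf()
  grid <- small_grid()
  p <- predict_timeseries(gaussian_prf(3, 3, 1.5), movie, h)
  fit <- coarse_fit(-as.numeric(p), movie, h, grid)
  expect_s3_class(fit, "prf_fit")
  # the negated series correlates poorly with every candidate
  expect_lt(fit$r_squared, 0.3)
})

test_that("fine_fit is a fixed point on noiseless self-generated data", {
  mv <- small_mapping()
  h <- canonical_hrf()
  truth <- gaussian_prf(4, -2.5, 1.2)
  p <- predict_timeseries(truth, mv, h)
  fit <- fine_fit(as.numeric(p), mv, h, truth)
  expect_equal(fit$prf$x_deg, truth$x_deg, tolerance = 1e-4)
  expect_equal(fit$prf$y_deg, truth$y_deg, tolerance = 1e-4)
  expect_equal(fit$prf$sigma_deg, truth$sigma_deg, tolerance = 1e-4)
  expect_gte(fit$r_squared, 1 - 1e-6)
  expect_equal(fit$stage, "fine")
})

test_that("fine_fit recovers off-grid truths from the nearest grid start", {
  mv <- small_mapping()
  h <- canonical_hrf()
  grid <- small_grid()
  set.seed(31)
  for (i in 1:12) {
    ecc <- runif(1, 1, 8)
    ang <- runif(1, 0, 2 * pi)
    truth <- gaussian_prf(ecc * cos(ang), ecc * sin(ang),
                          runif(1, 0.5, 2.5))
    p <- as.numeric(predict_timeseries(truth, mv, h))
    # init at the grid candidate nearest the (off-grid) truth
    near <- which.min((grid$x - truth$x_deg)^2 +
                        (grid$y - truth$y_deg)^2 +
                        (log(grid$sigma) - log(truth$sigma_deg))^2)
    init <- gaussian_prf(grid$x[near], grid$y[near], grid$sigma[near])
    fit <- fine_fit(p, mv, h, init)
    expect_lt(abs(fit$prf$x_deg - truth$x_deg), 0.05)
    expect_lt(abs(fit$prf$y_deg - truth$y_deg), 0.05)
    expect_lt(abs(fit$prf$sigma_deg - truth$sigma_deg) / truth$sigma_deg,
              0.05)
  }
})

test_that("recovery error grows monotonically with noise", {
  mv <- small_mapping()
  h <- canonical_hrf()
  truth <- make_ground_truth(12, max_ecc_deg = 9)
  med_err <- sapply(seq_along(levels <- c(0, 0.5, 1, 2)), function(li) {
    ts <- simulate_timeseries(truth, mv, h, noise_sd = levels[li],
                              seed = 100 + li)
    pre <- preprocess_sim(ts, mv)
    fits <- fit_prf(pre$series, mv, h, grid = small_grid(),
                    unfittable = pre$unfittable)
    median(sqrt((fits$x - truth$x)^2 + (fits$y - truth$y)^2), na.rm = TRUE)
  })
  expect_gt(cor(med_err, seq_along(med_err), method = "spearman"), 0)
  expect_lt(med_err[1], 0.05)   # zero-noise round trip is exact
})

test_that("fit_prf on a single vertex equals coarse + fine composition", {
  mv <- small_mapping()
  h <- canonical_hrf()
  grid <- small_grid()
  truth <- gaussian_prf(-3, 4, 1.5)
  set.seed(8)
  series <- as.numeric(predict_timeseries(truth, mv, h)) +
    rnorm(prfmapr:::prf_context(mv, h)$n_frames, sd = 0.3)
  series <- matrix(series, nrow = 1)
  surf <- fit_prf(series, mv, h, grid = grid, smoothing = "none")
  co <- coarse_fit(series[1, ], mv, h, grid)
  fi <- fine_fit(series[1, ], mv, h, co,
                 max_ecc_deg = attr(grid, "max_ecc_deg"))
  expect_equal(surf$x, fi$prf$x_deg)
  expect_equal(surf$y, fi$prf$y_deg)
  expect_equal(surf$sigma, fi$prf$sigma_deg)
  expect_equal(surf$r_squared, fi$r_squared)
})

test_that("unfittable vertices are flagged and skipped", {
  mv <- small_mapping()
  h <- canonical_hrf()
  nfr <- prfmapr:::prf_context(mv, h)$n_frames
  series <- rbind(rep(0, nfr), rnorm(nfr))
  fits <- fit_prf(series, mv, h, grid = small_grid(),
                  unfittable = c(TRUE, FALSE))
  expect_equal(fits$flags[1], "unfittable")
  expect_true(is.na(fits$x[1]))
  expect_false(is.na(fits$x[2]))
})

test_that("search grid respects the 1.5x eccentricity bound and log sigma", {
  grid <- prf_search_grid(10)
  expect_equal(attr(grid, "max_ecc_deg"), 15)
  expect_lte(max(sqrt(grid$x^2 + grid$y^2)), 15 + 1e-9)
  sig <- sort(unique(grid$sigma))
  r <- sig[-1] / sig[-length(sig)]
  expect_true(all(abs(r - r[1]) < 1e-9))
  expect_true(all(grid$sigma > 0))
})

test_that("temporal and graph smoothing behave as documented", {
  m <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  sm <- smooth_timeseries(m, "temporal", width = 3)
  expect_equal(sm[1, 2], mean(c(1, 2, 3)))
  expect_equal(sm[1, 1], mean(c(1, 2)))      # edge shrinks the window
  gr <- smooth_timeseries(m, "graph", adjacency = list(2, 1))
  expect_equal(gr[1, ], colMeans(m))
  expect_equal(smooth_timeseries(m, "none"), m)
})
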