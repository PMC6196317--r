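# Behavioral computations: perimetry screen, Bayes factor, staircases,
# illusion strength.

test_that("visual-field session layout matches the 32-position design", {
  s <- make_vf_session(seed = 2)
  expect_equal(nrow(s), 64)
  counts <- table(s$ring, s$sector)
  expect_true(all(counts == 2))
  per_pos <- aggregate(present ~ ring + sector, s, sum)
  expect_true(all(per_pos$present == 1))     # one present, one absent each
  expect_equal(nrow(make_vf_session(1, 1, 1, seed = 3)), 1)
  # ring spacing of the default screen: 37.5 / 4 = 9.375 deg
  expect_equal(diff(vf_ring_radii()), rep(9.375, 3))
  expect_equal(vf_ring_radii()[1], 9.375)
})

test_that("score_vf classifies perfect, always-absent and always-present", {
  s <- make_vf_session(seed = 4)
  perfect <- s
  perfect$response <- ifelse(perfect$present, "seen", "not-seen")
  sc <- score_vf(perfect)
  expect_equal(sc$n_intact, 32)
  expect_equal(sc$false_negative_rate, 0)
  # an always-"absent" responder (the anopic pattern outside the intact
  # quadrant): every position impaired, miss rate 1 on present trials
  absent <- s
  absent$response <- "not-seen"
  sa <- score_vf(absent)
  expect_equal(sa$n_intact, 0)
  expect_equal(sa$false_negative_rate, 1)
  expect_equal(sa$false_positive_rate, 0)
  # always-"present": false-positive rate 1 on absent trials
  pres <- s
  pres$response <- "seen"
  sp <- score_vf(pres)
  expect_equal(sp$false_positive_rate, 1)
  expect_equal(sp$n_intact, 0)
  # a quadrant-limited responder is intact exactly there (sectors 1-2 of
  # 8 cover polar angles 0-90 deg)
  quad <- s
  sees <- quad$sector %in% c(1, 2)
  quad$response <- ifelse(quad$present & sees, "seen", "not-seen")
  sq <- score_vf(quad)
  expect_equal(sq$n_intact, sum(unique(s[c("ring", "sector")])$sector %in%
                                  c(1, 2)))
})

test_that("score_vf warns on incomplete sessions", {
  s <- make_vf_session(seed = 5)
  partial <- s[s$present | s$sector > 1, ]   # drop absent trials, sector 1
  partial$response <- ifelse(partial$present, "seen", "not-seen")
  expect_warning(sc <- score_vf(partial), "incomplete")
  expect_true(any(is.na(sc$positions$intact)))
})

test_that("BF01 closed form matches hand values and symmetry", {
  b <- bf01_binomial(5, 10)
  expect_equal(b$bf01, 11 * 252 / 1024, tolerance = 1e-12)   # ~2.707
  expect_equal(bf01_binomial(10, 10)$bf01, 11 / 1024, tolerance = 1e-12)
  # symmetric in k <-> n - k at p0 = 1/2
  for (k in 0:6)
    expect_equal(bf01_binomial(k, 12)$bf01, bf01_binomial(12 - k, 12)$bf01)
  # k = n/2 maximizes BF01 over k
  bfs <- sapply(0:10, function(k) bf01_binomial(k, 10)$bf01)
  expect_equal(which.max(bfs) - 1, 5)
})

test_that("BF01 agrees with numerical integration, all sidedness variants", {
  for (n in c(1, 3, 10, 40)) for (k in 0:n) {
    num <- integrate(function(p) dbinom(k, n, p), 0, 1,
                     rel.tol = 1e-12)$value
    expect_equal(bf01_binomial(k, n)$bf01, dbinom(k, n, 0.5) / num,
                 tolerance = 1e-10)
    num_g <- integrate(function(p) dbinom(k, n, p), 0.5, 1,
                       rel.tol = 1e-12)$value / 0.5
    expect_equal(bf01_binomial(k, n, alternative = "greater")$bf01,
                 dbinom(k, n, 0.5) / num_g, tolerance = 1e-8)
  }
})

test_that("staircase steps, reversals and the step-size switch", {
  # alternating correct/incorrect: a reversal on every trial after the first
  st <- staircase(start_level = 0.3)
  for (i in 1:10) st <- staircase_step(st, i %% 2 == 1)
  expect_equal(length(st$reversal_levels), 9)
  # all-correct run: monotone descent, no reversals
  st2 <- staircase(start_level = 0.3)
  for (i in 1:8) st2 <- staircase_step(st2, TRUE)
  expect_equal(length(st2$reversal_levels), 0)
  expect_equal(st2$level, 0.3 - 8 * 0.04, tolerance = 1e-12)
  expect_true(all(diff(st2$history$level) < 0))
  # the step size halves after the 5th reversal (hand-traced trace)
  st3 <- staircase(start_level = 0)
  for (i in 1:11) st3 <- staircase_step(st3, i %% 2 == 1)
  # moves 1-6 precede the 5th reversal (0.04), later moves use 0.02
  lv <- st3$history$level
  expect_equal(abs(diff(lv))[1:6], rep(0.04, 6), tolerance = 1e-12)
  expect_equal(abs(diff(lv))[7:10], rep(0.02, 4), tolerance = 1e-12)
  # 2-down/1-up needs two consecutive correct to move down
  st4 <- staircase(start_level = 1, n_down = 2, step_initial = 0.05,
                   step_final = 0.05, bounds = c(0, 1))
  st4 <- staircase_step(st4, TRUE)
  expect_equal(st4$level, 1)
  st4 <- staircase_step(st4, TRUE)
  expect_equal(st4$level, 0.95)
})

test_that("staircases converge to the observer's tracked point", {
  # 1-down/1-up tracks the 50% point of the psychometric function
  obs <- logistic_observer(pse = 0.2, slope = 0.08)
  st <- run_staircase(staircase(start_level = 0.45), 500, obs, seed = 42)
  est <- mean(st$reversal_levels[-(1:5)])
  expect_lt(abs(est - 0.2), 0.05)
  # 2-down/1-up tracks the 70.7% point
  target <- 0.2 + 0.08 * log(sqrt(0.5) / (1 - sqrt(0.5)))
  st2 <- run_staircase(staircase(start_level = 0.45, n_down = 2),
                       500, obs, seed = 43)
  est2 <- mean(st2$reversal_levels[-(1:5)])
  expect_lt(abs(est2 - target), 0.05)
})

test_that("illusion strength: MAD filter hand examples and invariances", {
  expect_equal(illusion_strength(c(0.18, 0.20, 0.22)), 0.20)
  # outlier at 0.90: median 0.21, MAD 0.02, bounds [0.17, 0.25]
  expect_equal(illusion_strength(c(0.18, 0.20, 0.22, 0.90)), 0.20)
  # identical reversals: MAD 0, boundary values kept
  expect_equal(illusion_strength(rep(0.13, 6)), 0.13)
  # order invariance and shift equivariance
  r <- c(0.18, 0.25, 0.21, 0.9, 0.19)
  expect_equal(illusion_strength(r), illusion_strength(rev(r)))
  expect_equal(illusion_strength(r + 0.1), illusion_strength(r) + 0.1)
  expect_error(illusion_strength(c(0.1, 0.2)), "at least 3")
})

test_that("fixed-pair test: proportions and exact binomial p", {
  full <- fixed_pair_test(k = 40, n = 40)
  expect_equal(full$proportion_small, 1)
  expect_lt(full$p_value, 1e-9)
  chance <- fixed_pair_test(k = 20, n = 40)
  expect_equal(chance$proportion_small, 0.5)
  expect_equal(chance$p_value, 1)
  none <- fixed_pair_test(rep("large", 40))
  expect_equal(none$proportion_small, 0)
  expect_equal(fixed_pair_test(c("small", "large", "small"))$k, 2)
})
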