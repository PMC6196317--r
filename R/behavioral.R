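# Behavioral computations: computerized visual-field screen, binomial
# Bayes-factor blindsight test, adaptive staircases and the MAD-filtered
# illusion-strength estimator.

#' Ring radii of the computerized visual-field test
#'
#' The display is divided into `n_rings` concentric rings with equal radial
#' spacing out to `outer_deg` (default: 4 rings to 37.5 deg, i.e. radii in
#' steps of 9.375 deg).
#'
#' @param outer_deg radius of the outermost ring (degrees).
#' @param n_rings number of rings.
#' @return numeric vector of outer radii, one per ring.
#' @export
vf_ring_radii <- function(outer_deg = 37.5, n_rings = 4) {
  stopifnot(outer_deg > 0, n_rings >= 1)
  seq_len(n_rings) * outer_deg / n_rings
}

#' Build a computerized visual-field session
#'
#' Positions are the `n_rings x n_sectors` cells of the ring/sector grid
#' (sectors step `360 / n_sectors` deg of polar angle). Each position gets
#' `reps_per_position` trials, half of them stimulus-present (for the
#' default 2 reps: exactly one present and one absent trial per position,
#' 4 x 8 x 2 = 64 trials). Trial order is pseudo-random given `seed`.
#'
#' @param n_rings,n_sectors,reps_per_position positive counts.
#' @param duration_s stimulus duration tag carried on every trial (the
#'   screen is run once at 9 s and once at 0.5 s).
#' @param seed integer seed for the trial order.
#' @return data.frame: `trial`, `ring`, `sector`, `present`, `duration_s`;
#'   `response` is left NA for the responder to fill with `"seen"` /
#'   `"not-seen"`.
#' @export
make_vf_session <- function(n_rings = 4, n_sectors = 8,
                            reps_per_position = 2, duration_s = 9,
                            seed = 1) {
  stopifnot(n_rings >= 1, n_sectors >= 1, reps_per_position >= 1)
  pos <- expand.grid(ring = seq_len(n_rings), sector = seq_len(n_sectors),
                     KEEP.OUT.ATTRS = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
    pres <- rep(c(TRUE, FALSE), length.out = reps_per_position)
    data.frame(ring = pos$ring[i], sector = pos$sector[i], present = pres)
  }))
  set.seed(seed)
  rows <- rows[sample.int(nrow(rows)), ]
  rows$trial <- seq_len(nrow(rows))
  rows$duration_s <- duration_s
  rows$response <- NA_character_
  rownames(rows) <- NULL
  rows[, c("trial", "ring", "sector", "present", "duration_s", "response")]
}

#' Score a visual-field session
#'
#' Counts hits, misses, false alarms and correct rejections per position.
#' A position is classified intact only when every present trial was
#' detected AND every absent trial was correctly rejected; a single error
#' marks it impaired. Positions missing either trial type are scored NA
#' with a warning (partial session).
#'
#' @param trials a [make_vf_session()] table with the `response` column
#'   filled (`"seen"` / `"not-seen"`).
#' @return list: `positions` (per-position table with `intact`), `n_intact`,
#'   `false_negative_rate` (on present trials), `false_positive_rate` (on
#'   absent trials).
#' @export
score_vf <- function(trials) {
  if (any(is.na(trials$response)))
    stop("all trials need a response before scoring")
  seen <- trials$response == "seen"
  key <- interaction(trials$ring, trials$sector, drop = FALSE)
  pieces <- split(seq_len(nrow(trials)), key)
  pos <- do.call(rbind, lapply(pieces, function(ii) {
    pr <- trials$present[ii]
    data.frame(ring = trials$ring[ii[1]], sector = trials$sector[ii[1]],
               n_present = sum(pr), n_absent = sum(!pr),
               hits = sum(pr & seen[ii]), misses = sum(pr & !seen[ii]),
               false_alarms = sum(!pr & seen[ii]),
               correct_rejections = sum(!pr & !seen[ii]))
  }))
  rownames(pos) <- NULL
  incomplete <- pos$n_present == 0 | pos$n_absent == 0
  if (any(incomplete))
    warning("incomplete session: ", sum(incomplete),
            " position(s) lack a present or absent trial; scored NA")
  pos$intact <- ifelse(incomplete, NA,
                       pos$misses == 0 & pos$false_alarms == 0)
  list(positions = pos[order(pos$ring, pos$sector), ],
       n_intact = sum(pos$intact, na.rm = TRUE),
       false_negative_rate = sum(pos$misses) / max(sum(pos$n_present), 1),
       false_positive_rate = sum(pos$false_alarms) / max(sum(pos$n_absent), 1))
}

#' Binomial Bayes factor for chance performance (BF01)
#'
#' Evidence for the null `p = p0` (guessing) over the alternative that the
#' success probability is unknown with a uniform Beta(1, 1) prior
#' (restricted to `p > p0` or `p < p0` for the one-sided variants):
#' `BF01 = P(k | p0) / integral P(k | p) d prior(p)`. Two-sided this has
#' the closed form `(n + 1) * choose(n, k) * p0^k * (1 - p0)^(n - k)`.
#'
#' @param k number of correct responses (0..n).
#' @param n number of trials (>= 1).
#' @param p0 chance level (default 0.5).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `bf01`, `accuracy` (k/n), `k`, `n`.
#' @export
bf01_binomial <- function(k, n, p0 = 0.5,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 1, k >= 0, k <= n, p0 > 0, p0 < 1)
  null_lik <- stats::dbinom(k, n, p0)
  marginal <- switch(alternative,
    two.sided = 1 / (n + 1),
    greater = (1 - stats::pbeta(p0, k + 1, n - k + 1)) /
      ((n + 1) * (1 - p0)),
    less = stats::pbeta(p0, k + 1, n - k + 1) / ((n + 1) * p0))
  list(bf01 = null_lik / marginal, accuracy = k / n, k = k, n = n)
}

#' Create an adaptive staircase
#'
#' A transformed up-down track: after `n_down` consecutive correct
#' responses the level steps down, after `n_up` consecutive errors it steps
#' up. A change of movement direction records a reversal at the pre-change
#' level. The step size switches from `step_initial` to `step_final` after
#' the reversal numbered `switch_after` has been recorded (the move that
#' creates it still uses the initial step).
#'
#' Presets: the Ebbinghaus size-ratio track is 1-down/1-up with steps
#' 0.04 then 0.02 natural-log units (switch after the 5th reversal); the
#' motion-coherence track is 2-down/1-up with symmetric 5% (or 20% for the
#' five-dot variant) steps bounded to \[0, 1\].
#'
#' @param start_level initial stimulus level (log size-ratio, coherence
#'   proportion, ...).
#' @param n_down consecutive correct responses required to step down.
#' @param n_up consecutive errors required to step up.
#' @param step_initial,step_final step sizes before/after the switch.
#' @param switch_after reversal count triggering the smaller step.
#' @param bounds length-2 clamp on the level.
#' @return list of class `staircase`.
#' @export
staircase <- function(start_level, n_down = 1, n_up = 1,
                      step_initial = 0.04, step_final = 0.02,
                      switch_after = 5, bounds = c(-Inf, Inf)) {
  stopifnot(n_down >= 1, n_up >= 1, step_initial > 0, step_final > 0,
            length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(level = start_level, n_down = n_down, n_up = n_up,
                 step_initial = step_initial, step_final = step_final,
                 switch_after = switch_after, bounds = bounds,
                 run_correct = 0L, run_incorrect = 0L,
                 last_move = NA_character_,
                 reversal_levels = numeric(0),
                 history = data.frame(level = numeric(0),
                                      correct = logical(0))),
            class = "staircase")
}

#' Advance a staircase by one trial
#'
#' @param state a [staircase()] state.
#' @param correct logical: was the response correct?
#' @return The updated state.
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase"), is.logical(correct))
  state$history <- rbind(state$history,
                         data.frame(level = state$level, correct = correct))
  move <- NULL
  if (correct) {
    state$run_correct <- state$run_correct + 1L
    state$run_incorrect <- 0L
    if (state$run_correct >= state$n_down) {
      move <- "down"
      state$run_correct <- 0L
    }
  } else {
    state$run_incorrect <- state$run_incorrect + 1L
    state$run_correct <- 0L
    if (state$run_incorrect >= state$n_up) {
      move <- "up"
      state$run_incorrect <- 0L
    }
  }
  if (!is.null(move)) {
    n_before <- length(state$reversal_levels)
    if (!is.na(state$last_move) && move != state$last_move)
      state$reversal_levels <- c(state$reversal_levels, state$level)
    step <- if (n_before < state$switch_after)
      state$step_initial else state$step_final
    delta <- if (move == "down") -step else step
    state$level <- min(max(state$level + delta, state$bounds[1]),
                       state$bounds[2])
    state$last_move <- move
  }
  state
}

#' Run a staircase against a simulated observer
#'
#' @param state a [staircase()] state.
#' @param n_trials trials to run.
#' @param observer `function(level)` returning the probability of a correct
#'   response at that level (see [logistic_observer()]).
#' @param seed integer seed for the observer's responses.
#' @return The final state (with full `history` and `reversal_levels`).
#' @export
run_staircase <- function(state, n_trials, observer, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  for (i in seq_len(n_trials)) {
    p <- observer(state$level)
    state <- staircase_step(state, stats::runif(1) < p)
  }
  state
}

#' Logistic simulated observer
#'
#' Probability correct rises from `guess` (lapse-adjusted) to
#' `1 - lapse` along a logistic with point of subjective equality /
#' threshold `pse` and slope parameter `slope` (level units per logit).
#'
#' @param pse level of the 50% point of the underlying logistic.
#' @param slope logistic scale (larger = shallower).
#' @param lapse lapse rate (default 0).
#' @param guess lower asymptote (default 0: a yes/no-style ramp whose 50%
#'   point is `pse`; use 0.5 for a 2AFC observer).
#' @return `function(level)` giving P(correct).
#' @export
logistic_observer <- function(pse, slope, lapse = 0, guess = 0) {
  function(level) {
    p <- stats::plogis((level - pse) / slope)
    guess + (1 - guess - lapse) * p
  }
}

#' Illusion strength from staircase reversals (MAD-filtered mean)
#'
#' Reversal levels outside `median +/- n_mad * MAD` are discarded (MAD is
#' the raw median absolute deviation, no consistency factor; values exactly
#' on the boundary are retained) and the mean of the survivors is returned,
#' in the staircase's level units (natural-log size ratio for the
#' Ebbinghaus track). Positive values follow the classical illusion
#' direction (test target surrounded by small inducers judged larger at
#' physical equality).
#'
#' @param reversal_levels numeric vector of recorded reversal levels
#'   (>= 3); pooled across interleaved staircases.
#' @param n_mad MAD multiplier (default 2).
#' @export
illusion_strength <- function(reversal_levels, n_mad = 2) {
  if (length(reversal_levels) < 3)
    stop("need at least 3 reversals to estimate the illusion strength")
  med <- stats::median(reversal_levels)
  dev <- abs(reversal_levels - med)
  mad0 <- stats::median(dev)
  keep <- dev <= n_mad * mad0 + 1e-12
  if (!any(keep))
    stop("all reversals filtered out; inspect the staircase track")
  mean(reversal_levels[keep])
}

#' Fixed-pair (physically equal) illusion check
#'
#' When test and reference targets are physically identical, an observer
#' experiencing the illusion should keep choosing the small-inducer target
#' as larger. Reports the choice proportion and a two-sided exact binomial
#' test against chance.
#'
#' @param responses character vector with entries `"small"` (small-inducer
#'   target chosen as larger) or `"large"`; alternatively a count `k` via
#'   `k =` together with `n =`.
#' @param k,n optional count interface: `k` small-inducer choices out of
#'   `n` trials.
#' @return list: `proportion_small`, `p_value`, `k`, `n`.
#' @export
fixed_pair_test <- function(responses = NULL, k = NULL, n = NULL) {
  if (!is.null(responses)) {
    stopifnot(all(responses %in% c("small", "large")))
    k <- sum(responses == "small")
    n <- length(responses)
  }
  stopifnot(!is.null(k), !is.null(n), n >= 1, k >= 0, k <= n)
  list(proportion_small = k / n,
       p_value = stats::binom.test(k, n, 0.5)$p.value, k = k, n = n)
}
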