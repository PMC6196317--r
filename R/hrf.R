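# Per-subject hemodynamic response function estimation from the full-field
# event run: trial averaging, responsive-vertex selection, two-gamma fit.

#' Two-gamma hemodynamic response function parameters
#'
#' The HRF is modeled as a difference of two gamma-shaped kernels with four
#' free parameters: `amplitude` (peak response, z units), `peak_latency_s`
#' (time of the positive peak), `undershoot_latency_s` (time of the
#' undershoot trough) and `ratio` (peak/undershoot amplitude ratio, > 0).
#' Each kernel `g(t; tau)` is a gamma density with fixed shape `kappa = 6`
#' and scale `tau / (kappa - 1)` — so its mode sits exactly at `tau` —
#' rescaled to unit peak:
#' `hrf(t) = amplitude * (g(t; peak) - g(t; undershoot) / ratio)`.
#'
#' @param amplitude peak response.
#' @param peak_latency_s time of the positive peak (s); must be smaller
#'   than `undershoot_latency_s`.
#' @param undershoot_latency_s time of the undershoot trough (s).
#' @param ratio peak/undershoot amplitude ratio (> 0).
#' @return An object of class `two_gamma_hrf`.
#' @export
two_gamma_hrf <- function(amplitude = 1, peak_latency_s = 5,
                          undershoot_latency_s = 15, ratio = 6) {
  p <- c(amplitude = amplitude, peak_latency_s = peak_latency_s,
         undershoot_latency_s = undershoot_latency_s, ratio = ratio)
  if (!all(is.finite(p))) stop("HRF parameters must be finite")
  if (peak_latency_s <= 0 || undershoot_latency_s <= 0)
    stop("latencies must be positive")
  if (peak_latency_s >= undershoot_latency_s)
    stop("peak_latency_s must be smaller than undershoot_latency_s")
  if (ratio <= 0) stop("ratio must be positive")
  structure(as.list(p), class = "two_gamma_hrf")
}

#' @export
print.two_gamma_hrf <- function(x, ...) {
  cat(sprintf(paste0("<two_gamma_hrf> amplitude %.3g, peak %.3g s, ",
                     "undershoot %.3g s, ratio %.3g\n"),
              x$amplitude, x$peak_latency_s, x$undershoot_latency_s,
              x$ratio))
  if (!is.null(attr(x, "residual_norm")))
    cat(sprintf("  fitted to %d responsive vertices, residual norm %.4g\n",
                attr(x, "n_responsive"), attr(x, "residual_norm")))
  invisible(x)
}

# unit-peak gamma kernel with mode at tau (shape kappa fixed at 6)
gamma_kernel <- function(t_s, tau, kappa = 6) {
  k1 <- kappa - 1
  out <- numeric(length(t_s))
  ok <- t_s > 0
  out[ok] <- (t_s[ok] / tau)^k1 * exp(-(t_s[ok] - tau) * k1 / tau)
  out
}

#' Evaluate the two-gamma HRF
#'
#' @param t_s time(s) since the impulse, seconds (>= 0).
#' @param hrf a [two_gamma_hrf()] object.
#' @return Response value(s); 0 at `t_s = 0`.
#' @export
two_gamma <- function(t_s, hrf) {
  stopifnot(inherits(hrf, "two_gamma_hrf"), all(t_s >= 0))
  hrf$amplitude * (gamma_kernel(t_s, hrf$peak_latency_s) -
                     gamma_kernel(t_s, hrf$undershoot_latency_s) / hrf$ratio)
}

#' Sample the HRF as a discrete convolution kernel
#'
#' @param hrf a [two_gamma_hrf()].
#' @param tr_s sampling interval (the repetition time).
#' @param max_t_s kernel truncation time (default 32 s).
#' @export
hrf_kernel <- function(hrf, tr_s, max_t_s = 32) {
  two_gamma(seq(0, max_t_s, by = tr_s), hrf)
}

#' Average a vertex time series across event repetitions
#'
#' Cuts `trial_len_volumes`-long windows starting at each 1-based
#' `trial_onsets` index and returns the per-volume mean and standard error
#' of the mean across repetitions.
#'
#' @param vertex_timeseries numeric vector (one vertex, volumes in order).
#' @param trial_onsets 1-based start volume of each repetition.
#' @param trial_len_volumes window length in volumes.
#' @return list of class `event_average` with `mean_course`, `sem_course`
#'   and `n_trials`.
#' @export
event_average <- function(vertex_timeseries, trial_onsets,
                          trial_len_volumes) {
  stopifnot(trial_len_volumes >= 1, length(trial_onsets) >= 1)
  on <- sort(as.integer(trial_onsets))
  if (any(on < 1) || any(on + trial_len_volumes - 1 > length(vertex_timeseries)))
    stop("trial windows must fit inside the series")
  if (length(on) > 1 && any(diff(on) < trial_len_volumes))
    stop("design error: trial windows overlap")
  win <- vapply(on, function(o)
    vertex_timeseries[o:(o + trial_len_volumes - 1)],
    numeric(trial_len_volumes))            # volumes x trials
  m <- rowMeans(win)
  s <- if (length(on) > 1) apply(win, 1, stats::sd) / sqrt(length(on))
       else rep(0, trial_len_volumes)
  structure(list(mean_course = m, sem_course = s, n_trials = length(on)),
            class = "event_average")
}

#' Is a vertex visually responsive?
#'
#' A vertex counts as responsive when `mean - SEM`, averaged over the first
#' half of the trial window (volumes `1..ceiling(L/2)`), exceeds zero. With
#' `rule = "per_volume"` every volume in the first half must individually
#' exceed zero (a stricter variant).
#'
#' @param event_avg an [event_average()].
#' @param rule `"mean"` (default) or `"per_volume"`.
#' @export
is_responsive <- function(event_avg, rule = c("mean", "per_volume")) {
  rule <- match.arg(rule)
  L <- length(event_avg$mean_course)
  half <- seq_len(ceiling(L / 2))
  lower <- event_avg$mean_course[half] - event_avg$sem_course[half]
  if (rule == "mean") mean(lower) > 0 else all(lower > 0)
}

#' Fit the two-gamma HRF to responsive event averages
#'
#' Vertices failing [is_responsive()] are discarded; the remaining event
#' averages are grand-averaged and a [two_gamma_hrf()] is fitted by
#' derivative-free least squares (Nelder-Mead on logit-bounded parameters:
#' peak latency in \[2, 10\] s, undershoot latency in \[8, 25\] s, ratio in
#' \[1, 20\], amplitude free), sampling the model at
#' `t = (0, 1, ..., L-1) * tr_s`.
#'
#' @param event_averages a list of [event_average()] objects (one per
#'   vertex), or a single `event_average`.
#' @param tr_s repetition time in seconds.
#' @param start optional `two_gamma_hrf` used as the optimization start.
#' @return A fitted `two_gamma_hrf` with attributes `residual_norm`,
#'   `n_responsive` and `mean_course`.
#' @export
fit_hrf <- function(event_averages, tr_s, start = two_gamma_hrf()) {
  if (inherits(event_averages, "event_average"))
    event_averages <- list(event_averages)
  stopifnot(length(event_averages) >= 1)
  resp <- vapply(event_averages, is_responsive, TRUE)
  if (!any(resp))
    stop("no HRF: no vertex passed the responsiveness rule; ",
         "fall back to the canonical two_gamma_hrf() defaults")
  courses <- vapply(event_averages[resp], `[[`,
                    numeric(length(event_averages[[1]]$mean_course)),
                    "mean_course")
  grand <- rowMeans(as.matrix(courses))
  t_s <- (seq_along(grand) - 1) * tr_s

  lims <- list(peak = c(2, 10), under = c(8, 25), ratio = c(1, 20))
  to_unit <- function(v, l) stats::qlogis(pmin(pmax((v - l[1]) / (l[2] - l[1]),
                                                    1e-6), 1 - 1e-6))
  from_unit <- function(th, l) l[1] + (l[2] - l[1]) * stats::plogis(th)
  th0 <- c(start$amplitude,
           to_unit(start$peak_latency_s, lims$peak),
           to_unit(start$undershoot_latency_s, lims$under),
           to_unit(start$ratio, lims$ratio))
  obj <- function(th) {
    pk <- from_unit(th[2], lims$peak)
    un <- from_unit(th[3], lims$under)
    if (pk >= un) return(sum(grand^2) * (1 + (pk - un)^2))
    h <- two_gamma_hrf(th[1], pk, un, from_unit(th[4], lims$ratio))
    sum((grand - two_gamma(t_s, h))^2)
  }
  fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  out <- two_gamma_hrf(fit$par[1],
                       from_unit(fit$par[2], lims$peak),
                       from_unit(fit$par[3], lims$under),
                       from_unit(fit$par[4], lims$ratio))
  attr(out, "residual_norm") <- sqrt(fit$value)
  attr(out, "n_responsive") <- sum(resp)
  attr(out, "mean_course") <- grand
  out
}

#' Estimate the HRF from a full-field run time-series matrix
#'
#' Convenience wrapper: event-averages every vertex using the trial onsets
#' recorded in the full-field movie's design metadata, then calls
#' [fit_hrf()]. `ts` must already exclude dummy volumes (see
#' [load_timeseries()]); onsets are shifted accordingly.
#'
#' @param ts vertices x volumes matrix from the full-field run (dummy
#'   volumes removed).
#' @param movie the finalized full-field `aperture_movie`.
#' @param hemisphere optional per-vertex grouping labels; when given, one
#'   HRF is fitted per group and a named list is returned.
#' @export
estimate_hrf <- function(ts, movie, hemisphere = NULL) {
  stopifnot(inherits(movie, "aperture_movie"),
            movie$meta$kind == "fullfield")
  # meta$trial_onsets are 1-based in stimulus frames (dummies excluded),
  # which is exactly the frame of a dummy-stripped ts matrix
  onsets <- movie$meta$trial_onsets
  trial_len <- movie$meta$trial_len
  fit_one <- function(rows) {
    ev <- lapply(rows, function(i) event_average(ts[i, ], onsets, trial_len))
    fit_hrf(ev, movie$tr_s)
  }
  if (is.null(hemisphere)) return(fit_one(seq_len(nrow(ts))))
  groups <- split(seq_len(nrow(ts)), hemisphere)
  lapply(groups, fit_one)
}
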