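# Action-potential morphology metrics and the sum-of-squared-differences
# fitting error.
#
# Conventions, shared by every metric:
#   * AP upstroke onset = the interpolated time of the first upward crossing
#     of -40 mV (a sample exactly at threshold counts as the crossing);
#   * crossings are linearly interpolated between samples;
#   * the resting potential is the sample immediately preceding the stimulus
#     onset.

#' Resting membrane potential of an annotated trace
#'
#' The membrane potential in the sample immediately preceding the onset of
#' the stimulus current.
#'
#' @param trace A [voltage_trace()] with at least one stimulus annotation.
#' @param which Index of the stimulus to use (default first).
#' @return Resting potential (mV).
#' @export
resting_potential <- function(trace, which = 1L) {
  if (length(trace$stim_onsets) < which)
    stop("trace has no stimulus annotation")
  tt <- trace_times(trace)
  idx <- which(tt < trace$stim_onsets[which] - 1e-9)
  if (!length(idx)) stop("no samples precede the stimulus onset")
  trace$v[max(idx)]
}

#' Time of the action-potential upstroke
#'
#' Interpolated time of the first upward crossing of `threshold` (default
#' -40 mV, chosen to avoid the stimulus foot potential). A sample exactly at
#' threshold counts as the crossing.
#'
#' @inheritParams resting_potential
#' @param threshold Crossing threshold (mV).
#' @param after Only consider crossings at or after this time (ms).
#' @return Crossing time t0 (ms).
#' @export
align_upstroke <- function(trace, threshold = -40, after = -Inf) {
  tt <- trace_times(trace)
  v <- trace$v
  ok <- tt >= after
  i <- which(ok & v >= threshold &
               c(FALSE, head_lag(v) < threshold)[seq_along(v)])
  # also catch a first sample exactly at threshold
  exact <- which(ok & abs(v - threshold) < 1e-12)
  cand <- c(i, exact)
  if (!length(cand)) stop("trace never crosses ", threshold, " mV upward")
  k <- min(cand)
  if (abs(v[k] - threshold) < 1e-12 || k == 1) return(tt[k])
  # interpolate between k-1 and k
  tt[k - 1] + trace$dt * (threshold - v[k - 1]) / (v[k] - v[k - 1])
}

head_lag <- function(v) c(v[1], v[-length(v)])

# first downward crossing of `level` at or after time `from`
.downward_crossing <- function(trace, level, from) {
  tt <- trace_times(trace)
  v <- trace$v
  i <- which(tt > from & v <= level & head_lag(v) > level)
  if (!length(i)) return(NA_real_)
  k <- min(i)
  if (abs(v[k] - level) < 1e-12) return(tt[k])
  tt[k - 1] + trace$dt * (level - v[k - 1]) / (v[k] - v[k - 1])
}

#' APD80, mouse definition
#'
#' Duration from the upstroke onset (the -40 mV upward crossing) to the time
#' the potential has returned 80% of the way from 0 mV to the resting
#' membrane potential, i.e. to `0.8 * V_rest`.
#'
#' @inheritParams resting_potential
#' @param v_rest Resting potential; defaults to [resting_potential()] when
#'   the trace is annotated.
#' @return APD80 (ms).
#' @export
apd_mouse80 <- function(trace, which = 1L, v_rest = NULL) {
  if (is.null(v_rest)) v_rest <- resting_potential(trace, which)
  after <- if (length(trace$stim_onsets) >= which)
    trace$stim_onsets[which] else -Inf
  t0 <- align_upstroke(trace, -40, after = after)
  level <- 0.8 * v_rest
  tc <- .downward_crossing(trace, level, t0)
  if (is.na(tc))
    stop("APD80 undefined: no downward crossing of ", signif(level, 4),
         " mV after the upstroke")
  tc - t0
}

#' APD at a repolarization percentage of AP amplitude
#'
#' Duration from the upstroke onset to the first return to
#' `V_peak - level/100 * (V_peak - V_rest)`; the definition used for
#' CTC-converted beats (30, 50, and 90% repolarization).
#'
#' @inheritParams apd_mouse80
#' @param level Repolarization percentage (e.g. 30, 50, 90).
#' @return APD at that level (ms).
#' @export
apd_amplitude <- function(trace, level, which = 1L, v_rest = NULL) {
  stopifnot(level > 0, level <= 100)
  if (is.null(v_rest)) v_rest <- resting_potential(trace, which)
  after <- if (length(trace$stim_onsets) >= which)
    trace$stim_onsets[which] else -Inf
  t0 <- align_upstroke(trace, -40, after = after)
  tt <- trace_times(trace)
  seg <- trace$v[tt >= t0]
  v_peak <- max(seg)
  thr <- v_peak - level / 100 * (v_peak - v_rest)
  t_peak <- tt[tt >= t0][which.max(seg)]
  tc <- .downward_crossing(trace, thr, t_peak)
  if (is.na(tc))
    stop("APD", level, " undefined: no downward crossing of ",
         signif(thr, 4), " mV")
  tc - t0
}

#' Standard APD report for a beat
#'
#' @inheritParams apd_mouse80
#' @return Named list: `apd80` (mouse definition), `apd30`, `apd50`, `apd90`
#'   (amplitude definition), `v_rest`, `v_peak`.
#' @export
apd_report <- function(trace, which = 1L) {
  v_rest <- resting_potential(trace, which)
  tt <- trace_times(trace)
  after <- trace$stim_onsets[which]
  list(
    apd80 = apd_mouse80(trace, which, v_rest = v_rest),
    apd30 = apd_amplitude(trace, 30, which, v_rest = v_rest),
    apd50 = apd_amplitude(trace, 50, which, v_rest = v_rest),
    apd90 = apd_amplitude(trace, 90, which, v_rest = v_rest),
    v_rest = v_rest,
    v_peak = max(trace$v[tt >= after])
  )
}

#' Error window for the fitting objective
#'
#' @param threshold_mV Upstroke alignment threshold (mV).
#' @param t_max_ms Window length after alignment (ms).
#' @return An `error_window` list.
#' @export
error_window <- function(threshold_mV = -40, t_max_ms = 300) {
  stopifnot(t_max_ms > 0, threshold_mV > -80, threshold_mV < 0)
  structure(list(threshold_mV = threshold_mV, t_max_ms = t_max_ms),
            class = "error_window")
}

#' Sum of squared differences between two action potentials
#'
#' Both traces are aligned at their own -40 mV upstroke crossings, resampled
#' onto a common grid at the coarser of the two sample intervals, and the
#' squared voltage differences are summed over the window (default 300 ms).
#' This is the genetic algorithm's fitness (lower is better).
#'
#' @param trace1,trace2 [voltage_trace()] objects covering the window after
#'   their own alignment.
#' @param window An [error_window()].
#' @return SSD (mV^2).
#' @export
ssd <- function(trace1, trace2, window = error_window()) {
  t01 <- align_upstroke(trace1, window$threshold_mV)
  t02 <- align_upstroke(trace2, window$threshold_mV)
  step <- max(trace1$dt, trace2$dt)
  off <- seq(0, window$t_max_ms, by = step)
  if (t01 + window$t_max_ms > trace_end(trace1) + 1e-9 ||
      t02 + window$t_max_ms > trace_end(trace2) + 1e-9)
    stop("trace does not cover the full error window after alignment")
  v1 <- trace_interp(trace1, t01 + off)
  v2 <- trace_interp(trace2, t02 + off)
  sum((v1 - v2)^2)
}

#' Sup-norm deviation between two APs in upstroke-aligned time
#'
#' Both traces are aligned at their -40 mV upstroke crossings and compared
#' over `[-pre_ms, post_ms]` around the crossing, excluding a short blanking
#' window `(blank_ms[1], blank_ms[2])` around the crossing itself. On the
#' steep segments there (stimulus foot ~30 mV/ms, upstroke ~300 mV/ms, and
#' the Na-spike peak), comparing trajectories integrated at different steps
#' produces spikes of tens of mV that reflect only the discretization of
#' those segments, not conversion accuracy -- they vanish linearly as the
#' loop step shrinks, while the morphology deviation this metric targets
#' does not depend on them.
#'
#' @param trace1,trace2 [voltage_trace()] objects.
#' @param pre_ms,post_ms Comparison window around the aligned upstroke (ms).
#' @param blank_ms Length-2 blanking interval around the crossing (ms).
#' @return Maximum absolute voltage difference (mV).
#' @export
trace_supnorm_diff <- function(trace1, trace2, pre_ms = 50, post_ms = 500,
                               blank_ms = c(-2, 5)) {
  t01 <- align_upstroke(trace1, -40)
  t02 <- align_upstroke(trace2, -40)
  step <- max(trace1$dt, trace2$dt)
  off <- seq(-pre_ms, post_ms, by = step)
  off <- off[off <= blank_ms[1] | off >= blank_ms[2]]
  keep <- t01 + off >= trace1$t0 & t02 + off >= trace2$t0 &
    t01 + off <= trace_end(trace1) & t02 + off <= trace_end(trace2)
  v1 <- trace_interp(trace1, t01 + off[keep])
  v2 <- trace_interp(trace2, t02 + off[keep])
  max(abs(v1 - v2))
}
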