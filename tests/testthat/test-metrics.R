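# AP morphology metrics: closed-form oracle traces built in code.

# piecewise-linear trace builder: value `v0` before t_up, then linear from
# `v_top` at t_up to `v_end` at t_end, then flat
ramp_trace <- function(v0, t_up, v_top, t_end, v_end, dt = 0.1,
                       total = 400, onset = t_up - 5) {
  tt <- seq(0, total, by = dt)
  v <- ifelse(tt < t_up, v0,
              pmax(v_top + (v_end - v_top) * (tt - t_up) / (t_end - t_up),
                   v_end))
  voltage_trace(v, dt = dt, t0 = 0, stim_onsets = onset)
}

test_that("resting potential is the sample immediately before the stimulus", {
  tr <- voltage_trace(c(rep(-80, 100), rep(10, 50)), dt = 1, t0 = 0,
                      stim_onsets = 100)
  expect_equal(resting_potential(tr), -80)
  tr2 <- voltage_trace(c(rep(-80, 99), -71.3, rep(10, 50)), dt = 1, t0 = 0,
                       stim_onsets = 100)
  expect_equal(resting_potential(tr2), -71.3)
  expect_error(resting_potential(voltage_trace(c(1, 2), dt = 1)),
               "no stimulus")
})

test_that("upstroke alignment interpolates the -40 mV crossing", {
  # ramp -80 -> 0 over 8 ms starting at t = 100: -40 is reached at 104
  tt <- seq(0, 200, by = 0.5)
  v <- ifelse(tt < 100, -80, pmin(-80 + 10 * (tt - 100), 0))
  tr <- voltage_trace(v, dt = 0.5, t0 = 0, stim_onsets = 99)
  expect_equal(align_upstroke(tr, -40), 104, tolerance = 1e-12)
  # a sample exactly at threshold counts as the crossing
  tr2 <- voltage_trace(c(-80, -40, 0, 0), dt = 1, t0 = 10)
  expect_equal(align_upstroke(tr2, -40), 11)
  # no crossing -> error
  expect_error(align_upstroke(voltage_trace(rep(-80, 10), dt = 1), -40),
               "never crosses")
})

test_that("mouse-definition APD80 matches the closed-form line crossing", {
  # 0 mV at t=10 falling 1 mV/ms to rest -70 at t=80; stimulus at t=9
  tr <- ramp_trace(-70, 10, 0, 80, -70, dt = 0.1, onset = 9)
  # oracle: upstroke crossing of -40 between samples at 9.9 (-70) and 10 (0)
  t0 <- 9.9 + 0.1 * 30 / 70
  expect_equal(align_upstroke(tr, -40), t0, tolerance = 1e-9)
  # downward crossing of 0.8 * (-70) = -56 on the unit-slope ramp: t = 66
  expect_equal(apd_mouse80(tr), 66 - t0, tolerance = 1e-9)
})

test_that("amplitude-definition APDs match closed forms and are ordered", {
  # peak +30 at t=10, rest -70, linear fall over 100 ms
  tr <- ramp_trace(-70, 10, 30, 110, -70, dt = 0.1, onset = 9)
  t0 <- align_upstroke(tr, -40)
  # APD90 level: 30 - 0.9*100 = -60, crossed at t = 100 on the ramp
  expect_equal(apd_amplitude(tr, 90), 100 - t0, tolerance = 1e-6)
  expect_equal(apd_amplitude(tr, 50), 60 - t0, tolerance = 1e-6)
  a30 <- apd_amplitude(tr, 30); a50 <- apd_amplitude(tr, 50)
  a90 <- apd_amplitude(tr, 90)
  expect_true(a30 <= a50 && a50 <= a90)
})

test_that("a square AP has equal APDs at every level", {
  tt <- seq(0, 200, by = 0.01)
  v <- ifelse(tt >= 10 & tt < 60, 0, -70)
  tr <- voltage_trace(v, dt = 0.01, t0 = 0, stim_onsets = 9.5)
  w <- 60 - align_upstroke(tr, -40)
  expect_equal(apd_mouse80(tr), w, tolerance = 0.05)
  expect_equal(apd_amplitude(tr, 30), apd_amplitude(tr, 90), tolerance = 0.05)
  expect_equal(apd_amplitude(tr, 50), w, tolerance = 0.05)
})

test_that("all APD measures are invariant to a uniform time shift", {
  m <- neonatal_mouse_model()
  tr <- simulate_paced(m)
  sh <- voltage_trace(tr$v, dt = tr$dt, t0 = tr$t0 + 137.5,
                      stim_onsets = tr$stim_onsets + 137.5)
  expect_equal(apd_mouse80(tr), apd_mouse80(sh), tolerance = 1e-9)
  expect_equal(apd_amplitude(tr, 90), apd_amplitude(sh, 90),
               tolerance = 1e-9)
})

test_that("SSD is zero for identical traces, symmetric, and counts a constant offset", {
  m <- neonatal_mouse_model()
  tr <- simulate_paced(m)
  expect_equal(ssd(tr, tr), 0)
  tr2 <- simulate_paced(neonatal_mouse_model(apd80 = 80))
  expect_equal(ssd(tr, tr2), ssd(tr2, tr), tolerance = 1e-9)
  expect_gt(ssd(tr, tr2), 0)
  # step traces offset by 1 mV: after alignment the first common sample sits
  # at -40 on both, every one of the remaining 3000 grid points differs by 1
  tt <- seq(0, 500, by = 0.1)
  v1 <- ifelse(tt < 100, -80, 0)
  a <- voltage_trace(v1, dt = 0.1)
  b <- voltage_trace(v1 + 1, dt = 0.1)
  expect_equal(ssd(a, b), 3000, tolerance = 1e-6)
})

test_that("SSD resamples mixed-rate traces onto the coarser grid", {
  h <- human_recipient_model()
  fine <- simulate_paced(h)                       # dt = 0.01
  coarse <- voltage_trace(fine$v[seq(1, length(fine$v), by = 10)],
                          dt = 0.1, t0 = fine$t0,
                          stim_onsets = fine$stim_onsets)
  expect_lt(ssd(fine, coarse), 1)   # same AP, different sampling
})

test_that("SSD demands full window coverage", {
  tt <- seq(0, 150, by = 0.1)  # only ~50 ms beyond the upstroke
  v <- ifelse(tt < 100, -80, 0)
  a <- voltage_trace(v, dt = 0.1)
  expect_error(ssd(a, a), "window")
})

test_that("averaging aligns at stimulus onset and reduces noise ~ n-fold", {
  m <- neonatal_mouse_model()
  tr <- simulate_paced(m)
  expect_equal(average_aps(list(tr, tr))$v, tr$v, tolerance = 1e-12)
  up <- voltage_trace(tr$v + 1, tr$dt, tr$t0, tr$stim_onsets)
  dn <- voltage_trace(tr$v - 1, tr$dt, tr$t0, tr$stim_onsets)
  expect_equal(average_aps(list(up, dn))$v, tr$v, tolerance = 1e-12)
  # Monte-Carlo: additive independent noise shrinks by ~ n in variance
  set.seed(1)
  noisy <- lapply(1:10, function(i)
    voltage_trace(tr$v + rnorm(length(tr$v), sd = 0.5), tr$dt, tr$t0,
                  tr$stim_onsets))
  resid <- average_aps(noisy)$v - tr$v
  expect_lt(var(resid), 0.5^2 / 10 * 2)
  expect_gt(var(resid), 0.5^2 / 10 / 2)
  # mismatched sampling is rejected
  other <- voltage_trace(tr$v[seq(1, length(tr$v), 2)], tr$dt * 2, tr$t0,
                         tr$stim_onsets)
  expect_error(average_aps(list(tr, other)), "intervals")
})
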