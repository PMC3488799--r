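# The two ODE models: reference equivalence against the independent pure-R
# transcription, resting stability, AP properties, integration convergence.

test_that("mouse model matches the independent reference transcription", {
  m <- neonatal_mouse_model()
  amp <- default_stim_amplitude(m)
  n <- 10000L # one 1 Hz beat at dt = 0.1 ms
  sim <- ctcfit:::cpp_simulate(0L, m$state0, m$params, 0.1, n, 100, 1, amp,
                               FALSE)
  vref <- ref_simulate("mouse", m$state0, m$params, 0.1, n, 100, 1, amp)
  expect_lt(max(abs(sim$v - vref)) / max(abs(vref)), 1e-6)
  # total ionic current agrees along the AP at sampled states
  sim2 <- ctcfit:::cpp_simulate(0L, m$state0, m$params, 0.1, 3000L, 100, 1,
                                amp, TRUE)
  for (k in c(900, 1005, 1050, 1200, 1800, 2500)) {
    st <- sim2$states[k, ]
    i_cpp <- ionic_current(m, st)
    i_ref <- ref_mouse_current(st[1], st, m$params)
    expect_lt(abs(i_cpp - i_ref) / max(1, abs(i_ref)), 1e-6)
  }
})

test_that("human model matches the independent reference transcription", {
  h <- human_recipient_model()
  amp <- default_stim_amplitude(h)
  n <- 40000L # 400 ms at dt = 0.01 ms, covering the full AP
  sim <- ctcfit:::cpp_simulate(1L, h$state0, h$params, 0.01, n, 50, 1, amp,
                               FALSE)
  vref <- ref_simulate("human", h$state0, h$params, 0.01, n, 50, 1, amp)
  expect_lt(max(abs(sim$v - vref)) / max(abs(vref)), 1e-6)
  sim2 <- ctcfit:::cpp_simulate(1L, h$state0, h$params, 0.01, 20000L, 50, 1,
                                amp, TRUE)
  for (k in c(4000, 5200, 6000, 15000)) {
    st <- sim2$states[k, ]
    i_cpp <- ionic_current(h, st)
    i_ref <- ref_human_current(st[1], st, h$params)
    expect_lt(abs(i_cpp - i_ref) / max(1, abs(i_ref)), 1e-6)
  }
})

test_that("both models are stable at rest and only fire when stimulated", {
  for (model in list(neonatal_mouse_model(), human_recipient_model())) {
    tr <- simulate_paced(model, stimulus_protocol(amplitude = 1e-9))
    expect_lt(max(abs(tr$v - tr$v[1])), 1)   # ~zero stimulus: stays at rest
    ap <- simulate_paced(model)
    expect_gt(max(ap$v), 0)                  # suprathreshold: overshoot
    expect_lt(abs(resting_potential(ap) - model$state0[["V"]]), 1)
  }
})

test_that("sub-threshold pulses do not trigger a regenerative upstroke", {
  m <- neonatal_mouse_model()
  thr <- stimulus_threshold(m)
  tr <- simulate_paced(m, stimulus_protocol(amplitude = 0.5 * thr))
  expect_lt(max(tr$v), -20)
})

test_that("APD is insensitive to halving the integration step", {
  m <- neonatal_mouse_model()
  a1 <- apd_mouse80(simulate_paced(m, settings = sim_settings(dt = 0.1)))
  a2 <- apd_mouse80(simulate_paced(m, settings = sim_settings(dt = 0.05)))
  expect_lt(abs(a1 - a2), 0.5)
  h <- human_recipient_model()
  b1 <- apd_amplitude(simulate_paced(h, settings = sim_settings(dt = 0.01)), 90)
  b2 <- apd_amplitude(simulate_paced(h, settings = sim_settings(dt = 0.005)), 90)
  expect_lt(abs(b1 - b2), 0.5)
})

test_that("quasi-stationary pacing: consecutive beats have matching APD80", {
  m <- neonatal_mouse_model()
  tr <- simulate_paced(m, settings = sim_settings(beats = 3))
  # the very first beat from rest carries a slow-gate transient (~2.4 ms);
  # from the second beat on, 1 Hz pacing is quasi-stationary
  expect_lt(abs(apd_mouse80(tr, which = 2) - apd_mouse80(tr, which = 3)), 2)
  expect_lt(abs(apd_mouse80(tr, which = 1) - apd_mouse80(tr, which = 2)), 4)
})

test_that("each current component scales linearly with its conductance", {
  m <- neonatal_mouse_model()
  st <- m$state0; st[["V"]] <- -20; st[["rss"]] <- 0.5; st[["sss"]] <- 0.5
  base <- ionic_current(m, st, components = TRUE)
  m2 <- m; m2$params[["gss"]] <- 2 * m$params[["gss"]]
  doubled <- ionic_current(m2, st, components = TRUE)
  expect_equal(doubled[["iss"]], 2 * base[["iss"]], tolerance = 1e-12)
  expect_equal(doubled[["iNa"]], base[["iNa"]], tolerance = 1e-12)
})

test_that("K+ currents reverse at the K+ Nernst potential", {
  m <- neonatal_mouse_model()
  p <- m$params
  cond <- c("gNa", "gCaL", "gt", "gKslow", "gss", "gf", "gBNa", "gBCa",
            "gK1", "iNaKmax", "kNaCa", "iCaPmax")
  p[cond] <- 0
  m$params <- p   # only the ohmic K+ background remains (plus the fixed
                  # micro-ampere-scale term of the published I_K1 form)
  ek <- 8314.5 * 295 / 96487 * log(p[["Ko"]] / p[["Ki"]])
  expect_lt(abs(ionic_current(m, m$state0, V = ek)), 1e-5)
  # the inward rectifier (whose published form carries a +1.73 mV shift)
  # changes sign within a few mV of E_K
  m2 <- neonatal_mouse_model()
  i_lo <- ionic_current(m2, m2$state0, V = ek - 5, components = TRUE)[["iK1"]]
  i_hi <- ionic_current(m2, m2$state0, V = ek + 5, components = TRUE)[["iK1"]]
  expect_lt(i_lo, 0); expect_gt(i_hi, 0)
})

test_that("clamped stepping holds V, fixes the resting state, and keeps gates in [0,1]", {
  m <- neonatal_mouse_model()
  st1 <- step_clamped(m, m$state0, V = m$state0[["V"]])
  expect_lt(max(abs(st1 - m$state0)), 1e-9)
  for (V in c(-150, -80, 0, 80)) {
    st <- m$state0
    for (i in 1:50) st <- step_clamped(m, st, V = V)
    expect_true(all(st[-1] >= 0 & st[-1] <= 1))
  }
})

test_that("clamped stepping along a free-running V reproduces the free gates", {
  m <- neonatal_mouse_model()
  amp <- default_stim_amplitude(m)
  sim <- ctcfit:::cpp_simulate(0L, m$state0, m$params, 0.1, 2000L, 50, 1,
                               amp, TRUE)
  st <- m$state0
  for (k in 1:2000) st <- step_clamped(m, st, V = sim$states[k, 1])
  expect_lt(max(abs(st[-1] - sim$states[2001, -1])), 1e-6)
})

test_that("free stepping at equilibrium leaves V unchanged", {
  m <- neonatal_mouse_model()
  st <- step_free(m, m$state0, i_applied = 0)
  expect_lt(abs(st[["V"]] - m$state0[["V"]]), 1e-6)
})

test_that("the fast-exp flag approximates without changing AP character", {
  m <- neonatal_mouse_model()
  exact <- simulate_paced(m)
  fast <- simulate_paced(m, settings = sim_settings(fast_exp = TRUE))
  expect_false(ctcfit:::cpp_get_fast_exp()) # flag restored after the run
  expect_lt(abs(apd_mouse80(exact) - apd_mouse80(fast)), 2)
})

test_that("out-of-bounds genotypes and invalid parameters are rejected", {
  expect_error(neonatal_mouse_model(genotype = c(
    gNa = 0.95, gss = 0, gKslow = 0, gCaL = 0, gK1 = 0, gt = 0)),
    "out of bounds")
  p <- ctcfit:::.mouse_baseline_params
  p[["Cai"]] <- -1
  expect_error(neonatal_mouse_model(params = p), "concentrations")
})
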