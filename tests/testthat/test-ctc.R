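# Closed-loop CTC: exact identities, seal/LJP handling, conversion behavior.

t60 <- function() neonatal_mouse_model(apd80 = 60)

test_that("seal leak is ohmic toward bath ground and off at infinite resistance", {
  expect_equal(seal_leak(0, 5.6), 0)
  expect_equal(seal_leak(-77, Inf), 0)
  expect_equal(abs(seal_leak(-56, 5.6)), 10)  # mV / GOhm = pA
})

test_that("identical target, canceling and recipient models leave the cell native", {
  m <- t60()
  rec <- run_ctc(m, m, m, ctc_config(), beats = 1)
  expect_lt(max(abs(rec$i_diff)), 1e-9)
  native <- simulate_paced(
    m, stimulus_protocol(amplitude = attr(rec, "stim_amplitude")))
  expect_lt(max(abs(rec$v_target - native$v[seq_len(nrow(rec))])), 1e-9)
})

test_that("the record satisfies its arithmetic identities at every sample", {
  m <- t60()
  rec <- run_ctc(m, m, human_recipient_model(), ctc_config(), beats = 1)
  expect_equal(rec$i_diff, rec$i_recipient - rec$i_cancel, tolerance = 1e-12)
  # outside the stimulus, injection = difference - seal compensation (= 0 here)
  onset <- attr(rec, "stim_onsets")[1]
  outside <- rec$time_ms < onset - 1 | rec$time_ms > onset + 2
  expect_equal(rec$i_inject[outside], rec$i_diff[outside], tolerance = 1e-12)
  expect_true(all(rec$i_seal == 0))
})

test_that("infinite seal and zero LJP are exact no-ops; a compensated seal is too", {
  m <- t60(); h <- human_recipient_model()
  base <- run_ctc(m, m, h, ctc_config(), beats = 1)
  same <- run_ctc(m, m, h, ctc_config(r_seal_GOhm = Inf, ljp_mV = 0),
                  beats = 1)
  expect_identical(base$v_target, same$v_target)
  sealed <- run_ctc(m, m, h, ctc_config(r_seal_GOhm = 5.6), beats = 1)
  expect_lt(max(abs(sealed$v_target - base$v_target)), 1e-9)
  expect_gt(max(abs(sealed$i_seal)), 0)
})

test_that("capacitance bookkeeping cancels in normalized units", {
  m <- t60(); h <- human_recipient_model()
  a <- run_ctc(m, m, h, ctc_config(), beats = 1)
  b <- run_ctc(m, m, h, ctc_config(c_target_pF = 2 * m$capacitance_pF),
               beats = 1)
  expect_identical(a$v_target, b$v_target)
})

test_that("ideal conversion reproduces the free-running recipient AP", {
  m <- t60(); h <- human_recipient_model()
  cfg <- ctc_config()
  rec <- run_ctc(m, m, h, cfg, beats = 1)
  ref <- recipient_reference(h, cfg, beats = 1)
  expect_lt(trace_supnorm_diff(ctc_trace(rec), ref), 2)
  apds <- apd_comparison(rec, ref)
  expect_lt(abs(apds$apd90_conv - apds$apd90_ref), 2)
})

test_that("a longer-APD canceling model under-prolongs the converted AP", {
  m <- t60(); h <- human_recipient_model()
  cfg <- ctc_config()
  ideal <- apd_comparison(run_ctc(m, m, h, cfg, 1),
                          recipient_reference(h, cfg, 1))
  mm <- apd_comparison(run_ctc(m, neonatal_mouse_model(apd80 = 70), h, cfg, 1),
                       recipient_reference(h, cfg, 1))
  expect_lt(mm$apd90_conv, ideal$apd90_conv)
  expect_lt(mm$apd30_conv, ideal$apd30_ref)  # early repolarization too short
})

test_that("the plateau difference current is inward", {
  m <- t60(); h <- human_recipient_model()
  rec <- run_ctc(m, m, h, ctc_config(), beats = 1)
  sel <- rec$time_ms > 150 & rec$time_ms < 300
  expect_true(all(rec$i_diff[sel] < 0))
})

test_that("the compiled loop agrees with a step-by-step R assembly of the circuit", {
  m <- t60(); h <- human_recipient_model()
  cfg <- ctc_config()
  n <- 1200L  # 120 ms: baseline + stimulus + upstroke
  amp <- attr(run_ctc(m, m, h, cfg, beats = 1), "stim_amplitude")
  rec <- run_ctc(m, m, h, cfg, beats = 1)[seq_len(n), ]
  yt <- m$state0; yc <- m$state0; yr <- h$state0
  v <- numeric(n)
  for (k in seq_len(n)) {
    t <- (k - 1) * 0.1
    v[k] <- yt[["V"]]
    Vm <- yt[["V"]]
    i_cancel <- ionic_current(m, yc, V = Vm)
    i_recip <- ionic_current(h, yr, V = Vm)
    yc <- step_clamped(m, yc, Vm, 0.1)
    for (s in 1:10) yr <- step_clamped(h, yr, Vm, 0.01)
    i_stim <- if (t >= 100 - 0.05 && t < 101 - 0.05) -amp else 0
    yt <- step_free(m, yt, i_applied = i_recip - i_cancel + i_stim, dt = 0.1)
  }
  expect_lt(max(abs(v - rec$v_target)), 1e-9)
})

test_that("apd_comparison handles zero beats and multi-beat records", {
  m <- t60(); h <- human_recipient_model()
  cfg <- ctc_config()
  rec <- run_ctc(m, m, h, cfg, beats = 1)
  ref <- recipient_reference(h, cfg, beats = 1)
  attr(rec, "stim_onsets") <- numeric(0)
  expect_equal(nrow(apd_comparison(rec, ref)), 0)
  rec2 <- run_ctc(m, m, h, cfg, beats = 2)
  ref2 <- recipient_reference(h, cfg, beats = 2)
  tab <- apd_comparison(rec2, ref2)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$apd90_conv)))
})

test_that("CTC records export with all current columns", {
  m <- t60()
  rec <- run_ctc(m, m, human_recipient_model(), ctc_config(), beats = 1)
  f <- tempfile(fileext = ".tsv")
  write_ctc_record(rec, f)
  hdr <- readLines(f, n = 3)
  expect_match(hdr[3], "v_target\ti_cancel\ti_recipient\ti_diff")
  body <- utils::read.table(f, sep = "\t")
  expect_equal(ncol(body), 7)
  expect_equal(nrow(body), nrow(rec))
  unlink(f)
})
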