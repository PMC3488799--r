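# Independent pure-R reference transcriptions of the two cell models, keyed
# in separately from the compiled implementation and used as the
# reference-equivalence oracle: both copies must agree along a paced beat to
# 1e-6 relative. Same numerical scheme (forward Euler for V, exponential
# update for gates), all units ms / mV / pA/pF.

# ---- modified Pandit neonatal mouse -----------------------------------

ref_mouse_rates <- function(V, p) {
  inf <- numeric(13); tau <- numeric(13)
  # m
  dv <- V + 47.13
  am <- if (abs(dv) < 1e-6) 3.2 else 0.32 * dv / (1 - exp(-0.1 * dv))
  tau[1] <- 1.36 / (am + 0.08 * exp(-V / 11))
  inf[1] <- 1 / (1 + exp(-(V + 45) / 6.5))
  # h, j
  inf[2] <- inf[3] <- 1 / (1 + exp((V + 76.1) / 6.07))
  if (V >= -40) {
    tau[2] <- 0.4537 * (1 + exp(-(V + 10.66) / 11.1))
    tau[3] <- 11.63 * (1 + exp(-0.1 * (V + 32))) / exp(-2.535e-7 * V)
  } else {
    tau[2] <- 3.49 / (0.135 * exp(-(V + 80) / 6.8) + 3.56 * exp(0.079 * V) +
                        310000 * exp(0.35 * V))
    tau[3] <- 3.49 / ((V + 37.78) / (1 + exp(0.311 * (V + 79.23))) *
                        (-127140 * exp(0.2444 * V) -
                           3.474e-5 * exp(-0.04391 * V)) +
                        0.1212 * exp(-0.01052 * V) /
                          (1 + exp(-0.1378 * (V + 40.14))))
  }
  # d, f11, f12, cainact
  inf[4] <- 1 / (1 + exp(-(V + 15.3) / 5))
  tau[4] <- 3.05 * exp(-0.0045 * (V + 7)^2) +
    1.05 * exp(-0.002 * (V - 18)^2) + 0.25
  inf[5] <- inf[6] <- 1 / (1 + exp((V + 26.7) / 5.4))
  tau[5] <- 105 * exp(-((V + 45) / 12)^2) + 40 / (1 + exp((-V + 25) / 25)) +
    15 / (1 + exp((V + 75) / 25)) + 1.7
  tau[6] <- 41 * exp(-((V + 47) / 12)^2) + 80 / (1 + exp(-(V + 55) / 5)) +
    15 / (1 + exp((V + 75) / 25)) + 1.7
  inf[7] <- 1 / (1 + p[["Cai"]] / 0.01); tau[7] <- 9
  # r, s, sslow
  inf[8] <- 1 / (1 + exp(-(V + 10.6) / 11.42))
  den <- 45.16 * exp(0.03577 * (V + 50)) + 98.9 * exp(-0.1 * (V + 38))
  tau[8] <- 1000 / den
  inf[9] <- inf[10] <- 1 / (1 + exp((V + 45.3) / 6.8841))
  tau[9] <- 350 * exp(-((V + 70) / 15)^2) + 35
  tau[10] <- 3700 * exp(-((V + 70) / 30)^2) + 35
  # rss, sss
  inf[11] <- 1 / (1 + exp(-(V + 11.5) / 11.82)); tau[11] <- 10000 / den
  inf[12] <- 1 / (1 + exp((V + 87.5) / 10.3)); tau[12] <- 2100
  # y
  inf[13] <- 1 / (1 + exp((V + 138.6) / 10.48))
  tau[13] <- 1000 / (0.11885 * exp((V + 80) / 28.37) +
                       0.56236 * exp(-(V + 80) / 14.19))
  list(inf = inf, tau = tau)
}

ref_mouse_current <- function(V, y, p) {
  RTF <- 8314.5 * 295 / 96487
  ENa <- RTF * log(p[["Nao"]] / p[["Nai"]])
  EK <- RTF * log(p[["Ko"]] / p[["Ki"]])
  ECa <- RTF / 2 * log(p[["Cao"]] / p[["Cai"]])
  iNa <- p[["gNa"]] * y[2]^3 * y[3] * y[4] * (V - ENa)
  iCaL <- p[["gCaL"]] * y[5] *
    ((0.9 + y[8] / 10) * y[6] + (0.1 - y[8] / 10) * y[7]) * (V - 65)
  it <- p[["gt"]] * 0.886 * y[9] * y[10] * (V - EK)
  iKslow <- p[["gKslow"]] * 0.114 * y[9] * y[11] * (V - EK)
  iss <- p[["gss"]] * y[12] * y[13] * (V - EK)
  i_f <- p[["gf"]] * y[14] * (0.2 * (V - ENa) + 0.8 * (V - EK))
  iK1 <- (0.048 / (exp((V + 37) / 25) + exp(-(V + 37) / 25)) + 0.01) *
    0.001 / (1 + exp(-(V - EK - 76.77) / 17)) +
    p[["gK1"]] * (V - EK - 1.73) /
      ((1 + exp(1.613 * (V - EK - 1.73) / RTF)) *
         (1 + exp(-(p[["Ko"]] - 0.9988) / 0.124)))
  iB <- p[["gBNa"]] * (V - ENa) + p[["gBCa"]] * (V - ECa) +
    p[["gBK"]] * (V - EK)
  sig <- (exp(p[["Nao"]] / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) +
                 0.0365 * sig * exp(-V / RTF))
  iNaK <- p[["iNaKmax"]] * fNaK * p[["Ko"]] / (p[["Ko"]] + 1.5) /
    (1 + (10 / p[["Nai"]])^1.5)
  iNaCa <- p[["kNaCa"]] *
    (p[["Nai"]]^3 * p[["Cao"]] * exp(0.03743 * 0.5 * V) -
       p[["Nao"]]^3 * p[["Cai"]] * exp(-0.03743 * 0.5 * V)) /
    (1 + 1e-4 * (p[["Nai"]]^3 * p[["Cao"]] + p[["Nao"]]^3 * p[["Cai"]]))
  iCaP <- p[["iCaPmax"]] * p[["Cai"]] / (p[["Cai"]] + 4e-4)
  (iNa + iCaL + it + iKslow + iss + i_f + iK1 + iB + iNaK + iNaCa + iCaP) *
    1000 / p[["Cm"]]
}

# ---- reduced ten Tusscher-Panfilov human ------------------------------

ref_human_rates <- function(V) {
  inf <- numeric(11); tau <- numeric(11)
  inf[1] <- (1 / (1 + exp((-56.86 - V) / 9.03)))^2
  tau[1] <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  inf[2] <- inf[3] <- (1 / (1 + exp((V + 71.55) / 7.43)))^2
  if (V >= -40) {
    tau[2] <- 0.13 * (1 + exp(-(V + 10.66) / 11.1)) / 0.77
    tau[3] <- (1 + exp(-0.1 * (V + 32))) / (0.6 * exp(0.057 * V))
  } else {
    tau[2] <- 1 / (0.057 * exp(-(V + 80) / 6.8) + 2.7 * exp(0.079 * V) +
                     3.1e5 * exp(0.3485 * V))
    aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    tau[3] <- 1 / (aj + bj)
  }
  inf[4] <- 1 / (1 + exp((-5 - V) / 7.5))
  tau[4] <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  inf[5] <- 1 / (1 + exp((V + 20) / 7))
  tau[5] <- 1125 * exp(-(V + 27)^2 / 240) + 80 +
    165 / (1 + exp((25 - V) / 10))
  inf[6] <- 1 / (1 + exp((20 - V) / 6))
  tau[6] <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  inf[7] <- 1 / (1 + exp((V + 20) / 5))
  tau[7] <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  inf[8] <- 1 / (1 + exp((-26 - V) / 7))
  tau[8] <- (450 / (1 + exp((-45 - V) / 10))) *
    (6 / (1 + exp((V + 30) / 11.5)))
  inf[9] <- 1 / (1 + exp((V + 88) / 24))
  tau[9] <- (3 / (1 + exp((-60 - V) / 20))) *
    (1.12 / (1 + exp((V - 60) / 20)))
  inf[10] <- 1 / (1 + exp((-5 - V) / 14))
  tau[10] <- (1100 / sqrt(1 + exp((-10 - V) / 6))) *
    (1 / (1 + exp((V - 60) / 20)))
  list(inf = inf, tau = tau)
}

ref_human_fca_inf <- function(cai) {
  (1 / (1 + (cai / 0.000325)^8) + 0.1 / (1 + exp((cai - 0.0005) / 1e-4)) +
     0.2 / (1 + exp((cai - 0.00075) / 8e-4)) + 0.23) / 1.46
}

ref_human_current <- function(V, y, p) {
  FF <- 96485.3415
  RTF <- 8314.472 * 310 / FF
  ENa <- RTF * log(p[["Nao"]] / p[["Nai"]])
  EK <- RTF * log(p[["Ko"]] / p[["Ki"]])
  ECa <- RTF / 2 * log(p[["Cao"]] / p[["Cai"]])
  EKs <- RTF * log((p[["Ko"]] + 0.03 * p[["Nao"]]) /
                     (p[["Ki"]] + 0.03 * p[["Nai"]]))
  iNa <- p[["gNa"]] * y[2]^3 * y[3] * y[4] * (V - ENa)
  z <- 2 * V / RTF
  galv <- if (abs(z) < 1e-5) 2 * FF * (0.25 * p[["CaLdrive"]] - p[["Cao"]])
  else 4 * V * FF / RTF * (0.25 * p[["CaLdrive"]] * exp(z) - p[["Cao"]]) /
    (exp(z) - 1)
  iCaL <- p[["gCaL"]] * y[5] * y[6] * y[7] * galv
  ito <- p[["gto"]] * y[8] * y[9] * (V - EK)
  sq <- sqrt(p[["Ko"]] / 5.4)
  iKr <- p[["gKr"]] * sq * y[10] * y[11] * (V - EK)
  iKs <- p[["gKs"]] * y[12]^2 * (V - EKs)
  vk <- V - EK
  a1 <- 0.1 / (1 + exp(0.06 * (vk - 200)))
  b1 <- (3 * exp(2e-4 * (vk + 100)) + exp(0.1 * (vk - 10))) /
    (1 + exp(-0.5 * vk))
  iK1 <- p[["gK1"]] * a1 / (a1 + b1) * sq * vk
  e1 <- exp(0.35 * V / RTF); e2 <- exp(-0.65 * V / RTF)
  iNaCa <- p[["kNaCa"]] *
    (e1 * p[["Nai"]]^3 * p[["Cao"]] - e2 * p[["Nao"]]^3 * p[["Cai"]] * 2.5) /
    ((87.5^3 + p[["Nao"]]^3) * (1.38 + p[["Cao"]]) * (1 + 0.1 * e2))
  iNaK <- p[["pNaK"]] * p[["Ko"]] * p[["Nai"]] /
    ((p[["Ko"]] + 1) * (p[["Nai"]] + 40) *
       (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)))
  ipCa <- p[["gpCa"]] * p[["Cai"]] / (5e-4 + p[["Cai"]])
  ipK <- p[["gpK"]] * vk / (1 + exp((25 - V) / 5.98))
  ibNa <- p[["gbNa"]] * (V - ENa)
  ibCa <- p[["gbCa"]] * (V - ECa)
  iNa + iCaL + ito + iKr + iKs + iK1 + iNaCa + iNaK + ipCa + ipK + ibNa + ibCa
}

# ---- shared integrator -------------------------------------------------

# one step: forward Euler on V, exponential update on gates
ref_step <- function(kind, y, p, dt, i_app = 0, clamp_V = NULL) {
  V <- y[1]
  if (kind == "mouse") {
    itot <- ref_mouse_current(V, y, p)
    rt <- ref_mouse_rates(V, p)
    y[2:14] <- rt$inf + (y[2:14] - rt$inf) * exp(-dt / rt$tau)
  } else {
    itot <- ref_human_current(V, y, p)
    rt <- ref_human_rates(V)
    idx <- c(2:6, 8:12)
    y[idx] <- rt$inf[1:10] + (y[idx] - rt$inf[1:10]) * exp(-dt / rt$tau[1:10])
    finf <- ref_human_fca_inf(p[["Cai"]])
    if (!(finf > y[7] && V > -60))
      y[7] <- finf + (y[7] - finf) * exp(-dt / 2)
  }
  y[1] <- if (is.null(clamp_V)) V - dt * (itot + i_app) else clamp_V
  y
}

# paced free-running reference simulation; mirrors the sampling convention
# of the compiled integrator (V recorded at t = 0, dt, ..., n*dt)
ref_simulate <- function(kind, y0, p, dt, n_steps, stim_onset, stim_dur,
                         stim_amp) {
  v <- numeric(n_steps + 1)
  y <- as.numeric(y0)
  v[1] <- y[1]
  for (k in 0:(n_steps - 1)) {
    t <- k * dt
    on <- t >= stim_onset - 0.5 * dt & t < stim_onset + stim_dur - 0.5 * dt
    y <- ref_step(kind, y, p, dt, i_app = if (any(on)) -stim_amp else 0)
    v[k + 2] <- y[1]
  }
  v
}
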