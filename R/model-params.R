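# Parameter sets, state layouts and stored resting states for the two
# built-in cell models. Orders must match src/ctcfit.cpp.

# -- modified Pandit neonatal mouse ventricular model -----------------------

.mouse_state_names <- c(
  "V", "m", "h", "j", "d", "f11", "f12", "cainact",
  "r", "s", "sslow", "rss", "sss", "y"
)

.mouse_current_names <- c(
  "iNa", "iCaL", "it", "iKslow", "iss", "if", "iK1",
  "iBNa", "iBCa", "iBK", "iNaK", "iNaCa", "iCaP", "total"
)

# Conductances in uS, pump scales in nA, concentrations in mM, Cm in pF.
# g_Na = 0.8 uS; intracellular concentrations fixed (the real-time variant
# of the model holds them at their default values, so the SR/Ca-handling
# subsystem drops out and the Ca-dependent L-type inactivation gate relaxes
# to a constant).
.mouse_baseline_params <- c(
  gNa = 0.8, gCaL = 0.015, gt = 0.00875, gKslow = 0.00875, gss = 0.007,
  gK1 = 0.024, gf = 0.00145,
  gBNa = 8.015e-5, gBCa = 3.24e-5, gBK = 13.8e-5,
  iNaKmax = 0.08, kNaCa = 0.9984e-5, iCaPmax = 0.004,
  Ko = 5.4, Nao = 140, Cao = 1.2, Nai = 8.6, Ki = 142, Cai = 7.9e-5,
  Cm = 100
)

# Resting steady state of the baseline parameter set: obtained by relaxing
# the unstimulated system for 120 s at dt = 0.1 ms and frozen here
# (V drift over a further 1 s is zero to double precision).
.mouse_resting_state <- c(
  V = -80.39768815, m = 0.004295860942, h = 0.6699637505, j = 0.6699637505,
  d = 2.216591624e-06, f11 = 0.9999519882, f12 = 0.9999519882,
  cainact = 0.9921619208, r = 0.002211475038, s = 0.9939303723,
  sslow = 0.9939303723, rss = 0.002932662405, sss = 0.3341343335,
  y = 0.003858327418
)

# -- reduced ten Tusscher-Panfilov human ventricular model ------------------

.human_state_names <- c(
  "V", "m", "h", "j", "d", "f", "fca", "r", "s", "xr1", "xr2", "xs"
)

.human_current_names <- c(
  "iNa", "iCaL", "ito", "iKr", "iKs", "iK1", "iNaCa", "iNaK",
  "ipCa", "ipK", "ibNa", "ibCa", "total"
)

# Conductances in nS/pF (currents already capacitance-normalized);
# concentrations mM, fixed at diastolic values (the model reduction).
.human_baseline_params <- c(
  gNa = 14.838, gCaL = 3.06e-5, gto = 0.294, gKr = 0.153, gKs = 0.392,
  gK1 = 5.405, kNaCa = 1000, pNaK = 2.724, gpCa = 0.1238, gpK = 0.0146,
  gbNa = 0.00029, gbCa = 0.000592,
  Ko = 5.4, Nao = 140, Cao = 2, Nai = 11.6, Ki = 138.3, Cai = 2e-4,
  Cm = 115, CaLdrive = 0.09
)

# Settled for 120 s at dt = 0.01 ms, as above.
.human_resting_state <- c(
  V = -84.97872633, m = 0.001809360373, h = 0.7379551858, j = 0.7379551858,
  d = 2.337476462e-05, f = 0.9999069867, fca = 0.9850595237,
  r = 2.519917922e-08, s = 0.99999773, xr1 = 0.000219150575,
  xr2 = 0.4685698954, xs = 0.00329264448
)
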