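#' Construct the modified Pandit neonatal-mouse ventricular model
#'
#' Builds the target-canceling cell model: the Pandit rat left-ventricular
#' formulation adapted to the neonatal mouse as used in cell-type
#' transforming clamp work, with the sodium conductance at 0.8 uS, fixed
#' intracellular ion concentrations, and the transient outward current split
#' into a fast component (`gt`) and a slowly inactivating component
#' (`gKslow`) so that the six conductances tuned by the genetic algorithm
#' exist as independent knobs.
#'
#' @param genotype Optional named numeric of six fractional conductance
#'   changes (`gNa`, `gss`, `gKslow`, `gCaL`, `gK1`, `gt`), each applied
#'   multiplicatively as `(1 + s)` to the starting-point conductances. Must
#'   lie within [ga_bounds()]. `NULL` means no change.
#' @param apd80 Optional APD80 label (ms). When given, the `gss`/`gKslow`
#'   pair calibrated for that template label replaces the baseline values
#'   before the genotype is applied (see [calibrate_template()]).
#' @param params Optional full parameter vector overriding the baseline
#'   (advanced use; must keep the baseline's names and order).
#'
#' @return A `cell_model` object: list with elements `kind`, `params`,
#'   `state0`, `capacitance_pF`, `dt_default` (0.1 ms).
#' @seealso [human_recipient_model()], [simulate_paced()]
#' @export
neonatal_mouse_model <- function(genotype = NULL, apd80 = NULL,
                                 params = NULL) {
  p <- if (is.null(params)) .mouse_baseline_params else {
    stopifnot(identical(names(params), names(.mouse_baseline_params)))
    params
  }
  state0 <- .mouse_resting_state
  if (!is.null(apd80)) {
    cal <- calibrate_template(apd80)
    p[["gss"]] <- cal[["gss"]]
    p[["gKslow"]] <- cal[["gKslow"]]
    state0 <- attr(cal, "resting_state")
  }
  if (!is.null(genotype)) {
    genotype <- validate_genotype(genotype)
    for (g in names(genotype)) p[[g]] <- p[[g]] * (1 + genotype[[g]])
  }
  validate_parameter_set(p)
  structure(
    list(
      kind = "mouse", kind_id = 0L, name = "neonatal mouse (modified Pandit)",
      params = p, state0 = state0,
      state_names = .mouse_state_names,
      current_names = .mouse_current_names,
      capacitance_pF = unname(p[["Cm"]]), dt_default = 0.1,
      genotype = genotype
    ),
    class = "cell_model"
  )
}

#' Construct the reduced ten Tusscher-Panfilov human recipient model
#'
#' The human ventricular myocyte model (epicardial variant) in its reduced
#' form: intracellular ion concentrations are held at diastolic values so
#' the calcium-handling subsystem drops out, leaving twelve state variables.
#' Used as the recipient whose membrane dynamics the clamped cell should
#' express.
#'
#' @return A `cell_model` object with `dt_default` = 0.01 ms.
#' @export
human_recipient_model <- function() {
  structure(
    list(
      kind = "human", kind_id = 1L,
      name = "human ventricular (reduced ten Tusscher-Panfilov)",
      params = .human_baseline_params, state0 = .human_resting_state,
      state_names = .human_state_names,
      current_names = .human_current_names,
      capacitance_pF = unname(.human_baseline_params[["Cm"]]),
      dt_default = 0.01,
      genotype = NULL
    ),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>", x$name, "\n")
  cat("  states:", length(x$state0), " dt_default:", x$dt_default, "ms",
      " Cm:", x$capacitance_pF, "pF\n")
  if (!is.null(x$genotype)) {
    cat("  genotype (fractional change):\n")
    print(round(x$genotype, 4))
  }
  invisible(x)
}

validate_parameter_set <- function(p) {
  cond <- grepl("^g|max$", names(p))
  if (any(p[cond] < 0)) stop("conductances must be >= 0")
  conc <- c("Ko", "Nao", "Cao", "Nai", "Ki", "Cai")
  if (any(p[conc] <= 0)) stop("ionic concentrations must be > 0")
  if (p[["Cm"]] <= 0) stop("capacitance must be > 0")
  invisible(p)
}

validate_state <- function(model, state) {
  stopifnot(length(state) == length(model$state0))
  if (!all(is.finite(state))) stop("state contains non-finite entries")
  invisible(state)
}

#' Total ionic membrane current at an imposed voltage
#'
#' Sum of all sarcolemmal currents of the model, evaluated at voltage `V`
#' and the supplied gating state, capacitance-normalized (pA/pF) and
#' outward-positive.
#'
#' @param model A [`cell_model`][neonatal_mouse_model].
#' @param state State vector (defaults to the model's stored resting state).
#' @param V Membrane potential (mV). Defaults to the state's own voltage.
#' @param components If `TRUE`, return the named per-current decomposition
#'   (including `total`) instead of the scalar total.
#' @return Scalar total current (pA/pF), or a named vector of components.
#' @export
ionic_current <- function(model, state = model$state0, V = state[[1]],
                          components = FALSE) {
  validate_state(model, state)
  out <- cpp_currents(model$kind_id, as.numeric(state), model$params, V)
  names(out) <- model$current_names
  if (components) out else unname(out[["total"]])
}

#' Advance a model one step with the voltage clamped
#'
#' Gating variables advance one integration step with V held at the supplied
#' value; the returned state's voltage equals that value. This is the mode in
#' which the CTC drives its canceling and recipient models.
#'
#' @inheritParams ionic_current
#' @param dt Integration step (ms).
#' @return The advanced state vector.
#' @export
step_clamped <- function(model, state, V, dt = model$dt_default) {
  stopifnot(dt > 0)
  validate_state(model, state)
  out <- cpp_step_clamped(model$kind_id, as.numeric(state), model$params,
                          V, dt)
  names(out) <- model$state_names
  out
}

#' Advance a model one free-running step with an applied current
#'
#' One step of the full system under `dV/dt = -(i_ion + i_applied)`;
#' `i_applied` is capacitance-normalized and outward-positive, so a
#' depolarizing stimulus is negative.
#'
#' @inheritParams step_clamped
#' @param i_applied Applied current (pA/pF, outward-positive).
#' @return The advanced state vector.
#' @export
step_free <- function(model, state, i_applied = 0, dt = model$dt_default) {
  stopifnot(dt > 0)
  validate_state(model, state)
  out <- cpp_step_free(model$kind_id, as.numeric(state), model$params,
                       i_applied, dt)
  names(out) <- model$state_names
  out
}

#' Stimulus protocol for paced simulations
#'
#' @param period_ms Pacing period (ms); 1000 gives the 1 Hz pacing used
#'   throughout.
#' @param duration_ms Pulse duration (ms).
#' @param amplitude Depolarizing pulse amplitude (pA/pF, positive). `NULL`
#'   defers to the model-specific default: 1.5 x the model's diastolic
#'   threshold, computed once and cached (the experimental 0.9 nA value is
#'   cell-specific and not transferable to the models).
#' @param onset_ms First-pulse onset time (ms).
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(period_ms = 1000, duration_ms = 1,
                              amplitude = NULL, onset_ms = 100) {
  stopifnot(period_ms > duration_ms, duration_ms > 0,
            is.null(amplitude) || amplitude > 0, onset_ms >= 0)
  structure(list(period_ms = period_ms, duration_ms = duration_ms,
                 amplitude = amplitude, onset_ms = onset_ms),
            class = "stimulus_protocol")
}

#' Integration settings
#'
#' @param dt Integration step (ms). `NULL` uses the model default
#'   (0.1 ms mouse, 0.01 ms recipient).
#' @param beats Number of paced beats to simulate.
#' @param fast_exp Use the Schraudolph-style fast exponential approximation
#'   (opt-in; correctness tests run exact).
#' @return A `sim_settings` list.
#' @export
sim_settings <- function(dt = NULL, beats = 1, fast_exp = FALSE) {
  stopifnot(is.null(dt) || dt > 0, beats >= 1)
  structure(list(dt = dt, beats = as.integer(beats), fast_exp = fast_exp),
            class = "sim_settings")
}

.ctcfit_cache <- new.env(parent = emptyenv())

#' Diastolic threshold and default stimulus amplitude of a model
#'
#' The diastolic threshold is the smallest 1-ms pulse amplitude that elicits
#' a regenerative action potential (peak V > 0 mV) from the stored resting
#' state, found by bisection to 1 pA/pF. The default pacing amplitude is
#' 1.5 x this threshold, cached per model kind.
#'
#' @inheritParams ionic_current
#' @return Threshold (pA/pF), or for `default_stim_amplitude` the cached
#'   1.5 x threshold of the model kind's baseline.
#' @export
stimulus_threshold <- function(model) {
  lo <- 0; hi <- 20
  fires <- function(amp) {
    sim <- cpp_simulate(model$kind_id, model$state0, model$params,
                        model$dt_default, round(60 / model$dt_default),
                        10, 1, amp, FALSE)
    max(sim$v) > 0
  }
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 2000) stop("no threshold found below 2000 pA/pF")
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' @rdname stimulus_threshold
#' @export
default_stim_amplitude <- function(model) {
  key <- paste0("stim_amp_", model$kind)
  if (is.null(.ctcfit_cache[[key]])) {
    base <- if (model$kind == "mouse") neonatal_mouse_model()
            else human_recipient_model()
    .ctcfit_cache[[key]] <- 1.5 * stimulus_threshold(base)
  }
  .ctcfit_cache[[key]]
}

#' Free-running paced simulation
#'
#' Simulates the model from its stored initial state (optionally another
#' state) under the pacing protocol, and returns the voltage trace with
#' stimulus onsets annotated.
#'
#' @inheritParams ionic_current
#' @param protocol A [stimulus_protocol()].
#' @param settings A [sim_settings()].
#' @param state Initial state (defaults to the model's stored resting state).
#' @return A [voltage_trace()].
#' @export
simulate_paced <- function(model, protocol = stimulus_protocol(),
                           settings = sim_settings(), state = model$state0) {
  dt <- if (is.null(settings$dt)) model$dt_default else settings$dt
  amp <- if (is.null(protocol$amplitude)) default_stim_amplitude(model)
         else protocol$amplitude
  onsets <- protocol$onset_ms + protocol$period_ms * (seq_len(settings$beats) - 1)
  n_steps <- round(settings$beats * protocol$period_ms / dt)
  old <- cpp_get_fast_exp(); cpp_set_fast_exp(settings$fast_exp)
  on.exit(cpp_set_fast_exp(old))
  sim <- cpp_simulate(model$kind_id, as.numeric(state), model$params, dt,
                      n_steps, onsets, protocol$duration_ms, amp, FALSE)
  voltage_trace(sim$v, dt = dt, t0 = 0, stim_onsets = onsets)
}

# settle a model to its unstimulated steady state (used to freeze stored
# resting states and by the template calibrator)
settle_model <- function(model, duration_ms = 60000, dt = NULL,
                         state = model$state0) {
  dt <- if (is.null(dt)) model$dt_default else dt
  sim <- cpp_simulate(model$kind_id, as.numeric(state), model$params, dt,
                      round(duration_ms / dt), numeric(0), 1, 0, FALSE)
  st <- sim$final_state
  names(st) <- model$state_names
  st
}
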