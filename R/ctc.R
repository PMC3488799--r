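# In silico cell-type transforming clamp: the six-step closed loop in which
# a (simulated) target myocyte is coupled to a target-canceling model and a
# recipient model. Per loop cycle: (1) the target voltage is measured and
# corrected for the liquid junction potential; (2) both models are advanced
# clamped at that voltage; (3-4) their capacitance-normalized total currents
# are differenced (the capacitance ratios K_c and K_r cancel exactly in
# normalized units); (5) stimulus and seal-leak compensation are added; and
# (6) the resulting current is injected into the free-running target.

#' CTC loop configuration
#'
#' @param c_target_pF Target-cell capacitance (pF). `NULL` uses the target
#'   model's own capacitance.
#' @param r_seal_GOhm Patch seal resistance (GOhm); `Inf` (default) disables
#'   the seal leak and its compensation, the in silico ideal.
#' @param ljp_mV Liquid-junction-potential correction added to the measured
#'   voltage (0 in silico; -3 in the experiments).
#' @param loop_dt Loop (and mouse-model) step (ms).
#' @param sub_steps Recipient sub-steps per loop step (the recipient
#'   integrates at `loop_dt / sub_steps`, default 0.01 ms).
#' @param protocol Pacing [stimulus_protocol()] delivered through the
#'   injection path. A `NULL` amplitude uses 1.5 x the larger of the target
#'   and recipient diastolic thresholds.
#' @return A `ctc_config` list.
#' @export
ctc_config <- function(c_target_pF = NULL, r_seal_GOhm = Inf, ljp_mV = 0,
                       loop_dt = 0.1, sub_steps = 10L,
                       protocol = stimulus_protocol()) {
  stopifnot(loop_dt > 0, sub_steps >= 1,
            is.infinite(r_seal_GOhm) || r_seal_GOhm > 0)
  structure(list(c_target_pF = c_target_pF, r_seal_GOhm = r_seal_GOhm,
                 ljp_mV = ljp_mV, loop_dt = loop_dt,
                 sub_steps = as.integer(sub_steps), protocol = protocol),
            class = "ctc_config")
}

#' Ohmic seal-leak current
#'
#' Current through the imperfect pipette-membrane seal toward bath ground
#' (0 mV): `V / R_seal`, in pA (mV / GOhm). In the CTC a compensation of
#' opposite sign is added to the injected current.
#'
#' @param V Membrane potential (mV).
#' @param r_seal_GOhm Seal resistance (GOhm); `Inf` gives 0.
#' @return Leak current (pA, outward-positive).
#' @export
seal_leak <- function(V, r_seal_GOhm) {
  stopifnot(is.infinite(r_seal_GOhm) || r_seal_GOhm > 0)
  if (is.infinite(r_seal_GOhm)) return(0 * V)
  V / r_seal_GOhm
}

#' Run the in silico cell-type transforming clamp
#'
#' @param target `cell_model` standing in for the patched myocyte.
#' @param canceling `cell_model` whose current is subtracted (the
#'   target-canceling model).
#' @param recipient `cell_model` whose dynamics the target should express.
#' @param cfg A [ctc_config()].
#' @param beats Number of paced beats.
#' @return A `ctc_record` data frame with columns `time_ms`, `v_target`,
#'   `i_cancel`, `i_recipient`, `i_diff`, `i_seal`, `i_inject` (currents in
#'   pA/pF, outward-positive), with the configuration, sampling interval and
#'   stimulus onsets as attributes.
#' @export
run_ctc <- function(target, canceling, recipient, cfg = ctc_config(),
                    beats = 1) {
  stopifnot(inherits(target, "cell_model"),
            inherits(canceling, "cell_model"),
            inherits(recipient, "cell_model"))
  proto <- cfg$protocol
  amp <- proto$amplitude
  if (is.null(amp))
    amp <- 1.5 * max(stimulus_threshold(target), stimulus_threshold(recipient))
  onsets <- proto$onset_ms + proto$period_ms * (seq_len(beats) - 1)
  n_steps <- round(beats * proto$period_ms / cfg$loop_dt)
  c_target <- if (is.null(cfg$c_target_pF)) target$capacitance_pF
              else cfg$c_target_pF
  rec <- cpp_run_ctc(
    target$kind_id, as.numeric(target$state0), target$params,
    canceling$kind_id, as.numeric(canceling$state0), canceling$params,
    recipient$kind_id, as.numeric(recipient$state0), recipient$params,
    cfg$loop_dt, cfg$sub_steps, n_steps,
    onsets, proto$duration_ms, amp,
    cfg$r_seal_GOhm, c_target, cfg$ljp_mV)
  out <- as.data.frame(rec)
  names(out) <- c("time_ms", "v_target", "i_cancel", "i_recipient",
                  "i_diff", "i_seal", "i_inject")
  attr(out, "dt") <- cfg$loop_dt
  attr(out, "stim_onsets") <- onsets
  attr(out, "stim_amplitude") <- amp
  attr(out, "config") <- cfg
  class(out) <- c("ctc_record", "data.frame")
  out
}

#' Converted-AP voltage trace of a CTC record
#'
#' @param record A [run_ctc()] result.
#' @return A [voltage_trace()] of the target voltage with the pacing onsets
#'   annotated.
#' @export
ctc_trace <- function(record) {
  voltage_trace(record$v_target, dt = attr(record, "dt"),
                t0 = record$time_ms[1],
                stim_onsets = attr(record, "stim_onsets"))
}

#' Free-running recipient reference AP
#'
#' The recipient model paced on its own (CTC off), used as the reference the
#' converted AP should reproduce. The same pacing schedule and amplitude as
#' the CTC run are applied.
#'
#' @inheritParams run_ctc
#' @return A [voltage_trace()].
#' @export
recipient_reference <- function(recipient, cfg = ctc_config(), beats = 1) {
  proto <- cfg$protocol
  amp <- proto$amplitude
  if (is.null(amp)) amp <- 1.5 * stimulus_threshold(recipient)
  simulate_paced(recipient,
                 protocol = stimulus_protocol(proto$period_ms,
                                              proto$duration_ms, amp,
                                              proto$onset_ms),
                 settings = sim_settings(beats = beats))
}

#' Per-beat APD comparison of converted vs recipient APs
#'
#' Amplitude-definition APDs (30, 50, 90% repolarization) per beat for the
#' CTC-converted trace and for the free-running recipient reference.
#' Undefined APDs (no crossing) propagate as `NA`.
#'
#' @param record A [run_ctc()] result.
#' @param reference A [recipient_reference()] trace.
#' @return Data frame with one row per beat and columns `beat`,
#'   `apd30_conv`, `apd50_conv`, `apd90_conv`, `apd30_ref`, `apd50_ref`,
#'   `apd90_ref`.
#' @export
apd_comparison <- function(record, reference) {
  conv <- ctc_trace(record)
  n_beats <- length(attr(record, "stim_onsets"))
  if (n_beats == 0)
    return(data.frame(beat = integer(0), apd30_conv = numeric(0),
                      apd50_conv = numeric(0), apd90_conv = numeric(0),
                      apd30_ref = numeric(0), apd50_ref = numeric(0),
                      apd90_ref = numeric(0)))
  safe_apd <- function(tr, lev, b) {
    tryCatch(apd_amplitude(tr, lev, which = b), error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(n_beats), function(b) {
    data.frame(beat = b,
               apd30_conv = safe_apd(conv, 30, b),
               apd50_conv = safe_apd(conv, 50, b),
               apd90_conv = safe_apd(conv, 90, b),
               apd30_ref = safe_apd(reference, 30, b),
               apd50_ref = safe_apd(reference, 50, b),
               apd90_ref = safe_apd(reference, 90, b))
  })
  do.call(rbind, rows)
}

#' Plot a CTC record (converted AP and circuit currents)
#'
#' Four stacked panels: target/converted AP, target-canceling model current,
#' recipient model current, and the difference current, optionally with the
#' free-running recipient reference overlaid on the voltage panel.
#'
#' @param record A [run_ctc()] result.
#' @param reference Optional [recipient_reference()] trace.
#' @export
plot_ctc_record <- function(record, reference = NULL) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  t <- record$time_ms
  graphics::plot(t, record$v_target, type = "l", ylab = "V (mV)", xlab = "")
  if (!is.null(reference))
    graphics::lines(trace_times(reference), reference$v, lty = 2,
                    col = "red")
  graphics::plot(t, record$i_cancel, type = "l",
                 ylab = "I_cancel (pA/pF)", xlab = "")
  graphics::plot(t, record$i_recipient, type = "l",
                 ylab = "I_recipient (pA/pF)", xlab = "")
  graphics::plot(t, record$i_diff, type = "l",
                 ylab = "I_diff (pA/pF)", xlab = "time (ms)")
  invisible(record)
}

#' Export a CTC record as delimited text
#'
#' Tab-separated columns `time_ms, v_target, i_cancel, i_recipient, i_diff,
#' i_seal, i_inject` under a comment header with the loop step and stimulus
#' onsets.
#'
#' @param record A [run_ctc()] result.
#' @param path Output file.
#' @export
write_ctc_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dt_ms=%.17g", attr(record, "dt")),
    paste0("# stim_onsets_ms=",
           paste(sprintf("%.17g", attr(record, "stim_onsets")),
                 collapse = ",")),
    paste0("# ", paste(names(record), collapse = "\t"))
  ), con)
  utils::write.table(record, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
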