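# Synthetic "recorded myocyte" generator: emulates a patch-clamp recording
# of ten consecutive 1 Hz-paced APs with beat-to-beat variability, so the
# fitting and CTC pipelines are testable without experimental data.

#' Pseudo-cell noise settings
#'
#' Beat-to-beat variability is modelled as per-beat lognormal multiplicative
#' jitter on the six key conductances (unit mean, coefficient of variation
#' `jitter_cv`) plus additive Gaussian observation noise on the voltage
#' samples. The defaults (3% jitter, 0.5 mV) are package defaults chosen to
#' visually match the spread of recorded beats, not measured ground truth.
#'
#' @param jitter_cv Per-beat conductance jitter CV (fraction).
#' @param v_noise_sd_mV Additive voltage noise SD (mV).
#' @return A `pseudo_noise` list.
#' @export
pseudo_noise <- function(jitter_cv = 0.03, v_noise_sd_mV = 0.5) {
  stopifnot(jitter_cv >= 0, v_noise_sd_mV >= 0)
  structure(list(jitter_cv = jitter_cv, v_noise_sd_mV = v_noise_sd_mV),
            class = "pseudo_noise")
}

#' Generate a pseudo cell
#'
#' Draws a hidden true genotype (uniform within the GA bounds unless given),
#' simulates `n_beats` paced beats -- each with fresh conductance jitter and
#' observation noise -- and averages them into the fitting objective, the in
#' silico counterpart of averaging ten consecutive recorded APs.
#'
#' Because the generator emulates the recorded myocyte population (whose
#' APD80 values span the 40-120 ms template range), uniform draws are
#' rejection-sampled until the noiseless AP of the candidate genotype has a
#' measurable APD80 inside `apd80_range`; unrestricted corners of the
#' search box produce non-physiological cells (including ones that never
#' repolarize) that no recording resembles. Pass an explicit `genotype` to
#' bypass the restriction.
#'
#' Beats are simulated independently from the model's resting state (given
#' the jitter they are i.i.d.); rate-dependent beat-to-beat memory is not
#' emulated.
#'
#' @param seed RNG seed (the generator is deterministic given the seed).
#' @param noise A [pseudo_noise()].
#' @param genotype Optional true genotype (checked against [ga_bounds()]).
#' @param n_beats Number of beats recorded and averaged.
#' @param context A [ga_context()] supplying the starting-point model.
#' @param apd80_range Acceptance window (ms) for the hidden genotype's
#'   noiseless APD80 (mouse definition).
#' @return A `pseudo_cell`: list with `genotype`, `beats` (list of
#'   [voltage_trace()]), `objective` (their average), `noise_floor_ssd`
#'   (median SSD between individual beats and the average; `0` when
#'   noiseless), `noise`, `seed`.
#' @export
generate_pseudo_cell <- function(seed, noise = pseudo_noise(),
                                 genotype = NULL, n_beats = 10,
                                 context = ga_context(),
                                 apd80_range = c(40, 120)) {
  set.seed(seed)
  bounds <- ga_bounds()
  if (is.null(genotype)) {
    for (try in 1:200) {
      genotype <- stats::runif(6, bounds$lower, bounds$upper)
      names(genotype) <- .ga_gene_names
      apd <- tryCatch({
        tr <- .ga_phenotype(genotype, context$base_params,
                            context$base_state, context$stim_amp)
        apd_mouse80(tr)
      }, error = function(e) NA_real_)
      if (!is.na(apd) && apd >= apd80_range[1] && apd <= apd80_range[2])
        break
      genotype <- NULL
    }
    if (is.null(genotype))
      stop("could not sample a genotype with APD80 in the requested range")
  } else {
    genotype <- validate_genotype(genotype)
  }
  p_true <- context$base_params
  for (g in .ga_gene_names) p_true[[g]] <- p_true[[g]] * (1 + genotype[[g]])
  sdlog <- sqrt(log(1 + noise$jitter_cv^2))
  beats <- lapply(seq_len(n_beats), function(b) {
    p <- p_true
    if (noise$jitter_cv > 0) {
      jit <- stats::rlnorm(6, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      p[.ga_gene_names] <- p[.ga_gene_names] * jit
    }
    sim <- cpp_simulate(0L, context$base_state, p, 0.1, 10000L, 100, 1,
                        context$stim_amp, FALSE)
    v <- sim$v
    if (noise$v_noise_sd_mV > 0)
      v <- v + stats::rnorm(length(v), sd = noise$v_noise_sd_mV)
    voltage_trace(v, dt = 0.1, t0 = 0, stim_onsets = 100)
  })
  objective <- average_aps(beats)
  floor_ssd <- stats::median(vapply(
    beats, function(b) tryCatch(ssd(b, objective), error = function(e) NA_real_),
    numeric(1)), na.rm = TRUE)
  structure(list(genotype = genotype, beats = beats, objective = objective,
                 noise_floor_ssd = floor_ssd, noise = noise, seed = seed),
            class = "pseudo_cell")
}

#' @export
print.pseudo_cell <- function(x, ...) {
  cat("<pseudo_cell> seed", x$seed, "-", length(x$beats), "beats,",
      sprintf("jitter CV %.1f%%, noise %.2f mV\n",
              100 * x$noise$jitter_cv, x$noise$v_noise_sd_mV))
  cat("  noise-floor SSD:", signif(x$noise_floor_ssd, 4), "mV^2\n")
  invisible(x)
}

#' GA recovery experiment on seeded pseudo cells
#'
#' For each pseudo cell, fits the GA to the averaged objective and reports
#' the final best SSD next to the cell's beat-to-beat noise-floor SSD (the
#' median SSD between individual beats and their average) and the APD80
#' mismatch of fit vs objective. A fit "within the naturally occurring
#' beat-to-beat variability" has final SSD at or below the noise floor.
#'
#' @param n_cells Number of pseudo cells.
#' @param cfg A [ga_config()] (its `seed` is overridden per cell).
#' @param seeds Integer vector of per-cell seeds (length `n_cells`).
#' @param noise A [pseudo_noise()].
#' @param context A [ga_context()].
#' @return Data frame with one row per cell: `seed`, `final_ssd`,
#'   `gen1_best_ssd`, `noise_floor_ssd`, `apd80_objective`, `apd80_fit`,
#'   `apd80_error`.
#' @export
recovery_experiment <- function(n_cells, cfg = ga_config(),
                                seeds = seq_len(n_cells),
                                noise = pseudo_noise(),
                                context = ga_context()) {
  stopifnot(n_cells >= 1, length(seeds) == n_cells)
  rows <- lapply(seq_len(n_cells), function(i) {
    cell <- generate_pseudo_cell(seeds[i], noise = noise, context = context)
    cfg$seed <- seeds[i] + 10000L
    fit <- fit_cell(cell$objective, cfg, context)
    apd_obj <- tryCatch(apd_mouse80(cell$objective), error = function(e) NA_real_)
    apd_fit <- if (!is.null(fit$best$phenotype))
      tryCatch(apd_mouse80(fit$best$phenotype), error = function(e) NA_real_)
      else NA_real_
    data.frame(seed = seeds[i],
               final_ssd = fit$best$error,
               gen1_best_ssd = fit$best_errors[1],
               noise_floor_ssd = cell$noise_floor_ssd,
               apd80_objective = apd_obj,
               apd80_fit = apd_fit,
               apd80_error = apd_fit - apd_obj)
  })
  do.call(rbind, rows)
}
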