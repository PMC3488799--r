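# Workbench: JSON run configuration, logging, and the command-line entry
# point tying the pipeline together (subcommands: fit, ctc, template,
# pseudo, validate).

.runconfig_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    ga = list(pop_size = 40L, generations = 15L, p_crossover = 0.9,
              eta_crossover = 10, p_swap = 0.5, p_mutation = 0.1,
              eta_mutation = 20, elitism = TRUE),
    ctc = list(scenario = "ideal", r_seal_GOhm = Inf, ljp_mV = 0,
               loop_dt = 0.1, sub_steps = 10L, beats = 1L,
               target_apd80 = 60, canceling_apd80 = 60),
    pseudo = list(jitter_cv = 0.03, v_noise_sd_mV = 0.5, n_beats = 10L),
    sim = list(fast_exp = FALSE)
  )
}

#' Read a JSON run configuration
#'
#' Unknown keys are rejected; missing keys take the package defaults (the
#' published GA and CTC settings).
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .runconfig_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (k in names(user)) {
      if (is.list(cfg[[k]])) {
        badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(badk))
          stop("unknown config keys in '", k, "': ",
               paste(badk, collapse = ", "))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  # validation via the constructors
  do.call(ga_config, c(cfg$ga, list(seed = cfg$seed)))
  stopifnot(cfg$ctc$scenario %in% c("ideal", "mismatch", "template"))
  pseudo_noise(cfg$pseudo$jitter_cv, cfg$pseudo$v_noise_sd_mV)
  structure(cfg, class = "run_config")
}

.write_run_log <- function(cfg, out_dir, extra = list()) {
  canon <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(canon, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  info <- c(list(
    package = "ctcfit",
    version = as.character(utils::packageVersion("ctcfit")),
    seed = cfg$seed,
    config_md5 = hash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg)
  ), extra)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Fit a cell-specific model from the command line
#'
#' Reads an objective AP trace, runs the GA, and writes `genotype.json`
#' (best individual), `ga_errors.tsv` (per-generation best and mean error,
#' or per-individual with `verbose`), and `fit_phenotype.tsv` (the fitted
#' AP) into the output directory.
#'
#' @param objective_file Two-column delimited trace file
#'   (see [read_voltage_trace()]).
#' @param config A `run_config` (see [read_run_config()]).
#' @param verbose Log per-individual errors instead of summaries.
#' @return The [fit_cell()] result, invisibly.
#' @export
cli_fit <- function(objective_file, config = read_run_config(),
                    verbose = FALSE) {
  objective <- read_voltage_trace(objective_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(ga_config, c(config$ga, list(seed = config$seed)))
  ctx <- ga_context()
  fit <- fit_cell(objective, cfg, ctx)
  jsonlite::write_json(
    list(genotype_fractional_change = as.list(fit$best$genotype),
         ssd_mV2 = fit$best$error, seed = cfg$seed),
    file.path(config$out_dir, "genotype.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  errs <- if (verbose) {
    cbind(data.frame(generation = seq_len(ncol(fit$error_matrix))),
          as.data.frame(t(fit$error_matrix)))
  } else {
    data.frame(generation = seq_len(ncol(fit$error_matrix)),
               best_ssd = apply(fit$error_matrix, 2, min),
               mean_ssd = colMeans(fit$error_matrix))
  }
  utils::write.table(errs, file.path(config$out_dir, "ga_errors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$best$phenotype))
    write_voltage_trace(fit$best$phenotype,
                        file.path(config$out_dir, "fit_phenotype.tsv"))
  .write_run_log(config, config$out_dir,
                 list(command = "fit", objective = objective_file,
                      final_best_ssd = fit$best$error))
  invisible(fit)
}

#' Run a CTC scenario from the command line
#'
#' Scenarios: `"ideal"` (target and canceling model identical, APD80 per
#' `target_apd80`), `"mismatch"` (canceling model from `canceling_apd80`),
#' and `"template"` (a pseudo cell's APD80 selects the canceling model from
#' the template suite). Writes `ctc_record.tsv` and `apd_comparison.tsv`.
#'
#' @param config A `run_config`.
#' @return List with the record, reference and APD table, invisibly.
#' @export
cli_ctc <- function(config = read_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cc <- config$ctc
  cfg <- ctc_config(r_seal_GOhm = cc$r_seal_GOhm, ljp_mV = cc$ljp_mV,
                    loop_dt = cc$loop_dt, sub_steps = cc$sub_steps)
  recipient <- human_recipient_model()
  target <- neonatal_mouse_model(apd80 = cc$target_apd80)
  canceling <- switch(cc$scenario,
    ideal = target,
    mismatch = neonatal_mouse_model(apd80 = cc$canceling_apd80),
    template = {
      cell <- generate_pseudo_cell(config$seed,
                                   pseudo_noise(config$pseudo$jitter_cv,
                                                config$pseudo$v_noise_sd_mV),
                                   n_beats = config$pseudo$n_beats)
      sel <- select_template(build_suite(), apd_mouse80(cell$objective))
      neonatal_mouse_model(apd80 = sel$label_ms)
    })
  record <- run_ctc(target, canceling, recipient, cfg, beats = cc$beats)
  reference <- recipient_reference(recipient, cfg, beats = cc$beats)
  apds <- apd_comparison(record, reference)
  write_ctc_record(record, file.path(config$out_dir, "ctc_record.tsv"))
  utils::write.table(apds, file.path(config$out_dir, "apd_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dev <- trace_supnorm_diff(ctc_trace(record), reference)
  .write_run_log(config, config$out_dir,
                 list(command = "ctc", scenario = cc$scenario,
                      supnorm_deviation_mV = dev))
  message(sprintf("CTC '%s': sup-norm deviation from recipient = %.3f mV",
                  cc$scenario, dev))
  invisible(list(record = record, reference = reference, apds = apds,
                 supnorm_deviation_mV = dev))
}

#' Command-line entry point
#'
#' `ctcfit_main(c("fit", "--objective", "trace.tsv", "--config", "cfg.json",
#' "--out", "dir"))` and similarly for `ctc`, `template`, `pseudo`,
#' `validate`. Returns an exit status (0 on success) rather than raising, so
#' a wrapper script can pass it to [base::quit()].
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
ctcfit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: ctcfit <fit|ctc|template|pseudo|validate> [options]")
    cmd <- args[1]
    opts <- .parse_cli_opts(args[-1])
    config <- read_run_config(opts$config)
    if (!is.null(opts$out)) config$out_dir <- opts$out
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    switch(cmd,
      fit = {
        if (is.null(opts$objective)) stop("fit requires --objective <file>")
        cli_fit(opts$objective, config)
      },
      ctc = cli_ctc(config),
      template = {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        suite <- build_suite()
        utils::write.table(suite,
                           file.path(config$out_dir, "template_suite.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message("wrote template suite (", nrow(suite), " members)")
      },
      pseudo = {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        cell <- generate_pseudo_cell(
          config$seed,
          pseudo_noise(config$pseudo$jitter_cv, config$pseudo$v_noise_sd_mV),
          n_beats = config$pseudo$n_beats)
        write_voltage_trace(cell$objective,
                            file.path(config$out_dir, "objective.tsv"))
        for (i in seq_along(cell$beats))
          write_voltage_trace(cell$beats[[i]],
                              file.path(config$out_dir,
                                        sprintf("beat_%02d.tsv", i)))
        jsonlite::write_json(as.list(cell$genotype),
                             file.path(config$out_dir, "true_genotype.json"),
                             auto_unbox = TRUE, digits = NA)
        message("wrote pseudo cell (seed ", config$seed, ")")
      },
      validate = {
        message("config OK")
      },
      stop("unknown command: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!grepl("^--", args[i]) || i == length(args))
      stop("malformed option: ", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
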