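# Rapid genetic algorithm tuning six conductance scale factors of the mouse
# model against an objective AP, minimizing the 300 ms windowed SSD.
#
# Stochastic draws consume R's global RNG stream in a fixed, documented
# order: population init (gene-major per individual); then per generation:
# two tournament permutations, then per parent pair the crossover-decision
# draw, per-gene swap draws, per-blended-gene spread draws, and per-child
# per-gene mutation draws (decision, then offset). fit_cell() seeds the
# stream from its config, so runs are bit-reproducible.

.ga_gene_names <- c("gNa", "gss", "gKslow", "gCaL", "gK1", "gt")

#' Search bounds of the six conductance scale factors
#'
#' Fractional changes around the starting-point model's conductances:
#' gNa, gK1, gt within +/-90%; gCaL within +/-10%; gss and gKslow within
#' -90% to +200%.
#'
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
ga_bounds <- function() {
  list(
    lower = c(gNa = -0.9, gss = -0.9, gKslow = -0.9,
              gCaL = -0.1, gK1 = -0.9, gt = -0.9),
    upper = c(gNa = 0.9, gss = 2.0, gKslow = 2.0,
              gCaL = 0.1, gK1 = 0.9, gt = 0.9)
  )
}

validate_genotype <- function(g, bounds = ga_bounds()) {
  if (is.null(names(g))) names(g) <- .ga_gene_names
  stopifnot(length(g) == 6, setequal(names(g), .ga_gene_names))
  g <- g[.ga_gene_names]
  bad <- g < bounds$lower - 1e-12 | g > bounds$upper + 1e-12
  if (any(bad))
    stop("genotype out of bounds: ",
         paste(names(g)[bad], collapse = ", "))
  g
}

#' Genetic-algorithm configuration
#'
#' Defaults are the published rapid-GA settings: 40 individuals, 15
#' generations, SBX crossover (probability 0.9, distribution index 10,
#' genewise swap probability 0.5), polynomial mutation (probability 0.1 per
#' gene, index 20), tournament selection without replacement, elitism.
#'
#' @param pop_size Individuals per generation (even, >= 2).
#' @param generations Number of generations including the random initial one.
#' @param p_crossover Per-pair SBX probability.
#' @param eta_crossover SBX polynomial distribution index.
#' @param p_swap Per-gene probability that a gene undergoes the SBX blend.
#' @param p_mutation Per-gene polynomial-mutation probability.
#' @param eta_mutation Mutation polynomial distribution index.
#' @param elitism Copy each generation's best into the next, replacing the
#'   worst.
#' @param seed RNG seed for the run (integer or `NULL`).
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 40, generations = 15, p_crossover = 0.9,
                      eta_crossover = 10, p_swap = 0.5, p_mutation = 0.1,
                      eta_mutation = 20, elitism = TRUE, seed = NULL) {
  stopifnot(pop_size >= 2, pop_size %% 2 == 0, generations >= 1,
            p_crossover >= 0, p_crossover <= 1, p_swap >= 0, p_swap <= 1,
            p_mutation >= 0, p_mutation <= 1,
            eta_crossover > 0, eta_mutation > 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, eta_crossover = eta_crossover,
                 p_swap = p_swap, p_mutation = p_mutation,
                 eta_mutation = eta_mutation, elitism = isTRUE(elitism),
                 seed = seed),
            class = "ga_config")
}

#' Create an unevaluated GA individual
#'
#' An individual couples a genotype (six conductance scale factors) with its
#' phenotype (the simulated AP) and its fitness (SSD against the objective),
#' both filled in by [evaluate_individual()].
#'
#' @param genotype Named numeric of six fractional conductance changes.
#' @return List with `genotype`, `phenotype` (`NULL`), `error` (`NA`).
#' @export
new_individual <- function(genotype) {
  list(genotype = genotype, phenotype = NULL, error = NA_real_)
}

#' Random initial population
#'
#' Genotypes are drawn i.i.d. uniform within the per-gene search bounds.
#'
#' @param n Population size (even, >= 2).
#' @param bounds Per-gene bounds, as [ga_bounds()].
#' @return List of unevaluated individuals.
#' @export
initialize_population <- function(n, bounds = ga_bounds()) {
  stopifnot(n >= 2, n %% 2 == 0)
  lapply(seq_len(n), function(i) {
    g <- stats::runif(6, bounds$lower, bounds$upper)
    names(g) <- .ga_gene_names
    new_individual(g)
  })
}

# worst-case sentinel fitness for unstable/unmeasurable phenotypes, so that
# selection can proceed (mV^2)
.ga_sentinel <- 1e9

# simulate the phenotype of a genotype applied to the starting-point params
.ga_phenotype <- function(genotype, base_params, base_state, amp) {
  p <- base_params
  for (g in .ga_gene_names) p[[g]] <- p[[g]] * (1 + genotype[[g]])
  sim <- cpp_simulate(0L, base_state, p, 0.1, 10000L, 100, 1, amp, FALSE)
  voltage_trace(sim$v, dt = 0.1, t0 = 0, stim_onsets = 100)
}

#' Evaluate an individual against the objective AP
#'
#' Simulates one 1 Hz paced beat with the individual's genotype applied to
#' the starting-point model and computes the windowed SSD against the
#' objective. A failed simulation (numerical blow-up, no measurable
#' upstroke) receives a finite worst-case sentinel error of 1e9 mV^2 rather
#' than raising, so that selection can continue.
#'
#' @param individual An individual (see [initialize_population()]).
#' @param objective Objective [voltage_trace()] covering the error window.
#' @param context A [ga_context()].
#' @return The individual with `phenotype` and `error` filled in.
#' @export
evaluate_individual <- function(individual, objective, context) {
  if (!is.na(individual$error)) return(individual)
  res <- tryCatch({
    ph <- .ga_phenotype(individual$genotype, context$base_params,
                        context$base_state, context$stim_amp)
    list(ph = ph, err = ssd(ph, objective, context$window))
  }, error = function(e) NULL)
  if (is.null(res)) {
    individual$phenotype <- NULL
    individual$error <- .ga_sentinel
  } else {
    individual$phenotype <- res$ph
    individual$error <- res$err
  }
  individual
}

#' Fitting context: starting-point model and error window
#'
#' The GA perturbs conductances around a starting-point model (by default
#' the template-suite member with APD80 = 60 ms); the context carries its
#' parameters, resting state, stimulus amplitude, and the SSD window.
#'
#' @param base_model Starting-point `cell_model` (mouse).
#' @param window An [error_window()].
#' @return A `ga_context` list.
#' @export
ga_context <- function(base_model = neonatal_mouse_model(apd80 = 60),
                       window = error_window()) {
  stopifnot(inherits(base_model, "cell_model"), base_model$kind == "mouse")
  structure(list(base_params = base_model$params,
                 base_state = as.numeric(base_model$state0),
                 stim_amp = default_stim_amplitude(base_model),
                 window = window),
            class = "ga_context")
}

#' Tournament selection without replacement
#'
#' Two passes; each pass randomly partitions the population into pairs and
#' sends each pair's lower-error member (ties: the first drawn wins) into
#' the mating pool in win order. Every individual plays exactly two
#' tournaments; the pool size equals the population size.
#'
#' @param population List of evaluated individuals (even count).
#' @return List of individuals (the mating pool).
#' @export
tournament_pool <- function(population) {
  n <- length(population)
  stopifnot(n %% 2 == 0)
  errs <- vapply(population, function(x) x$error, numeric(1))
  if (anyNA(errs)) stop("population contains unevaluated individuals")
  pool <- vector("list", n)
  k <- 0
  for (pass in 1:2) {
    perm <- sample.int(n)
    for (i in seq(1, n, by = 2)) {
      a <- perm[i]; b <- perm[i + 1]
      k <- k + 1
      pool[[k]] <- if (errs[b] < errs[a]) population[[b]] else population[[a]]
    }
  }
  pool
}

#' Simulated binary crossover (SBX)
#'
#' With probability `p_crossover` the pair recombines: per gene a spread
#' factor beta is drawn from the polynomial distribution with index
#' `eta_crossover` (`beta = (2u)^(1/(eta+1))` for `u <= 0.5`, else
#' `(2(1-u))^(-1/(eta+1))`) and the blended values are
#' `((1+beta) p1 + (1-beta) p2)/2` and `((1-beta) p1 + (1+beta) p2)/2`;
#' with the genewise swap probability `p_swap` the two children's
#' assignments of that gene are exchanged ("parameter values are swapped in
#' the progeny"). Children are clipped to bounds. Pairs that do not
#' recombine become their own children.
#'
#' @param p1,p2 Parent genotypes.
#' @param cfg A [ga_config()].
#' @param bounds Per-gene bounds.
#' @return List of two child genotypes.
#' @export
sbx_crossover <- function(p1, p2, cfg = ga_config(), bounds = ga_bounds()) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= cfg$p_crossover) {
    for (i in seq_along(p1)) {
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (cfg$eta_crossover + 1))
              else (2 * (1 - u))^(-1 / (cfg$eta_crossover + 1))
      a <- 0.5 * ((1 + beta) * p1[i] + (1 - beta) * p2[i])
      b <- 0.5 * ((1 - beta) * p1[i] + (1 + beta) * p2[i])
      if (stats::runif(1) <= cfg$p_swap) { c1[i] <- b; c2[i] <- a }
      else { c1[i] <- a; c2[i] <- b }
    }
    c1 <- pmin(pmax(c1, bounds$lower), bounds$upper)
    c2 <- pmin(pmax(c2, bounds$lower), bounds$upper)
  }
  list(c1, c2)
}

#' Polynomial mutation
#'
#' Per gene, with probability `p_mutation`, adds a bounded polynomial-
#' distributed offset centered on the current value:
#' `delta = (2u)^(1/(eta_m+1)) - 1` for `u < 0.5`, else
#' `1 - (2(1-u))^(1/(eta_m+1))`; the gene becomes
#' `x + delta * (upper - lower)`, clipped to bounds.
#'
#' @param g Genotype.
#' @inheritParams sbx_crossover
#' @return Mutated genotype.
#' @export
polynomial_mutation <- function(g, cfg = ga_config(), bounds = ga_bounds()) {
  for (i in seq_along(g)) {
    if (stats::runif(1) <= cfg$p_mutation) {
      u <- stats::runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (cfg$eta_mutation + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (cfg$eta_mutation + 1))
      g[i] <- g[i] + delta * (bounds$upper[i] - bounds$lower[i])
    }
  }
  pmin(pmax(g, bounds$lower), bounds$upper)
}

#' Produce the next generation
#'
#' Builds the mating pool by tournament selection, pairs parents
#' sequentially in the order they won, applies SBX crossover then
#' polynomial mutation, evaluates the children, and (with elitism) copies
#' the previous generation's best individual over the new generation's
#' worst, keeping its cached error.
#'
#' @inheritParams tournament_pool
#' @param objective Objective [voltage_trace()].
#' @param cfg A [ga_config()].
#' @param context A [ga_context()].
#' @return The next evaluated population (same size).
#' @export
next_generation <- function(population, objective, cfg = ga_config(),
                            context = ga_context()) {
  bounds <- ga_bounds()
  pool <- tournament_pool(population)
  n <- length(pool)
  children <- vector("list", n)
  for (i in seq(1, n, by = 2)) {
    pair <- sbx_crossover(pool[[i]]$genotype, pool[[i + 1]]$genotype,
                          cfg, bounds)
    children[[i]] <- new_individual(polynomial_mutation(pair[[1]], cfg, bounds))
    children[[i + 1]] <- new_individual(polynomial_mutation(pair[[2]], cfg, bounds))
  }
  children <- lapply(children, evaluate_individual, objective = objective,
                     context = context)
  if (cfg$elitism) {
    errs_old <- vapply(population, function(x) x$error, numeric(1))
    errs_new <- vapply(children, function(x) x$error, numeric(1))
    children[[which.max(errs_new)]] <- population[[which.min(errs_old)]]
  }
  children
}

#' Fit a cell-specific mouse model to an objective AP
#'
#' Runs the full rapid GA: a uniform random initial generation followed by
#' `generations - 1` evolution steps; the lowest-error individual of the
#' final generation is the cell-specific model fit.
#'
#' @param objective Objective [voltage_trace()] (e.g. an averaged recorded
#'   or pseudo-cell AP) covering the 300 ms error window.
#' @param cfg A [ga_config()].
#' @param context A [ga_context()]; defaults to the APD80 = 60 ms
#'   starting-point model.
#' @return A `ga_run_result`: list with `error_matrix`
#'   (pop_size x generations), `best_errors` (per generation),
#'   `best` (final lowest-error individual), `seed`, `wall_time_s`, `config`.
#' @export
fit_cell <- function(objective, cfg = ga_config(), context = ga_context()) {
  t_start <- proc.time()[["elapsed"]]
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- initialize_population(cfg$pop_size)
  pop <- lapply(pop, evaluate_individual, objective = objective,
                context = context)
  errmat <- matrix(NA_real_, nrow = cfg$pop_size, ncol = cfg$generations)
  errmat[, 1] <- vapply(pop, function(x) x$error, numeric(1))
  if (cfg$generations > 1) {
    for (gen in 2:cfg$generations) {
      pop <- next_generation(pop, objective, cfg, context)
      errmat[, gen] <- vapply(pop, function(x) x$error, numeric(1))
    }
  }
  best_errors <- apply(errmat, 2, min)
  best <- pop[[which.min(errmat[, cfg$generations])]]
  structure(list(
    error_matrix = errmat,
    best_errors = best_errors,
    best = best,
    seed = cfg$seed,
    wall_time_s = proc.time()[["elapsed"]] - t_start,
    config = cfg
  ), class = "ga_run_result")
}

#' @export
print.ga_run_result <- function(x, ...) {
  cat("<ga_run_result>", ncol(x$error_matrix), "generations x",
      nrow(x$error_matrix), "individuals\n")
  cat("  best SSD by generation (mV^2):\n  ")
  cat(signif(x$best_errors, 4), sep = " ")
  cat("\n  final best genotype (fractional change):\n")
  print(round(x$best$genotype, 4))
  cat("  wall time:", round(x$wall_time_s, 2), "s\n")
  invisible(x)
}
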