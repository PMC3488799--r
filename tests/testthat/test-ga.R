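# GA operator mechanics and end-to-end fitting behavior.

wide_bounds <- list(lower = rep(-Inf, 6), upper = rep(Inf, 6))

test_that("initial population is uniform within bounds and seed-reproducible", {
  b <- ga_bounds()
  set.seed(5); pop <- initialize_population(40)
  g <- t(vapply(pop, function(x) x$genotype, numeric(6)))
  expect_true(all(t(g) >= b$lower & t(g) <= b$upper))
  set.seed(5); pop2 <- initialize_population(40)
  expect_identical(pop, pop2)
  # per-gene mean over 1e4 draws ~ bound midpoint within 3 SE
  set.seed(7); big <- initialize_population(10000)
  G <- t(vapply(big, function(x) x$genotype, numeric(6)))
  mid <- (b$lower + b$upper) / 2
  se <- (b$upper - b$lower) / sqrt(12) / sqrt(10000)
  expect_true(all(abs(colMeans(G) - mid) < 3 * se))
})

fake_pop <- function(errs) {
  lapply(seq_along(errs), function(i) {
    ind <- new_individual(structure(rep(0, 6), names = ctcfit:::.ga_gene_names))
    ind$error <- errs[i]
    ind$id <- i
    ind
  })
}

test_that("tournament pool holds the best twice, never the worst", {
  errs <- c(5, 1, 9, 3, 7, 2, 8, 4) # distinct; best = 2nd, worst = 3rd
  for (seed in 1:25) {
    set.seed(seed)
    pool <- tournament_pool(fake_pop(errs))
    ids <- vapply(pool, function(x) x$id, numeric(1))
    expect_length(pool, 8)
    expect_equal(sum(ids == 2), 2)  # best wins both its tournaments
    expect_equal(sum(ids == 3), 0)  # worst loses both
  }
  # population of two: pool is the better one twice
  set.seed(1)
  pool2 <- tournament_pool(fake_pop(c(4, 6)))
  expect_equal(vapply(pool2, function(x) x$id, numeric(1)), c(1, 1))
  expect_error(tournament_pool(fake_pop(c(NA, 1))), "unevaluated")
})

test_that("SBX preserves the per-gene parent mean before clipping", {
  set.seed(11)
  cfg <- ga_config(p_crossover = 1)
  for (i in 1:50) {
    p1 <- runif(6, -1, 1); p2 <- runif(6, -1, 1)
    names(p1) <- names(p2) <- ctcfit:::.ga_gene_names
    ch <- sbx_crossover(p1, p2, cfg, wide_bounds)
    expect_equal((ch[[1]] + ch[[2]]) / 2, (p1 + p2) / 2, tolerance = 1e-12)
  }
})

test_that("SBX spread factor follows the polynomial distribution", {
  set.seed(13)
  cfg <- ga_config(p_crossover = 1, eta_crossover = 10)
  p1 <- structure(rep(0, 6), names = ctcfit:::.ga_gene_names)
  p2 <- structure(rep(1, 6), names = ctcfit:::.ga_gene_names)
  betas <- unlist(lapply(1:2000, function(i) {
    ch <- sbx_crossover(p1, p2, cfg, wide_bounds)
    abs(ch[[2]] - ch[[1]])  # |c2 - c1| = beta * |p2 - p1|, swap-invariant
  }))
  # closed-form CDF of beta for eta = 10
  pbeta10 <- function(b) ifelse(b <= 1, b^11 / 2, 1 - b^(-11) / 2)
  ks <- suppressWarnings(stats::ks.test(betas, pbeta10))
  expect_gt(ks$p.value, 0.01)
})

test_that("SBX respects the crossover probability and clips to bounds", {
  p1 <- structure(rep(-0.5, 6), names = ctcfit:::.ga_gene_names)
  p2 <- structure(rep(0.5, 6), names = ctcfit:::.ga_gene_names)
  set.seed(3)
  ch <- sbx_crossover(p1, p2, ga_config(p_crossover = 0), ga_bounds())
  expect_identical(ch[[1]], p1)  # non-crossover pairs become their children
  expect_identical(ch[[2]], p2)
  set.seed(4)
  b <- ga_bounds()
  for (i in 1:200) {
    ch <- sbx_crossover(b$lower, b$upper, ga_config(p_crossover = 1), b)
    expect_true(all(ch[[1]] >= b$lower & ch[[1]] <= b$upper))
    expect_true(all(ch[[2]] >= b$lower & ch[[2]] <= b$upper))
  }
})

test_that("polynomial mutation is symmetric, centered, and bounded", {
  g0 <- structure(rep(0.2, 6), names = ctcfit:::.ga_gene_names)
  roomy <- list(lower = rep(-10, 6), upper = rep(10, 6)) # no clipping in play
  set.seed(17)
  cfg <- ga_config(p_mutation = 1)
  M <- t(vapply(1:20000, function(i) polynomial_mutation(g0, cfg, roomy),
                numeric(6)))
  # symmetric operator: mean offset ~ 0 (3 SE); typical |delta| is small at
  # eta = 20, so the SE is computed from the sample itself
  for (j in 1:6) {
    se <- stats::sd(M[, j]) / sqrt(nrow(M))
    expect_lt(abs(mean(M[, j]) - 0.2), 3 * se + 1e-4)
  }
  # with real bounds, mutants stay inside
  b <- ga_bounds()
  set.seed(18)
  for (i in 1:200) {
    m <- polynomial_mutation(b$upper, cfg, b)
    expect_true(all(m >= b$lower & m <= b$upper))
  }
  # p_mutation = 0: an in-bounds genotype passes through unchanged
  g1 <- structure(c(0.2, 0.2, 0.2, 0.05, 0.2, 0.2),
                  names = ctcfit:::.ga_gene_names)
  set.seed(19)
  expect_identical(polynomial_mutation(g1, ga_config(p_mutation = 0), b), g1)
})

test_that("evaluation is pure, near-zero for the generating genotype, and sentinel-guarded", {
  cell <- generate_pseudo_cell(21, pseudo_noise(0, 0))
  ctx <- ga_context()
  ind <- new_individual(cell$genotype)
  e1 <- evaluate_individual(ind, cell$objective, ctx)
  e2 <- evaluate_individual(new_individual(cell$genotype), cell$objective, ctx)
  expect_identical(e1$error, e2$error)
  expect_lt(e1$error, 10)  # self-fit floor (Euler/resampling only)
  # an objective with no upstroke cannot be scored: finite sentinel error
  flat <- voltage_trace(rep(-80, 5000), dt = 0.1, stim_onsets = 100)
  bad <- evaluate_individual(new_individual(cell$genotype), flat, ctx)
  expect_equal(bad$error, 1e9)
})

test_that("next_generation keeps size, never worsens the best, and degenerates to selection", {
  cell <- generate_pseudo_cell(22, pseudo_noise(0, 0))
  ctx <- ga_context()
  cfg <- ga_config(pop_size = 8, generations = 3, seed = 1)
  set.seed(cfg$seed)
  pop <- lapply(initialize_population(8), evaluate_individual,
                objective = cell$objective, context = ctx)
  nxt <- next_generation(pop, cell$objective, cfg, ctx)
  expect_length(nxt, 8)
  expect_lte(min(vapply(nxt, function(x) x$error, numeric(1))),
             min(vapply(pop, function(x) x$error, numeric(1))))
  # crossover and mutation off: children inherit parent errors exactly
  cfg0 <- ga_config(pop_size = 8, p_crossover = 0, p_mutation = 0)
  set.seed(2)
  nxt0 <- next_generation(pop, cell$objective, cfg0, ctx)
  e_old <- vapply(pop, function(x) x$error, numeric(1))
  e_new <- vapply(nxt0, function(x) x$error, numeric(1))
  expect_true(all(e_new %in% e_old))
  expect_equal(min(e_new), min(e_old))
})

test_that("fit_cell records full history, converges monotonically, and is seed-stable", {
  cell <- generate_pseudo_cell(23, pseudo_noise(0, 0))
  ctx <- ga_context()
  cfg <- ga_config(pop_size = 8, generations = 4, seed = 42)
  fit <- fit_cell(cell$objective, cfg, ctx)
  expect_equal(dim(fit$error_matrix), c(8, 4))
  expect_true(all(diff(fit$best_errors) <= 0))
  expect_equal(fit$best$error, min(fit$error_matrix[, 4]))
  fit2 <- fit_cell(cell$objective, cfg, ctx)
  expect_identical(fit$best$genotype, fit2$best$genotype)
  expect_identical(fit$error_matrix, fit2$error_matrix)
})
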