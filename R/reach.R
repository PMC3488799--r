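# Reach of the GA search space: the range of APD80 attainable by six-gene
# conductance scaling inside the search bounds, located by coarse directed
# search (all bound-box corners plus coordinate-wise refinement around the
# best corner). The published search ranges were chosen to span AP durations
# of roughly 40-160 ms.

.apd80_of_genotype <- function(genotype, context) {
  tryCatch({
    tr <- .ga_phenotype(genotype, context$base_params, context$base_state,
                        context$stim_amp)
    apd_mouse80(tr)
  }, error = function(e) NA_real_)
}

#' APD80 extremes attainable inside the GA search bounds
#'
#' Evaluates the 1 Hz paced APD80 (mouse definition) of the starting-point
#' model at all 64 corners of the six-gene bound box, then refines around
#' the longest- and shortest-APD corners by coordinate descent over a
#' per-gene grid. Genotypes whose AP has no measurable APD80 (e.g. loss of
#' repolarization) are skipped.
#'
#' @param context A [ga_context()].
#' @param grid_points Grid size per gene during refinement.
#' @param sweeps Coordinate-descent sweeps.
#' @return List with `max_apd80`, `min_apd80` (ms), the corresponding
#'   genotypes, and `corner_apd80` (the 64 corner values, `NA` when
#'   unmeasurable).
#' @export
apd80_search_extremes <- function(context = ga_context(), grid_points = 5,
                                  sweeps = 2) {
  bounds <- ga_bounds()
  corners <- as.matrix(expand.grid(rep(list(c(1, 2)), 6)))
  vals <- apply(corners, 1, function(idx) {
    g <- ifelse(idx == 1, bounds$lower, bounds$upper)
    names(g) <- .ga_gene_names
    .apd80_of_genotype(g, context)
  })
  refine <- function(g, better) {
    best <- .apd80_of_genotype(g, context)
    for (sweep in seq_len(sweeps)) {
      for (i in seq_along(g)) {
        for (x in seq(bounds$lower[i], bounds$upper[i],
                      length.out = grid_points)) {
          cand <- g; cand[i] <- x
          a <- .apd80_of_genotype(cand, context)
          if (!is.na(a) && (is.na(best) || better(a, best))) {
            best <- a; g <- cand
          }
        }
      }
    }
    list(apd80 = best, genotype = g)
  }
  corner_g <- function(k) {
    g <- ifelse(corners[k, ] == 1, bounds$lower, bounds$upper)
    names(g) <- .ga_gene_names
    g
  }
  up <- refine(corner_g(which.max(vals)), `>`)
  dn <- refine(corner_g(which.min(vals)), `<`)
  list(max_apd80 = up$apd80, min_apd80 = dn$apd80,
       max_genotype = up$genotype, min_genotype = dn$genotype,
       corner_apd80 = vals)
}
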