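# shared miniature inputs for the test suite

mini_map <- function() genome_map(chrom_lengths = c(5e7, 5e7))

# founder candidate pool as a plain data frame (n1 source-1, n2 source-2)
founder_pool <- function(n1, n2) {
  data.frame(
    x = rep(c(1, 0), c(n1, n2)),
    s = rep(c("A", "B"), c(n1, n2))
  )
}

# mating-record table from parallel vectors
records_from_pairs <- function(xi, xj, si = "A", sj = "A",
                               migrant_i = FALSE, migrant_j = FALSE, t = 1L) {
  data.frame(
    t = t, parent1 = seq_along(xi), parent2 = rev(seq_along(xi)),
    xi = xi, xj = xj, si = si, sj = sj,
    migrant_i = migrant_i, migrant_j = migrant_j
  )
}

# quick scaled-down simulation
mini_sim <- function(model = "random", alpha = 1, N = 200, generations = 3,
                     seed = 1, migration_rate = 0, snapshots = integer(0),
                     ...) {
  cfg <- sim_config(
    N = N, generations = generations, model = model, alpha = alpha,
    migration_rate = migration_rate, map = mini_map(), seed = seed,
    snapshot_generations = snapshots
  )
  run_simulation(cfg, ...)
}

# total-variation distance between empirical mate frequencies and an exact
# probability row
tv_distance <- function(p, q) sum(abs(p - q)) / 2

# empirical mate-choice frequencies for one focal individual
empirical_mate_freq <- function(focal, candidates, model, n_draws,
                                var_t = NULL) {
  draws <- vapply(seq_len(n_draws), function(i) {
    sample_mate(focal, candidates, model, var_t = var_t)
  }, integer(1))
  tabulate(draws, nbins = nrow(candidates)) / n_draws
}
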