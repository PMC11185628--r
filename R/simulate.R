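#' Run a full simulation
#'
#' Founds the population, steps it `generations` times under the
#' configured mate-choice model, and collects per-generation statistics
#' and mating records, plus full tract tables at the configured snapshot
#' generations. A run is fully reproducible given `(config$seed,
#' replicate)`.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (combined with `config$seed` to seed
#'   the RNG).
#' @param n_perm If > 0, a one-sided permutation test of the mate
#'   correlation is run each generation with this many permutations.
#' @param keep_records Keep the per-event mating records of every
#'   generation (default `TRUE`).
#' @param keep_population Keep the final `admix_population` object.
#' @param verbose Print a line per generation.
#' @return An object of class `admix_sim`: a list with `summary` (one row
#'   per generation: `t`, `r`, `sigma2`, `admixed_fraction`,
#'   `migrant_mating_fraction`, `group_assoc`, and `perm_p` when
#'   requested), `records`, `tracts` (named list of tract tables), and
#'   optionally `population`.
#' @examples
#' cfg <- sim_config(N = 100, generations = 3, model = "social", alpha = 4,
#'                   map = genome_map(chrom_lengths = c(5e7, 5e7)),
#'                   snapshot_generations = 3)
#' sim <- run_simulation(cfg)
#' sim$summary
#' @export
run_simulation <- function(config, replicate = 1L, n_perm = 0L,
                           keep_records = TRUE, keep_population = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, replicate))
  pop <- init_population(config)
  rows <- vector("list", config$generations)
  recs <- if (keep_records) vector("list", config$generations) else NULL
  tracts <- list()
  for (t in seq_len(config$generations)) {
    step <- step_generation(pop, config$model, config$migration_rate)
    pop <- step$population
    rows[[t]] <- generation_stats(pop, step$records, n_perm = n_perm)
    if (keep_records) recs[[t]] <- step$records
    if (t %in% config$snapshot_generations) {
      tracts[[as.character(t)]] <- population_tracts(pop)
    }
    if (verbose) {
      cat(sprintf("t=%d r=%.4f sigma2=%.5f\n",
                  t, rows[[t]]$r, rows[[t]]$sigma2))
    }
  }
  structure(
    list(
      config = config, replicate = as.integer(replicate),
      summary = do.call(rbind, rows),
      records = if (keep_records) do.call(rbind, recs) else NULL,
      tracts = tracts,
      population = if (keep_population) pop else NULL
    ),
    class = "admix_sim"
  )
}

# replicate-specific seed below 2^31
derive_seed <- function(seed, replicate) {
  (as.numeric(seed) * 1009 + as.numeric(replicate) * 7919) %% 2147483647
}

#' @export
print.admix_sim <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<admix_sim> %s alpha=%g N=%d, %d generations (replicate %d)\n",
    x$config$model$kind, x$config$model$alpha, x$config$N,
    x$config$generations, x$replicate
  ))
  cat(sprintf("  final generation: r=%.4f sigma2=%.5f admixed=%.3f\n",
              last$r, last$sigma2, last$admixed_fraction))
  invisible(x)
}

#' Run replicate simulations
#'
#' @inheritParams run_simulation
#' @param n_replicates Number of replicates; defaults to
#'   `config$n_replicates`.
#' @param ... Passed on to [run_simulation()].
#' @return A list with `replicates` (list of `admix_sim`) and `summary`
#'   (row-bound per-generation summaries with a `replicate` column).
#' @export
run_replicates <- function(config, n_replicates = config$n_replicates, ...) {
  sims <- lapply(seq_len(n_replicates), function(k) {
    run_simulation(config, replicate = k, ...)
  })
  summ <- do.call(rbind, lapply(sims, function(s) {
    cbind(replicate = s$replicate, s$summary)
  }))
  list(replicates = sims, summary = summ)
}

#' Write simulation outputs to a directory
#'
#' Emits `summary.csv` (one row per generation), `pairs_t{T}.csv` (the
#' final generation's mating records), BED-like `tracts_t{G}.bed` for each
#' retained snapshot generation, and `run_log.yaml` (config echo, seed,
#' package version).
#'
#' @param sim An `admix_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(sim$summary, file.path(dir, "summary.csv"))
  if (!is.null(sim$records)) {
    Tlast <- max(sim$records$t)
    data.table::fwrite(sim$records[sim$records$t == Tlast, , drop = FALSE],
                       file.path(dir, sprintf("pairs_t%d.csv", Tlast)))
  }
  for (g in names(sim$tracts)) {
    write_tracts(sim$tracts[[g]], file.path(dir, sprintf("tracts_t%s.bed", g)))
  }
  yaml::write_yaml(
    list(
      config = list(
        N = sim$config$N, generations = sim$config$generations,
        model = sim$config$model$kind, alpha = sim$config$model$alpha,
        m = sim$config$m, migration_rate = sim$config$migration_rate,
        recomb_rate = sim$config$map$recomb_rate,
        L = sim$config$map$L, seed = sim$config$seed
      ),
      replicate = sim$replicate,
      derived_seed = derive_seed(sim$config$seed, sim$replicate),
      package_version = as.character(utils::packageVersion("assortmate"))
    ),
    file.path(dir, "run_log.yaml")
  )
  invisible(dir)
}
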