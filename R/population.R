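#' Simulation configuration
#'
#' Bundles every parameter of a run. Defaults reproduce the study
#' conditions used throughout: census size `N = 10,000` per generation, a
#' single admixture pulse with equal founder contributions (`m = 0.5`), a
#' 22-chromosome 2.88 Gb genome with uniform recombination `1e-8`, and 50
#' generations (analyses typically focus on the first 20).
#'
#' @param N Census population size per generation (even, >= 2).
#' @param generations Number of generations to simulate (>= 1).
#' @param model A [mate_choice_model()], or a kind string combined with
#'   `alpha`.
#' @param alpha Strength parameter, used when `model` is a string.
#' @param m Founding fraction from source population 1, in `(0, 1)`.
#' @param migration_rate Fraction of each generation replaced by unadmixed
#'   migrants (`0` for a single pulse; the continuous-migration scenario
#'   uses `0.01`). Migrants are split round-half-even between the two
#'   sources, join the source-associated social group, and mate from the
#'   next generation onward.
#' @param map A [genome_map()].
#' @param seed Base RNG seed; combined with the replicate index by
#'   [run_simulation()].
#' @param n_replicates Number of replicates for [run_replicates()].
#' @param snapshot_generations Generations at which full tract tables are
#'   retained in the result (intersected with `1:generations`).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(N = 200, generations = 5, model = "social", alpha = 4)
#' @export
sim_config <- function(N = 10000, generations = 50,
                       model = "random", alpha = 1,
                       m = 0.5, migration_rate = 0,
                       map = genome_map(), seed = 1L, n_replicates = 1L,
                       snapshot_generations = c(1, 10, 20, 50)) {
  if (is.character(model)) model <- mate_choice_model(model, alpha = alpha)
  stopifnot(inherits(model, "mate_choice_model"), inherits(map, "genome_map"))
  if (!is.numeric(N) || length(N) != 1 || N < 2 || N %% 2 != 0) {
    stop("`N` must be an even integer >= 2", call. = FALSE)
  }
  if (!is.numeric(generations) || length(generations) != 1 ||
      generations < 1) {
    stop("`generations` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m >= 1) {
    stop("`m` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(migration_rate) || length(migration_rate) != 1 ||
      migration_rate < 0 || migration_rate >= 1) {
    stop("`migration_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      N = as.integer(N), generations = as.integer(generations),
      model = model, m = m, migration_rate = migration_rate, map = map,
      seed = as.integer(seed), n_replicates = as.integer(n_replicates),
      snapshot_generations = intersect(snapshot_generations,
                                       seq_len(generations))
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> N=%d T=%d model=%s alpha=%g m=%g ",
           "migration=%g seed=%d replicates=%d\n"),
    x$N, x$generations, x$model$kind, x$model$alpha, x$m,
    x$migration_rate, x$seed, x$n_replicates
  ))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file.
#' @param config A [sim_config()].
#' @return `read_sim_config()`: a `sim_config`. `write_sim_config()`:
#'   `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  map <- genome_map(
    chrom_lengths = if (!is.null(y$chrom_lengths)) unlist(y$chrom_lengths)
                    else default_chrom_lengths(),
    recomb_rate = if (!is.null(y$recomb_rate)) y$recomb_rate else 1e-8
  )
  args <- y[intersect(names(y), c("N", "generations", "model", "alpha", "m",
                                  "migration_rate", "seed", "n_replicates",
                                  "snapshot_generations"))]
  args$map <- map
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(
    list(
      N = config$N, generations = config$generations,
      model = config$model$kind, alpha = config$model$alpha,
      m = config$m, migration_rate = config$migration_rate,
      chrom_lengths = config$map$chrom_lengths,
      recomb_rate = config$map$recomb_rate,
      seed = config$seed, n_replicates = config$n_replicates,
      snapshot_generations = config$snapshot_generations
    ),
    path
  )
  invisible(path)
}

#' Found the admixed population
#'
#' Creates generation 0: `round(m * N)` source-1 founders (`x = 1`, group
#' "A") and the rest source-2 (`x = 0`, group "B"), each with a single
#' tract per chromosome. The founder ancestry variance
#' \eqn{\sigma_x^2(0) = m(1-m)} is stored on the population as the
#' reference variance for the increasing-preference kernel.
#'
#' @param config A [sim_config()].
#' @return An object of class `admix_population`.
#' @export
init_population <- function(config) {
  N <- config$N
  C <- length(config$map$chrom_lengths)
  n1 <- round(config$m * N)  # round-half-even
  src <- rep(c(1L, 2L), c(n1, N - n1))
  x <- as.numeric(src == 1)
  pop <- structure(
    list(
      n = N, t = 0L, map = config$map,
      ends = rep(as.numeric(config$map$chrom_lengths), times = 2L * N),
      nt = rep(1L, N * 2L * C),
      src1 = rep(src, each = 2L * C),
      x = x,
      s = src,  # group A(1) for source 1, B(2) for source 2
      migrant = rep(FALSE, N),
      var0 = mean((x - mean(x))^2)
    ),
    class = "admix_population"
  )
  pop
}

#' @export
print.admix_population <- function(x, ...) {
  cat(sprintf(
    paste0("<admix_population> N=%d t=%d mean(x)=%.4f var(x)=%.5f ",
           "groups A:%d B:%d migrants:%d\n"),
    x$n, x$t, mean(x$x), mean((x$x - mean(x$x))^2),
    sum(x$s == 1L), sum(x$s == 2L), sum(x$migrant)
  ))
  invisible(x)
}

#' Individual-level views of a population
#'
#' `pop_individuals()` returns one row per individual (`id`, `x`, `s`,
#' `is_migrant`); `as_individual()` materializes one individual with its
#' tract sets; `population_tracts()` expands the whole population into a
#' long tract table.
#'
#' @param pop An `admix_population`.
#' @param ids Individuals to include (default all).
#' @return See above; tract tables have columns `chrom`, `start`, `end`,
#'   `source`, `id`, `haplotype`.
#' @export
pop_individuals <- function(pop) {
  data.frame(
    id = seq_len(pop$n),
    x = pop$x,
    s = c("A", "B")[pop$s],
    is_migrant = pop$migrant
  )
}

#' @rdname pop_individuals
#' @param i Individual index.
#' @export
as_individual <- function(pop, i) {
  stopifnot(i >= 1, i <= pop$n)
  tr <- population_tracts(pop, ids = i)
  structure(
    list(
      hap1 = tr[tr$haplotype == 1, c("chrom", "start", "end", "source")],
      hap2 = tr[tr$haplotype == 2, c("chrom", "start", "end", "source")],
      x = pop$x[i], s = c("A", "B")[pop$s[i]],
      is_migrant = pop$migrant[i], id = i
    ),
    class = "admix_individual"
  )
}

#' @rdname pop_individuals
#' @export
population_tracts <- function(pop, ids = NULL) {
  C <- length(pop$map$chrom_lengths)
  nt <- pop$nt
  n_blocks <- length(nt)
  block_id <- rep(seq_len(n_blocks), nt)
  within <- sequence(nt)
  ind <- (seq_len(n_blocks) - 1L) %/% (2L * C) + 1L
  hap <- ((seq_len(n_blocks) - 1L) %/% C) %% 2L + 1L
  chrom <- (seq_len(n_blocks) - 1L) %% C + 1L
  first <- within == 1L
  # start of tract k is the end of tract k-1 within the same block
  starts <- c(0, pop$ends[-length(pop$ends)])
  starts[first] <- 0
  out <- data.frame(
    chrom = chrom[block_id],
    start = starts,
    end = pop$ends,
    source = ((rep(pop$src1, nt) - 1L + within - 1L) %% 2L) + 1L,
    id = ind[block_id],
    haplotype = hap[block_id]
  )
  if (!is.null(ids)) out <- out[out$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Advance the population by one generation
#'
#' Performs `N` mating events, each producing one child. Parent 1 is
#' sampled uniformly with replacement; parent 2 proportional to the
#' model's mating weight, with selfing prohibited. Each child receives one
#' recombinant gamete per parent and inherits parent 1's social group.
#' Under the increasing-preference kernel \eqn{\sigma_x^2(t)} is computed
#' once over the parental generation before any mating event. If
#' `migration_rate > 0`, `round(migration_rate * N)` children are then
#' replaced by fresh unadmixed migrants (half per source) that carry the
#' source-associated group and the migrant flag.
#'
#' @param pop An `admix_population`.
#' @param model A [mate_choice_model()].
#' @param migration_rate Per-generation migrant replacement fraction.
#' @return A list with `population` (the next generation) and `records`
#'   (the generation's mating records: `t`, `parent1`, `parent2`, `xi`,
#'   `xj`, `si`, `sj`, `migrant_i`, `migrant_j`).
#' @export
step_generation <- function(pop, model, migration_rate = 0) {
  stopifnot(inherits(pop, "admix_population"),
            inherits(model, "mate_choice_model"))
  st <- cpp_step_generation(
    pop[c("ends", "nt", "src1", "x", "s", "migrant")],
    pop$map$chrom_lengths, pop$map$recomb_rate,
    model$kind_code, model$alpha, pop$var0, migration_rate
  )
  p1 <- st$parent1
  p2 <- st$parent2
  records <- data.frame(
    t = pop$t + 1L,
    parent1 = p1, parent2 = p2,
    xi = pop$x[p1], xj = pop$x[p2],
    si = c("A", "B")[pop$s[p1]], sj = c("A", "B")[pop$s[p2]],
    migrant_i = pop$migrant[p1], migrant_j = pop$migrant[p2]
  )
  new_pop <- structure(
    list(
      n = pop$n, t = pop$t + 1L, map = pop$map,
      ends = st$ends, nt = st$nt, src1 = st$src1,
      x = st$x, s = st$s, migrant = st$migrant,
      var0 = pop$var0
    ),
    class = "admix_population"
  )
  list(population = new_pop, records = records)
}
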