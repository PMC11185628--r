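test_that("mate correlation handles exact and degenerate cases", {
  # fully endogamous binary pairs
  rec <- records_from_pairs(xi = rep(c(1, 0), each = 10),
                            xj = rep(c(1, 0), each = 10))
  expect_equal(mate_correlation(rec), 1)
  # exact mixture with p_same = 0.75 and symmetric margins: r = 0.5
  rec <- records_from_pairs(
    xi = c(rep(1, 375), rep(0, 375), rep(1, 125), rep(0, 125)),
    xj = c(rep(1, 375), rep(0, 375), rep(0, 125), rep(1, 125))
  )
  expect_equal(mate_correlation(rec), binary_pair_correlation(0.75))
  expect_equal(mate_correlation(rec), 0.5)
  # degenerate margins return an NA marker, not an error
  rec <- records_from_pairs(xi = rep(0.5, 5), xj = runif(5))
  expect_true(is.na(mate_correlation(rec)))
})

test_that("mate correlation is near zero under random mating", {
  sim <- mini_sim("random", N = 1000, generations = 3, seed = 3)
  expect_lt(max(abs(sim$summary$r)), 4 / sqrt(1000))
})

test_that("ordered and symmetrized correlations agree within tolerance", {
  sim <- mini_sim("increasing", alpha = 8, N = 800, generations = 5, seed = 7)
  rec <- sim$records[sim$records$t == 5, ]
  expect_lt(abs(mate_correlation(rec) - mate_correlation(rec, symmetrized = TRUE)),
            0.05)
})

test_that("permutation test ranks the observed correlation correctly", {
  set.seed(2)
  # strong assortment: observed r exceeds every permutation
  sim <- mini_sim("increasing", alpha = 10, N = 500, generations = 2, seed = 11)
  rec <- sim$records[sim$records$t == 2, ]
  pt <- permutation_test(rec, n_perm = 1000)
  expect_equal(pt$p_value, 1 / 1001)
  expect_lt(pt$p_value, 0.001)
  # an effectively median observation has p near 0.5
  rec_null <- records_from_pairs(xi = runif(400), xj = runif(400))
  pt0 <- permutation_test(rec_null, n_perm = 999)
  expect_gt(pt0$p_value, 0.05)
  expect_error(permutation_test(rec, n_perm = 0), ">= 1")
})

test_that("permutation p-values are (super-)uniform under the null", {
  set.seed(13)
  x_pool <- runif(600)  # an admixed generation's ancestry distribution
  ps <- vapply(seq_len(200), function(i) {
    rec <- records_from_pairs(xi = sample(x_pool, 100, replace = TRUE),
                              xj = sample(x_pool, 100, replace = TRUE))
    permutation_test(rec, n_perm = 99)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
  # no excess of small p-values beyond binomial noise
  expect_lt(mean(ps <= 0.05), 0.11)
  expect_lt(mean(ps <= 0.10), 0.18)
})

test_that("ancestry variance and admixed fraction behave as defined", {
  expect_equal(ancestry_variance(rep(c(0, 1), 50)), 0.25)
  expect_equal(ancestry_variance(rep(0.4, 10)), 0)
  expect_error(ancestry_variance(0.3), "two")
  expect_equal(admixed_fraction(c(0, 1, 0.5, 0.2)), 0.5)
})

test_that("non-random mating keeps early ancestry variance above random", {
  r_sim <- mini_sim("random", N = 1500, generations = 3, seed = 19)
  s_sim <- mini_sim("stationary", alpha = 8, N = 1500, generations = 3,
                    seed = 19)
  expect_true(all(s_sim$summary$sigma2 > r_sim$summary$sigma2))
})

test_that("pair-density binning scales the maximum cell to one", {
  # all pairs identical: a single occupied cell at density 1
  rec <- records_from_pairs(xi = rep(0.31, 50), xj = rep(0.52, 50))
  m <- hexbin_density(rec, geometry = "square")
  expect_equal(max(m), 1)
  expect_equal(sum(m == 1), 1)
  expect_equal(sum(m > 0), 1)
  h <- hexbin_density(rec, geometry = "hex")
  expect_equal(nrow(h), 1)
  expect_equal(h$density, 1)
  # two equal clusters: two cells at density 1 after scaling
  rec2 <- records_from_pairs(xi = rep(c(0.1, 0.9), each = 30),
                             xj = rep(c(0.1, 0.9), each = 30))
  m2 <- hexbin_density(rec2, geometry = "square")
  expect_equal(sum(m2 == 1), 2)
  # scaled maximum is 1 for arbitrary records under both geometries
  set.seed(23)
  rec3 <- records_from_pairs(xi = runif(500), xj = runif(500))
  expect_equal(max(hexbin_density(rec3, geometry = "square")), 1)
  expect_equal(max(hexbin_density(rec3, geometry = "hex")$density), 1)
  # subsampling bounds the total count
  h3 <- hexbin_density(rec3, geometry = "hex", subsample = 100)
  expect_equal(sum(h3$count), 100)
  expect_error(hexbin_density(rec3, binwidth = 0), "positive")
})

test_that("a strong social barrier keeps two on-diagonal pair clusters", {
  # full 22-chromosome map while the group-ancestry association, which
  # decays as (alpha/(alpha+1))^t, still separates the two group clusters
  run_full <- function(kind, alpha) {
    cfg <- sim_config(N = 1000, generations = 5, model = kind, alpha = alpha,
                      seed = 31, snapshot_generations = integer(0))
    run_simulation(cfg, keep_population = TRUE)
  }
  soc <- run_full("social", 9)
  rec_s <- soc$records[soc$records$t == 5, ]
  rnd <- run_full("random", 1)
  # the social population stays bimodal in ancestry; random mating does not
  expect_true(ancestry_bimodality(soc$population)$bimodal)
  expect_false(ancestry_bimodality(rnd$population)$bimodal)
  # the two densest pair cells sit on the diagonal, one per group cluster
  m <- hexbin_density(rec_s, geometry = "square")
  centers <- as.numeric(rownames(m))
  top2 <- order(m, decreasing = TRUE)[1:2]
  cx <- centers[(top2 - 1) %% nrow(m) + 1]
  cy <- centers[(top2 - 1) %/% nrow(m) + 1]
  expect_true(all(abs(cx - cy) < 0.2))        # on-diagonal
  expect_equal(sum(cx < 0.5), 1)              # one low-, one high-ancestry
})

test_that("delta-x distribution matches construction and a resampling oracle", {
  rec <- records_from_pairs(xi = rep(0.7, 20), xj = rep(0.7, 20))
  d <- delta_x_distribution(rec)
  expect_true(all(d$delta == 0))
  # random binary founder pairs: dx in {0, 1} equally likely
  rec2 <- records_from_pairs(xi = c(1, 1, 0, 0), xj = c(1, 0, 1, 0))
  expect_equal(sort(unique(delta_x_distribution(rec2)$delta)), c(0, 1))
  expect_equal(mean(delta_x_distribution(rec2)$delta), 0.5)
  # alpha=1: dx is the difference of two independent draws from x
  set.seed(37)
  sim <- mini_sim("random", N = 1500, generations = 4, seed = 41)
  rec4 <- sim$records[sim$records$t == 4, ]
  oracle <- abs(sample(rec4$xi) - sample(rec4$xj))
  ks <- suppressWarnings(ks.test(delta_x_distribution(rec4)$delta, oracle))
  expect_gt(ks$p.value, 0.001)
})

test_that("migrant-mating fraction counts flagged pairs", {
  rec <- records_from_pairs(xi = runif(100), xj = runif(100),
                            migrant_i = rep(c(TRUE, FALSE), c(10, 90)),
                            migrant_j = rep(c(TRUE, FALSE), c(5, 95)))
  mm <- migrant_mating_fraction(rec)
  expect_equal(mm$fraction, 0.05)
  expect_equal(mm$migrant_fraction, 0.1)
  expect_equal(mm$random_expectation, 0.01)
  rec0 <- records_from_pairs(xi = runif(10), xj = runif(10))
  expect_equal(migrant_mating_fraction(rec0)$fraction, 0)
})

test_that("group-ancestry association starts at one and decays", {
  cfg <- sim_config(N = 500, generations = 1, map = mini_map())
  expect_equal(group_ancestry_association(init_population(cfg)), 1)
  expect_true(is.na(group_ancestry_association(
    data.frame(x = runif(5), s = rep("A", 5)))))
  sim <- mini_sim("social", alpha = 4, N = 1000, generations = 15, seed = 43,
                  keep_population = TRUE)
  assoc <- sim$summary$group_assoc
  expect_gt(assoc[15], 0)
  expect_lt(assoc[15], 1)
  expect_lt(assoc[15], assoc[1])
})

test_that("interior-valley heuristic flags bimodal ancestry distributions", {
  set.seed(47)
  bimodal <- c(rnorm(500, 0.15, 0.05), rnorm(500, 0.85, 0.05))
  bimodal <- pmin(pmax(bimodal, 0), 1)
  expect_true(ancestry_bimodality(bimodal)$bimodal)
  unimodal <- pmin(pmax(rnorm(1000, 0.5, 0.1), 0), 1)
  expect_false(ancestry_bimodality(unimodal)$bimodal)
})

test_that("generation_stats assembles one coherent row", {
  sim <- mini_sim("social", alpha = 4, N = 200, generations = 2,
                  keep_population = TRUE)
  rec <- sim$records[sim$records$t == 2, ]
  row <- generation_stats(sim$population, rec, n_perm = 49)
  expect_equal(row$t, 2)
  expect_named(row, c("t", "r", "sigma2", "admixed_fraction",
                      "migrant_mating_fraction", "group_assoc", "perm_p"))
})
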