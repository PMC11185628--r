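test_that("alpha follows from the admixed-offspring fraction", {
  expect_equal(alpha_from_admixed_fraction(0.5), 1)  # random mating
  expect_equal(alpha_from_admixed_fraction(1), 0)    # exclusive exogamy
  expect_equal(alpha_from_admixed_fraction(0.2), 4)
  expect_error(alpha_from_admixed_fraction(0), "\\(0, 1\\]")
  expect_error(alpha_from_admixed_fraction(1.2), "\\(0, 1\\]")
})

test_that("stationary kernel decays exponentially in |dx| at rate ln(alpha)", {
  expect_equal(stationary_weight(0.3, 0.3, alpha = 5), 1)
  expect_equal(stationary_weight(0, 1, alpha = 10), 0.1)
  expect_equal(stationary_weight(0.2, 0.7, alpha = 4), exp(-log(4) * 0.5))
  expect_equal(stationary_weight(c(0, 1), c(0.5, 0.5), alpha = 1), c(1, 1))
  expect_error(stationary_weight(-0.1, 0.5, 2), "\\[0, 1\\]")
})

test_that("increasing kernel rescales with current ancestry variance", {
  # at var_t = var0 it coincides with the stationary kernel
  expect_equal(increasing_weight(0, 1, alpha = 4, var_t = 0.25), 0.25)
  # halving the variance doubles the exponent
  expect_equal(increasing_weight(0, 1, alpha = 4, var_t = 0.125), 1 / 16)
  # degenerate population falls back to uniform weights
  expect_equal(increasing_weight(c(0, 0.5), c(1, 0.5), alpha = 4, var_t = 0),
               c(1, 1))
  expect_error(increasing_weight(0, 1, 4, var_t = -1), "non-negative")
})

test_that("broad kernel is Gaussian with endogamy:exogamy ratio exactly alpha", {
  for (a in c(2, 4, 10)) {
    expect_equal(broad_weight(0, 0, a) / broad_weight(0, 1, a), a)
  }
  # maximal on the diagonal
  w <- broad_weight(0.5, c(0.1, 0.4, 0.5, 0.9), alpha = 6)
  expect_equal(which.max(w), 3)
  expect_equal(broad_weight(c(0, 1), c(1, 0), alpha = 1), c(1, 1))
  expect_error(broad_weight(0, 1, alpha = 0.5), ">= 1")
})

test_that("social kernel takes two values with within:between ratio alpha", {
  expect_equal(social_weight("A", "A", alpha = 4), 0.8)
  expect_equal(social_weight("A", "B", alpha = 4), 0.2)
  expect_equal(social_weight("B", "B", alpha = 1), 0.5)
  for (a in c(0, 1, 2.5, 9)) {
    expect_equal(social_weight("A", "A", a) / social_weight("A", "B", a),
                 a, tolerance = 1e-12)
  }
  expect_error(social_weight("A", "C", 4), "group")
})

test_that("all non-random kernels are symmetric in (i, j)", {
  set.seed(21)
  xi <- runif(20)
  xj <- runif(20)
  expect_equal(stationary_weight(xi, xj, 7), stationary_weight(xj, xi, 7))
  expect_equal(increasing_weight(xi, xj, 7, 0.1), increasing_weight(xj, xi, 7, 0.1))
  expect_equal(broad_weight(xi, xj, 7), broad_weight(xj, xi, 7))
  expect_equal(social_weight("A", "B", 7), social_weight("B", "A", 7))
})

test_that("model constructor enforces its domain", {
  expect_error(mate_choice_model("random", alpha = 2), "alpha = 1")
  expect_error(mate_choice_model("stationary", alpha = 0.5), ">= 1")
  expect_error(mate_choice_model("nope"), "arg")
  m <- mate_choice_model("broad", alpha = 10)
  expect_s3_class(m, "mate_choice_model")
})

test_that("enumerated mate probabilities match hand calculations", {
  # two individuals: each must choose the other
  two <- founder_pool(1, 1)
  P <- enumerate_mate_probabilities(two, mate_choice_model("stationary", 4))
  expect_equal(P, matrix(c(0, 1, 1, 0), 2))
  # three founders (two source-1, one source-2), stationary alpha=4:
  # focal source-1 picks the same-source candidate with 1/(1 + 1/4) = 4/5
  three <- founder_pool(2, 1)
  P <- enumerate_mate_probabilities(three, mate_choice_model("stationary", 4))
  expect_equal(P[1, ], c(0, 0.8, 0.2))
  # social alpha=1 is uniform over non-focal candidates
  P <- enumerate_mate_probabilities(founder_pool(2, 2),
                                    mate_choice_model("social", 1))
  expect_equal(P[2, ], c(1, 0, 1, 1) / 3)
  expect_error(enumerate_mate_probabilities(founder_pool(4, 4),
                                            mate_choice_model("random")),
               "guard")
})

test_that("sample_mate matches enumerated probabilities (TV < 0.01)", {
  set.seed(31)
  pools <- list(
    list(cand = founder_pool(2, 2),
         model = mate_choice_model("social", 4), n = 1e5),
    list(cand = data.frame(x = c(0, 0.25, 0.5, 0.8, 1),
                           s = c("A", "A", "B", "B", "B")),
         model = mate_choice_model("stationary", 6), n = 3e4),
    list(cand = data.frame(x = c(0, 0.4, 0.6, 1),
                           s = c("A", "A", "B", "B")),
         model = mate_choice_model("broad", 10), n = 3e4),
    list(cand = data.frame(x = c(0.1, 0.5, 0.9),
                           s = c("A", "B", "B")),
         model = mate_choice_model("increasing", 8), n = 3e4)
  )
  for (p in pools) {
    var_t <- mean((p$cand$x - mean(p$cand$x))^2)
    P <- enumerate_mate_probabilities(p$cand, p$model, var_t = var_t)
    focal <- 1
    freq <- empirical_mate_freq(focal, p$cand, p$model, p$n, var_t = var_t)
    expect_lt(tv_distance(freq, P[focal, ]), 0.01)
    expect_equal(freq[focal], 0)  # no selfing
  }
})

test_that("founder exogamy probability approximates 1/(1 + alpha)", {
  set.seed(41)
  cand <- founder_pool(50, 50)
  for (kind in c("stationary", "broad", "social")) {
    alpha <- 4
    model <- mate_choice_model(kind, alpha)
    draws <- vapply(seq_len(2e4), function(i) {
      sample_mate(1, cand, model)  # focal is source 1
    }, integer(1))
    p_exo <- mean(cand$x[draws] == 0)
    expect_lt(abs(p_exo - 1 / (1 + alpha)), 0.015)
  }
})

test_that("stationary alpha=1 and random give bit-identical runs", {
  run <- function(kind) {
    cfg <- sim_config(N = 100, generations = 3, model = kind, alpha = 1,
                      map = mini_map(), seed = 99,
                      snapshot_generations = 3)
    run_simulation(cfg)
  }
  a <- run("stationary")
  b <- run("random")
  expect_identical(a$records, b$records)
  expect_identical(a$tracts, b$tracts)
  expect_identical(a$summary, b$summary)
})

test_that("sample_mate rejects degenerate candidate pools", {
  expect_error(sample_mate(1, data.frame(x = 0.5, s = "A"),
                           mate_choice_model("random")), "two")
})
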