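#' Exact mate-choice probabilities by enumeration
#'
#' Brute-force oracle for tiny populations: evaluates the model's kernel
#' for every ordered (focal, candidate) pair, zeroes the diagonal
#' (selfing is prohibited) and row-normalizes. Refuses populations larger
#' than `max_n` as a combinatorial guard.
#'
#' @param candidates Data frame with columns `x` (and `s` for the social
#'   kernel).
#' @param model A [mate_choice_model()].
#' @param var_t,var0 Variance inputs for the increasing kernel.
#' @param max_n Guard on population size (default 6).
#' @return An `n x n` matrix; row `i` holds the exact probability that
#'   focal `i` chooses each candidate.
#' @examples
#' pop <- data.frame(x = c(1, 1, 0), s = c("A", "A", "B"))
#' enumerate_mate_probabilities(pop, mate_choice_model("stationary", 4))
#' @export
enumerate_mate_probabilities <- function(candidates, model, var_t = NULL,
                                         var0 = 0.25, max_n = 6) {
  n <- nrow(candidates)
  if (n < 2) stop("need at least two candidates", call. = FALSE)
  if (n > max_n) {
    stop(sprintf("population of %d exceeds the enumeration guard (%d)",
                 n, max_n), call. = FALSE)
  }
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- mating_weights(model, candidates[i, , drop = FALSE], candidates,
                        var_t = var_t, var0 = var0)
    w[i] <- 0
    P[i, ] <- w / sum(w)
  }
  P
}

#' Expected mate correlation for symmetric binary ancestries
#'
#' Closed-form oracle for the founder generation: with `x` binary at equal
#' frequency on both margins and probability `p_same` that a pair is
#' same-source, the Pearson correlation is `2 * p_same - 1`. Under any
#' kernel with strength `alpha` at founding, `p_same = alpha/(alpha + 1)`,
#' giving a correlation of `(alpha - 1)/(alpha + 1)`.
#'
#' @param p_same Probability that a mating pair is endogamous.
#' @return Expected correlation in `[-1, 1]`.
#' @examples
#' binary_pair_correlation(0.75)  # 0.5 (alpha = 3)
#' @export
binary_pair_correlation <- function(p_same) {
  stopifnot(p_same >= 0, p_same <= 1)
  2 * p_same - 1
}
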