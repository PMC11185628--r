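#' Convert admixed-offspring fraction to mating-bias strength
#'
#' All mate-choice models share a strength parameter \eqn{\alpha}, defined
#' through the first-generation admixed-offspring fraction `A`:
#' \eqn{\alpha = 1/A - 1}. At founding an individual is \eqn{\alpha} times
#' more likely to choose a mate from its own source population than from
#' the other; `A = 0.5` gives \eqn{\alpha = 1} (random mating), `A = 1`
#' gives \eqn{\alpha = 0} (exclusive exogamy).
#'
#' @param A Admixed-offspring fraction in `(0, 1]`.
#' @return \eqn{\alpha \ge 0}.
#' @examples
#' alpha_from_admixed_fraction(0.5)  # 1: random mating
#' alpha_from_admixed_fraction(0.2)  # 4
#' @export
alpha_from_admixed_fraction <- function(A) {
  if (!is.numeric(A) || any(!is.finite(A)) || any(A <= 0) || any(A > 1)) {
    stop("`A` must be in (0, 1]", call. = FALSE)
  }
  1 / A - 1
}

#' Mate-choice models
#'
#' Constructs one of the five mating kernels. `"random"` ignores ancestry
#' and group entirely (and therefore requires `alpha = 1`). The three
#' ancestry-similarity kernels weight candidate `j` for focal `i` by:
#' \describe{
#'   \item{stationary}{\eqn{\psi = e^{-c|x_i-x_j|}} with \eqn{c = \ln\alpha};
#'     selectiveness per unit \eqn{|\Delta x|} is constant over time.}
#'   \item{increasing}{the stationary exponent rescaled each generation by
#'     the current ancestry variance, \eqn{\psi =
#'     e^{-(\ln\alpha)\,\sigma_x^2(0)/\sigma_x^2(t)\,|\Delta x|}}, so
#'     selectiveness grows as the population homogenizes; at `t = 0` it
#'     coincides with the stationary kernel.}
#'   \item{broad}{Gaussian, \eqn{\psi \propto e^{-(x_i-x_j)^2/(2\sigma^2)}}
#'     with \eqn{\sigma^2 = 1/(2\ln\alpha)}, the unique width giving an
#'     endogamy:exogamy weight ratio of exactly \eqn{\alpha} at founding.}
#' }
#' The `"social"` kernel depends only on group membership:
#' \eqn{\psi = 1 - 1/(\alpha+1)} within group, \eqn{1/(\alpha+1)} between,
#' a within:between ratio of exactly \eqn{\alpha}.
#'
#' With `alpha = 1` every kernel reduces exactly to uniform weights.
#'
#' @param kind One of `"random"`, `"stationary"`, `"increasing"`,
#'   `"broad"`, `"social"`.
#' @param alpha Strength \eqn{\alpha \ge 1} (this package targets
#'   positive assortment).
#' @return An object of class `mate_choice_model`.
#' @examples
#' mate_choice_model("stationary", alpha = 10)
#' @export
mate_choice_model <- function(kind = c("random", "stationary", "increasing",
                                       "broad", "social"),
                              alpha = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < 1) {
    stop("`alpha` must be a single number >= 1", call. = FALSE)
  }
  if (kind == "random" && alpha != 1) {
    stop("`kind = \"random\"` requires alpha = 1; ",
         "use an explicit kernel for biased mating", call. = FALSE)
  }
  structure(
    list(
      kind = kind,
      alpha = alpha,
      kind_code = match(kind, c("random", "stationary", "increasing",
                                "broad", "social")) - 1L
    ),
    class = "mate_choice_model"
  )
}

#' @export
print.mate_choice_model <- function(x, ...) {
  cat(sprintf("<mate_choice_model> kind=%s alpha=%g\n", x$kind, x$alpha))
  invisible(x)
}

#' Mating-weight kernels
#'
#' Scalar/vectorized weight functions behind [mate_choice_model()]. See
#' that help page for the functional forms.
#'
#' @param xi,xj Global ancestry proportions in `[0, 1]`.
#' @param alpha Strength parameter (>= 1 except where noted).
#' @return Non-negative mating weights, recycled to the common length.
#' @examples
#' stationary_weight(0, 1, alpha = 10)  # 0.1
#' social_weight("A", "B", alpha = 4)   # 0.2
#' @export
stationary_weight <- function(xi, xj, alpha) {
  check_ancestry(xi, xj)
  check_alpha(alpha, min = 1)
  exp(-log(alpha) * abs(xi - xj))
}

#' @rdname stationary_weight
#' @param var_t Ancestry variance \eqn{\sigma_x^2(t)} of the current
#'   generation (>= 0). A degenerate population (`var_t = 0`) falls back to
#'   uniform weights, the limiting behaviour.
#' @param var0 Reference founder variance \eqn{\sigma_x^2(0)} (> 0);
#'   0.25 for equal founder contributions.
#' @export
increasing_weight <- function(xi, xj, alpha, var_t, var0 = 0.25) {
  check_ancestry(xi, xj)
  check_alpha(alpha, min = 1)
  if (!is.numeric(var_t) || length(var_t) != 1 || !is.finite(var_t) ||
      var_t < 0) {
    stop("`var_t` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(var0) || length(var0) != 1 || !is.finite(var0) ||
      var0 <= 0) {
    stop("`var0` must be a single positive number", call. = FALSE)
  }
  if (var_t == 0 || alpha == 1) {
    return(rep(1, length(abs(xi - xj))))
  }
  exp(-(log(alpha) * var0 / var_t) * abs(xi - xj))
}

#' @rdname stationary_weight
#' @export
broad_weight <- function(xi, xj, alpha) {
  check_ancestry(xi, xj)
  check_alpha(alpha, min = 1)
  if (alpha == 1) {
    return(rep(1, length(xi - xj)))
  }
  # sigma^2 = 1/(2 ln alpha); the Gaussian normalizing constant is dropped
  # since weights are renormalized at sampling
  exp(-(xi - xj)^2 * log(alpha))
}

#' @rdname stationary_weight
#' @param si,sj Social group labels, `"A"`/`"B"` (or 1/2).
#' @export
social_weight <- function(si, sj, alpha) {
  si <- normalize_group(si)
  sj <- normalize_group(sj)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < 0) {
    stop("`alpha` must be a single number >= 0", call. = FALSE)
  }
  ifelse(si == sj, 1 - 1 / (alpha + 1), 1 / (alpha + 1))
}

check_ancestry <- function(xi, xj) {
  if (any(!is.finite(c(xi, xj))) || any(c(xi, xj) < 0) ||
      any(c(xi, xj) > 1)) {
    stop("ancestry proportions must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

check_alpha <- function(alpha, min = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < min) {
    stop(sprintf("`alpha` must be a single number >= %g", min),
         call. = FALSE)
  }
  invisible(TRUE)
}

normalize_group <- function(s) {
  if (is.numeric(s)) {
    if (any(!s %in% c(1, 2))) stop("unknown group label", call. = FALSE)
    return(c("A", "B")[s])
  }
  s <- as.character(s)
  if (any(!s %in% c("A", "B"))) stop("unknown group label", call. = FALSE)
  s
}

#' Mating weights of a focal individual over a candidate pool
#'
#' Evaluates the model's kernel for one focal individual against every
#' candidate (including the focal itself; exclude it when sampling).
#'
#' @param model A [mate_choice_model()].
#' @param focal A list or one-row data frame with `x` (and `s` for the
#'   social kernel).
#' @param candidates Data frame with columns `x` (and `s`).
#' @param var_t,var0 Current and founder ancestry variance, used only by
#'   the increasing kernel.
#' @return Numeric vector of weights, one per candidate.
#' @export
mating_weights <- function(model, focal, candidates, var_t = NULL,
                           var0 = 0.25) {
  stopifnot(inherits(model, "mate_choice_model"))
  n <- nrow(candidates)
  switch(model$kind,
    random = rep(1, n),
    stationary = stationary_weight(focal$x, candidates$x, model$alpha),
    increasing = {
      if (is.null(var_t)) {
        var_t <- mean((candidates$x - mean(candidates$x))^2)
      }
      increasing_weight(focal$x, candidates$x, model$alpha, var_t, var0)
    },
    broad = broad_weight(focal$x, candidates$x, model$alpha),
    social = social_weight(rep(focal$s, n), candidates$s, model$alpha)
  )
}

#' Sample a mate proportional to mating weight
#'
#' Draws one candidate other than the focal individual with probability
#' proportional to the model's kernel; selfing is excluded and the
#' remaining weights renormalized.
#'
#' @param focal Index of the focal individual within `candidates`.
#' @param candidates Data frame with columns `x` (and `s` for the social
#'   kernel); at least two rows.
#' @param model A [mate_choice_model()].
#' @inheritParams mating_weights
#' @return The index of the sampled mate (never equal to `focal`).
#' @export
sample_mate <- function(focal, candidates, model, var_t = NULL,
                        var0 = 0.25) {
  n <- nrow(candidates)
  if (n < 2) stop("need at least two candidates", call. = FALSE)
  stopifnot(focal >= 1, focal <= n)
  w <- mating_weights(model, candidates[focal, , drop = FALSE], candidates,
                      var_t = var_t, var0 = var0)
  w[focal] <- 0
  sample.int(n, size = 1, prob = w)
}
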