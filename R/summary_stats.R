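#' Mate-pair ancestry correlation
#'
#' Pearson correlation of `(xi, xj)` over the ordered mating events of one
#' generation (one record per child). Ordered records are the primary
#' statistic; `symmetrized = TRUE` appends each pair with roles swapped,
#' as a cross-check (parent roles are exchangeable here).
#'
#' @param records Mating records with columns `xi`, `xj`.
#' @param symmetrized Duplicate records with roles swapped before
#'   correlating.
#' @return The correlation, or `NA` (with a message attribute) when either
#'   margin is degenerate.
#' @export
mate_correlation <- function(records, symmetrized = FALSE) {
  xi <- records$xi
  xj <- records$xj
  if (symmetrized) {
    tmp <- c(xi, xj)
    xj <- c(xj, xi)
    xi <- tmp
  }
  if (length(xi) < 2 || var(xi) == 0 || var(xj) == 0) {
    return(structure(NA_real_, reason = "degenerate margin"))
  }
  cor(xi, xj)
}

#' Permutation test for the mate correlation
#'
#' Permutes the parent-2 column of the mating records `n_perm` times and
#' recomputes the correlation, giving the empirical null of random pair
#' formation with the observed ancestry margins. The one-sided p-value is
#' `(1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`; an observed correlation
#' exceeding every one of 1,000 permutations therefore gives p < 0.001.
#'
#' @param records Mating records with columns `xi`, `xj`.
#' @param n_perm Number of permutations (default 1000).
#' @param alternative `"greater"` (positive assortment, the default) or
#'   `"two.sided"` (on `|r|`).
#' @return A list with `p_value`, `r_obs`, and the vector `r_perm`.
#' @export
permutation_test <- function(records, n_perm = 1000,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(n_perm) || n_perm < 1) {
    stop("`n_perm` must be >= 1", call. = FALSE)
  }
  r_obs <- mate_correlation(records)
  n <- nrow(records)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    xj <- records$xj[sample.int(n)]
    suppressWarnings(cor(records$xi, xj))
  }, numeric(1))
  p <- if (alternative == "greater") {
    (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (n_perm + 1)
  } else {
    (1 + sum(abs(r_perm) >= abs(r_obs), na.rm = TRUE)) / (n_perm + 1)
  }
  list(p_value = p, r_obs = r_obs, r_perm = r_perm)
}

#' Ancestry variance across individuals
#'
#' Population variance (divide by N) of global ancestry proportion,
#' \eqn{\sigma_x^2(t)}. For founders with equal contributions this is
#' 0.25.
#'
#' @param x Numeric vector of ancestry proportions, or an
#'   `admix_population`.
#' @return \eqn{\sigma_x^2 \ge 0}.
#' @export
ancestry_variance <- function(x) {
  if (inherits(x, "admix_population")) x <- x$x
  if (length(x) < 2) stop("need at least two individuals", call. = FALSE)
  mean((x - mean(x))^2)
}

#' Fraction of admixed individuals
#'
#' Individuals whose global ancestry proportion is strictly between 0 and
#' 1. In generation 1 post-admixture this equals the fraction of
#' exogamous mating events, the quantity that calibrates `alpha`.
#'
#' @inheritParams ancestry_variance
#' @return Fraction in `[0, 1]`.
#' @export
admixed_fraction <- function(x) {
  if (inherits(x, "admix_population")) x <- x$x
  mean(x > 0 & x < 1)
}

#' Binned density of mating pairs
#'
#' Two-dimensional binned counts of `(xi, xj)` over `[0,1]^2`, rescaled so
#' the maximum cell equals 1. The default is a hexagonal lattice of pitch
#' `binwidth`; `geometry = "square"` uses a regular grid with the same
#' pitch (visually equivalent and exactly testable). Optionally subsamples
#' records first (studies of mating structure often display n = 100
#' pairs).
#'
#' @param records Mating records with columns `xi`, `xj`.
#' @param binwidth Bin pitch in ancestry units (default 0.025).
#' @param geometry `"hex"` or `"square"`.
#' @param subsample If non-`NULL`, sample this many records (without
#'   replacement) before binning.
#' @return For `"square"`, a matrix of scaled densities with bin-center
#'   dimnames (`xi` in rows). For `"hex"`, a data frame with `cx`, `cy`,
#'   `count`, `density`.
#' @export
hexbin_density <- function(records, binwidth = 0.025,
                           geometry = c("hex", "square"),
                           subsample = NULL) {
  geometry <- match.arg(geometry)
  if (!is.numeric(binwidth) || binwidth <= 0) {
    stop("`binwidth` must be positive", call. = FALSE)
  }
  xi <- records$xi
  xj <- records$xj
  if (!is.null(subsample) && subsample < length(xi)) {
    keep <- sample.int(length(xi), subsample)
    xi <- xi[keep]
    xj <- xj[keep]
  }
  if (geometry == "square") {
    brk <- seq(0, 1 + binwidth, by = binwidth)
    bi <- findInterval(xi, brk, rightmost.closed = FALSE)
    bj <- findInterval(xj, brk, rightmost.closed = FALSE)
    nb <- length(brk) - 1
    m <- matrix(0, nb, nb)
    for (k in seq_along(bi)) m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1
    centers <- brk[-length(brk)] + binwidth / 2
    dimnames(m) <- list(xi = signif(centers, 6), xj = signif(centers, 6))
    keep_rc <- seq_len(ceiling(1 / binwidth) + 1)
    m <- m[keep_rc, keep_rc, drop = FALSE]
    return(m / max(m))
  }
  # pointy-top hex lattice: horizontal pitch = binwidth, row height =
  # binwidth * sqrt(3)/2, odd rows offset half a pitch; each point goes to
  # the nearest of four candidate centers
  h <- binwidth * sqrt(3) / 2
  rows <- cbind(floor(xj / h), floor(xj / h) + 1)
  best_d <- rep(Inf, length(xi))
  best_cx <- best_cy <- numeric(length(xi))
  for (rcand in 1:2) {
    ry <- rows[, rcand]
    offset <- ifelse(ry %% 2 == 0, 0, binwidth / 2)
    for (ccand in 0:1) {
      cx <- (floor((xi - offset) / binwidth) + ccand) * binwidth + offset
      cy <- ry * h
      d <- (xi - cx)^2 + (xj - cy)^2
      upd <- d < best_d
      best_d[upd] <- d[upd]
      best_cx[upd] <- cx[upd]
      best_cy[upd] <- cy[upd]
    }
  }
  key <- paste(signif(best_cx, 10), signif(best_cy, 10))
  tab <- table(key)
  first <- !duplicated(key)
  lut <- data.frame(key = key[first], cx = best_cx[first], cy = best_cy[first])
  out <- merge(lut, data.frame(key = names(tab), count = as.integer(tab)),
               by = "key")
  out$density <- out$count / max(out$count)
  out[order(-out$count), c("cx", "cy", "count", "density")]
}

#' Distribution of mate-pair ancestry differences
#'
#' Summaries of \eqn{\Delta x = |x_i - x_j|} over the mating events of a
#' generation.
#'
#' @param records Mating records with columns `xi`, `xj`.
#' @param probs Quantile probabilities.
#' @param binwidth Histogram bin width.
#' @return A list with `delta` (the raw values), `mean`, `quantiles`, and
#'   `histogram` (data frame of bin mids and counts).
#' @export
delta_x_distribution <- function(records,
                                 probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                 binwidth = 0.025) {
  d <- abs(records$xi - records$xj)
  brk <- seq(0, 1, by = binwidth)
  if (max(brk) < 1) brk <- c(brk, 1)
  cnt <- tabulate(pmin(findInterval(d, brk, rightmost.closed = TRUE),
                       length(brk) - 1),
                  nbins = length(brk) - 1)
  list(
    delta = d,
    mean = mean(d),
    quantiles = quantile(d, probs = probs, names = TRUE),
    histogram = data.frame(mid = brk[-length(brk)] + diff(brk) / 2,
                           count = cnt)
  )
}

#' Fraction of mating events between new migrants
#'
#' Events in which both parents carry the migrant flag. Under random
#' mating with migrant fraction `p` the expectation is approximately
#' `p^2`; a rising excess over that expectation signals that migrants
#' preferentially pair with one another.
#'
#' @param records Mating records with columns `migrant_i`, `migrant_j`.
#' @return A list with `fraction`, the parental `migrant_fraction`, and
#'   `random_expectation` (its square).
#' @export
migrant_mating_fraction <- function(records) {
  frac <- mean(records$migrant_i & records$migrant_j)
  p <- mean(records$migrant_i)  # parent 1 is a uniform draw
  list(fraction = frac, migrant_fraction = p, random_expectation = p^2)
}

#' Association between social group and ancestry
#'
#' Difference in mean global ancestry proportion between groups A and B.
#' It is 1 at founding (groups coincide with sources) and is expected to
#' decay toward 0 as group membership, inherited from parent 1 alone,
#' decouples from genetic ancestry.
#'
#' @param pop An `admix_population`, or a data frame with columns `x` and
#'   `s`.
#' @return `mean(x | s = "A") - mean(x | s = "B")`, or `NA` if either
#'   group is extinct.
#' @export
group_ancestry_association <- function(pop) {
  if (inherits(pop, "admix_population")) pop <- pop_individuals(pop)
  a <- pop$x[pop$s == "A"]
  b <- pop$x[pop$s == "B"]
  if (length(a) == 0 || length(b) == 0) {
    return(structure(NA_real_, reason = "group extinct"))
  }
  mean(a) - mean(b)
}

#' Interior-valley bimodality summary
#'
#' Heuristic check for a bimodal ancestry distribution: the histogram's
#' maximum bin within `[0.4, 0.6]` must be less than half of each flanking
#' mode's maximum bin.
#'
#' @inheritParams ancestry_variance
#' @param binwidth Histogram bin width (default 0.05).
#' @return A list with `bimodal` (logical), `valley`, `mode_left`,
#'   `mode_right`.
#' @export
ancestry_bimodality <- function(x, binwidth = 0.05) {
  if (inherits(x, "admix_population")) x <- x$x
  brk <- seq(0, 1, by = binwidth)
  if (max(brk) < 1) brk <- c(brk, 1)
  cnt <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE),
                       length(brk) - 1),
                  nbins = length(brk) - 1)
  mid <- brk[-length(brk)] + diff(brk) / 2
  valley <- max(cnt[mid >= 0.4 & mid <= 0.6])
  mode_left <- max(cnt[mid < 0.4])
  mode_right <- max(cnt[mid > 0.6])
  list(
    bimodal = valley < 0.5 * mode_left && valley < 0.5 * mode_right,
    valley = valley, mode_left = mode_left, mode_right = mode_right
  )
}

#' Per-generation statistics row
#'
#' Builds one summary row from a stepped population and its mating
#' records: mate correlation, ancestry variance, admixed fraction,
#' migrant-mating fraction and group-ancestry association (plus a
#' permutation p-value when `n_perm > 0`).
#'
#' @param pop The offspring `admix_population` of generation `t`.
#' @param records The generation's mating records.
#' @param n_perm Permutations for the mate-correlation test (0 to skip).
#' @return A one-row data frame.
#' @export
generation_stats <- function(pop, records, n_perm = 0) {
  row <- data.frame(
    t = pop$t,
    r = as.numeric(mate_correlation(records)),
    sigma2 = ancestry_variance(pop),
    admixed_fraction = admixed_fraction(pop),
    migrant_mating_fraction = migrant_mating_fraction(records)$fraction,
    group_assoc = as.numeric(group_ancestry_association(pop))
  )
  if (n_perm > 0) {
    row$perm_p <- permutation_test(records, n_perm = n_perm)$p_value
  }
  row
}
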