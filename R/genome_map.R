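#' The 22-autosome genome map
#'
#' Coordinate system for the simulated diploid genome: 22 independently
#' segregating chromosomes with a uniform per-bp, per-generation
#' recombination rate. With the defaults (total length 2.88 Gb,
#' `recomb_rate = 1e-8`) 1 cM corresponds to 1 Mb, the unit conversion used
#' throughout reporting.
#'
#' The default chromosome lengths are the GRCh38 autosome lengths linearly
#' rescaled so they sum to exactly 2.88e9 bp (the per-chromosome vector is
#' configurable; only totals enter most expectations).
#'
#' @param chrom_lengths Integer-valued vector of chromosome lengths in bp.
#'   Defaults to [default_chrom_lengths()].
#' @param recomb_rate Uniform recombination probability per bp per
#'   generation. Default `1e-8`.
#'
#' @return An object of class `genome_map`: a list with elements
#'   `chrom_lengths`, `L` (total bp) and `recomb_rate`.
#' @examples
#' map <- genome_map()
#' map$L                     # 2.88e9
#' map$L * map$recomb_rate   # genetic map length in Morgans: 28.8
#' @export
genome_map <- function(chrom_lengths = default_chrom_lengths(),
                       recomb_rate = 1e-8) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) < 1 ||
      any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("`chrom_lengths` must be positive finite numbers", call. = FALSE)
  }
  if (any(chrom_lengths != round(chrom_lengths))) {
    stop("`chrom_lengths` must be whole numbers of bp", call. = FALSE)
  }
  if (!is.numeric(recomb_rate) || length(recomb_rate) != 1 ||
      !is.finite(recomb_rate) || recomb_rate < 0) {
    stop("`recomb_rate` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(
      chrom_lengths = as.numeric(chrom_lengths),
      L = sum(as.numeric(chrom_lengths)),
      recomb_rate = recomb_rate
    ),
    class = "genome_map"
  )
}

#' Default human autosome lengths rescaled to 2.88 Gb
#'
#' GRCh38 autosome lengths (chr1-chr22) linearly rescaled so that the total
#' is exactly `total` bp.
#'
#' @param total Target total genome length in bp (default 2.88e9).
#' @return Numeric vector of 22 whole-number chromosome lengths summing to
#'   exactly `total`.
#' @export
default_chrom_lengths <- function(total = 2.88e9) {
  grch38 <- c(
    248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
    159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
    114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
    58617616, 64444167, 46709983, 50818468
  )
  scaled <- round(grch38 * total / sum(grch38))
  # absorb the rounding residual into chr1 so the sum is exact
  scaled[1] <- scaled[1] + (total - sum(scaled))
  scaled
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf(
    "<genome_map> %d chromosomes, L = %.4g bp, r = %g /bp/gen (%.3g Morgans)\n",
    length(x$chrom_lengths), x$L, x$recomb_rate, x$L * x$recomb_rate
  ))
  invisible(x)
}

#' Convert physical length to genetic length
#'
#' Under the uniform map, genetic length is `bp * recomb_rate` Morgans;
#' with the defaults 1 Mb = 1 cM.
#'
#' @param bp Lengths in bp.
#' @param map A [genome_map()].
#' @return `bp_to_morgans()`: lengths in Morgans. `bp_to_cM()`: lengths in
#'   centimorgans.
#' @export
bp_to_morgans <- function(bp, map = genome_map()) {
  bp * map$recomb_rate
}

#' @rdname bp_to_morgans
#' @export
bp_to_cM <- function(bp, map = genome_map()) {
  100 * bp * map$recomb_rate
}
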