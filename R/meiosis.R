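#' Draw crossover positions along a chromosome
#'
#' Crossover count is Poisson with mean `chrom_length * r`, positions i.i.d.
#' uniform on `[0, chrom_length)`, floored to integer bp; returned sorted
#' and deduplicated. No crossover interference is modelled, consistent with
#' a uniform recombination rate.
#'
#' @param chrom_length Chromosome length in bp (> 0).
#' @param r Per-bp per-generation recombination probability (>= 0).
#' @return Sorted numeric vector of distinct crossover positions (possibly
#'   empty).
#' @examples
#' set.seed(1)
#' draw_crossovers(1e8, 1e-8)  # on average one crossover
#' @export
draw_crossovers <- function(chrom_length, r) {
  if (!is.numeric(chrom_length) || length(chrom_length) != 1 ||
      !is.finite(chrom_length) || chrom_length <= 0) {
    stop("`chrom_length` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0) {
    stop("`r` must be a single non-negative number", call. = FALSE)
  }
  cpp_draw_crossovers(chrom_length, r)
}

# tract-set data frame -> the per-chromosome list layout the C++ core uses
hap_to_cpp <- function(tracts, map) {
  C <- length(map$chrom_lengths)
  ends <- vector("list", C)
  src1 <- integer(C)
  for (c_idx in seq_len(C)) {
    tr <- tracts[tracts$chrom == c_idx, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    ends[[c_idx]] <- as.numeric(tr$end)
    src1[c_idx] <- as.integer(tr$source[1])
  }
  list(ends = ends, src1 = src1)
}

cpp_to_hap <- function(hap) {
  C <- length(hap$ends)
  parts <- lapply(seq_len(C), function(c_idx) {
    e <- hap$ends[[c_idx]]
    k <- length(e)
    data.frame(
      chrom = c_idx,
      start = c(0, e[-k]),
      end = e,
      source = ((hap$src1[c_idx] - 1 + seq_len(k) - 1) %% 2) + 1
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Meiosis: produce one gamete from a parent
#'
#' Per chromosome the starting haplotype is chosen by a fair coin
#' (independent assortment), then haplotypes alternate at each crossover
#' drawn as in [draw_crossovers()]. The gamete's tracts exactly tile every
#' chromosome and are maximally merged; its expected source-1 fraction
#' equals the parent's global ancestry proportion.
#'
#' @param parent An `admix_individual` (or list with `hap1`/`hap2`
#'   tract-set data frames).
#' @param map A [genome_map()].
#' @return A tract-set data frame for the gamete haplotype.
#' @examples
#' map <- genome_map(chrom_lengths = c(5e7, 5e7))
#' parent <- founder_individual(map, source = 1)
#' set.seed(1)
#' gam <- meiosis(parent, map)
#' all(gam$source == 1)
#' @export
meiosis <- function(parent, map) {
  validate_tracts(parent$hap1, map)
  validate_tracts(parent$hap2, map)
  res <- cpp_meiosis(
    hap_to_cpp(parent$hap1, map), hap_to_cpp(parent$hap2, map),
    map$chrom_lengths, map$recomb_rate
  )
  cpp_to_hap(res)
}
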