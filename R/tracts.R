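#' Local-ancestry tract sets and individuals
#'
#' A haplotype is represented as a *tract set*: a data frame with columns
#' `chrom` (1-based chromosome index), `start`, `end` (bp, 0-based
#' half-open) and `source` (1 or 2), whose intervals exactly tile every
#' chromosome, are sorted, and are maximally merged (no two adjacent tracts
#' share a source). An *individual* bundles two haplotypes with its global
#' ancestry proportion `x`, social group `s` ("A" or "B"), migrant flag and
#' id.
#'
#' @param map A [genome_map()].
#' @param source Founder source population, 1 or 2.
#' @name tract_set
NULL

#' Single-source founder haplotype
#'
#' @inheritParams tract_set
#' @return A tract-set data frame with one tract per chromosome.
#' @export
founder_tracts <- function(map, source) {
  stopifnot(source %in% c(1, 2))
  data.frame(
    chrom = seq_along(map$chrom_lengths),
    start = 0,
    end = map$chrom_lengths,
    source = as.integer(source)
  )
}

#' Construct a founder individual
#'
#' Founders carry a single tract per chromosome and `x` of exactly 0 or 1;
#' source-1 founders belong to social group "A", source-2 founders to "B".
#'
#' @inheritParams tract_set
#' @param id Opaque identifier.
#' @param is_migrant Logical migrant flag.
#' @return An object of class `admix_individual`.
#' @export
founder_individual <- function(map, source, id = NA_integer_,
                               is_migrant = FALSE) {
  hap <- founder_tracts(map, source)
  structure(
    list(
      hap1 = hap, hap2 = hap,
      x = if (source == 1) 1 else 0,
      s = if (source == 1) "A" else "B",
      is_migrant = isTRUE(is_migrant),
      id = id
    ),
    class = "admix_individual"
  )
}

#' Validate a tract set against its genome map
#'
#' Checks the tract-set invariants: sorted, non-overlapping intervals that
#' exactly tile `[0, chrom_length)` on every chromosome, and maximal
#' merging (no two adjacent tracts with the same source).
#'
#' @param tracts A tract-set data frame (`chrom`, `start`, `end`, `source`).
#' @param map A [genome_map()].
#' @param merged Also require maximal merging (default `TRUE`).
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_tracts <- function(tracts, map, merged = TRUE) {
  req <- c("chrom", "start", "end", "source")
  if (!all(req %in% names(tracts))) {
    stop("tract set must have columns chrom, start, end, source", call. = FALSE)
  }
  if (!all(tracts$source %in% c(1, 2))) {
    stop("tract sources must be 1 or 2", call. = FALSE)
  }
  for (c_idx in seq_along(map$chrom_lengths)) {
    tr <- tracts[tracts$chrom == c_idx, , drop = FALSE]
    if (nrow(tr) == 0) {
      stop(sprintf("chromosome %d has no tracts", c_idx), call. = FALSE)
    }
    tr <- tr[order(tr$start), , drop = FALSE]
    if (tr$start[1] != 0 ||
        tr$end[nrow(tr)] != map$chrom_lengths[c_idx] ||
        any(tr$end <= tr$start) ||
        (nrow(tr) > 1 && any(tr$start[-1] != tr$end[-nrow(tr)]))) {
      stop(sprintf("tracts do not tile chromosome %d", c_idx), call. = FALSE)
    }
    if (merged && nrow(tr) > 1 && any(tr$source[-1] == tr$source[-nrow(tr)])) {
      stop(sprintf("chromosome %d tracts are not maximally merged", c_idx),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Merge adjacent same-source tracts
#'
#' Collapses runs of adjacent tracts with the same source into maximal
#' tracts. Merging an already-merged tract set is the identity.
#'
#' @param tracts A tract-set data frame (sorted within chromosome).
#' @return The maximally merged tract-set data frame.
#' @export
merge_tracts <- function(tracts) {
  tracts <- tracts[order(tracts$chrom, tracts$start), , drop = FALSE]
  n <- nrow(tracts)
  if (n <= 1) {
    rownames(tracts) <- NULL
    return(tracts)
  }
  new_run <- c(TRUE, tracts$chrom[-1] != tracts$chrom[-n] |
                 tracts$source[-1] != tracts$source[-n])
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tracts$chrom[new_run],
    start = tracts$start[new_run],
    end = as.numeric(tapply(tracts$end, run, max)),
    source = tracts$source[new_run]
  )
  rownames(out) <- NULL
  out
}

#' Global ancestry proportion of an individual
#'
#' The proportion of the diploid genome derived from source population 1:
#' summed source-1 bp over both haplotypes divided by `2L`. Deterministic,
#' recomputable from the tracts at any time.
#'
#' @param ind An `admix_individual` (or a list with `hap1`/`hap2` tract-set
#'   data frames).
#' @param map A [genome_map()].
#' @return `x` in `[0, 1]`.
#' @export
global_ancestry <- function(ind, map) {
  validate_tracts(ind$hap1, map, merged = FALSE)
  validate_tracts(ind$hap2, map, merged = FALSE)
  bp1 <- sum(with(ind$hap1, end - start)[ind$hap1$source == 1])
  bp2 <- sum(with(ind$hap2, end - start)[ind$hap2$source == 1])
  (bp1 + bp2) / (2 * map$L)
}

#' Collect local-ancestry tract lengths
#'
#' Lengths (bp) of all maximally merged tracts of the requested source
#' across all haplotypes. Tracts abutting chromosome ends (length-censored)
#' are included, matching a naive extraction of tract tables.
#'
#' @param population An `admix_population`, a list of `admix_individual`s,
#'   or a tract table as returned by [population_tracts()].
#' @param source `1`, `2`, or `"both"` (default).
#' @return Numeric vector of tract lengths in bp.
#' @export
collect_tract_lengths <- function(population, source = "both") {
  tr <- as_tract_table(population)
  if (nrow(tr) == 0) stop("empty population", call. = FALSE)
  if (!identical(source, "both")) {
    stopifnot(source %in% c(1, 2))
    tr <- tr[tr$source == source, , drop = FALSE]
  }
  tr$end - tr$start
}

# normalize the accepted population-ish inputs to one tract table
as_tract_table <- function(population) {
  if (inherits(population, "admix_population")) {
    return(population_tracts(population))
  }
  if (is.data.frame(population)) {
    return(population)
  }
  if (is.list(population) && length(population) > 0) {
    parts <- lapply(seq_along(population), function(i) {
      ind <- population[[i]]
      h1 <- ind$hap1; h1$id <- i; h1$haplotype <- 1L
      h2 <- ind$hap2; h2$id <- i; h2$haplotype <- 2L
      rbind(h1, h2)
    })
    return(do.call(rbind, parts))
  }
  stop("cannot interpret `population` as tracts", call. = FALSE)
}

#' Write and read BED-like tract tables
#'
#' Six tab-separated columns without header: chrom (as `chr<i>`), start,
#' end (0-based half-open bp), source, individual id, haplotype.
#'
#' @param tracts Tract table with columns `chrom`, `start`, `end`,
#'   `source`, and optionally `id` and `haplotype`.
#' @param path Output file.
#' @return `write_tracts()`: `path`, invisibly. `read_tracts()`: the tract
#'   table with integer `chrom`.
#' @export
write_tracts <- function(tracts, path) {
  out <- data.table::data.table(
    chrom = paste0("chr", tracts$chrom),
    start = format(tracts$start, scientific = FALSE, trim = TRUE),
    end = format(tracts$end, scientific = FALSE, trim = TRUE),
    source = tracts$source,
    id = if ("id" %in% names(tracts)) tracts$id else NA_integer_,
    haplotype = if ("haplotype" %in% names(tracts)) tracts$haplotype else NA_integer_
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_tracts
#' @export
read_tracts <- function(path) {
  dt <- data.table::fread(
    path, sep = "\t", header = FALSE,
    col.names = c("chrom", "start", "end", "source", "id", "haplotype")
  )
  df <- as.data.frame(dt)
  df$chrom <- as.integer(sub("^chr", "", as.character(df$chrom)))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df
}

#' @export
print.admix_individual <- function(x, ...) {
  cat(sprintf(
    "<admix_individual> id=%s x=%.4f group=%s%s (%d+%d tracts)\n",
    as.character(x$id), x$x, x$s, if (x$is_migrant) " migrant" else "",
    nrow(x$hap1), nrow(x$hap2)
  ))
  invisible(x)
}
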