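#' Convenience plots
#'
#' Quick ggplot2 views of simulation results; the underlying tables are
#' the primary interface and these helpers are optional (ggplot2 is in
#' Suggests).
#'
#' @param summary A per-generation summary table (possibly with a
#'   `replicate` column), as in `admix_sim$summary` or
#'   `run_replicates()$summary`.
#' @return A ggplot object.
#' @export
plot_mate_correlation <- function(summary) {
  require_ggplot()
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = t, y = r))
  if ("replicate" %in% names(summary)) {
    p <- p + ggplot2::aes(group = replicate)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "generations post-admixture",
                  y = expression(r[x[i] * "," * x[j]]))
}

#' @rdname plot_mate_correlation
#' @param records Mating records with columns `xi`, `xj`.
#' @param binwidth Bin pitch (default 0.025).
#' @param subsample Optional subsample size before binning.
#' @export
plot_hexbin <- function(records, binwidth = 0.025, subsample = NULL) {
  require_ggplot()
  dens <- hexbin_density(records, binwidth = binwidth, geometry = "hex",
                         subsample = subsample)
  ggplot2::ggplot(dens, ggplot2::aes(x = cx, y = cy,
                                     fill = density)) +
    ggplot2::geom_tile(width = binwidth, height = binwidth * sqrt(3) / 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(x[i]), y = expression(x[j]),
                  fill = "scaled\ndensity")
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}
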