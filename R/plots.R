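#' Plot a coverage track with CIs
#'
#' Draws the normalized-coverage track for a locus: one point per bin with
#' its exact-Poisson 95% CI as an error bar, shaded by mean mapping score
#' (light = high, dark = low), with horizontal guides at 1.0 (diploid) and
#' 1.5 (clonal single-copy gain).
#'
#' @param bins \code{GRanges} of coverage bins.
#' @param highlight optional \code{GRanges} to shade (e.g. the gene body).
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotCoverageTrack <- function(bins, highlight = NULL, ...) {
  x <- (start(bins) + end(bins)) / 2
  y <- mcols(bins)$normCov
  mq <- mcols(bins)$meanMapq
  shade <- grDevices::grey(0.8 * pmin(1, pmax(0, ifelse(is.na(mq), 1, mq / 60))))
  plot(x, y, pch = 16, cex = 0.5, col = shade, xlab = "genomic position",
       ylab = "normalized coverage",
       ylim = c(0, max(mcols(bins)$ciHigh, 2, na.rm = TRUE)), ...)
  if (!is.null(highlight))
    graphics::rect(start(highlight), graphics::par("usr")[3], end(highlight),
                   graphics::par("usr")[4], col = grDevices::adjustcolor("gold", 0.2),
                   border = NA)
  graphics::segments(x, mcols(bins)$ciLow, x, mcols(bins)$ciHigh, col = shade)
  graphics::abline(h = c(1, 1.5), lty = c(1, 3), col = "steelblue")
  invisible(NULL)
}

#' Plot a phased BAF track
#'
#' Plots each heterozygous SNP's B-allele frequency coloured by the
#' inferred parental haplotype of its alternate allele; grey where phase is
#' unknown. A single-copy gain separates the colours into two bands around
#' 2/3 and 1/3 (at full purity).
#'
#' @param snps phase-annotated \code{GRanges} (\code{\link{phaseBafs}}).
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotBafTrack <- function(snps, ...) {
  cols <- c(A = "firebrick", B = "navy", unknown = "grey60")
  plot(start(snps), mcols(snps)$baf, pch = 16, cex = 0.7,
       col = cols[mcols(snps)$hapOfAlt], ylim = c(0, 1),
       xlab = "genomic position", ylab = "B-allele frequency", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(NULL)
}
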