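## Garwood exact 95% CI for a Poisson count (lower bound 0 when n = 0)
.poissonCI <- function(n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(n == 0, 0, stats::qchisq(a, 2 * n) / 2)
  hi <- stats::qchisq(1 - a, 2 * n + 2) / 2
  cbind(lo = lo, hi = hi)
}

## attach normalized coverage + CI + mapq to a GRanges of bins.
## norm_cov = n5prime / (bin_length * total_reads) * 3e9 (the standard
## genome-size rescaling so a diploid bin averages 1).
.coverageBinsFromCounts <- function(binsGR, n5, mapq, totalReads) {
  scale <- 3e9 / (width(binsGR) * totalReads)
  ci <- .poissonCI(n5)
  mcols(binsGR)$n5prime <- as.integer(n5)
  mcols(binsGR)$normCov <- n5 * scale
  mcols(binsGR)$ciLow <- as.numeric(ci[, "lo"]) * scale
  mcols(binsGR)$ciHigh <- as.numeric(ci[, "hi"]) * scale
  mcols(binsGR)$meanMapq <- mapq
  metadata(binsGR)$totalReads <- totalReads
  binsGR
}

#' Bin fragment starts into normalized coverage
#'
#' Tiles the locus left to right into bins of \code{binSize} bp (the last
#' bin may be shorter), counts fragment 5' ends per bin, and computes the
#' normalized coverage
#' \deqn{\mathrm{normCov} = \frac{n_{5'}}{\mathrm{bin\ length} \times \mathrm{total\ reads}} \times 3\times10^9,}
#' with a 95% CI obtained by rescaling the Garwood exact Poisson interval
#' on the raw count, and the mean mapping score of contributing fragments.
#' Fragment positions outside the locus are ignored (their number is
#' reported via \code{message}).
#'
#' @param fragmentStarts data.frame with columns \code{chrom}, \code{pos}
#'   (1-based 5'-most aligned base of read 1), \code{mapq}; or a
#'   \code{GRanges} with an mcol \code{mapq}.
#' @param locus \code{GRanges} of length 1.
#' @param binSize bin width, bp (>= 1).
#' @param totalReads sample-wide fragment count (>= 1), the normalization
#'   denominator.
#' @return \code{GRanges} of bins with mcols \code{n5prime}, \code{normCov},
#'   \code{ciLow}, \code{ciHigh}, \code{meanMapq};
#'   \code{metadata()$totalReads} records the denominator.
#' @export
binCoverage <- function(fragmentStarts, locus, binSize, totalReads) {
  stopifnot(binSize >= 1, totalReads >= 1, length(locus) == 1L)
  if (width(locus) < 1L) stop("empty locus")
  if (is(fragmentStarts, "GRanges")) {
    fragmentStarts <- data.frame(chrom = as.character(seqnames(fragmentStarts)),
                                 pos = start(fragmentStarts),
                                 mapq = mcols(fragmentStarts)$mapq)
  }
  inside <- fragmentStarts$chrom == as.character(seqnames(locus)) &
            fragmentStarts$pos >= start(locus) & fragmentStarts$pos <= end(locus)
  nOut <- sum(!inside)
  if (nOut > 0) message(nOut, " fragment start(s) outside locus ignored")
  fr <- fragmentStarts[inside, , drop = FALSE]

  starts <- seq(start(locus), end(locus), by = binSize)
  ends <- pmin(starts + binSize - 1L, end(locus))
  binIdx <- findInterval(fr$pos, starts)
  n5 <- tabulate(binIdx, nbins = length(starts))
  mapq <- rep(NA_real_, length(starts))
  if (nrow(fr))
    mapq[sort(unique(binIdx))] <- as.numeric(tapply(fr$mapq, binIdx, mean))
  binsGR <- GRanges(seqnames(locus), IRanges(starts, ends))
  .coverageBinsFromCounts(binsGR, n5, mapq, totalReads)
}

#' Ratio of mean normalized coverage: target vs flanks
#'
#' Quantifies the coverage step of a focal gain: the mean normalized
#' coverage over bins in the target region divided by the mean over
#' flanking bins. Expected 1.0 with no gain and 1.5 for a clonal
#' single-copy gain on a diploid background. The 95% CI is propagated from
#' the underlying Poisson counts by conditioning on the count total
#' (exact binomial interval on the target share, transformed to the odds
#' scale and corrected for the two regions' total bin lengths).
#'
#' Bins whose mean mapping score is below \code{mapqFloor} are excluded
#' from both sides before the ratio is formed.
#'
#' @param binsInTarget,binsFlanking non-empty \code{GRanges} of coverage
#'   bins as produced by \code{\link{binCoverage}}.
#' @param mapqFloor mapping-score floor; bins below it are dropped.
#' @return named numeric: \code{estimate}, \code{ciLow}, \code{ciHigh}.
#' @export
coverageRatio <- function(binsInTarget, binsFlanking, mapqFloor = 0) {
  if (length(binsInTarget) == 0L || length(binsFlanking) == 0L)
    stop("both bin sets must be non-empty")
  keepT <- is.na(mcols(binsInTarget)$meanMapq) |
           mcols(binsInTarget)$meanMapq >= mapqFloor
  keepF <- is.na(mcols(binsFlanking)$meanMapq) |
           mcols(binsFlanking)$meanMapq >= mapqFloor
  tgt <- binsInTarget[keepT]
  flk <- binsFlanking[keepF]
  if (length(tgt) == 0L || length(flk) == 0L)
    stop("no bins left after mapping-score filtering")
  Tn <- sum(mcols(tgt)$n5prime)
  Fn <- sum(mcols(flk)$n5prime)
  if (Fn == 0) stop("zero flanking coverage: ratio undefined")
  wT <- sum(width(tgt))
  wF <- sum(width(flk))
  est <- (Tn / wT) / (Fn / wF)
  ## conditional on Tn + Fn, Tn ~ Binom(Tn + Fn, p); ratio = odds(p) * wF/wT
  ci <- stats::binom.test(Tn, Tn + Fn)$conf.int
  c(estimate = est,
    ciLow = ci[1] / (1 - ci[1]) * wF / wT,
    ciHigh = ci[2] / (1 - ci[2]) * wF / wT)
}
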