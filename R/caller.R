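#' Call a focal single-copy gain for one gene
#'
#' Fuses the two evidence channels for the assayed gene: the coverage ratio
#' of target bins over flanking bins (\code{\link{coverageRatio}}) and the
#' phased-BAF split with its permutation p-value
#' (\code{\link{bafSplitStatistic}}). Sensitivity depends on heterozygous
#' SNPs being present in the footprint, so samples whose het-SNP count does
#' not exceed \code{snpInformativeThreshold} (strictly) are returned as
#' "uninformative" — the evidence channels are still computed and stored so
#' the call can be re-gated at other thresholds without re-running them
#' (\code{\link{cohortInformativeness}}).
#'
#' Under the default AND rule a gain requires a coverage-ratio point
#' estimate above 1 and a BAF-split p-value at or below \code{alpha}; with
#' \code{requireBothChannels = FALSE} either a coverage CI excluding 1
#' (above) or a significant split suffices.
#'
#' @param bins \code{GRanges} of coverage bins spanning the gene and its
#'   flanks (\code{\link{binCoverage}}).
#' @param phasedSnps phase-annotated het SNPs (\code{\link{phaseBafs}}).
#' @param gene \code{GRanges} of length 1, the gene body; the BAF evidence
#'   channel uses the SNPs inside it and the flanking bins form the
#'   coverage-ratio denominator.
#' @param config a \code{\link{CallerConfig}}.
#' @param footprint \code{GRanges} of length 1, the assayed footprint over
#'   which het SNPs are counted for informativeness (the gene plus
#'   adjacent targeted intergenic regions). Defaults to the span of
#'   \code{bins}.
#' @param nPerms,seed permutation settings for the BAF channel.
#' @return a \code{\link{GainCall}}.
#' @export
callGain <- function(bins, phasedSnps, gene, config = CallerConfig(),
                     footprint = NULL, nPerms = 500L, seed = 1L) {
  validObject(config)
  stopifnot(length(gene) == 1L)
  if (is.null(footprint)) footprint <- range(granges(bins))
  inGene <- IRanges::overlapsAny(phasedSnps, gene)
  n <- sum(IRanges::overlapsAny(phasedSnps, footprint))
  inform <- n > config@snpInformativeThreshold

  binIn <- bins[IRanges::overlapsAny(bins, gene)]
  binOut <- bins[!IRanges::overlapsAny(bins, gene)]
  cr <- c(estimate = NA_real_, ciLow = NA_real_, ciHigh = NA_real_)
  if (length(binIn) == 0L || length(binOut) == 0L) {
    message("no target or flanking bins: coverage ratio undefined, sample uninformative")
    inform <- FALSE
  } else {
    cr <- coverageRatio(binIn, binOut, mapqFloor = config@mapqFloor)
  }

  bs <- c(split = NA_real_, p = NA_real_)
  geneSnps <- phasedSnps[inGene]
  nPhased <- sum(mcols(geneSnps)$hapOfAlt %in% c("A", "B"))
  if (nPhased >= 2L) {
    bs <- bafSplitStatistic(geneSnps, nPerms = nPerms, seed = seed)
  } else if (inform) {
    message("fewer than 2 phased SNPs in gene: BAF channel unavailable, sample uninformative")
    inform <- FALSE
  }

  covUp <- !is.na(cr[["estimate"]]) && cr[["estimate"]] > 1
  covSig <- !is.na(cr[["ciLow"]]) && cr[["ciLow"]] > 1
  bafSig <- !is.na(bs[["p"]]) && bs[["p"]] <= config@alpha
  evid <- if (config@requireBothChannels) covUp && bafSig else covSig || bafSig
  verdict <- if (!inform) "uninformative" else if (evid) "gain" else "no_gain"

  new("GainCall", gene = gene, nHetSnps = as.integer(n), informative = inform,
      coverageRatio = cr, bafSplit = bs, evidenceGain = evid, verdict = verdict)
}

#' Reclassify a cohort of gain calls across SNP-count thresholds
#'
#' Given calls computed at the loosest informativeness threshold, tabulates
#' for each candidate threshold how many samples remain informative and how
#' many carry a gain, without re-running the evidence channels. Raising the
#' threshold can only move samples from informative to uninformative, so
#' \code{nInformative} (and \code{nGain}) are monotonically non-increasing.
#'
#' @param calls list of \code{\link{GainCall}} objects.
#' @param thresholds integer vector of het-SNP-count thresholds (strict
#'   \code{>} applies, as in the informativeness definition).
#' @return data.frame with columns \code{threshold}, \code{nInformative},
#'   \code{nGain}.
#' @export
cohortInformativeness <- function(calls, thresholds) {
  nsnp <- vapply(calls, nHetSnps, integer(1))
  ## a call missing an evidence channel stays uninformative at any threshold
  usable <- vapply(calls, function(x)
    !is.na(x@coverageRatio[["estimate"]]) && !is.na(x@bafSplit[["p"]]),
    logical(1))
  evid <- vapply(calls, function(x) x@evidenceGain, logical(1))
  out <- lapply(thresholds, function(th) {
    inf <- usable & nsnp > th
    data.frame(threshold = th, nInformative = sum(inf), nGain = sum(inf & evid))
  })
  do.call(rbind, out)
}
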