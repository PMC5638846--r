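#' @include AllGenerics.R
#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width tileGenome
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
NULL

.CONSEQUENCE_VOCAB <- c("missense", "nonsense", "essential_splice", "start_lost",
                        "frameshift_indel", "inframe_indel", "synonymous", "other")
.TRUNCATING_CLASSES <- c("nonsense", "essential_splice", "start_lost", "frameshift_indel")

#' Configuration of a simulated targeted-capture locus
#'
#' Holds every parameter of the synthetic tumour sample generator: the
#' targeted locus, tumour purity, the (optional) single-copy tandem
#' duplication and which parental haplotype carries it, sequencing depth,
#' bin geometry, heterozygous-SNP density and depth, and the haploblock
#' switch-error rate. All randomness downstream flows from the single
#' \code{seed}.
#'
#' @slot locus \code{GRanges} of length 1, the targeted region.
#' @slot purity numeric in [0, 1], fraction of cells that are tumour.
#' @slot dupPresent logical, whether a single-copy duplication is simulated.
#' @slot dupInterval \code{GRanges} of length 1 contained in \code{locus}.
#' @slot dupHaplotype "A" or "B", the parental haplotype carrying the gain.
#' @slot meanDepth expected fragment 5' ends per bin at diploid copy number.
#' @slot binSize coverage bin width in bp.
#' @slot hetSnpCount number of heterozygous SNPs placed in the locus.
#' @slot snpDepth expected read depth at a diploid SNP.
#' @slot switchErrorRate probability of a phase flip between adjacent blocks.
#' @slot snpsPerBlock mean number of SNPs per haplotype block.
#' @slot seed integer seed driving all draws.
#' @export
setClass("SimulationConfig",
  representation(locus = "GRanges", purity = "numeric", dupPresent = "logical",
                 dupInterval = "GRanges", dupHaplotype = "character",
                 meanDepth = "numeric", binSize = "integer",
                 hetSnpCount = "integer", snpDepth = "numeric",
                 switchErrorRate = "numeric", snpsPerBlock = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@locus) != 1L) msg <- c(msg, "locus must be a single interval")
  if (length(object@locus) == 1L && width(object@locus) < 1L)
    msg <- c(msg, "locus must have positive width")
  if (object@purity < 0 || object@purity > 1) msg <- c(msg, "purity must lie in [0, 1]")
  if (object@switchErrorRate < 0 || object@switchErrorRate > 1)
    msg <- c(msg, "switchErrorRate must lie in [0, 1]")
  if (object@dupPresent) {
    if (length(object@dupInterval) != 1L)
      msg <- c(msg, "dupInterval must be a single interval when dupPresent")
    else if (!(start(object@dupInterval) >= start(object@locus) &&
               end(object@dupInterval) <= end(object@locus) &&
               as.character(seqnames(object@dupInterval)) == as.character(seqnames(object@locus))))
      msg <- c(msg, "dupInterval must be contained in locus")
    if (!object@dupHaplotype %in% c("A", "B"))
      msg <- c(msg, "dupHaplotype must be 'A' or 'B'")
  }
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (object@binSize < 1L) msg <- c(msg, "binSize must be a positive integer")
  if (object@hetSnpCount < 0L) msg <- c(msg, "hetSnpCount must be >= 0")
  if (length(object@locus) == 1L && object@hetSnpCount > width(object@locus))
    msg <- c(msg, "hetSnpCount exceeds locus length")
  if (object@snpDepth <= 0) msg <- c(msg, "snpDepth must be positive")
  if (object@snpsPerBlock < 1) msg <- c(msg, "snpsPerBlock must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Haplotype blocks with per-SNP phase
#'
#' A set of non-overlapping haplotype blocks together with, for each phased
#' SNP position, which allele (ref or alt) lies on parental haplotype A.
#' Blocks are internally consistent; switch errors may occur between blocks.
#'
#' @slot ranges \code{GRanges} of block extents with an mcol \code{blockId}.
#' @slot phases data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{blockId}, \code{altOnA} (logical).
#' @export
setClass("HaplotypeBlockSet",
  representation(ranges = "GRanges", phases = "data.frame"))

setValidity("HaplotypeBlockSet", function(object) {
  msg <- character()
  if (!"blockId" %in% names(mcols(object@ranges)))
    msg <- c(msg, "ranges must carry a blockId mcol")
  need <- c("chrom", "pos", "blockId", "altOnA")
  if (!all(need %in% names(object@phases)))
    msg <- c(msg, sprintf("phases must have columns %s", paste(need, collapse = ", ")))
  if (length(object@ranges) > 1L) {
    ov <- GenomicRanges::findOverlaps(object@ranges, drop.self = TRUE)
    if (length(ov)) msg <- c(msg, "blocks must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' A simulated targeted-capture tumour sample
#'
#' Bundle of the generator's output: coverage bins (fragment-start counts,
#' normalized coverage with exact Poisson CIs, mean mapping score),
#' heterozygous SNPs (allele counts and BAF), haplotype blocks with phase
#' (including simulated switch errors), and the per-haplotype copy-number
#' truth used to generate the data.
#'
#' @slot bins \code{GRanges} of coverage bins.
#' @slot snps \code{GRanges} of het SNPs with mcols \code{refCount},
#'   \code{altCount}, \code{baf}, and truth annotations.
#' @slot blocks \code{HaplotypeBlockSet}.
#' @slot truth \code{GRanges} with mcols \code{cnA}, \code{cnB} (tumour
#'   copies per haplotype).
#' @slot config the \code{SimulationConfig} that produced the sample.
#' @export
setClass("SimulatedSample",
  representation(bins = "GRanges", snps = "GRanges",
                 blocks = "HaplotypeBlockSet", truth = "GRanges",
                 config = "SimulationConfig"))

setValidity("SimulatedSample", function(object) {
  tr <- object@truth
  if (length(tr) && !all(c("cnA", "cnB") %in% names(mcols(tr))))
    return("truth must carry cnA and cnB mcols")
  TRUE
})

#' Gain-caller configuration
#'
#' @slot snpInformativeThreshold minimum het-SNP count (strict \code{>}) for
#'   a sample to be informative; default 40.
#' @slot alpha per-channel significance level; default 0.01, chosen
#'   specificity-first since the targeted assay is meant to be specific
#'   rather than maximally sensitive.
#' @slot requireBothChannels if TRUE (default) a gain needs coverage ratio
#'   > 1 AND a significant phased-BAF split; if FALSE either channel alone
#'   suffices (the coverage channel then requires its CI to exclude 1).
#' @slot mapqFloor bins with mean mapping score below this are excluded
#'   from the coverage ratio.
#' @export
setClass("CallerConfig",
  representation(snpInformativeThreshold = "integer", alpha = "numeric",
                 requireBothChannels = "logical", mapqFloor = "numeric"))

setValidity("CallerConfig", function(object) {
  msg <- character()
  if (object@snpInformativeThreshold < 0L)
    msg <- c(msg, "snpInformativeThreshold must be >= 0")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Per-gene copy-number gain verdict
#'
#' Result of fusing the two evidence channels for one gene in one sample:
#' the coverage ratio (target vs flanks, with CI) and the phased-BAF split
#' (with permutation p-value), gated by the het-SNP informativeness
#' threshold. \code{verdict} is one of "gain", "no_gain", "uninformative".
#'
#' @slot gene \code{GRanges} of the assayed gene footprint.
#' @slot nHetSnps het SNPs within the footprint.
#' @slot informative whether \code{nHetSnps} exceeds the threshold (strict).
#' @slot coverageRatio named numeric: estimate, ciLow, ciHigh.
#' @slot bafSplit named numeric: split, p.
#' @slot evidenceGain logical: do the evidence channels support a gain
#'   (independently of informativeness)?
#' @slot verdict character.
#' @export
setClass("GainCall",
  representation(gene = "GRanges", nHetSnps = "integer", informative = "logical",
                 coverageRatio = "numeric", bafSplit = "numeric",
                 evidenceGain = "logical", verdict = "character"))

setValidity("GainCall", function(object) {
  if (!object@verdict %in% c("gain", "no_gain", "uninformative"))
    return("verdict must be gain, no_gain or uninformative")
  if (object@verdict == "gain" && !isTRUE(object@informative))
    return("a gain verdict requires an informative sample")
  TRUE
})

#' Cohort mutation catalogue
#'
#' Per-sample mutation records (gene, consequence class, hotspot flag)
#' together with each sample's coding substitution count, the quantity the
#' hypermutator filter operates on.
#'
#' @slot mutations data.frame with columns \code{sample}, \code{gene},
#'   \code{consequence}, \code{isHotspot}.
#' @slot codingSubstitutions named integer vector, one entry per sample.
#' @export
setClass("CohortCatalogue",
  representation(mutations = "data.frame", codingSubstitutions = "integer"))

setValidity("CohortCatalogue", function(object) {
  msg <- character()
  need <- c("sample", "gene", "consequence")
  if (!all(need %in% names(object@mutations)))
    msg <- c(msg, sprintf("mutations must have columns %s", paste(need, collapse = ", ")))
  else if (nrow(object@mutations) &&
           !all(object@mutations$consequence %in% .CONSEQUENCE_VOCAB))
    msg <- c(msg, "consequence values outside the closed vocabulary")
  if (any(object@codingSubstitutions < 0L)) msg <- c(msg, "substitution counts must be >= 0")
  if (is.null(names(object@codingSubstitutions)))
    msg <- c(msg, "codingSubstitutions must be named by sample")
  if (nrow(object@mutations) &&
      !all(object@mutations$sample %in% names(object@codingSubstitutions)))
    msg <- c(msg, "every mutated sample needs a codingSubstitutions entry")
  if (length(msg)) msg else TRUE
})

## ---- constructors ----

#' @describeIn SimulationConfig-class Constructor with study-condition
#'   defaults: a 200 kb targeted locus around the brachyury (T) gene, a
#'   central 100 kb tandem duplication on haplotype A, purity 0.6, 100
#'   expected fragment starts per 1 kb bin, 60 het SNPs at 100x, 1% block
#'   switch-error rate.
#' @param locus,purity,dupPresent,dupInterval,dupHaplotype,meanDepth,binSize
#'   see slots.
#' @param hetSnpCount,snpDepth,switchErrorRate,snpsPerBlock,seed see slots.
#' @export
SimulationConfig <- function(locus = GRanges("chr6", IRanges(166080001, 166280000)),
                             purity = 0.6,
                             dupPresent = TRUE,
                             dupInterval = NULL,
                             dupHaplotype = "A",
                             meanDepth = 100,
                             binSize = 1000L,
                             hetSnpCount = 60L,
                             snpDepth = 100,
                             switchErrorRate = 0.01,
                             snpsPerBlock = 10,
                             seed = 1L) {
  if (is.null(dupInterval)) {
    mid <- (start(locus) + end(locus)) %/% 2
    dupInterval <- GRanges(seqnames(locus), IRanges(mid - 50000L + 1L, mid + 50000L))
  }
  new("SimulationConfig", locus = locus, purity = purity, dupPresent = dupPresent,
      dupInterval = dupInterval, dupHaplotype = dupHaplotype,
      meanDepth = meanDepth, binSize = as.integer(binSize),
      hetSnpCount = as.integer(hetSnpCount), snpDepth = snpDepth,
      switchErrorRate = switchErrorRate, snpsPerBlock = snpsPerBlock,
      seed = as.integer(seed))
}

#' @describeIn CallerConfig-class Constructor.
#' @param snpInformativeThreshold,alpha,requireBothChannels,mapqFloor see slots.
#' @export
CallerConfig <- function(snpInformativeThreshold = 40L, alpha = 0.01,
                         requireBothChannels = TRUE, mapqFloor = 20) {
  new("CallerConfig", snpInformativeThreshold = as.integer(snpInformativeThreshold),
      alpha = alpha, requireBothChannels = requireBothChannels, mapqFloor = mapqFloor)
}

#' @describeIn HaplotypeBlockSet-class Constructor.
#' @param ranges,phases see slots.
#' @export
HaplotypeBlockSet <- function(ranges, phases) {
  phases$altOnA <- as.logical(phases$altOnA)
  new("HaplotypeBlockSet", ranges = ranges, phases = phases)
}

#' @describeIn CohortCatalogue-class Constructor.
#' @param mutations,codingSubstitutions see slots.
#' @export
CohortCatalogue <- function(mutations, codingSubstitutions) {
  if (!"isHotspot" %in% names(mutations)) mutations$isHotspot <- FALSE
  storage.mode(codingSubstitutions) <- "integer"
  new("CohortCatalogue", mutations = mutations,
      codingSubstitutions = codingSubstitutions)
}

## ---- accessors ----

#' @rdname GainCall-class
#' @param x a \code{GainCall}, \code{SimulatedSample} or \code{CohortCatalogue}.
#' @export
setMethod("verdict", "GainCall", function(x) x@verdict)

#' @rdname GainCall-class
#' @export
setMethod("nHetSnps", "GainCall", function(x) x@nHetSnps)

#' @rdname GainCall-class
#' @export
setMethod("informative", "GainCall", function(x) x@informative)

#' @rdname GainCall-class
#' @export
setMethod("coverageRatioOf", "GainCall", function(x) x@coverageRatio)

#' @rdname GainCall-class
#' @export
setMethod("bafSplitOf", "GainCall", function(x) x@bafSplit)

#' @rdname SimulatedSample-class
#' @param x a \code{SimulatedSample}.
#' @export
setMethod("coverageBins", "SimulatedSample", function(x) x@bins)

#' @rdname SimulatedSample-class
#' @export
setMethod("hetSnps", "SimulatedSample", function(x) x@snps)

#' @rdname SimulatedSample-class
#' @export
setMethod("haploBlocks", "SimulatedSample", function(x) x@blocks)

#' @rdname SimulatedSample-class
#' @export
setMethod("truthCN", "SimulatedSample", function(x) x@truth)

#' @rdname CohortCatalogue-class
#' @param x a \code{CohortCatalogue}.
#' @export
setMethod("mutations", "CohortCatalogue", function(x) x@mutations)

#' @rdname CohortCatalogue-class
#' @export
setMethod("codingSubstitutions", "CohortCatalogue", function(x) x@codingSubstitutions)

## ---- show ----

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  locus: %s:%d-%d (%d bp)\n", seqnames(object@locus),
              start(object@locus), end(object@locus), width(object@locus)))
  if (object@dupPresent)
    cat(sprintf("  duplication: %d-%d on haplotype %s\n",
                start(object@dupInterval), end(object@dupInterval), object@dupHaplotype))
  else cat("  duplication: none (diploid)\n")
  cat(sprintf("  purity %.2f | depth %g/bin | bin %d bp | %d het SNPs @ %gx | switch-error %.3f | seed %d\n",
              object@purity, object@meanDepth, object@binSize, object@hetSnpCount,
              object@snpDepth, object@switchErrorRate, object@seed))
})

setMethod("show", "SimulatedSample", function(object) {
  cat(sprintf("SimulatedSample: %d coverage bins, %d het SNPs, %d haploblocks\n",
              length(object@bins), length(object@snps), length(object@blocks@ranges)))
  show(object@config)
})

setMethod("show", "GainCall", function(object) {
  cat(sprintf("GainCall [%s]\n", object@verdict))
  cat(sprintf("  gene: %s:%d-%d | het SNPs: %d (%s)\n",
              seqnames(object@gene), start(object@gene), end(object@gene),
              object@nHetSnps,
              if (object@informative) "informative" else "not informative"))
  cr <- object@coverageRatio
  bs <- object@bafSplit
  cat(sprintf("  coverage ratio %.3f [%.3f, %.3f] | BAF split %+.3f (p = %.4g)\n",
              cr[["estimate"]], cr[["ciLow"]], cr[["ciHigh"]],
              bs[["split"]], bs[["p"]]))
})

setMethod("show", "CohortCatalogue", function(object) {
  cat(sprintf("CohortCatalogue: %d samples, %d mutation records\n",
              length(object@codingSubstitutions), nrow(object@mutations)))
})
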