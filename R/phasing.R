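#' Select usable heterozygous SNPs
#'
#' Filters SNP records down to the heterozygous SNPs whose B-allele
#' frequencies carry copy-number information: tumour depth at least
#' \code{minDepth} and, when matched-normal allele counts are present,
#' normal BAF inside \code{hetBand} at normal depth >= \code{minDepth}
#' (bounding genotyping error). Without a normal, all sites are assumed to
#' be pre-restricted to known polymorphic het calls and only the depth
#' filter applies. Records with missing or negative counts are skipped and
#' their number reported via \code{message}.
#'
#' @param records \code{GRanges} with mcols \code{refCount}, \code{altCount}
#'   (and optionally \code{normalRefCount}, \code{normalAltCount}), e.g.
#'   from \code{\link{readHetSnpVcf}}; or a data.frame with \code{chrom},
#'   \code{pos} and those columns.
#' @param minDepth minimum read depth (default 15).
#' @param hetBand normal-BAF band defining a usable het site, default
#'   \code{c(0.3, 0.7)}.
#' @return \code{GRanges} of het SNPs with mcols \code{refCount},
#'   \code{altCount}, \code{baf}; phase mcols (\code{hapOfAlt},
#'   \code{blockId}) are added by \code{\link{phaseBafs}}.
#' @export
selectHetSnps <- function(records, minDepth = 15L, hetBand = c(0.3, 0.7)) {
  stopifnot(minDepth >= 1, length(hetBand) == 2L,
            hetBand[1] >= 0, hetBand[1] < hetBand[2], hetBand[2] <= 1)
  if (is.data.frame(records)) {
    gr <- GRanges(records$chrom, IRanges(records$pos, records$pos))
    mcols(gr) <- records[, setdiff(names(records), c("chrom", "pos")), drop = FALSE]
    records <- gr
  }
  mc <- mcols(records)
  bad <- is.na(mc$refCount) | is.na(mc$altCount) |
         mc$refCount < 0 | mc$altCount < 0
  if (any(bad)) message(sum(bad), " malformed record(s) skipped")
  records <- records[!bad]
  mc <- mcols(records)
  depth <- mc$refCount + mc$altCount
  keep <- depth >= minDepth
  if (all(c("normalRefCount", "normalAltCount") %in% names(mc))) {
    nd <- mc$normalRefCount + mc$normalAltCount
    nbaf <- ifelse(nd > 0, mc$normalAltCount / nd, NA_real_)
    keep <- keep & !is.na(nbaf) & nd >= minDepth &
            nbaf >= hetBand[1] & nbaf <= hetBand[2]
  }
  out <- records[keep]
  mcols(out)$baf <- mcols(out)$altCount /
    (mcols(out)$refCount + mcols(out)$altCount)
  out
}

#' Assign SNP alleles to parental haplotypes
#'
#' Looks each SNP up in the haplotype-block phase table and records which
#' haplotype ("A" or "B") carries its alternate allele, plus the block
#' identifier. SNPs not covered by any block get \code{hapOfAlt =
#' "unknown"} and are excluded from the split statistic downstream. The
#' per-haplotype BAF series follows: the haplotype-A series value is
#' \code{baf} when the alt allele is on A and \code{1 - baf} otherwise, and
#' the A and B series sum to 1 at every SNP.
#'
#' @param snps \code{GRanges} from \code{\link{selectHetSnps}}.
#' @param blocks a \code{\link{HaplotypeBlockSet}}.
#' @return \code{snps} with mcols \code{hapOfAlt} and \code{blockId} added.
#' @export
phaseBafs <- function(snps, blocks) {
  ph <- blocks@phases
  dup <- duplicated(ph[, c("chrom", "pos", "blockId")]) |
         duplicated(ph[, c("chrom", "pos", "blockId")], fromLast = TRUE)
  if (any(dup)) {
    conf <- stats::aggregate(altOnA ~ chrom + pos + blockId, ph,
                             function(x) length(unique(x)))
    if (any(conf$altOnA > 1))
      stop("contradictory duplicate phase entries within a block")
    ph <- ph[!duplicated(ph[, c("chrom", "pos")]), ]
  }
  key <- paste(as.character(seqnames(snps)), start(snps))
  idx <- match(key, paste(ph$chrom, ph$pos))
  hap <- ifelse(is.na(idx), "unknown", ifelse(ph$altOnA[idx], "A", "B"))
  mcols(snps)$hapOfAlt <- hap
  mcols(snps)$blockId <- ifelse(is.na(idx), NA_character_, ph$blockId[idx])
  snps
}

## haplotype-A BAF series: baf if alt on A, else 1 - baf
.hapASeries <- function(snps) {
  ifelse(mcols(snps)$hapOfAlt == "A", mcols(snps)$baf, 1 - mcols(snps)$baf)
}

#' Phased-BAF split statistic with permutation p-value
#'
#' Measures the separation between the haplotype-A and haplotype-B BAF
#' series that a single-copy gain produces (two bands instead of one at
#' 0.5). Each block contributes its mean A-minus-B series difference; to
#' tolerate switch errors between blocks (whose sign the imputation cannot
#' guarantee), block contributions are aggregated by magnitude, weighted by
#' SNP count, and the reported split carries the sign of the
#' (count-weighted) majority block orientation. A balanced locus gives a
#' split near 0; a clonal single-copy gain gives |split| near 1/3
#' (haplotype series 2/3 vs 1/3).
#'
#' The null distribution permutes the haplotype-of-alt labels among the
#' SNPs \emph{within} each block (block structure preserved; under no gain
#' the BAF is exchangeable against the labels), recomputing the aligned
#' magnitude each time. The p-value uses the add-one correction
#' \code{(1 + #[perm >= obs]) / (nPerms + 1)}.
#'
#' @param snps phase-annotated \code{GRanges} (\code{\link{phaseBafs}});
#'   at least 2 SNPs with known phase are required.
#' @param nPerms number of label permutations.
#' @param seed integer seed; fixed seed gives a reproducible p.
#' @return named numeric: \code{split} (signed), \code{p}.
#' @export
bafSplitStatistic <- function(snps, nPerms = 1000L, seed = 1L) {
  known <- mcols(snps)$hapOfAlt %in% c("A", "B")
  if (!any(known)) stop("all SNPs have unknown phase")
  snps <- snps[known]
  if (length(snps) < 2L) stop("need at least 2 phased SNPs")
  x <- 2 * mcols(snps)$baf - 1            # signed deviation from 0.5
  e <- ifelse(mcols(snps)$hapOfAlt == "A", 1, -1)
  blk <- factor(mcols(snps)$blockId)
  nb <- as.integer(table(blk))
  sObs <- as.numeric(tapply(e * x, blk, mean))  # per-block A-minus-B split
  mag <- function(s) sum(nb * abs(s)) / sum(nb)
  obsMag <- mag(sObs)
  orient <- sum(nb * sign(sObs))
  splitStat <- (if (orient < 0) -1 else 1) * obsMag

  set.seed(as.integer(seed))
  idxByBlock <- base::split(seq_along(x), blk)
  ## per block: an (nPerms x 1) vector of permuted block splits, then the
  ## count-weighted magnitude across blocks per permutation
  permAbs <- matrix(0, nrow = nPerms, ncol = length(idxByBlock))
  for (j in seq_along(idxByBlock)) {
    ii <- idxByBlock[[j]]
    m <- length(ii)
    eperm <- vapply(seq_len(nPerms), function(i) e[ii][sample.int(m)],
                    numeric(m))
    permAbs[, j] <- abs(as.numeric(crossprod(x[ii], eperm))) / m
  }
  permMag <- as.numeric(permAbs %*% nb) / sum(nb)
  p <- (1 + sum(permMag >= obsMag)) / (nPerms + 1)
  c(split = splitStat, p = p)
}
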