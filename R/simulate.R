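#' Expected B-allele frequency under the purity model
#'
#' Closed form for the expected alternate-allele fraction at a heterozygous
#' SNP when a fraction \code{purity} of cells are tumour carrying
#' \code{alleleCopiesTumour} copies of the allele out of
#' \code{totalCopiesTumour} total copies, and the remaining normal cells are
#' diploid heterozygous (1 of 2 copies):
#' \deqn{\mathrm{BAF} = \frac{\rho\,c_{allele} + (1-\rho)}{\rho\,c_{total} + 2(1-\rho)}}
#' A single-copy gain of the allele-bearing haplotype in a pure tumour gives
#' 2/3; zero purity always gives 1/2.
#'
#' @param purity tumour cell fraction in [0, 1]; vectorised.
#' @param alleleCopiesTumour tumour copies carrying the allele.
#' @param totalCopiesTumour total tumour copies at the SNP (>= 1).
#' @return expected BAF, a fraction.
#' @examples
#' expectedBaf(1, 2, 3)    # 2/3, clonal single-copy gain of the alt haplotype
#' expectedBaf(0.5, 2, 3)  # 0.6
#' @export
expectedBaf <- function(purity, alleleCopiesTumour, totalCopiesTumour) {
  stopifnot(all(purity >= 0 & purity <= 1),
            all(alleleCopiesTumour >= 0),
            all(totalCopiesTumour >= 1),
            all(alleleCopiesTumour <= totalCopiesTumour))
  (purity * alleleCopiesTumour + (1 - purity)) /
    (purity * totalCopiesTumour + 2 * (1 - purity))
}

## tumour copies per haplotype at positions `pos` (vectorised)
.truthCopies <- function(config, pos) {
  cnA <- rep(1L, length(pos))
  cnB <- rep(1L, length(pos))
  if (config@dupPresent) {
    inDup <- pos >= start(config@dupInterval) & pos <= end(config@dupInterval)
    if (config@dupHaplotype == "A") cnA[inDup] <- 2L else cnB[inDup] <- 2L
  }
  list(cnA = cnA, cnB = cnB)
}

#' Simulate one targeted-capture tumour sample
#'
#' Generates a \code{SimulatedSample} under the purity mixture model: bin
#' fragment-start counts are Poisson with mean proportional to the local
#' tumour copy number mixed with a diploid normal at the configured purity;
#' SNP read depths are Poisson scaled the same way and alternate-allele
#' counts are Binomial at the purity-adjusted expected BAF
#' (\code{\link{expectedBaf}}). SNPs are grouped into haplotype blocks and
#' phase flips are introduced between adjacent blocks at the switch-error
#' rate. Identical configs (including seed) give identical output.
#'
#' The sample-wide read count is set to \code{meanDepth * 3e9 / binSize} so
#' that normalized coverage (the per-bin count over bin length times total
#' reads, scaled by 3e9) averages exactly 1 for diploid regions.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return a \code{\link{SimulatedSample}}.
#' @export
simulateSample <- function(config) {
  validObject(config)
  set.seed(config@seed)
  locus <- config@locus
  chrom <- as.character(seqnames(locus))
  W <- width(locus)

  ## ---- coverage bins ----
  starts <- seq(start(locus), end(locus), by = config@binSize)
  ends <- pmin(starts + config@binSize - 1L, end(locus))
  binsGR <- GRanges(chrom, IRanges(starts, ends))
  ## per-bin copy ratio: average of (rho * cnTot + 2 (1 - rho)) / 2 over the bin
  rho <- config@purity
  dupFrac <- rep(0, length(binsGR))
  if (config@dupPresent) {
    ov <- pmax(0L, pmin(ends, end(config@dupInterval)) -
                    pmax(starts, start(config@dupInterval)) + 1L)
    dupFrac <- ov / width(binsGR)
  }
  copyRatio <- (rho * (2 + dupFrac) + (1 - rho) * 2) / 2
  lambda <- config@meanDepth * copyRatio * width(binsGR) / config@binSize
  n5 <- stats::rpois(length(binsGR), lambda)
  mapq <- round(pmax(0, pmin(60, stats::rnorm(length(binsGR), 58, 1.5))), 2)
  totalReads <- round(config@meanDepth * 3e9 / config@binSize)
  bins <- .coverageBinsFromCounts(binsGR, n5, mapq, totalReads)

  ## ---- heterozygous SNPs ----
  n <- config@hetSnpCount
  pos <- sort(sample.int(W, n)) + start(locus) - 1L
  altOnA <- stats::runif(n) < 0.5
  cn <- .truthCopies(config, pos)
  altCopies <- ifelse(altOnA, cn$cnA, cn$cnB)
  totCopies <- cn$cnA + cn$cnB
  eb <- expectedBaf(rho, altCopies, totCopies)
  depth <- stats::rpois(n, config@snpDepth * (rho * totCopies + 2 * (1 - rho)) / 2)
  alt <- stats::rbinom(n, depth, eb)
  snps <- GRanges(rep(chrom, n), IRanges(pos, pos),
                  refCount = depth - alt, altCount = alt,
                  baf = ifelse(depth > 0, alt / depth, NA_real_),
                  truthAltOnA = altOnA, truthBaf = eb)

  ## ---- haplotype blocks with switch errors ----
  blocks <- .simulateBlocks(chrom, pos, altOnA, config)

  ## ---- truth segments ----
  if (config@dupPresent) {
    ts <- c(start(locus), start(config@dupInterval), end(config@dupInterval) + 1L)
    te <- c(start(config@dupInterval) - 1L, end(config@dupInterval), end(locus))
    keep <- te >= ts
    truth <- GRanges(chrom, IRanges(ts[keep], te[keep]))
    inDup <- start(truth) >= start(config@dupInterval) &
             end(truth) <= end(config@dupInterval)
    mcols(truth)$cnA <- ifelse(inDup & config@dupHaplotype == "A", 2L, 1L)
    mcols(truth)$cnB <- ifelse(inDup & config@dupHaplotype == "B", 2L, 1L)
  } else {
    truth <- GRanges(chrom, IRanges(start(locus), end(locus)), cnA = 1L, cnB = 1L)
  }

  new("SimulatedSample", bins = bins, snps = snps, blocks = blocks,
      truth = truth, config = config)
}

## group SNPs into consecutive blocks (~snpsPerBlock each) and apply phase
## flips between adjacent blocks at switchErrorRate
.simulateBlocks <- function(chrom, pos, altOnA, config) {
  n <- length(pos)
  if (n == 0L) {
    return(HaplotypeBlockSet(
      GRanges(character(), IRanges(integer(), integer()), blockId = character()),
      data.frame(chrom = character(), pos = integer(),
                 blockId = character(), altOnA = logical())))
  }
  sizes <- integer()
  while (sum(sizes) < n)
    sizes <- c(sizes, max(1L, stats::rpois(1L, config@snpsPerBlock)))
  blockIdx <- rep(seq_along(sizes), sizes)[seq_len(n)]
  nb <- max(blockIdx)
  flipped <- cumsum(c(FALSE, stats::runif(nb - 1L) < config@switchErrorRate)) %% 2 == 1
  reported <- xor(altOnA, flipped[blockIdx])
  ids <- sprintf("B%03d", seq_len(nb))
  rng <- GRanges(chrom,
                 IRanges(as.integer(tapply(pos, blockIdx, min)),
                         as.integer(tapply(pos, blockIdx, max))),
                 blockId = ids)
  phases <- data.frame(chrom = chrom, pos = pos,
                       blockId = ids[blockIdx], altOnA = reported)
  HaplotypeBlockSet(rng, phases)
}

#' Simulate cohort mutation catalogues
#'
#' Draws per-tumour mutation catalogues: for each gene, the count of
#' mutations in each consequence class is Poisson with the supplied
#' per-tumour rate. A configurable fraction of tumours are hypermutators,
#' whose coding substitution count is drawn around 300 (others around 20,
#' capped below 100), so the conventional >= 100-substitutions exome cutoff
#' separates the two groups.
#'
#' @param nTumours number of tumours.
#' @param geneRates named list: gene -> named numeric vector of per-tumour
#'   rates by consequence class (e.g. \code{list(LYST = c(nonsense = 0.03))}).
#' @param hypermutFraction fraction of tumours that are hypermutators.
#' @param seed integer seed.
#' @param hotspotFraction fraction of missense mutations flagged as hotspot.
#' @return a \code{\link{CohortCatalogue}}.
#' @export
simulateCohortMutations <- function(nTumours, geneRates = list(),
                                    hypermutFraction = 0, seed = 1L,
                                    hotspotFraction = 0) {
  stopifnot(nTumours >= 1, hypermutFraction >= 0, hypermutFraction <= 1)
  rates <- unlist(geneRates)
  if (length(rates) && any(rates < 0)) stop("rates must be >= 0")
  set.seed(as.integer(seed))
  samples <- sprintf("S%05d", seq_len(nTumours))
  hyper <- stats::runif(nTumours) < hypermutFraction
  subs <- integer(nTumours)
  subs[hyper] <- 100L + stats::rpois(sum(hyper), 200)
  subs[!hyper] <- pmin(99L, stats::rpois(sum(!hyper), 20))
  names(subs) <- samples

  recs <- list()
  for (gene in names(geneRates)) {
    classRates <- geneRates[[gene]]
    bad <- setdiff(names(classRates), .CONSEQUENCE_VOCAB)
    if (length(bad))
      stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
    for (cls in names(classRates)) {
      k <- stats::rpois(nTumours, classRates[[cls]])
      if (any(k > 0)) {
        recs[[length(recs) + 1L]] <- data.frame(
          sample = rep(samples, k), gene = gene, consequence = cls,
          isHotspot = cls == "missense" & stats::runif(sum(k)) < hotspotFraction)
      }
    }
  }
  muts <- if (length(recs)) do.call(rbind, recs)
          else data.frame(sample = character(), gene = character(),
                          consequence = character(), isHotspot = logical())
  CohortCatalogue(muts, subs)
}
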