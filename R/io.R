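#' Write a simulated sample to standard text formats
#'
#' Emits four files under \code{dir}: coverage bins as BED-like TSV
#' (0-based half-open; columns chrom, start, end, n5prime, mean_mapq),
#' SNP allele counts as a minimal VCF 4.2 with GT:AD genotypes, haplotype
#' blocks as TSV (chrom, block start/end in BED convention, block_id, SNP
#' position 1-based, which allele is on haplotype A), and the per-haplotype
#' copy-number truth as TSV.
#'
#' @param sample a \code{\link{SimulatedSample}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of file paths written.
#' @export
writeSimulatedSample <- function(sample, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bins = file.path(dir, paste0(prefix, ".bins.tsv")),
             vcf = file.path(dir, paste0(prefix, ".snps.vcf")),
             blocks = file.path(dir, paste0(prefix, ".blocks.tsv")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")))

  bins <- coverageBins(sample)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(bins)), start = start(bins) - 1L,
               end = end(bins), n5prime = mcols(bins)$n5prime,
               mean_mapq = mcols(bins)$meanMapq),
    paths[["bins"]], sep = "\t", quote = FALSE, row.names = FALSE)

  snps <- hetSnps(sample)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##total_reads=%d", metadata(bins)$totalReads),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "TUMOUR", sep = "\t"))
  body <- sprintf("%s\t%d\t.\tA\tC\t.\t.\t.\tGT:AD\t0/1:%d,%d",
                  as.character(seqnames(snps)), start(snps),
                  mcols(snps)$refCount, mcols(snps)$altCount)
  writeLines(c(hdr, body), paths[["vcf"]])

  blocks <- haploBlocks(sample)
  ph <- blocks@phases
  rng <- blocks@ranges
  i <- match(ph$blockId, mcols(rng)$blockId)
  utils::write.table(
    data.frame(chrom = ph$chrom, start = start(rng)[i] - 1L, end = end(rng)[i],
               block_id = ph$blockId, pos = ph$pos,
               hap_a_allele = ifelse(ph$altOnA, "alt", "ref")),
    paths[["blocks"]], sep = "\t", quote = FALSE, row.names = FALSE)

  tr <- truthCN(sample)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(tr)), start = start(tr) - 1L,
               end = end(tr), cn_a = mcols(tr)$cnA, cn_b = mcols(tr)$cnB),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read precomputed coverage bins from TSV
#'
#' Reads a BED-like bins file (chrom, start, end, n5prime, mean_mapq;
#' 0-based half-open coordinates) and recomputes normalized coverage and
#' exact Poisson CIs from the raw counts using the supplied sample-wide
#' read count.
#'
#' @param path TSV path.
#' @param totalReads sample-wide fragment count used as the normalization
#'   denominator.
#' @return \code{GRanges} of coverage bins (see \code{\link{binCoverage}}).
#' @export
readCoverageBins <- function(path, totalReads) {
  df <- utils::read.delim(path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  .coverageBinsFromCounts(gr, df$n5prime, df$mean_mapq, totalReads)
}

#' Read tumour SNP allele counts from VCF
#'
#' Extracts per-site ref/alt allele depths from the AD genotype field of
#' the first sample in a VCF, returning one record per biallelic site.
#'
#' @param path VCF path (plain or bgzipped).
#' @return \code{GRanges} with mcols \code{refCount}, \code{altCount}.
#' @export
readHetSnpVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD[, 1]
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- lengths(ad) == 2L
  rr <- rr[keep]
  ad <- ad[keep]
  gr <- GRanges(seqnames(rr), IRanges(start(rr), start(rr)))
  mcols(gr)$refCount <- unname(vapply(ad, `[`, numeric(1), 1L))
  mcols(gr)$altCount <- unname(vapply(ad, `[`, numeric(1), 2L))
  gr
}

#' Read haplotype blocks from TSV
#'
#' Reads the block file written by \code{\link{writeSimulatedSample}}
#' (chrom, start, end in BED convention, block_id, pos, hap_a_allele) into
#' a \code{\link{HaplotypeBlockSet}}.
#'
#' @param path TSV path.
#' @return a \code{HaplotypeBlockSet}.
#' @export
readHaplotypeBlocks <- function(path) {
  df <- utils::read.delim(path)
  ub <- !duplicated(df$block_id)
  rng <- GRanges(df$chrom[ub], IRanges(df$start[ub] + 1L, df$end[ub]),
                 blockId = df$block_id[ub])
  HaplotypeBlockSet(rng,
    data.frame(chrom = df$chrom, pos = df$pos, blockId = df$block_id,
               altOnA = df$hap_a_allele == "alt"))
}
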