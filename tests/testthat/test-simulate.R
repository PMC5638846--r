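test_that("expectedBaf matches the purity-mixture closed form", {
  expect_equal(expectedBaf(0, 2, 3), 0.5)
  expect_equal(expectedBaf(1, 2, 3), 2 / 3)
  expect_equal(expectedBaf(0.5, 2, 3), 0.6)  # (0.5*2 + 0.5) / (0.5*3 + 1)
  # vectorised over purity
  expect_equal(expectedBaf(c(0, 1), 1, 3), c(0.5, 1 / 3))
  expect_error(expectedBaf(0.5, 4, 3))
  expect_error(expectedBaf(1.2, 1, 2))
})

test_that("config validity rejects degenerate loci and out-of-bound rates", {
  expect_error(SimulationConfig(purity = 1.5), "purity")
  expect_error(SimulationConfig(hetSnpCount = 300000L), "exceeds locus length")
  expect_error(SimulationConfig(locus = GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 4))),
               "positive width")
  expect_error(SimulationConfig(
    dupInterval = GenomicRanges::GRanges("chr6", IRanges::IRanges(1, 10))),
    "contained in locus")
})

test_that("simulation is deterministic given the seed", {
  cfg <- SimulationConfig(seed = 99L)
  s1 <- simulateSample(cfg)
  s2 <- simulateSample(cfg)
  expect_identical(S4Vectors::mcols(coverageBins(s1)), S4Vectors::mcols(coverageBins(s2)))
  expect_identical(S4Vectors::mcols(hetSnps(s1)), S4Vectors::mcols(hetSnps(s2)))
  expect_identical(haploBlocks(s1)@phases, haploBlocks(s2)@phases)
  s3 <- simulateSample(SimulationConfig(seed = 100L))
  expect_false(identical(S4Vectors::mcols(hetSnps(s1)), S4Vectors::mcols(hetSnps(s3))))
})

test_that("truth copy number conserves haplotype totals and encodes the dup", {
  for (hap in c("A", "B")) {
    cfg <- SimulationConfig(dupHaplotype = hap, seed = 3L)
    tr <- truthCN(simulateSample(cfg))
    cn <- S4Vectors::mcols(tr)
    expect_true(all(cn$cnA + cn$cnB >= 2))
    inDup <- GenomicRanges::start(tr) >= GenomicRanges::start(cfg@dupInterval) &
             GenomicRanges::end(tr) <= GenomicRanges::end(cfg@dupInterval)
    dupHapCn <- if (hap == "A") cn$cnA else cn$cnB
    expect_equal(unname(dupHapCn[inDup]), 2L)
    expect_true(all(cn$cnA[!inDup] == 1L & cn$cnB[!inDup] == 1L))
  }
  trd <- truthCN(simulateSample(SimulationConfig(dupPresent = FALSE)))
  expect_true(all(S4Vectors::mcols(trd)$cnA == 1L & S4Vectors::mcols(trd)$cnB == 1L))
})

test_that("zero purity gives balanced BAFs and unit coverage in the dup", {
  cfg <- SimulationConfig(purity = 0, hetSnpCount = 500L, seed = 11L)
  s <- simulateSample(cfg)
  expect_true(all(S4Vectors::mcols(hetSnps(s))$truthBaf == 0.5))
  bins <- coverageBins(s)
  inDup <- IRanges::overlapsAny(bins, cfg@dupInterval)
  expect_lt(abs(mean(S4Vectors::mcols(bins)$normCov[inDup]) - 1), 0.02)
})

test_that("diploid BAFs centre on 0.5 over many SNPs (Monte-Carlo)", {
  cfg <- SimulationConfig(locus = GenomicRanges::GRanges("chr6", IRanges::IRanges(1, 2e6)),
                          dupPresent = FALSE, hetSnpCount = 10000L, seed = 21L)
  s <- simulateSample(cfg)
  expect_lt(abs(mean(S4Vectors::mcols(hetSnps(s))$baf, na.rm = TRUE) - 0.5), 0.01)
})

test_that("swapping the duplicated haplotype mirrors expected BAFs around 0.5", {
  cfgA <- SimulationConfig(purity = 0.8, dupHaplotype = "A", seed = 5L)
  cfgB <- SimulationConfig(purity = 0.8, dupHaplotype = "B", seed = 5L)
  sA <- hetSnps(simulateSample(cfgA))
  sB <- hetSnps(simulateSample(cfgB))
  # same seed, same SNP positions and phase; expected BAFs mirror
  expect_identical(GenomicRanges::start(sA), GenomicRanges::start(sB))
  expect_equal(S4Vectors::mcols(sA)$truthBaf + S4Vectors::mcols(sB)$truthBaf,
               rep(1, length(sA)))
})

test_that("haploblocks cover every SNP and flips occur only between blocks", {
  cfg <- SimulationConfig(switchErrorRate = 0.5, seed = 31L)
  s <- simulateSample(cfg)
  ph <- haploBlocks(s)@phases
  expect_setequal(ph$pos, GenomicRanges::start(hetSnps(s)))
  # within any block the reported phase differs from truth uniformly or not at all
  truth <- S4Vectors::mcols(hetSnps(s))$truthAltOnA[match(ph$pos, GenomicRanges::start(hetSnps(s)))]
  flips <- tapply(ph$altOnA != truth, ph$blockId, function(x) length(unique(x)))
  expect_true(all(flips == 1))
})

test_that("cohort mutation generator respects rates, fractions, determinism", {
  empty <- simulateCohortMutations(50, list(LYST = c(nonsense = 0)), seed = 2L)
  expect_equal(nrow(mutations(empty)), 0L)

  # truncating rate chosen so P(>=1 mutation) = 0.05
  rate <- -log(0.95)
  co <- simulateCohortMutations(10000, list(LYST = c(nonsense = rate)), seed = 3L)
  frac <- length(unique(mutations(co)$sample)) / 10000
  ci <- 2.58 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), ci)

  hy <- simulateCohortMutations(1000, hypermutFraction = 0.1, seed = 4L)
  nHyper <- sum(codingSubstitutions(hy) >= 100)
  expect_lt(abs(nHyper - 100), 2.58 * sqrt(1000 * 0.1 * 0.9) + 1)

  expect_identical(mutations(simulateCohortMutations(100, list(T = c(missense = 0.3)), seed = 7L)),
                   mutations(simulateCohortMutations(100, list(T = c(missense = 0.3)), seed = 7L)))
  expect_error(simulateCohortMutations(10, list(T = c(bogus = 1))), "unknown consequence")
})
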