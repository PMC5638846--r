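# shared fixtures: all synthetic, generated in code at test time

# simulate + select + phase in one step
simPhased <- function(cfg) {
  s <- simulateSample(cfg)
  snps <- suppressMessages(phaseBafs(selectHetSnps(hetSnps(s)), haploBlocks(s)))
  list(sample = s, snps = snps)
}

# end-to-end gain call on a fresh simulated locus
simCall <- function(purity, depth = 100, nsnp = 60, dup = TRUE, seed = 1L,
                    nPerms = 199L, config = CallerConfig()) {
  cfg <- SimulationConfig(purity = purity, meanDepth = depth, snpDepth = depth,
                          hetSnpCount = nsnp, dupPresent = dup, seed = seed)
  sp <- simPhased(cfg)
  suppressMessages(callGain(coverageBins(sp$sample), sp$snps, cfg@dupInterval,
                            config, nPerms = nPerms, seed = seed))
}

# a small mutation catalogue built by hand
handCatalogue <- function(samples, mutated, gene = "LYST",
                          consequence = "nonsense", subs = 20L) {
  muts <- data.frame(sample = mutated, gene = gene, consequence = consequence,
                     isHotspot = FALSE)
  CohortCatalogue(muts, stats::setNames(rep(as.integer(subs), length(samples)),
                                        samples))
}
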