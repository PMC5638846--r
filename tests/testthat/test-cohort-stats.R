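test_that("one-sided Fisher reproduces known tails", {
  # truncating-mutation enrichment table: 5/67 vs 13/4947 tumours
  expect_equal(signif(fisherExactOneSided(5, 62, 13, 4934), 2), 2.7e-6)
  expect_equal(fisherExactOneSided(0, 67, 0, 4947), 1.0)
  # hand enumeration over k in 0..3: P(X >= 2) = (C(3,2)C(3,1) + C(3,3)) / C(6,3)
  expect_equal(fisherExactOneSided(2, 1, 1, 2), 0.5)
})

test_that("log-space tail matches the hypergeometric distribution function", {
  set.seed(3)
  a <- sample(0:40, 200, replace = TRUE)
  b <- sample(0:40, 200, replace = TRUE)
  c_ <- sample(0:40, 200, replace = TRUE)
  d <- sample(0:4000, 200, replace = TRUE)
  mine <- fisherExactOneSided(a, b, c_, d)
  ref <- stats::phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
  expect_equal(mine, ref, tolerance = 1e-12)
  # and the R fisher.test oracle on a handful of tables
  for (i in 1:10) {
    ft <- stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(mine[i], ft, tolerance = 1e-9)
  }
})

test_that("enrichment p never increases as the observed count grows", {
  p <- fisherExactOneSided(0:10, 67 - 0:10, 13, 4934)
  expect_true(all(diff(p) < 0))
})

test_that("hypermutator exclusion is inclusive at the cutoff", {
  co <- CohortCatalogue(
    data.frame(sample = "s1", gene = "LYST", consequence = "nonsense",
               isHotspot = FALSE),
    c(s1 = 99L, s2 = 100L, s3 = 350L))
  expect_message(out <- excludeHypermutators(co), "2 hypermutator")
  expect_equal(names(codingSubstitutions(out)), "s1")

  sim <- simulateCohortMutations(2000, hypermutFraction = 0.1, seed = 31L)
  kept <- suppressMessages(excludeHypermutators(sim))
  removed <- 2000 - length(codingSubstitutions(kept))
  expect_lt(abs(removed / 2000 - 0.1), 2.58 * sqrt(0.1 * 0.9 / 2000))
})

test_that("enrichment test counts tumours, not mutations", {
  # cohort 1: 67 tumours, 5 with a truncating LYST mutation (one has two
  # records, which must not double-count); cohort 2: 4947 with 13
  c1 <- handCatalogue(sprintf("t%03d", 1:67), c(sprintf("t%03d", 1:5), "t001"))
  c2 <- handCatalogue(sprintf("u%04d", 1:4947), sprintf("u%04d", 1:13))
  res <- enrichmentTest(c1, c2, "LYST")
  expect_equal(unname(res$table), c(5, 62, 13, 4934))
  expect_equal(signif(res$p, 2), 2.7e-6)

  # a gene absent from every catalogue: p = 1
  expect_equal(enrichmentTest(c1, c2, "PTEN")$p, 1.0)
  # non-truncating mutations do not count
  c3 <- handCatalogue(sprintf("v%02d", 1:20), "v01", consequence = "missense")
  expect_equal(unname(enrichmentTest(c3, c2, "LYST")$table[1]), 0)
})

test_that("indel pattern permutation matches its closed-form null", {
  # background without in-frame indels cannot beat an all-frameshift observation
  expect_equal(indelPatternPermutation(c(frameshift = 5, inframe = 0),
                                       c(frameshift = 1, inframe = 0),
                                       nPerms = 999, seed = 1), 1.0)
  # with in-frame probability q, P(0 in-frame among 5) = (1-q)^5
  q <- 0.4
  p <- indelPatternPermutation(c(frameshift = 5, inframe = 0),
                               c(frameshift = 1 - q, inframe = q),
                               nPerms = 40000, seed = 2)
  expect_lt(abs(p - (1 - q)^5), 0.005)
  # a character background catalogue is accepted
  bg <- c(rep("frameshift", 60), rep("inframe", 40))
  p2 <- indelPatternPermutation(c(frameshift = 5, inframe = 0), bg,
                                nPerms = 40000, seed = 2)
  expect_equal(p2, p)
  # determinism
  expect_identical(
    indelPatternPermutation(c(frameshift = 7, inframe = 1), c(frameshift = .7, inframe = .3),
                            nPerms = 500, seed = 9),
    indelPatternPermutation(c(frameshift = 7, inframe = 1), c(frameshift = .7, inframe = .3),
                            nPerms = 500, seed = 9))
  expect_error(indelPatternPermutation(c(frameshift = 0, inframe = 0),
                                       c(frameshift = .5, inframe = .5)),
               "at least one")
  expect_error(indelPatternPermutation(c(frameshift = 5, inframe = 0),
                                       c(frameshift = 0, inframe = 0)),
               "degenerate background")
})

test_that("mutability comparison tests both classes with BH correction", {
  # zero locus mutations in cohort 1: one-sided p = 1 for that class
  res <- mutabilityTest(list(subs = c(locus = 0, total = 500),
                             indels = c(locus = 5, total = 50)),
                        list(subs = c(locus = 20, total = 5000),
                             indels = c(locus = 10, total = 500)))
  expect_equal(res$p[res$class == "subs"], 1.0)
  expect_equal(res$pAdjusted, stats::p.adjust(res$p, "BH"))

  # a genuinely doubled locus rate at large counts is detected after correction
  res2 <- mutabilityTest(list(subs = c(locus = 80, total = 2000),
                              indels = c(locus = 40, total = 1000)),
                         list(subs = c(locus = 200, total = 10000),
                              indels = c(locus = 100, total = 5000)))
  expect_true(all(res2$pAdjusted <= 0.05))
  expect_error(mutabilityTest(list(subs = c(locus = 0, total = 0),
                                   indels = c(locus = 0, total = 1)),
                              list(subs = c(locus = 0, total = 1),
                                   indels = c(locus = 0, total = 1))),
               "zero total")
})

test_that("identical-rate cohorts rarely reject after correction", {
  set.seed(77)
  rej <- vapply(1:200, function(r) {
    l1 <- stats::rbinom(1, 400, 0.04); l2 <- stats::rbinom(1, 4000, 0.04)
    i1 <- stats::rbinom(1, 100, 0.04); i2 <- stats::rbinom(1, 1000, 0.04)
    res <- mutabilityTest(list(subs = c(locus = l1, total = 400),
                               indels = c(locus = i1, total = 100)),
                          list(subs = c(locus = l2, total = 4000),
                               indels = c(locus = i2, total = 1000)))
    any(res$pAdjusted <= 0.05)
  }, logical(1))
  # family-wise rejection under the null stays within the binomial band of 5%
  expect_lte(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("cohort order within catalogues does not change the statistics", {
  c1 <- handCatalogue(sprintf("t%02d", 1:30), sprintf("t%02d", 1:4))
  c2 <- handCatalogue(sprintf("u%02d", 1:50), sprintf("u%02d", 1:2))
  shuf <- CohortCatalogue(mutations(c1)[sample(4), ],
                          codingSubstitutions(c1)[sample(30)])
  expect_equal(enrichmentTest(shuf, c2, "LYST"), enrichmentTest(c1, c2, "LYST"))
})
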