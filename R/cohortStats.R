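#' One-sided Fisher's exact test for cohort enrichment
#'
#' Exact hypergeometric tail probability \eqn{P(X \ge a)} that cohort 1
#' shows at least the observed number of mutated cases, conditioning on
#' both margins of the 2x2 table
#' \tabular{lcc}{
#'       \tab mutated \tab not mutated \cr
#'   cohort 1 \tab a \tab b \cr
#'   cohort 2 \tab c \tab d
#' }
#' The tail is summed in log space (via \code{lchoose}) so the computation
#' is overflow-safe for cohort sizes in the thousands; no asymptotic
#' approximation is used. Vectorised over tables.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return p-value(s) in (0, 1].
#' @examples
#' ## truncating-mutation enrichment, 5/67 vs 13/4947 tumours
#' fisherExactOneSided(5, 62, 13, 4934)   # 2.7e-06
#' @export
fisherExactOneSided <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
    M <- a[i] + c[i]; N <- r1 + r2
    if (M == 0 || r1 == 0) return(1)
    kmax <- min(r1, M)
    if (a[i] <= max(0, M - r2)) return(1)   # at or below the support minimum
    k <- a[i]:kmax
    lt <- lchoose(r1, k) + lchoose(r2, M - k) - lchoose(N, M)
    m <- max(lt)
    min(1, exp(m) * sum(exp(lt - m)))
  }, numeric(1))
}

#' Exclude hypermutator samples from a cohort
#'
#' Drops samples whose coding substitution count reaches the cutoff
#' (inclusive: a sample at exactly the cutoff is removed). The number of
#' removed samples is reported via \code{message}.
#'
#' @param cohort a \code{\link{CohortCatalogue}}.
#' @param cutoff coding substitutions per exome defining a hypermutator
#'   (default 100).
#' @return a filtered \code{CohortCatalogue}.
#' @export
excludeHypermutators <- function(cohort, cutoff = 100L) {
  subs <- codingSubstitutions(cohort)
  keep <- names(subs)[subs < cutoff]
  removed <- length(subs) - length(keep)
  if (removed > 0) message(removed, " hypermutator sample(s) removed")
  muts <- mutations(cohort)
  CohortCatalogue(muts[muts$sample %in% keep, , drop = FALSE], subs[keep])
}

## samples in a catalogue with >= 1 truncating mutation in `gene`
.truncatingCases <- function(cohort, gene) {
  m <- mutations(cohort)
  m <- m[m$gene == gene & isTruncating(m$consequence), , drop = FALSE]
  length(unique(m$sample))
}

#' Truncating-mutation enrichment between two cohorts
#'
#' Counts tumours (not mutations) carrying at least one truncating mutation
#' in \code{gene} in each cohort, forms the 2x2 table against tumours
#' without one, and returns the one-sided Fisher p for enrichment in cohort
#' 1. Cohorts are expected to have been pre-filtered with
#' \code{\link{excludeHypermutators}}.
#'
#' @param cohort1,cohort2 \code{\link{CohortCatalogue}} objects.
#' @param gene gene symbol.
#' @return list with \code{table} (named integer a, b, c, d) and \code{p}.
#' @export
enrichmentTest <- function(cohort1, cohort2, gene) {
  n1 <- length(codingSubstitutions(cohort1))
  n2 <- length(codingSubstitutions(cohort2))
  if (n1 == 0 || n2 == 0) stop("empty cohort")
  a <- .truncatingCases(cohort1, gene)
  c_ <- .truncatingCases(cohort2, gene)
  tab <- c(a = a, b = n1 - a, c = c_, d = n2 - c_)
  list(table = tab, p = fisherExactOneSided(a, n1 - a, c_, n2 - c_))
}

#' Permutation test on indel frame composition
#'
#' Tests whether the observed split of indels into frameshift vs in-frame
#' is compatible with a background indel catalogue — in particular, whether
#' in-frame indels are depleted (as expected when selection favours
#' gene-truncating events). The statistic is the observed in-frame count;
#' the null redraws the same total number of indels with class labels
#' resampled from the background, and
#' \deqn{p = \frac{1 + \#\{perms: stat \le observed\}}{n_{perms} + 1}}
#' (add-one correction, so p is never 0).
#'
#' @param observed named counts, \code{c(frameshift = , inframe = )}.
#' @param background either a named probability vector over the two classes
#'   or a character vector of background indel classes from which
#'   proportions are taken.
#' @param nPerms number of permutations (default 10000).
#' @param seed integer seed; identical inputs and seed give identical p.
#' @return p-value.
#' @export
indelPatternPermutation <- function(observed, background, nPerms = 10000L,
                                    seed = 1L) {
  classes <- c("frameshift", "inframe")
  obs <- observed[classes]
  obs[is.na(obs)] <- 0
  ntot <- sum(obs)
  if (ntot < 1) stop("need at least one observed indel")
  if (is.character(background)) {
    background <- c(frameshift = mean(background == "frameshift"),
                    inframe = mean(background == "inframe"))
  }
  s <- sum(background[classes], na.rm = TRUE)
  if (is.na(s) || s <= 0)
    stop("degenerate background: both class weights missing or zero")
  q <- unname(background["inframe"]) / s
  if (is.na(q)) q <- 0
  set.seed(as.integer(seed))
  permInframe <- stats::rbinom(nPerms, ntot, q)
  (1 + sum(permInframe <= obs[["inframe"]])) / (nPerms + 1)
}

#' Locus mutability comparison with multiple-testing correction
#'
#' Compares the rate at which mutations fall into a locus of interest
#' between two cohorts, separately for substitutions and indels: for each
#' class, a one-sided Fisher's exact test of (locus mutations vs all other
#' mutations) in cohort 1 against cohort 2, asking whether the locus is
#' hypermutable in cohort 1. Benjamini-Hochberg correction is applied
#' across the two class tests; raw and adjusted p-values are both
#' returned.
#'
#' @param cohort1Counts,cohort2Counts named lists with elements \code{subs}
#'   and \code{indels}, each \code{c(locus = , total = )} (total includes
#'   the locus counts).
#' @param locusLength optional locus length in bp, echoed in the output for
#'   rate reporting; not used by the tests.
#' @return data.frame with one row per class: counts, \code{p},
#'   \code{pAdjusted}.
#' @export
mutabilityTest <- function(cohort1Counts, cohort2Counts, locusLength = NA) {
  classes <- c("subs", "indels")
  rows <- lapply(classes, function(cl) {
    x1 <- cohort1Counts[[cl]]; x2 <- cohort2Counts[[cl]]
    if (is.null(x1) || is.null(x2)) stop("counts missing for class ", cl)
    if (x1[["total"]] == 0 || x2[["total"]] == 0)
      stop("zero total mutations for class ", cl)
    if (x1[["locus"]] > x1[["total"]] || x2[["locus"]] > x2[["total"]])
      stop("locus counts exceed totals")
    data.frame(class = cl,
               locus1 = x1[["locus"]], total1 = x1[["total"]],
               locus2 = x2[["locus"]], total2 = x2[["total"]],
               p = fisherExactOneSided(x1[["locus"]], x1[["total"]] - x1[["locus"]],
                                       x2[["locus"]], x2[["total"]] - x2[["locus"]]))
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- stats::p.adjust(out$p, method = "BH")
  attr(out, "locusLength") <- locusLength
  out
}
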