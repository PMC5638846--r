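#' Is a consequence class truncating?
#'
#' Truncating classes — predicted to abolish protein function — are
#' nonsense, essential splice, start lost, and out-of-frame (frameshift)
#' indel. In-frame indels, missense and synonymous changes are not.
#'
#' @param consequence character vector from the closed consequence
#'   vocabulary (see \code{\link{consequenceClasses}}).
#' @return logical vector.
#' @export
isTruncating <- function(consequence) {
  bad <- setdiff(unique(consequence), .CONSEQUENCE_VOCAB)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  consequence %in% .TRUNCATING_CLASSES
}

#' Closed consequence vocabulary
#' @return character vector of the recognised consequence classes.
#' @export
consequenceClasses <- function() .CONSEQUENCE_VOCAB

#' Default gene role table
#'
#' A small curated role table for genes recurrently implicated in chordoma:
#' brachyury (T) and PIK3CA act as oncogenes (gain / hotspot mechanisms);
#' PIK3R1, PTEN, ARID1A, PBRM1, SETD2, CDKN2A and LYST act as recessive
#' cancer genes (truncating / homozygous-deletion mechanisms). CDKN2A is
#' flagged as a bona fide recessive gene for which the focality requirement
#' on homozygous deletions is relaxed, as it presents with both focal and
#' larger deletions.
#'
#' @return data.frame with columns \code{gene}, \code{role},
#'   \code{bonaFideRecessiveRelaxation}.
#' @export
defaultGeneRoles <- function() {
  data.frame(
    gene = c("T", "PIK3CA", "PIK3R1", "PTEN", "ARID1A", "PBRM1", "SETD2",
             "CDKN2A", "LYST"),
    role = c("oncogene", "oncogene", "recessive", "recessive", "recessive",
             "recessive", "recessive", "recessive", "recessive"),
    bonaFideRecessiveRelaxation = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                    FALSE, TRUE, FALSE))
}

.roleOf <- function(roles, gene) {
  i <- match(gene, roles$gene)
  if (is.na(i)) stop("no role known for gene ", gene)
  roles[i, ]
}

#' Call a point-mutation driver
#'
#' Rule engine for point events: in recessive cancer genes a mutation is a
#' driver iff it truncates the gene footprint; in oncogenes a point
#' mutation is a driver iff it hits a previously curated hotspot.
#'
#' @param mutation one-row data.frame (or list) with \code{sample},
#'   \code{gene}, \code{consequence}, \code{isHotspot}.
#' @param roles gene role table (see \code{\link{defaultGeneRoles}}).
#' @return one-row data.frame (\code{sample}, \code{gene},
#'   \code{mechanism}, \code{evidence}) or \code{NULL} if not a driver.
#' @export
callPointDriver <- function(mutation, roles = defaultGeneRoles()) {
  role <- .roleOf(roles, mutation$gene)
  if (role$role == "recessive" && isTruncating(mutation$consequence)) {
    return(data.frame(sample = mutation$sample, gene = mutation$gene,
                      mechanism = "truncating",
                      evidence = mutation$consequence))
  }
  if (role$role == "oncogene" && isTRUE(mutation$isHotspot)) {
    return(data.frame(sample = mutation$sample, gene = mutation$gene,
                      mechanism = "hotspot",
                      evidence = mutation$consequence))
  }
  NULL
}

#' Call a copy-number driver
#'
#' Copy-number gains are oncogenic when an oncogene reaches 5 copies in a
#' diploid sample or 9 in a tetraploid one; amplification segments must be
#' focal, strictly under 1 Mb. Homozygous deletions (0 copies) of recessive
#' genes are drivers when the segment is focal, except for bona fide
#' recessive genes where the focality requirement is relaxed. Segment
#' length is \code{end - start} in the half-open convention.
#'
#' @param segment one-row data.frame (or list) with \code{sample},
#'   \code{chrom}, \code{start}, \code{end} (half-open), \code{totalCopies},
#'   \code{ploidyClass} ("diploid" or "tetraploid").
#' @param roles gene role table.
#' @param gene gene symbol; the segment must overlap the gene footprint
#'   (the caller's responsibility upstream).
#' @return one-row data.frame or \code{NULL}.
#' @export
callCnDriver <- function(segment, gene, roles = defaultGeneRoles()) {
  role <- .roleOf(roles, gene)
  if (is.null(segment$ploidyClass) || is.na(segment$ploidyClass))
    stop("ploidy class missing for sample ", segment$sample)
  if (!segment$ploidyClass %in% c("diploid", "tetraploid"))
    stop("ploidyClass must be 'diploid' or 'tetraploid'")
  len <- segment$end - segment$start
  focal <- len < 1e6
  ampCut <- if (segment$ploidyClass == "diploid") 5L else 9L
  if (role$role == "oncogene" && segment$totalCopies >= ampCut && focal) {
    return(data.frame(sample = segment$sample, gene = gene,
                      mechanism = "amplification",
                      evidence = sprintf("%d copies / %s", segment$totalCopies,
                                         segment$ploidyClass)))
  }
  if (role$role == "recessive" && segment$totalCopies == 0 &&
      (focal || isTRUE(role$bonaFideRecessiveRelaxation))) {
    return(data.frame(sample = segment$sample, gene = gene,
                      mechanism = "homozygous_deletion",
                      evidence = sprintf("%d bp segment", len)))
  }
  NULL
}

#' Call drivers over a mutation table
#'
#' Vectorised convenience wrapper applying \code{\link{callPointDriver}} to
#' every row of a mutation table; genes absent from the role table are
#' skipped.
#'
#' @param mutationTable data.frame with columns \code{sample}, \code{gene},
#'   \code{consequence}, \code{isHotspot}.
#' @param roles gene role table.
#' @return data.frame of driver calls (possibly 0 rows).
#' @export
callPointDrivers <- function(mutationTable, roles = defaultGeneRoles()) {
  keep <- mutationTable$gene %in% roles$gene
  rows <- lapply(which(keep), function(i)
    callPointDriver(mutationTable[i, ], roles))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(sample = character(), gene = character(),
                      mechanism = character(), evidence = character()))
  do.call(rbind, rows)
}

#' Gene-by-sample driver matrix
#'
#' Builds the full driver landscape matrix: one row per gene, one column
#' per sample, each cell the (comma-joined, deduplicated) set of driver
#' mechanisms called, empty string where none. Per-gene prevalence is the
#' number of samples with at least one driver in that gene.
#'
#' @param calls data.frame of driver calls (\code{sample}, \code{gene},
#'   \code{mechanism}).
#' @param samples,genes character vectors fixing matrix dimensions
#'   (including empty rows/columns).
#' @return list with \code{matrix} (character gene x sample) and
#'   \code{prevalence} (named integer per gene).
#' @export
driverMatrix <- function(calls, samples, genes) {
  m <- matrix("", nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(calls)) {
    calls <- calls[calls$gene %in% genes & calls$sample %in% samples, ]
    if (nrow(calls)) {
      agg <- stats::aggregate(mechanism ~ gene + sample, calls,
                              function(x) paste(sort(unique(x)), collapse = ","))
      m[cbind(agg$gene, agg$sample)] <- agg$mechanism
    }
  }
  prevalence <- apply(m, 1, function(r) sum(nzchar(r)))
  list(matrix = m, prevalence = prevalence)
}
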