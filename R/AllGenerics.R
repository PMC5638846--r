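NULL

#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @export
setGeneric("nHetSnps", function(x) standardGeneric("nHetSnps"))

#' @export
setGeneric("informative", function(x) standardGeneric("informative"))

#' @export
setGeneric("coverageRatioOf", function(x) standardGeneric("coverageRatioOf"))

#' @export
setGeneric("bafSplitOf", function(x) standardGeneric("bafSplitOf"))

#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @export
setGeneric("codingSubstitutions", function(x) standardGeneric("codingSubstitutions"))

#' @export
setGeneric("coverageBins", function(x) standardGeneric("coverageBins"))

#' @export
setGeneric("hetSnps", function(x) standardGeneric("hetSnps"))

#' @export
setGeneric("haploBlocks", function(x) standardGeneric("haploBlocks"))

#' @export
setGeneric("truthCN", function(x) standardGeneric("truthCN"))
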