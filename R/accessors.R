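# Accessor generics and methods for the core containers.

#' Accessors for mtxsim containers
#'
#' Small accessor family for the S4 containers; use these rather than slot
#' access.
#'
#' @param x An mtxsim object.
#' @return \code{abundances}: named integer vector. \code{targetTotal}:
#'   integer. \code{exprValues}: named integer vector. \code{poolEntries},
#'   \code{clusterMembers}: data.frame. \code{poolSequences}:
#'   \code{DNAStringSet}. \code{poolSize}: numeric total copies.
#'   \code{clusterParams}: named numeric. \code{clusterSizes},
#'   \code{contigReads}: named structures. \code{debrisReads}: character.
#'   \code{evalCounts}: named numeric with TP/FP/TN/potential/pearson.
#' @name accessors
#' @examples
#' pp <- scaleAbundances(data.frame(species_id = c("a", "b"),
#'                                  coverage = c(3, 1)), targetTotal = 100)
#' abundances(pp)
#' targetTotal(pp)
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "PopulationProfile", function(x) x@abundances)

#' @rdname accessors
#' @export
setGeneric("targetTotal", function(x) standardGeneric("targetTotal"))
#' @rdname accessors
#' @export
setMethod("targetTotal", "PopulationProfile", function(x) x@targetTotal)

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setMethod("speciesId", "ExpressionProfile", function(x) x@speciesId)

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionProfile", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("exponent", function(x) standardGeneric("exponent"))
#' @rdname accessors
#' @export
setMethod("exponent", "ExpressionProfile", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("poolEntries", function(x) standardGeneric("poolEntries"))
#' @rdname accessors
#' @export
setMethod("poolEntries", "TranscriptPool", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("poolSequences", function(x) standardGeneric("poolSequences"))
#' @rdname accessors
#' @export
setMethod("poolSequences", "TranscriptPool", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))
#' @rdname accessors
#' @export
setMethod("poolSize", "TranscriptPool", function(x) sum(as.numeric(x@entries$copy_number)))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("clusterParams", function(x) standardGeneric("clusterParams"))
#' @rdname accessors
#' @export
setMethod("clusterParams", "ClusterSet", function(x) x@parameters)

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterSet", function(x) {
  tab <- table(x@members$representative_id)
  setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setMethod("representatives", "ClusterSet", function(x) unique(x@members$representative_id))

#' @rdname accessors
#' @export
setGeneric("contigReads", function(x) standardGeneric("contigReads"))
#' @rdname accessors
#' @export
setMethod("contigReads", "ContigMembership", function(x) x@contigs)

#' @rdname accessors
#' @export
setGeneric("debrisReads", function(x) standardGeneric("debrisReads"))
#' @rdname accessors
#' @export
setMethod("debrisReads", "ContigMembership", function(x) x@debris)

#' @rdname accessors
#' @export
setGeneric("evalCounts", function(x) standardGeneric("evalCounts"))
#' @rdname accessors
#' @export
setMethod("evalCounts", "EvalReport", function(x) {
  c(TP = x@TP, FP = x@FP, TN = x@TN, potential = x@potential, pearson = x@pearson)
})

#' @rdname accessors
#' @export
setGeneric("routeLabel", function(x) standardGeneric("routeLabel"))
#' @rdname accessors
#' @export
setMethod("routeLabel", "EvalReport", function(x) x@route)
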