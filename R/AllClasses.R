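#' @title Core S4 containers
#' @description S4 classes carrying the central objects of the simulation and
#'   evaluation pipeline. All are created by exported constructors or pipeline
#'   functions; slots are reached through accessors, not \code{@}.
#' @name mtxsim-classes
NULL

#' Discrete community population profile
#'
#' Maps species to discrete organism abundances (copies of each organism in
#' the simulated sample). Produced by \code{\link{scaleAbundances}}. The sum
#' of abundances is constrained to lie within 1\% of \code{targetTotal}.
#'
#' @slot abundances Named integer vector, species id -> abundance (>= 1).
#' @slot targetTotal Integer scalar, the population size the profile was
#'   scaled to (default 1000).
#' @exportClass PopulationProfile
setClass("PopulationProfile",
  representation(abundances = "integer", targetTotal = "integer"),
  validity = function(object) {
    a <- object@abundances
    if (length(a) == 0L) return("abundances must be non-empty")
    if (is.null(names(a)) || anyNA(names(a)) || any(names(a) == ""))
      return("abundances must be named by species id")
    if (anyDuplicated(names(a))) return("duplicate species ids")
    if (any(a < 1L)) return("every abundance must be >= 1")
    tt <- object@targetTotal
    if (length(tt) != 1L || tt < 1L) return("targetTotal must be a positive integer")
    if (abs(sum(a) - tt) > 0.01 * tt)
      return(sprintf("abundance total %d deviates from target %d by more than 1%%",
                     sum(a), tt))
    TRUE
  })

#' Per-species gene expression profile
#'
#' Integer expression level (transcript copies per cell) for each gene of one
#' species, drawn from the bounded discrete power law
#' P(k) = k^-r / sum_{j=1..kMax} j^-r. Produced by
#' \code{\link{sampleExpression}}.
#'
#' @slot speciesId Character scalar.
#' @slot values Named integer vector, gene id -> expression in [1, kMax].
#' @slot r Positive numeric power-law exponent.
#' @slot kMax Integer upper bound of the expression range.
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  representation(speciesId = "character", values = "integer",
                 r = "numeric", kMax = "integer"),
  validity = function(object) {
    v <- object@values
    if (length(v) == 0L) return("values must be non-empty")
    if (is.null(names(v)) || anyDuplicated(names(v))) return("values must have unique gene ids")
    if (any(v < 1L) || any(v > object@kMax)) return("expression values outside [1, kMax]")
    if (object@r <= 0) return("r must be positive")
    TRUE
  })

#' Weighted full-length transcript pool
#'
#' The transcript content of a simulated sample: one entry per (species,
#' gene) with copy number = expression x organism abundance. Copy numbers are
#' stored as weights; sequences are never materialized per copy, so memory is
#' O(genes) rather than O(copies).
#'
#' @slot entries data.frame with columns \code{species_id}, \code{gene_id},
#'   \code{copy_number} (positive integer).
#' @slot sequences \code{DNAStringSet} named by gene id (sense strand CDS).
#' @exportClass TranscriptPool
setClass("TranscriptPool",
  representation(entries = "data.frame", sequences = "DNAStringSet"),
  validity = function(object) {
    e <- object@entries
    need <- c("species_id", "gene_id", "copy_number")
    if (!all(need %in% names(e))) return("entries needs species_id, gene_id, copy_number")
    if (nrow(e) == 0L) return("pool must be non-empty")
    if (any(e$copy_number < 1)) return("copy numbers must be positive")
    if (anyDuplicated(e$gene_id)) return("gene ids must be unique across the pool")
    if (!all(e$gene_id %in% names(object@sequences)))
      return("every entry needs a sequence")
    TRUE
  })

#' Sequence cluster set
#'
#' The outcome of greedy sequence clustering (or a parsed CD-HIT
#' \code{.clstr} file): a partition of sequence ids into clusters, each with
#' a representative, plus the (C, aL, aS) thresholds used.
#'
#' @slot members data.frame with columns \code{member_id},
#'   \code{representative_id}, \code{identity} (fraction in [0, 1]; 1 for the
#'   representative itself).
#' @slot parameters Named numeric vector \code{c(C=, aL=, aS=)} in percent;
#'   may be NA when parsed from an external file.
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(members = "data.frame", parameters = "numeric"),
  validity = function(object) {
    m <- object@members
    need <- c("member_id", "representative_id", "identity")
    if (!all(need %in% names(m))) return("members needs member_id, representative_id, identity")
    if (anyDuplicated(m$member_id)) return("a sequence appears in more than one cluster")
    reps <- unique(m$representative_id)
    if (!all(reps %in% m$member_id)) return("every representative must be a member of its own cluster")
    if (nrow(m) > 0L && (any(m$identity < 0) || any(m$identity > 1)))
      return("identities must lie in [0, 1]")
    TRUE
  })

#' Read-to-contig membership
#'
#' Which reads an assembler incorporated into which contig, plus the debris
#' (reads in no contig). Membership and debris partition the input read set.
#'
#' @slot contigs Named list, contig id -> character vector of read ids.
#' @slot debris Character vector of read ids not in any contig.
#' @exportClass ContigMembership
setClass("ContigMembership",
  representation(contigs = "list", debris = "character"),
  validity = function(object) {
    all_members <- unlist(object@contigs, use.names = FALSE)
    if (anyDuplicated(c(all_members, object@debris)))
      return("a read id appears in more than one of {contig, debris}")
    if (length(object@contigs) && any(lengths(object@contigs) == 0L))
      return("contigs must contain at least one read")
    TRUE
  })

#' Annotation evaluation report
#'
#' TP/FP/TN/potential accounting plus the Pearson correlation between the
#' observed and theoretical domain-content vectors, for one processing route
#' (all reads, clustered, contigs, debris, a combination, ...).
#'
#' @slot route Character label of the processing route.
#' @slot TP,FP,TN,potential Non-negative numerics (integers unless weighted
#'   classification was requested).
#' @slot pearson Numeric in [-1, 1], or NA when not computed.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(route = "character", TP = "numeric", FP = "numeric",
                 TN = "numeric", potential = "numeric", pearson = "numeric"),
  prototype(pearson = NA_real_),
  validity = function(object) {
    cnt <- c(object@TP, object@FP, object@TN, object@potential)
    if (any(cnt < 0)) return("counts must be non-negative")
    p <- object@pearson
    if (!is.na(p) && (p < -1 - 1e-12 || p > 1 + 1e-12)) return("pearson outside [-1, 1]")
    TRUE
  })

## show methods ---------------------------------------------------------------

setMethod("show", "PopulationProfile", function(object) {
  a <- object@abundances
  cat(sprintf("PopulationProfile: %d species, total %d (target %d)\n",
              length(a), sum(a), object@targetTotal))
  show(head(a, 5L))
  if (length(a) > 5L) cat("...\n")
})

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile '%s': %d genes, r = %.3g, k in [1, %d]\n",
              object@speciesId, length(object@values), object@r, object@kMax))
})

setMethod("show", "TranscriptPool", function(object) {
  e <- object@entries
  cat(sprintf("TranscriptPool: %d transcripts from %d species, %s copies total\n",
              nrow(e), length(unique(e$species_id)),
              format(sum(as.numeric(e$copy_number)), big.mark = ",")))
})

setMethod("show", "ClusterSet", function(object) {
  p <- object@parameters
  cat(sprintf("ClusterSet: %d sequences in %d clusters (C=%s, aL=%s, aS=%s)\n",
              nrow(object@members), length(unique(object@members$representative_id)),
              format(p[["C"]]), format(p[["aL"]]), format(p[["aS"]])))
})

setMethod("show", "ContigMembership", function(object) {
  cat(sprintf("ContigMembership: %d contigs (%d reads), %d debris reads\n",
              length(object@contigs), length(unlist(object@contigs, use.names = FALSE)),
              length(object@debris)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: TP=%g FP=%g TN=%g potential=%g pearson=%s\n",
              object@route, object@TP, object@FP, object@TN, object@potential,
              ifelse(is.na(object@pearson), "NA", sprintf("%.3f", object@pearson))))
})
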