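# Evaluate module: domain-content vectors, TP/FP/TN/potential accounting,
# Pearson correlation, best-parameter selection, contig entropy.

# Normalize an annotation input (data.frame with seq_id/domain_id, or a
# named list of domain sets) to a named list of unique domain-id vectors.
asDomainSets <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopIfNot(all(c("seq_id", "domain_id") %in% names(annotations)),
              "annotation table needs seq_id and domain_id columns")
    lapply(split(as.character(annotations$domain_id),
                 as.character(annotations$seq_id)), unique)
  } else {
    stopIfNot(is.list(annotations), "annotations must be a data.frame or named list")
    lapply(annotations, function(x) unique(as.character(x)))
  }
}

#' Ground-truth domain sets for simulated reads
#'
#' Derives, from the simulator's provenance table and the per-gene domain
#' truth, the domain set each read should be credited with. Mode
#' \code{"full"} credits every domain anywhere on the read's source
#' transcript (the default used for TP judgement: an annotation transferred
#' to a read that only partially covers the domain is still correct at the
#' transcript level). Mode \code{"fragment"} restricts to domains whose
#' protein-coordinate interval overlaps the read's translated interval
#' (stricter; the read could in principle have been annotated directly).
#'
#' @param readTruth data.frame with \code{read_id}, \code{gene_id},
#'   \code{start}, \code{end} (0-based half-open, nucleotide, on the
#'   transcript).
#' @param geneDomains data.frame with \code{gene_id}, \code{domain_id},
#'   \code{aa_start}, \code{aa_end} (0-based half-open on the protein).
#' @param mode \code{"full"} or \code{"fragment"}.
#' @return Named list, read id -> character vector of domain ids.
#' @export
readTruthDomains <- function(readTruth, geneDomains, mode = c("full", "fragment")) {
  mode <- match.arg(mode)
  stopIfNot(all(c("read_id", "gene_id") %in% names(readTruth)),
            "readTruth needs read_id and gene_id")
  # a gene absent from geneDomains simply has no domains
  byGene <- split(seq_len(nrow(geneDomains)), geneDomains$gene_id)
  out <- vector("list", nrow(readTruth))
  for (i in seq_len(nrow(readTruth))) {
    rows <- byGene[[readTruth$gene_id[i]]]
    if (is.null(rows)) { out[[i]] <- character(0); next }
    if (mode == "full") {
      out[[i]] <- unique(geneDomains$domain_id[rows])
    } else {
      aaS <- readTruth$start[i] %/% 3L
      aaE <- (readTruth$end[i] + 2L) %/% 3L
      hit <- geneDomains$aa_start[rows] < aaE & geneDomains$aa_end[rows] > aaS
      out[[i]] <- unique(geneDomains$domain_id[rows][hit])
    }
  }
  setNames(out, readTruth$read_id)
}

#' Theoretical (full) domain content of a sample
#'
#' The ground-truth domain tally the observed annotation is compared
#' against: for each sampled read, each unique domain of its full-length
#' source transcript contributes weight 1 — the domain content of the
#' equivalent number of full transcripts.
#'
#' @param readTruth data.frame with \code{read_id} and \code{gene_id}.
#' @param geneDomains data.frame with \code{gene_id}, \code{domain_id}.
#' @return Named numeric vector, domain id -> weighted count.
#' @export
theoreticalContent <- function(readTruth, geneDomains) {
  stopIfNot(all(c("read_id", "gene_id") %in% names(readTruth)),
            "readTruth needs read_id and gene_id")
  pairs <- unique(geneDomains[, c("gene_id", "domain_id")])
  counts <- table(readTruth$gene_id)
  w <- as.numeric(counts[pairs$gene_id])
  w[is.na(w)] <- 0
  v <- tapply(w, pairs$domain_id, sum)
  out <- setNames(as.numeric(v), names(v))
  out[out > 0]
}

#' Observed (annotated) domain content
#'
#' Tallies annotations over any processing route. Each unique domain per
#' annotated sequence contributes that sequence's weight once: weight 1 for
#' an unclustered read or a debris read, cluster size for a cluster
#' representative, reads-mapped for a contig.
#'
#' @param annotations Named list (seq id -> domain ids) or data.frame with
#'   \code{seq_id}, \code{domain_id}.
#' @param weights Named numeric vector of positive weights covering every
#'   annotated sequence; NULL means weight 1 everywhere.
#' @return Named numeric vector, domain id -> weighted count.
#' @export
observedContent <- function(annotations, weights = NULL) {
  sets <- asDomainSets(annotations)
  if (is.null(weights)) weights <- setNames(rep(1, length(sets)), names(sets))
  missing <- setdiff(names(sets), names(weights))
  stopIfNot(length(missing) == 0L,
            sprintf("no weight for annotated sequences: %s",
                    paste(head(missing, 3L), collapse = ", ")))
  stopIfNot(all(weights[names(sets)] > 0), "weights must be positive")
  doms <- unlist(sets, use.names = FALSE)
  reps <- rep(as.numeric(weights[names(sets)]), lengths(sets))
  if (length(doms) == 0L) return(setNames(numeric(0), character(0)))
  v <- tapply(reps, doms, sum)
  setNames(as.numeric(v), names(v))
}

#' Pearson correlation between domain-content vectors
#'
#' Zero-fills both vectors over the union of their domains, then computes
#' the standard product-moment correlation. Errors when either vector is
#' constant over the union (undefined correlation).
#'
#' @param observed,theoretical Named numeric vectors (domain id -> count).
#' @return Correlation in [-1, 1].
#' @examples
#' domainPearson(c(A = 1, B = 2, C = 3), c(A = 1, B = 2, C = 3))
#' @export
domainPearson <- function(observed, theoretical) {
  universe <- union(names(observed), names(theoretical))
  stopIfNot(length(universe) >= 2L, "need at least two domains to correlate")
  x <- setNames(rep(0, length(universe)), universe)
  y <- x
  x[names(observed)] <- observed
  y[names(theoretical)] <- theoretical
  stopIfNot(stats::var(x) > 0 && stats::var(y) > 0,
            "correlation undefined: a vector has zero variance")
  as.numeric(cor(x, y))
}

#' Classify annotations against truth
#'
#' Per-sequence, per-domain accounting against transcript-level truth:
#' a predicted domain present in the truth set is a true positive, a
#' predicted domain absent from it a false positive, and a truth domain
#' that was not predicted a potential domain (present on the original
#' full-length transcript, missed by this route). A sequence with no
#' predictions and an empty truth set counts one true negative.
#'
#' @param predicted Named list / data.frame of annotations (sequences with
#'   no predictions may simply be absent).
#' @param truth Named list, sequence id -> true domain set (e.g. from
#'   \code{\link{readTruthDomains}}); must cover every classified sequence.
#' @param ids Universe of sequence ids to classify (default: names of
#'   \code{truth}).
#' @param weights Optional named positive weights per sequence for weighted
#'   (real-valued) counts; default 1 (integer counts).
#' @param route Label stored on the report.
#' @return An \code{\linkS4class{EvalReport}} with \code{pearson} left NA.
#' @export
classifyAnnotations <- function(predicted, truth, ids = names(truth),
                                weights = NULL, route = "route") {
  sets <- asDomainSets(predicted)
  stopIfNot(!is.null(ids) && length(ids) > 0L, "empty sequence universe")
  unknown <- setdiff(names(sets), ids)
  stopIfNot(length(unknown) == 0L,
            sprintf("predictions for unknown sequences: %s",
                    paste(head(unknown, 3L), collapse = ", ")))
  missingTruth <- setdiff(ids, names(truth))
  stopIfNot(length(missingTruth) == 0L,
            sprintf("no truth entry for sequences: %s",
                    paste(head(missingTruth, 3L), collapse = ", ")))
  if (is.null(weights)) weights <- setNames(rep(1, length(ids)), ids)
  TP <- 0; FP <- 0; TN <- 0; potential <- 0
  for (id in ids) {
    pred <- sets[[id]]
    tru <- unique(as.character(truth[[id]]))
    w <- as.numeric(weights[[id]])
    if (length(pred) == 0L && length(tru) == 0L) { TN <- TN + w; next }
    TP <- TP + w * sum(pred %in% tru)
    FP <- FP + w * sum(!(pred %in% tru))
    potential <- potential + w * sum(!(tru %in% pred))
  }
  new("EvalReport", route = route, TP = TP, FP = FP, TN = TN,
      potential = potential, pearson = NA_real_)
}

#' Evaluate one processing route end to end
#'
#' Convenience wrapper: classifies the route's annotations against truth and
#' correlates its weighted observed domain content with the theoretical
#' content of the sample.
#'
#' @inheritParams classifyAnnotations
#' @param theoretical Named numeric vector from
#'   \code{\link{theoreticalContent}}.
#' @param contentWeights Weights for \code{\link{observedContent}} (cluster
#'   sizes / reads per contig); default the classification weights.
#' @return An \code{\linkS4class{EvalReport}} with \code{pearson} filled.
#' @export
evaluateRoute <- function(predicted, truth, theoretical, ids = names(truth),
                          weights = NULL, contentWeights = weights,
                          route = "route") {
  rep_ <- classifyAnnotations(predicted, truth, ids = ids, weights = weights,
                              route = route)
  obs <- observedContent(predicted, contentWeights)
  p <- tryCatch(domainPearson(obs, theoretical), error = function(e) NA_real_)
  initialize(rep_, pearson = p)
}

#' Select the best processing route
#'
#' Picks the candidate with the largest increase in true positives minus
#' false positives over the baseline route (typically the annotation of all
#' unclustered reads): argmax of (TP - FP) - (TP_baseline - FP_baseline).
#' Ties break by higher TP, then by candidate order.
#'
#' @param reports List of \code{\linkS4class{EvalReport}} candidates.
#' @param baseline The baseline \code{\linkS4class{EvalReport}}.
#' @return List with \code{index}, \code{route}, \code{gain}, and the
#'   winning \code{report}.
#' @export
selectBest <- function(reports, baseline) {
  stopIfNot(length(reports) >= 1L, "need at least one candidate report")
  stopIfNot(is(baseline, "EvalReport"), "baseline must be an EvalReport")
  base_gain <- baseline@TP - baseline@FP
  gains <- vapply(reports, function(r) (r@TP - r@FP) - base_gain, numeric(1))
  tps <- vapply(reports, function(r) r@TP, numeric(1))
  best <- order(-gains, -tps, seq_along(reports))[1]
  list(index = best, route = reports[[best]]@route, gain = gains[best],
       report = reports[[best]])
}

#' Contig read-provenance entropy
#'
#' Chimerism measure per contig: with n_i reads from source transcript i and
#' N reads in the contig, H = -sum (n_i/N) log(n_i/N) in nats. H = 0 iff all
#' reads share one source transcript (a non-chimeric contig); the maximum is
#' log(number of distinct sources).
#'
#' @param membership A \code{\linkS4class{ContigMembership}}.
#' @param readTruth data.frame with \code{read_id} and \code{gene_id}
#'   covering every contig member.
#' @return Named numeric vector, contig id -> entropy (nats).
#' @export
contigEntropy <- function(membership, readTruth) {
  stopIfNot(is(membership, "ContigMembership"), "membership must be a ContigMembership")
  contigs <- contigReads(membership)
  stopIfNot(length(contigs) > 0L, "no contigs")
  src <- setNames(as.character(readTruth$gene_id), readTruth$read_id)
  vapply(contigs, function(reads) {
    stopIfNot(length(reads) > 0L, "empty contig")
    g <- src[reads]
    stopIfNot(!anyNA(g), "contig member without provenance")
    p <- as.numeric(table(g)) / length(g)
    -sum(p * log(p))
  }, numeric(1))
}

#' Fraction of contigs with zero entropy
#'
#' @param entropies Numeric vector from \code{\link{contigEntropy}}.
#' @param eps Tolerance below which an entropy counts as zero (default
#'   1e-12).
#' @return Fraction in [0, 1].
#' @export
zeroEntropyFraction <- function(entropies, eps = 1e-12) {
  stopIfNot(length(entropies) >= 1L, "need at least one contig")
  mean(entropies <= eps)
}

#' Read a minimal domain annotation table
#'
#' Tab-separated \code{seq_id, domain_id, aa_start, aa_end, score} (header
#' required), the minimal dialect of a pfam_scan-style hit table.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readAnnotations <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  stopIfNot(all(c("seq_id", "domain_id") %in% names(df)),
            sprintf("'%s' lacks seq_id/domain_id columns", path))
  df
}

#' Write an evaluation report (or several) as TSV
#'
#' @param reports An \code{\linkS4class{EvalReport}} or list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeEvalReports <- function(reports, path) {
  if (is(reports, "EvalReport")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(route = r@route, TP = r@TP, FP = r@FP, TN = r@TN,
               potential = r@potential, pearson = r@pearson)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Observed-vs-theoretical domain content scatter plot
#'
#' One point per domain in the union of the two vectors, with the Pearson
#' correlation in the legend.
#'
#' @param observed,theoretical Named numeric content vectors.
#' @param main Plot title (default the route question).
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the correlation shown.
#' @export
plotDomainContent <- function(observed, theoretical, main = "Domain content", ...) {
  universe <- union(names(observed), names(theoretical))
  x <- setNames(rep(0, length(universe)), universe)
  y <- x
  x[names(theoretical)] <- theoretical
  y[names(observed)] <- observed
  r <- tryCatch(domainPearson(y, x), error = function(e) NA_real_)
  plot(x, y, xlab = "theoretical content", ylab = "observed content",
       main = main, ...)
  abline(0, 1, lty = 2)
  legend("topleft", bty = "n",
         legend = sprintf("r = %s", ifelse(is.na(r), "NA", sprintf("%.3f", r))))
  invisible(r)
}
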