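# Pool module: gene sequences x expression x abundance -> weighted transcript pool.

#' Read one species' gene set from FASTA
#'
#' Loads CDS nucleotide sequences, one record per gene, headers giving gene
#' ids. Sequences must be plain A/C/G/T; ambiguity codes are rejected at load
#' so downstream error models and translation stay well defined.
#'
#' @param path FASTA file path.
#' @return A named \code{DNAStringSet}.
#' @export
readGeneSet <- function(path) {
  s <- readDNAStringSet(path)
  stopIfNot(length(s) > 0L, sprintf("'%s' contains no sequences", path))
  names(s) <- sub("\\s.*$", "", names(s))
  stopIfNot(!anyDuplicated(names(s)), sprintf("'%s' has duplicate gene ids", path))
  stopIfNot(all(width(s) > 0L), sprintf("'%s' has an empty sequence", path))
  bad <- rowSums(alphabetFrequency(s)[, c("A", "C", "G", "T"), drop = FALSE]) != width(s)
  if (any(bad)) {
    stop(sprintf("'%s': non-A/C/G/T characters in %s", path,
                 paste(head(names(s)[bad], 3L), collapse = ", ")), call. = FALSE)
  }
  s
}

#' Build the weighted transcript pool
#'
#' For every gene of every species present in the population, the pool holds
#' copy_number = expression(gene) x abundance(species): the per-cell
#' transcript count scaled up by how many copies of the organism the sample
#' contains. Copy numbers are weights; no sequence is duplicated in memory.
#'
#' @param geneSets Named list, species id -> named \code{DNAStringSet} of
#'   gene sequences (see \code{\link{readGeneSet}}).
#' @param population A \code{\linkS4class{PopulationProfile}}.
#' @param expression Named list of \code{\linkS4class{ExpressionProfile}}
#'   (names = species ids), e.g. from \code{\link{sampleExpressionProfiles}}.
#' @return A \code{\linkS4class{TranscriptPool}}.
#' @examples
#' genes <- Biostrings::DNAStringSet(c(g1 = "ATGAAATTTGGGTAA"))
#' pop <- scaleAbundances(data.frame(species_id = "s1", coverage = 1), 10)
#' ep <- sampleExpression("g1", seed = 1, speciesId = "s1")
#' buildPool(list(s1 = genes), pop, list(s1 = ep))
#' @export
buildPool <- function(geneSets, population, expression) {
  stopIfNot(is(population, "PopulationProfile"), "population must be a PopulationProfile")
  ab <- abundances(population)
  missing_gs <- setdiff(names(ab), names(geneSets))
  stopIfNot(length(missing_gs) == 0L,
            sprintf("no gene set for species: %s", paste(missing_gs, collapse = ", ")))
  missing_ex <- setdiff(names(ab), names(expression))
  stopIfNot(length(missing_ex) == 0L,
            sprintf("no expression profile for species: %s", paste(missing_ex, collapse = ", ")))

  entry_list <- vector("list", length(ab))
  seqs_list <- vector("list", length(ab))
  for (i in seq_along(ab)) {
    sp <- names(ab)[i]
    gs <- geneSets[[sp]]
    ex <- exprValues(expression[[sp]])
    stopIfNot(setequal(names(gs), names(ex)),
              sprintf("gene ids of species '%s' differ between gene set and expression profile", sp))
    ex <- ex[names(gs)]
    entry_list[[i]] <- data.frame(species_id = sp, gene_id = names(gs),
                                  copy_number = as.integer(ex) * ab[[i]],
                                  stringsAsFactors = FALSE)
    seqs_list[[i]] <- gs
  }
  entries <- do.call(rbind, entry_list)
  rownames(entries) <- NULL
  seqs <- do.call(c, seqs_list)
  new("TranscriptPool", entries = entries, sequences = seqs)
}

#' Write the pool manifest as TSV
#'
#' Emits \code{species_id<TAB>gene_id<TAB>copy_number} with a header.
#'
#' @param pool A \code{\linkS4class{TranscriptPool}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writePoolManifest <- function(pool, path) {
  stopIfNot(is(pool, "TranscriptPool"), "pool must be a TranscriptPool")
  write.table(poolEntries(pool), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
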