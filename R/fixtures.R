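# Fixtures module: fully synthetic, self-annotating inputs — gene sets with
# planted amino-acid motif "domains" and an exact-match toy domain scanner.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# One fixed codon per amino acid for back-translation; chosen so planted
# motifs are exactly recoverable in frame +1 and never introduce stops.
BACK_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

backTranslate <- function(aa) {
  paste(BACK_CODON[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

#' Generate a planted-motif library
#'
#' Random amino-acid motifs of length 20-60 standing in for protein domain
#' models. No motif is a substring of another, so scanner hits are
#' unambiguous; the library is deterministic given the seed.
#'
#' @param nMotifs Number of motifs (>= 1).
#' @param seed Integer seed.
#' @param lengthRange Motif length bounds in amino acids (default c(20, 60)).
#' @return Named character vector, domain id (\code{"PFS00001"}, ...) ->
#'   motif.
#' @export
makeMotifLibrary <- function(nMotifs, seed = 1L, lengthRange = c(20L, 60L)) {
  stopIfNot(nMotifs >= 1L, "nMotifs must be >= 1")
  withSeed(seed, {
    motifs <- character(0)
    while (length(motifs) < nMotifs) {
      len <- sample(lengthRange[1]:lengthRange[2], 1L)
      cand <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      ok <- !any(vapply(motifs, function(m) {
        grepl(cand, m, fixed = TRUE) || grepl(m, cand, fixed = TRUE)
      }, logical(1)))
      if (ok) motifs <- c(motifs, cand)
    }
    setNames(motifs, sprintf("PFS%05d", seq_len(nMotifs)))
  })
}

#' Generate a synthetic gene set with planted domains
#'
#' Each gene is an in-frame CDS (starts ATG, ends with a stop, no internal
#' stops): random non-stop codons with 0 to \code{maxDomains} motifs from
#' the library back-translated and planted at non-overlapping positions.
#' Translating frame +1 reproduces every planted motif exactly at its
#' recorded protein coordinates, so the truth table is correct by
#' construction.
#'
#' @param speciesId Species label; gene ids are
#'   \code{<speciesId>_g<number>}.
#' @param nGenes Number of genes.
#' @param lengthRange Nucleotide CDS length bounds; must allow the longest
#'   motif plus start and stop (>= 3 * (longest motif + 2)).
#' @param motifs Library from \code{\link{makeMotifLibrary}}.
#' @param domainsPerGene Integer vector of candidate domain counts per gene,
#'   sampled uniformly (default 0:3).
#' @param seed Integer seed.
#' @return List with \code{genes} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame \code{gene_id}, \code{domain_id},
#'   \code{aa_start}, \code{aa_end}; protein coordinates, 0-based
#'   half-open).
#' @export
makeGeneSet <- function(speciesId, nGenes, lengthRange = c(300L, 900L),
                        motifs, domainsPerGene = 0:3, seed = 1L) {
  stopIfNot(nGenes >= 1L, "nGenes must be >= 1")
  stopIfNot(length(motifs) >= 1L, "empty motif library")
  maxMotif <- max(nchar(motifs))
  stopIfNot(lengthRange[1] >= 3L * (maxMotif + 2L),
            sprintf("lengthRange too short for the longest motif (%d aa): need >= %d nt",
                    maxMotif, 3L * (maxMotif + 2L)))
  codons <- BACK_CODON  # non-stop by construction
  withSeed(seed, {
    seqs <- character(nGenes)
    truth <- list()
    for (g in seq_len(nGenes)) {
      ntLen <- sample(lengthRange[1]:lengthRange[2], 1L)
      m <- ntLen %/% 3L - 1L              # aa length incl. initial M, excl. stop
      aa <- c("M", sample(AA20, m - 1L, replace = TRUE))
      nd <- sample(domainsPerGene, 1L)
      planted <- character(0); starts <- integer(0); ends <- integer(0)
      if (nd > 0L) {
        picks <- sample(names(motifs), min(nd, length(motifs)))
        occupied <- logical(m)
        occupied[1] <- TRUE               # keep the start codon intact
        for (d in picks) {
          w <- nchar(motifs[[d]])
          # free, non-overlapping placement; skip the domain if none remains
          cand <- which(vapply(seq_len(m - w + 1L),
                               function(p) !any(occupied[p:(p + w - 1L)]),
                               logical(1)))
          if (length(cand) == 0L) next
          p <- cand[sample.int(length(cand), 1L)]
          aa[p:(p + w - 1L)] <- strsplit(motifs[[d]], "", fixed = TRUE)[[1]]
          occupied[p:(p + w - 1L)] <- TRUE
          planted <- c(planted, d)
          starts <- c(starts, p - 1L)     # 0-based
          ends <- c(ends, p - 1L + w)
        }
      }
      gid <- sprintf("%s_g%d", speciesId, g)
      seqs[g] <- paste0(backTranslate(paste(aa, collapse = "")), "TAA")
      if (length(planted)) {
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, domain_id = planted, aa_start = starts,
          aa_end = ends, stringsAsFactors = FALSE)
      }
    }
    genes <- DNAStringSet(seqs)
    names(genes) <- sprintf("%s_g%d", speciesId, seq_len(nGenes))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), domain_id = character(0),
                 aa_start = integer(0), aa_end = integer(0))
    list(genes = genes, truth = truth)
  })
}

#' Toy domain scanner over planted motifs
#'
#' Reports every occurrence of every library motif in the amino-acid input
#' with at most \code{maxMismatches} mismatches (Hamming; no gaps). The
#' exact-match default makes annotation noiseless so evaluation logic can be
#' tested in isolation; mismatch tolerance emulates divergent homologs.
#'
#' @param aaSequences Named character vector or named \code{AAStringSet}.
#' @param motifs Library from \code{\link{makeMotifLibrary}}.
#' @param maxMismatches Allowed mismatches per hit (default 0).
#' @return data.frame \code{seq_id}, \code{domain_id}, \code{aa_start},
#'   \code{aa_end} (0-based half-open), \code{score} (number of matching
#'   positions).
#' @export
scanDomains <- function(aaSequences, motifs, maxMismatches = 0L) {
  if (!is(aaSequences, "AAStringSet")) {
    stopIfNot(!is.null(names(aaSequences)), "aaSequences must be named")
    aaSequences <- AAStringSet(aaSequences)
  }
  out <- list()
  for (d in names(motifs)) {
    hits <- vmatchPattern(motifs[[d]], aaSequences,
                          max.mismatch = maxMismatches, with.indels = FALSE)
    n <- S4Vectors::elementNROWS(hits)
    if (sum(n) == 0L) next
    idx <- rep(seq_along(aaSequences), n)
    ir <- unlist(hits)
    out[[d]] <- data.frame(
      seq_id = names(aaSequences)[idx], domain_id = d,
      aa_start = IRanges::start(ir) - 1L, aa_end = IRanges::end(ir),
      score = nchar(motifs[[d]]) - maxMismatches,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(0), domain_id = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      score = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$seq_id, res$domain_id, res$aa_start), , drop = FALSE]
}

#' Build a complete synthetic demo workspace
#'
#' Creates a self-contained workspace emulating the full set of inputs the
#' pipeline consumes, for three diversity tiers: LD (few dominant species),
#' MD (intermediate) and HD (many, evenly covered species). Writes, per
#' tier, the coverage profile, per-species gene FASTAs, the domain truth
#' table and the motif library, all in the dialects the pipeline reads.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root integer seed; everything derives from it.
#' @param nMotifs Size of the motif library (default 25).
#' @param genesPerSpecies Genes per synthetic species (default 30).
#' @return Invisibly, a list with the motif library, per-tier species lists
#'   and file paths.
#' @export
makeDemo <- function(dir, seed = 1L, nMotifs = 25L, genesPerSpecies = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  motifs <- makeMotifLibrary(nMotifs, seed = deriveSeed("motifs", seed))
  tiers <- list(
    LD = list(n = 6L, decay = 0.45),   # few dominant species
    MD = list(n = 12L, decay = 0.75),  # intermediate
    HD = list(n = 20L, decay = 0.97))  # many, near-even species
  write.table(
    data.frame(domain_id = names(motifs), motif = unname(motifs)),
    file.path(dir, "motifs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(motifs = motifs, tiers = list(),
              motifPath = file.path(dir, "motifs.tsv"))
  for (tier in names(tiers)) {
    tdir <- file.path(dir, tier)
    dir.create(tdir, showWarnings = FALSE)
    n <- tiers[[tier]]$n
    species <- sprintf("%s_sp%02d", tolower(tier), seq_len(n))
    coverage <- 20 * tiers[[tier]]$decay^(seq_len(n) - 1)
    covPath <- file.path(tdir, "coverage.tsv")
    write.table(data.frame(species_id = species, coverage = coverage, tier = tier),
                covPath, sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- list(); fastas <- character(n)
    for (i in seq_along(species)) {
      gs <- makeGeneSet(species[i], genesPerSpecies, motifs = motifs,
                        seed = deriveSeed(species[i], seed))
      fastas[i] <- file.path(tdir, paste0(species[i], ".fasta"))
      writeXStringSet(gs$genes, fastas[i])
      truth[[i]] <- gs$truth
    }
    truthPath <- file.path(tdir, "gene_domains.tsv")
    write.table(do.call(rbind, truth), truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$tiers[[tier]] <- list(species = species, coverage = covPath,
                              fastas = fastas, geneDomains = truthPath)
  }
  invisible(out)
}
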