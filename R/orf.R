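# ORF module: six-frame longest open reading frame translation.

# Vectorized six-frame scan. Returns a list (one element per input, NULL when
# no run reaches minAa) of list(frame, aa, ntStart, ntEnd). Translation is
# batched per frame (one Biostrings call for the whole set); run-finding is
# plain string work.
findLongestOrfs <- function(seqs, minAa) {
  n <- length(seqs)
  seqs <- toupper(seqs)
  L <- nchar(seqs)
  rc <- character(n)
  ok <- L > 0L
  if (any(ok)) rc[ok] <- revcompChar(seqs[ok])
  best <- vector("list", n)
  bestLen <- integer(n)
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    offset <- abs(fr) - 1L
    m <- pmax((L - offset) %/% 3L, 0L)
    idx <- which(m >= pmax(minAa, 1L))
    if (length(idx) == 0L) next
    sub <- substr(if (fr > 0L) seqs[idx] else rc[idx], offset + 1L,
                  offset + 3L * m[idx])
    # no.init.codon: fragments are internal, so CTG/TTG/GTG are Leu/Val, not Met
    aa <- as.character(translate(DNAStringSet(sub), if.fuzzy.codon = "X",
                                 no.init.codon = TRUE))
    runs_by_seq <- strsplit(aa, "*", fixed = TRUE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      runs <- runs_by_seq[[k]]
      if (length(runs) == 0L) next
      wbest <- which.max(nchar(runs))
      rl <- nchar(runs[wbest])
      if (rl == 0L || rl <= bestLen[i]) next   # earlier frame wins ties
      aaStart <- sum(nchar(runs[seq_len(wbest - 1L)])) + (wbest - 1L)
      s <- offset + 3L * aaStart               # 0-based on translated strand
      e <- s + 3L * rl
      if (fr < 0L) { tmp <- s; s <- L[i] - e; e <- L[i] - tmp }
      best[[i]] <- list(frame = fr, aa = runs[wbest],
                        ntStart = as.integer(s), ntEnd = as.integer(e))
      bestLen[i] <- rl
    }
  }
  for (i in seq_len(n)) if (bestLen[i] < minAa) best[i] <- list(NULL)
  best
}

#' Longest open reading frame over six frames
#'
#' Finds the longest stop-free codon run (stop-to-stop; no start-codon
#' requirement, since reads are typically internal gene fragments) over all
#' six reading frames and returns its translation. Ambiguous bases (N) are
#' translated as X and treated as non-stop. Frames are searched in the order
#' +1, +2, +3, -1, -2, -3 and the first maximal-length run wins, so results
#' are deterministic.
#'
#' @param sequence A single nucleotide string (A/C/G/T, N tolerated).
#' @param minAa Minimum ORF length in amino acids (default 10); shorter best
#'   runs return NULL. On short reads this suppresses noise ORFs.
#' @return NULL, or a list with \code{frame} (one of +1, +2, +3, -1, -2,
#'   -3), \code{aa} (amino-acid string, no stop symbol), and \code{ntStart},
#'   \code{ntEnd}: 0-based half-open coordinates of the codon run on the
#'   input sequence (for negative frames, the coordinates of the region
#'   whose reverse complement was translated).
#' @examples
#' longestOrf("ATGAAATAG", minAa = 1)  # reverse frame wins with "LFH"
#' @export
longestOrf <- function(sequence, minAa = 10L) {
  stopIfNot(is.character(sequence) && length(sequence) == 1L,
            "sequence must be a single string")
  findLongestOrfs(sequence, minAa)[[1]]
}

#' Longest ORFs for a set of sequences
#'
#' Set-level driver with per-frame batched translation; sequences with no
#' ORF of at least \code{minAa} amino acids are dropped.
#'
#' @param sequences Named character vector or named \code{DNAStringSet}.
#' @param minAa Minimum ORF length in amino acids.
#' @return A named \code{AAStringSet} of ORF translations; per-sequence
#'   frame and nucleotide coordinates are in \code{mcols()} (\code{frame},
#'   \code{nt_start}, \code{nt_end}, 0-based half-open).
#' @export
longestOrfs <- function(sequences, minAa = 10L) {
  if (is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopIfNot(!is.null(names(sequences)), "sequences must be named")
  hits <- findLongestOrfs(sequences, minAa)
  keep <- !vapply(hits, is.null, logical(1))
  aa <- AAStringSet(vapply(hits[keep], `[[`, character(1), "aa"))
  names(aa) <- names(sequences)[keep]
  S4Vectors::mcols(aa) <- S4Vectors::DataFrame(
    frame = vapply(hits[keep], `[[`, integer(1), "frame"),
    nt_start = vapply(hits[keep], `[[`, integer(1), "ntStart"),
    nt_end = vapply(hits[keep], `[[`, integer(1), "ntEnd"))
  aa
}

#' Write ORF translations as amino-acid FASTA
#'
#' Headers carry the source id plus the frame and nucleotide coordinates:
#' \code{>id frame=f coords=start-end}.
#'
#' @param orfs Result of \code{\link{longestOrfs}}.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
writeOrfs <- function(orfs, path) {
  m <- S4Vectors::mcols(orfs)
  out <- orfs
  names(out) <- sprintf("%s frame=%+d coords=%d-%d", names(orfs),
                        m$frame, m$nt_start, m$nt_end)
  writeXStringSet(out, path)
  invisible(path)
}
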