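# Shared fixture builders and independent oracles.

AA_ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomAa <- function(n, lens, seed = NULL, prefix = "s") {
  build <- function() {
    setNames(vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHA, sample(lens, 1L), replace = TRUE), collapse = "")
    }, character(1)), paste0(prefix, seq_len(n)))
  }
  if (is.null(seed)) build() else { set.seed(seed); build() }
}

randomDna <- function(n, lens, seed = NULL, prefix = "t") {
  build <- function() {
    setNames(vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(lens, 1L), replace = TRUE),
            collapse = "")
    }, character(1)), paste0(prefix, seq_len(n)))
  }
  if (is.null(seed)) build() else { set.seed(seed); build() }
}

# A small pool: one species, genes drawn uniformly, abundance via a flat
# coverage profile. Gene length range chosen per test.
tinyPool <- function(nGenes = 8, lens = 450:900, abundance = 20, seed = 11) {
  genes <- Biostrings::DNAStringSet(randomDna(nGenes, lens, seed = seed, prefix = "g"))
  pop <- scaleAbundances(data.frame(species_id = "sp1", coverage = 1), abundance)
  ex <- sampleExpressionProfiles(list(sp1 = genes), seed = seed)
  buildPool(list(sp1 = genes), pop, ex)
}

# Independent six-frame longest-ORF oracle: seqinr translation, linear scan
# of stop-free codon runs, same frame order and first-maximal tie-break.
oracleLongestOrf <- function(seq, minAa = 1L) {
  L <- nchar(seq)
  rc <- paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1]]),
              collapse = "")
  best <- NULL
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0L) seq else rc
    off <- abs(fr) - 1L
    m <- (L - off) %/% 3L
    if (m < 1L) next
    chars <- strsplit(tolower(s), "")[[1]]
    aa <- seqinr::translate(chars[(off + 1L):(off + 3L * m)])
    run_len <- 0L; run_start <- 0L
    best_len <- 0L; best_start <- 0L
    for (p in seq_along(aa)) {
      if (aa[p] == "*") {
        run_len <- 0L
      } else {
        if (run_len == 0L) run_start <- p
        run_len <- run_len + 1L
        if (run_len > best_len) { best_len <- run_len; best_start <- run_start }
      }
    }
    if (best_len == 0L) next
    if (!is.null(best) && best_len <= nchar(best$aa)) next
    best <- list(frame = fr,
                 aa = paste(aa[best_start:(best_start + best_len - 1L)],
                            collapse = ""))
  }
  if (is.null(best) || nchar(best$aa) < minAa) return(NULL)
  best
}

# Write a minimal SAM file mapping reads to contigs; `rows` is a data.frame
# with qname, flag, rname, pos.
writeTinySam <- function(rows, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:1000", contigs))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (bitwAnd(r$flag, 4L) > 0L) {
      sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*", r$qname, r$flag)
    } else {
      sprintf("%s\t%d\t%s\t%d\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
              r$qname, r$flag, r$rname, r$pos)
    }
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Direct-formula entropy oracle over explicit read-source assignments.
oracleEntropy <- function(sources) {
  p <- as.numeric(table(sources)) / length(sources)
  -sum(p * log(p))
}
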