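# Readsim module: platform-styled read sampling from the transcript pool,
# surrogate error models, ground-truth provenance.

#' Surrogate sequencing error model
#'
#' A deliberately simple, pluggable error model standing in for full
#' platform simulators. Substitutions occur per base at
#' \code{substitutionRate}, optionally ramping linearly along the read by
#' \code{positionRateSlope} (rate at the last base =
#' \code{substitutionRate + positionRateSlope}; Illumina-style). Homopolymer
#' runs gain or lose one repeat unit with probability
#' \code{hpIndelBaseRate * hpLengthFactor^(run length - 1)}, capped at 0.99
#' (454-style: errors concentrate in long homopolymers).
#'
#' @slot substitutionRate Per-base substitution probability in [0, 1).
#' @slot hpIndelBaseRate Homopolymer indel base probability in [0, 1).
#' @slot hpLengthFactor Multiplicative growth of the indel probability per
#'   extra run base (>= 1).
#' @slot positionRateSlope Total linear increase of the substitution rate
#'   across the read (>= 0).
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(substitutionRate = "numeric", hpIndelBaseRate = "numeric",
                 hpLengthFactor = "numeric", positionRateSlope = "numeric"),
  validity = function(object) {
    if (object@substitutionRate < 0 || object@substitutionRate >= 1)
      return("substitutionRate must be in [0, 1)")
    if (object@hpIndelBaseRate < 0 || object@hpIndelBaseRate >= 1)
      return("hpIndelBaseRate must be in [0, 1)")
    if (object@hpLengthFactor < 1) return("hpLengthFactor must be >= 1")
    if (object@positionRateSlope < 0) return("positionRateSlope must be >= 0")
    if (object@substitutionRate + object@positionRateSlope >= 1)
      return("substitution rate at the read end must stay below 1")
    TRUE
  })

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel: sub=%.4g (+%.4g along read), homopolymer indel=%.4g x %.3g^(run-1)\n",
    object@substitutionRate, object@positionRateSlope,
    object@hpIndelBaseRate, object@hpLengthFactor))
})

#' @rdname ErrorModel-class
#' @param substitutionRate,hpIndelBaseRate,hpLengthFactor,positionRateSlope
#'   See slots.
#' @return An \code{ErrorModel}.
#' @export
errorModel <- function(substitutionRate = 0, hpIndelBaseRate = 0,
                       hpLengthFactor = 1, positionRateSlope = 0) {
  new("ErrorModel", substitutionRate = substitutionRate,
      hpIndelBaseRate = hpIndelBaseRate, hpLengthFactor = hpLengthFactor,
      positionRateSlope = positionRateSlope)
}

#' @rdname ErrorModel-class
#' @details \code{error454Model()} and \code{errorIlluminaModel()} return the
#'   platform defaults: 454 = 0.1\% substitutions plus homopolymer indels
#'   (base 0.5\%, factor 1.8); Illumina = substitutions ramping 0.1\% to
#'   1.0\% along the read, no indels.
#' @export
error454Model <- function() errorModel(0.001, 0.005, 1.8, 0)

#' @rdname ErrorModel-class
#' @export
errorIlluminaModel <- function() errorModel(0.001, 0, 1, 0.009)

# Replace the base at (read, pos) pairs with a uniformly chosen different
# base. `seqs` character vector; `i` read indices; `j` scalar or vector pos.
substituteBases <- function(seqs, i, j) {
  if (length(i) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  cur <- substr(seqs[i], j, j)
  k <- sample.int(3L, length(i), replace = TRUE)
  idx <- match(cur, bases)
  nb <- ifelse(is.na(idx), bases[sample.int(4L, length(i), replace = TRUE)],
               bases[((idx - 1L + k) %% 4L) + 1L])
  # substr<- is vectorized over the string vector
  tmp <- seqs[i]
  substr(tmp, j, j) <- nb
  seqs[i] <- tmp
  seqs
}

#' Apply 454-style errors to sequences
#'
#' Per-base substitutions at the model's (position-constant) rate, then
#' homopolymer-run indels: each maximal single-base run of length m gains or
#' loses (50/50) one base with probability
#' \code{min(hpIndelBaseRate * hpLengthFactor^(m-1), 0.99)}. Uses the
#' current RNG state; seed at the caller (the samplers do this).
#'
#' @param seqs Character vector of A/C/G/T sequences (empty strings pass
#'   through unchanged).
#' @param error An \code{\linkS4class{ErrorModel}}.
#' @return Character vector of mutated sequences.
#' @export
apply454Errors <- function(seqs, error) {
  stopIfNot(is(error, "ErrorModel"), "error must be an ErrorModel")
  L <- nchar(seqs)
  rate <- min(error@substitutionRate, 0.999)
  if (rate > 0) {
    bases <- c("A", "C", "G", "T")
    nsub <- rbinom(length(seqs), L, rate)
    for (i in which(nsub > 0L)) {
      s <- seqs[i]
      for (j in sample.int(L[i], nsub[i])) {
        idx <- match(substr(s, j, j), bases)
        nb <- if (is.na(idx)) bases[sample.int(4L, 1L)] else
          bases[((idx - 1L + sample.int(3L, 1L)) %% 4L) + 1L]
        substr(s, j, j) <- nb
      }
      seqs[i] <- s
    }
  }
  if (error@hpIndelBaseRate > 0) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    for (i in seq_along(seqs)) {
      if (L[i] == 0L) next
      r <- rle(chars[[i]])
      p <- pmin(error@hpIndelBaseRate * error@hpLengthFactor^(r$lengths - 1), 0.99)
      fire <- runif(length(p)) < p
      if (!any(fire)) next
      delta <- ifelse(runif(sum(fire)) < 0.5, -1L, 1L)
      r$lengths[fire] <- pmax(0L, r$lengths[fire] + delta)
      seqs[i] <- paste(inverse.rle(r), collapse = "")
    }
  }
  seqs
}

# Position-ramped substitutions (Illumina): rate at base j of a read of
# nominal length `readLen` is sub + slope*(j-1)/(readLen-1).
applyPositionRampErrors <- function(seqs, error, readLen) {
  rates <- positionErrorRates(error, readLen)
  L <- nchar(seqs)
  for (j in seq_len(readLen)) {
    if (rates[j] <= 0) next
    eligible <- which(L >= j)
    if (length(eligible) == 0L) next
    hit <- eligible[runif(length(eligible)) < rates[j]]
    seqs <- substituteBases(seqs, hit, j)
  }
  seqs
}

# Per-position substitution rates implied by an ErrorModel for reads of
# nominal length readLen.
positionErrorRates <- function(error, readLen) {
  frac <- if (readLen > 1L) (seq_len(readLen) - 1) / (readLen - 1) else 0
  pmin(error@substitutionRate + error@positionRateSlope * frac, 0.999)
}

# Phred+33 quality string consistent with the per-position error rates.
qualityString <- function(error, readLen) {
  p <- pmax(positionErrorRates(error, readLen), 1e-9)
  q <- pmin(round(-10 * log10(p)), 93)
  intToUtf8(33L + as.integer(q))
}

# Integer truncated-normal draws on per-element bounds [lo, hi].
truncNormInt <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo - 0.5, mean, sd)
  phi <- pnorm(hi + 0.5, mean, sd)
  x <- round(qnorm(plo + runif(n) * (phi - plo), mean, sd))
  pmin(pmax(x, lo), hi)
}

# Shared core: draw source transcripts and fragment coordinates.
drawFragments <- function(pool, n, fragLenFun, strandProb) {
  entries <- poolEntries(pool)
  seqs <- poolSequences(pool)
  tlen <- width(seqs)[match(entries$gene_id, names(seqs))]
  idx <- sample.int(nrow(entries), n, replace = TRUE,
                    prob = as.numeric(entries$copy_number))
  len_i <- tlen[idx]
  frag <- fragLenFun(len_i)
  start <- floor(runif(n) * (len_i - frag + 1))  # 0-based
  end <- start + frag
  txt <- as.character(seqs)[match(entries$gene_id[idx], names(seqs))]
  seq <- substring(txt, start + 1, end)
  strand <- ifelse(runif(n) < strandProb, "-", "+")
  neg <- strand == "-"
  if (any(neg)) seq[neg] <- revcompChar(seq[neg])
  data.frame(sequence = seq, species_id = entries$species_id[idx],
             gene_id = entries$gene_id[idx], start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate a 454-style read set
#'
#' Samples \code{n} fragments from the transcript pool, each source
#' transcript drawn with probability proportional to its copy number.
#' Fragment lengths follow a truncated normal (defaults mean 200, sd 60,
#' bounds [40, 400]) further truncated at the transcript length, so the
#' default configuration of 250,000 reads totals about 50 Mb; the 400 bp cap
#' reflects the platform limit. Start positions are uniform, either strand
#' is sampled (unstranded library), and 454-style errors
#' (\code{\link{apply454Errors}}) are applied last. Truth fields record the
#' pre-error, sense-strand fragment coordinates (0-based, half-open).
#'
#' @param pool A \code{\linkS4class{TranscriptPool}}.
#' @param n Number of reads (default 250000).
#' @param maxLen Maximum fragment length in bp (default 400).
#' @param lengthModel List with \code{mean}, \code{sd}, \code{min},
#'   \code{max} of the truncated-normal fragment-length model.
#' @param error An \code{\linkS4class{ErrorModel}} (default
#'   \code{error454Model()}).
#' @param strandProb Probability a read comes from the antisense strand
#'   (default 0.5).
#' @param seed Integer seed; the full read set is reproducible.
#' @return data.frame with columns \code{read_id}, \code{sequence},
#'   \code{quality} (NA for 454), \code{species_id}, \code{gene_id},
#'   \code{start}, \code{end}, \code{strand}, \code{platform}, \code{short}.
#' @seealso \code{\link{sampleIlluminaReads}}, \code{\link{writeReads}}
#' @export
sample454Reads <- function(pool, n = 250000L, maxLen = 400L,
                           lengthModel = list(mean = 200, sd = 60, min = 40, max = 400),
                           error = error454Model(), strandProb = 0.5, seed = 1L) {
  stopIfNot(is(pool, "TranscriptPool"), "pool must be a TranscriptPool")
  n <- as.integer(n)
  stopIfNot(n >= 1L, "n must be positive")
  stopIfNot(maxLen >= 1L, "maxLen must be >= 1")
  withSeed(seed, {
    df <- drawFragments(pool, n, function(tlen) {
      hi <- pmin(min(maxLen, lengthModel$max), tlen)
      lo <- pmin(lengthModel$min, hi)
      truncNormInt(length(tlen), lengthModel$mean, lengthModel$sd, lo, hi)
    }, strandProb)
    df$sequence <- apply454Errors(df$sequence, error)
    data.frame(read_id = paste0("r", seq_len(n)), sequence = df$sequence,
               quality = NA_character_, species_id = df$species_id,
               gene_id = df$gene_id, start = df$start, end = df$end,
               strand = df$strand, platform = "LS454", short = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Simulate an Illumina-style single-end read set
#'
#' Samples \code{n} fixed-length reads (default 7.5 million x 100 bp, about
#' 15x the bases of the default 454 configuration). Transcripts shorter than
#' \code{readLen} are sampled whole, keeping pool weights honest, and
#' flagged \code{short = TRUE} in the truth table. Errors are
#' substitution-only with the per-base rate increasing linearly along the
#' read; Phred+33 qualities consistent with the realized per-position error
#' probability are emitted.
#'
#' @inheritParams sample454Reads
#' @param n Number of reads (default 7500000).
#' @param readLen Read length in bp (default 100).
#' @param error Default \code{errorIlluminaModel()}.
#' @return data.frame as in \code{\link{sample454Reads}}, with
#'   \code{quality} filled and \code{platform = "ILLUMINA"}.
#' @export
sampleIlluminaReads <- function(pool, n = 7500000L, readLen = 100L,
                                error = errorIlluminaModel(), strandProb = 0.5,
                                seed = 1L) {
  stopIfNot(is(pool, "TranscriptPool"), "pool must be a TranscriptPool")
  n <- as.integer(n)
  stopIfNot(n >= 1L, "n must be positive")
  readLen <- as.integer(readLen)
  stopIfNot(readLen >= 1L, "readLen must be >= 1")
  withSeed(seed, {
    df <- drawFragments(pool, n, function(tlen) pmin(readLen, tlen), strandProb)
    df$sequence <- applyPositionRampErrors(df$sequence, error, readLen)
    qual <- qualityString(error, readLen)
    L <- df$end - df$start
    data.frame(read_id = paste0("r", seq_len(n)), sequence = df$sequence,
               quality = substr(rep(qual, n), 1L, L), species_id = df$species_id,
               gene_id = df$gene_id, start = df$start, end = df$end,
               strand = df$strand, platform = "ILLUMINA", short = L < readLen,
               stringsAsFactors = FALSE)
  })
}

#' Write reads and their truth table
#'
#' 454 reads go to FASTA, Illumina reads to FASTQ (Phred+33); provenance
#' goes to a tab-separated truth table with columns \code{read_id},
#' \code{species_id}, \code{gene_id}, \code{start}, \code{end},
#' \code{strand}, \code{platform}, \code{short}. Read headers carry only the
#' read id, keeping the sequence files tool-friendly.
#'
#' @param reads data.frame from \code{\link{sample454Reads}} or
#'   \code{\link{sampleIlluminaReads}} (one platform per call).
#' @param seqPath FASTA/FASTQ output path.
#' @param truthPath Truth TSV output path.
#' @return Invisibly, \code{c(seqPath, truthPath)}.
#' @export
writeReads <- function(reads, seqPath, truthPath) {
  stopIfNot(is.data.frame(reads) && nrow(reads) > 0L, "reads must be a non-empty data.frame")
  platform <- unique(reads$platform)
  stopIfNot(length(platform) == 1L, "write one platform per file")
  dss <- DNAStringSet(reads$sequence)
  names(dss) <- reads$read_id
  if (platform == "ILLUMINA") {
    stopIfNot(all(nchar(reads$quality) == nchar(reads$sequence)),
              "quality length must equal sequence length")
    writeXStringSet(dss, seqPath, format = "fastq",
                    qualities = BStringSet(reads$quality))
  } else {
    writeXStringSet(dss, seqPath, format = "fasta")
  }
  truth <- reads[, c("read_id", "species_id", "gene_id", "start", "end",
                     "strand", "platform", "short")]
  write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(seqPath, truthPath))
}

#' Read back a simulated read set
#'
#' Inverse of \code{\link{writeReads}}: joins the sequence file (FASTA or
#' FASTQ, auto-detected from the first byte) with its truth table.
#'
#' @param seqPath FASTA/FASTQ path.
#' @param truthPath Truth TSV path.
#' @return data.frame in the layout produced by the samplers.
#' @export
readReads <- function(seqPath, truthPath) {
  first <- readChar(seqPath, 1L)
  if (identical(first, "@")) {
    # construction drops (empty) metadata columns and warns; harmless here
    qs <- suppressWarnings(readQualityScaledDNAStringSet(seqPath))
    seqs <- setNames(as.character(qs), names(qs))
    qual <- setNames(as.character(quality(qs)), names(qs))
  } else {
    s <- readDNAStringSet(seqPath)
    seqs <- setNames(as.character(s), names(s))
    qual <- setNames(rep(NA_character_, length(s)), names(s))
  }
  truth <- read.table(truthPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
  stopIfNot(setequal(truth$read_id, names(seqs)),
            "truth table and sequence file disagree on read ids")
  truth$sequence <- unname(seqs[truth$read_id])
  truth$quality <- unname(qual[truth$read_id])
  truth[, c("read_id", "sequence", "quality", "species_id", "gene_id",
            "start", "end", "strand", "platform", "short")]
}
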