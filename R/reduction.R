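# Reduction module: clustering parameter sweep, reference greedy clusterer,
# CD-HIT .clstr / SAM membership ingestion, annotation transfer.

#' The clustering parameter grid
#'
#' Cross product of overall sequence similarity C in {40, 60, 80, 100}
#' percent with representative coverage aL and member coverage aS each in
#' {0, 25, 50, 75, 100} percent: 100 parameter sets, in deterministic order
#' (C outermost, then aL, then aS).
#'
#' @return data.frame with integer columns \code{C}, \code{aL}, \code{aS}.
#' @export
parameterGrid <- function() {
  g <- expand.grid(aS = c(0L, 25L, 50L, 75L, 100L),
                   aL = c(0L, 25L, 50L, 75L, 100L),
                   C = c(40L, 60L, 80L, 100L))
  g <- g[, c("C", "aL", "aS")]
  rownames(g) <- NULL
  g
}

kmerSet <- function(s, k = 3L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# Batched global-alignment statistics of `members` against one reference:
# identity = matching columns / alignment length; covMember / covRef =
# both-residue columns / sequence length.
alignToRef <- function(members, ref) {
  st <- .alignStatsBatch(unname(members), ref)
  data.frame(identity = st[, 1] / st[, 3],
             covMember = st[, 2] / nchar(members),
             covRef = st[, 2] / nchar(ref))
}

#' Precomputed pairwise alignment statistics
#'
#' All-vs-all global-alignment identity and coverage fractions for a
#' sequence set, reusable across clustering runs (see
#' \code{\link{clusterSweep}}). Pairs sharing no amino-acid 3-mer are
#' skipped by the prefilter and recorded as identity 0.
#'
#' @param sequences Named character vector or named \code{AAStringSet}.
#' @param kmerFilter Apply the shared 3-mer prefilter (default TRUE).
#' @return List of three n x n matrices (\code{identity}, \code{covRow},
#'   \code{covCol}), dimnames = sequence ids; \code{covRow[i, j]} is the
#'   aligned fraction of sequence i when aligned to j.
#' @export
pairAlignStats <- function(sequences, kmerFilter = TRUE) {
  if (is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopIfNot(length(sequences) > 0L && !is.null(names(sequences)),
            "sequences must be named")
  n <- length(sequences)
  ids <- names(sequences)
  km <- if (kmerFilter) lapply(sequences, kmerSet) else NULL
  identity <- matrix(0, n, n, dimnames = list(ids, ids))
  covRow <- identity; covCol <- identity
  for (j in seq_len(n)) {
    cand <- seq_len(n)
    if (kmerFilter) {
      kj <- km[[j]]
      cand <- cand[vapply(cand, function(i) {
        i == j || length(km[[i]]) == 0L || length(kj) == 0L || any(km[[i]] %in% kj)
      }, logical(1))]
    }
    if (length(cand) == 0L) next
    st <- alignToRef(sequences[cand], sequences[[j]])
    identity[cand, j] <- st$identity
    covRow[cand, j] <- st$covMember
    covCol[cand, j] <- st$covRef
  }
  list(identity = identity, covRow = covRow, covCol = covCol)
}

#' Reference greedy sequence clusterer
#'
#' A longest-first greedy clusterer in the CD-HIT mould (not bit-compatible
#' with CD-HIT; external CD-HIT output can be ingested with
#' \code{\link{parseClstr}} instead). Sequences are sorted by length
#' descending (ties by id) and each joins the first existing cluster whose
#' representative it matches at identity >= C with aligned fraction of the
#' representative >= aL and of the member >= aS; otherwise it founds a new
#' cluster. Identity is matching positions over global-alignment length; a
#' coverage threshold of 0 means no constraint. A shared 3-mer prefilter
#' skips hopeless alignments.
#'
#' @param sequences Named character vector or named \code{AAStringSet} of
#'   amino-acid sequences (reads are clustered as their longest ORFs).
#' @param C Identity threshold in percent (0 < C <= 100).
#' @param aL,aS Representative / member coverage thresholds in percent.
#' @param kmerFilter Use the 3-mer prefilter (default TRUE; disable to
#'   cross-check against the unfiltered path).
#' @param cache Optional precomputed statistics from
#'   \code{\link{pairAlignStats}} on the same sequence set; makes repeated
#'   clustering of one set (the parameter sweep) cheap.
#' @return A \code{\linkS4class{ClusterSet}}.
#' @examples
#' greedyCluster(c(a = "MKLVAHEWQPRS", b = "MKLVAHEWQPRS"), C = 100)
#' @export
greedyCluster <- function(sequences, C, aL = 0, aS = 0, kmerFilter = TRUE,
                          cache = NULL) {
  if (is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopIfNot(length(sequences) > 0L, "no sequences to cluster")
  stopIfNot(!is.null(names(sequences)) && !anyDuplicated(names(sequences)),
            "sequences must have unique names")
  stopIfNot(C > 0 && C <= 100, "C must be in (0, 100]")
  if (!is.null(cache)) {
    stopIfNot(setequal(rownames(cache$identity), names(sequences)),
              "cache was computed on a different sequence set")
  }
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  ids <- names(sequences)
  n <- length(sequences)
  useKmers <- kmerFilter && is.null(cache)
  km <- if (useKmers) lapply(sequences, kmerSet) else NULL
  # inverted index: k-mer -> founding-ordered representative indices
  kmIndex <- if (useKmers) new.env(hash = TRUE, parent = emptyenv()) else NULL
  shortReps <- integer(0)       # reps too short to carry a k-mer: always candidates
  repIdx <- integer(0)          # indices (into sequences) of representatives
  assign_rep <- character(n)
  assign_idt <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(repIdx)) {
      if (useKmers) {
        ki <- km[[i]]
        cand <- if (length(ki) == 0L) repIdx else {
          hits <- unlist(mget(ki, envir = kmIndex, ifnotfound = list(NULL)),
                         use.names = FALSE)
          sort(unique(c(hits, shortReps)))     # ascending = founding order
        }
      } else {
        cand <- repIdx
      }
      if (length(cand)) {
        if (is.null(cache)) {
          # one batched alignment call: current sequence vs candidate reps
          st <- alignToRef(sequences[cand], sequences[[i]])
          idt <- st$identity; cR <- st$covMember; cM <- st$covRef
        } else {
          idt <- cache$identity[ids[i], ids[cand]]
          cM <- cache$covRow[ids[i], ids[cand]]
          cR <- cache$covCol[ids[i], ids[cand]]
        }
        ok <- idt * 100 >= C & (aL <= 0 | cR * 100 >= aL) &
          (aS <= 0 | cM * 100 >= aS)
        if (any(ok)) {
          hit <- which(ok)[1]   # first matching cluster in founding order
          assign_rep[i] <- ids[cand[hit]]
          assign_idt[i] <- idt[hit]
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      repIdx <- c(repIdx, i)
      if (useKmers) {
        if (length(km[[i]]) == 0L) {
          shortReps <- c(shortReps, i)
        } else {
          for (k in km[[i]]) kmIndex[[k]] <- c(kmIndex[[k]], i)
        }
      }
      assign_rep[i] <- ids[i]
      assign_idt[i] <- 1
    }
  }
  new("ClusterSet",
      members = data.frame(member_id = ids, representative_id = assign_rep,
                           identity = assign_idt, stringsAsFactors = FALSE),
      parameters = c(C = as.numeric(C), aL = as.numeric(aL), aS = as.numeric(aS)))
}

#' Cluster one sequence set across the whole parameter grid
#'
#' Runs \code{\link{greedyCluster}} for every (C, aL, aS) row of the grid,
#' computing pairwise alignment statistics once and reusing them, the way
#' the nested-loop clustering sweep is meant to be run.
#'
#' @inheritParams greedyCluster
#' @param grid data.frame with columns \code{C}, \code{aL}, \code{aS}
#'   (default \code{\link{parameterGrid}()}).
#' @return List of \code{\linkS4class{ClusterSet}}, one per grid row, named
#'   \code{"C<C>_aL<aL>_aS<aS>"}.
#' @export
clusterSweep <- function(sequences, grid = parameterGrid(), kmerFilter = TRUE) {
  cache <- pairAlignStats(sequences, kmerFilter = kmerFilter)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    greedyCluster(sequences, grid$C[i], grid$aL[i], grid$aS[i], cache = cache)
  })
  names(out) <- sprintf("C%d_aL%d_aS%d", grid$C, grid$aL, grid$aS)
  out
}

#' Parse a CD-HIT .clstr file
#'
#' Reads the CD-HIT cluster dialect: \code{>Cluster n} headers followed by
#' member lines such as \code{0  120aa, >id... *} (representative) or
#' \code{1  95aa, >id... at 97.50\%} (member; nucleotide mode strands like
#' \code{at +/97.50\%} are handled). Malformed lines fail with their line
#' number; a cluster with no representative fails.
#'
#' @param path Path to the .clstr file.
#' @param parameters Optional \code{c(C=, aL=, aS=)} to record on the result.
#' @return A \code{\linkS4class{ClusterSet}} (empty file -> zero clusters).
#' @export
parseClstr <- function(path, parameters = c(C = NA_real_, aL = NA_real_, aS = NA_real_)) {
  lines <- readLines(path)
  members <- character(0); reps <- character(0); idents <- numeric(0)
  cl_members <- character(0); cl_idents <- numeric(0); cl_rep <- NA_character_
  cl_line <- NA_integer_
  flush <- function() {
    if (length(cl_members) == 0L) return()
    if (is.na(cl_rep))
      stop(sprintf("%s: cluster starting at line %d has no representative (*)",
                   path, cl_line), call. = FALSE)
    members <<- c(members, cl_members)
    reps <<- c(reps, rep(cl_rep, length(cl_members)))
    idents <<- c(idents, cl_idents)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^>Cluster", line)) {
      flush()
      cl_members <- character(0); cl_idents <- numeric(0)
      cl_rep <- NA_character_; cl_line <- ln
    } else if (nzchar(trimws(line))) {
      m <- regmatches(line, regexec(
        "^[0-9]+\\s+[0-9]+(?:aa|nt), >(.+)\\.\\.\\.\\s+(\\*|at\\s+(?:[+-]/)?([0-9.]+)%)\\s*$",
        line))[[1]]
      if (length(m) == 0L)
        stop(sprintf("%s: malformed cluster line %d: %s", path, ln, line), call. = FALSE)
      id <- m[2]
      if (is.na(cl_line))
        stop(sprintf("%s: member line %d before any >Cluster header", path, ln),
             call. = FALSE)
      if (m[3] == "*") {
        if (!is.na(cl_rep))
          stop(sprintf("%s: two representatives in cluster at line %d", path, ln),
               call. = FALSE)
        cl_rep <- id
        cl_members <- c(cl_members, id); cl_idents <- c(cl_idents, 1)
      } else {
        cl_members <- c(cl_members, id)
        cl_idents <- c(cl_idents, as.numeric(m[4]) / 100)
      }
    }
  }
  flush()
  new("ClusterSet",
      members = data.frame(member_id = members, representative_id = reps,
                           identity = idents, stringsAsFactors = FALSE),
      parameters = parameters)
}

#' Read-to-contig membership from a SAM file
#'
#' Ingests an assembler's read-to-contig alignment (reads as queries,
#' contigs as references): primary alignments define membership; unmapped
#' reads and reads absent from the file become debris. Secondary (0x100) and
#' supplementary (0x800) alignments are ignored. Two primary alignments for
#' one read indicate corrupt input and fail.
#'
#' @param samPath Path to a SAM file with \code{@SQ} headers.
#' @param allReadIds Character vector of every read in the data set; debris
#'   is defined relative to this universe.
#' @return A \code{\linkS4class{ContigMembership}}.
#' @export
parseSamMembership <- function(samPath, allReadIds) {
  stopIfNot(length(allReadIds) > 0L, "allReadIds must be non-empty")
  bam <- Rsamtools::asBam(samPath, tempfile(), indexDestination = FALSE,
                          overwrite = TRUE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname")))[[1]]
  flag <- rec$flag
  primary <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  qn <- rec$qname[primary]
  rn <- as.character(rec$rname[primary])
  if (anyDuplicated(qn)) {
    dup <- qn[duplicated(qn)][1]
    stop(sprintf("read '%s' has more than one primary alignment", dup), call. = FALSE)
  }
  unknown <- setdiff(qn, allReadIds)
  stopIfNot(length(unknown) == 0L,
            sprintf("SAM contains reads not in allReadIds: %s",
                    paste(head(unknown, 3L), collapse = ", ")))
  contigs <- split(qn, rn)
  contigs <- contigs[lengths(contigs) > 0L]
  new("ContigMembership", contigs = as.list(contigs),
      debris = setdiff(allReadIds, qn))
}

#' Transfer annotations from representatives to cluster members
#'
#' Every cluster member (including the representative itself) receives
#' exactly its representative's domain set — the data-reduction payoff:
#' members that only partially cover a domain inherit the full-length
#' representative's annotation.
#'
#' @param clusters A \code{\linkS4class{ClusterSet}}.
#' @param repAnnotations Named list, representative id -> character vector
#'   of domain ids (empty sets allowed, but every representative must be
#'   present).
#' @return Named list, member id -> character vector of domain ids.
#' @export
transferAnnotations <- function(clusters, repAnnotations) {
  stopIfNot(is(clusters, "ClusterSet"), "clusters must be a ClusterSet")
  m <- clusterMembers(clusters)
  reps <- unique(m$representative_id)
  missing <- setdiff(reps, names(repAnnotations))
  stopIfNot(length(missing) == 0L,
            sprintf("no annotation entry for representatives: %s",
                    paste(head(missing, 3L), collapse = ", ")))
  setNames(lapply(m$representative_id, function(r) {
    unique(as.character(repAnnotations[[r]]))
  }), m$member_id)
}

#' Write a cluster table as TSV
#'
#' Emits \code{member_id<TAB>representative_id<TAB>identity} with a header.
#'
#' @param clusters A \code{\linkS4class{ClusterSet}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
  write.table(clusterMembers(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
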