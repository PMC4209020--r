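# Community module: continuous genome coverage -> discrete organism abundances.

#' Scale a coverage profile to discrete organism abundances
#'
#' Converts continuous genome-coverage values into discrete organism counts
#' summing to approximately \code{targetTotal} (default 1000), the population
#' size used for each simulated sample. Apportionment is largest-remainder
#' (Hamilton): each species receives \code{floor(coverage/total * target)},
#' floored at 1 so no observed species disappears, and the residual seats go
#' to the largest fractional remainders. Remainder ties break by species id
#' lexicographic order, so the result is deterministic.
#'
#' When the number of species exceeds \code{targetTotal} the min-1 floor makes
#' the exact total infeasible; the profile is still returned as long as the
#' total stays within the 1\% tolerance, otherwise construction fails.
#'
#' @param coverages data.frame with columns \code{species_id} and
#'   \code{coverage} (> 0); an optional \code{tier} column (LD/MD/HD label) is
#'   carried along unchanged but unused.
#' @param targetTotal Positive integer target population size.
#' @return A \code{\linkS4class{PopulationProfile}}.
#' @examples
#' scaleAbundances(data.frame(species_id = c("A", "B", "C"),
#'                            coverage = c(2, 1, 1)), 1000)
#' @export
scaleAbundances <- function(coverages, targetTotal = 1000L) {
  stopIfNot(is.data.frame(coverages) && nrow(coverages) > 0L,
            "coverage profile must be a non-empty data.frame")
  stopIfNot(all(c("species_id", "coverage") %in% names(coverages)),
            "coverage profile needs columns species_id and coverage")
  sp <- as.character(coverages$species_id)
  cv <- as.numeric(coverages$coverage)
  stopIfNot(!anyDuplicated(sp), "duplicate species ids in coverage profile")
  stopIfNot(all(is.finite(cv)) && all(cv > 0), "all coverages must be positive")
  targetTotal <- as.integer(targetTotal)
  stopIfNot(length(targetTotal) == 1L && targetTotal >= 1L,
            "targetTotal must be a positive integer")

  quota <- cv / sum(cv) * targetTotal
  base <- pmax(1L, as.integer(floor(quota)))
  residual <- targetTotal - sum(base)
  if (residual > 0L) {
    # Award remaining seats by largest fractional remainder; species already
    # lifted by the min-1 floor have negative remainders and come last.
    remainder <- quota - base
    ord <- order(-remainder, sp)
    take <- ord[seq_len(residual)]
    base[take] <- base[take] + 1L
  } else if (residual < 0L) {
    # Floors pushed the total over target: claw back from species that can
    # spare a copy, smallest remainder first.
    for (i in seq_len(-residual)) {
      remainder <- quota - base
      cand <- which(base > 1L)
      if (length(cand) == 0L) break
      take <- cand[order(remainder[cand], sp[cand])][1L]
      base[take] <- base[take] - 1L
    }
  }
  new("PopulationProfile", abundances = setNames(base, sp),
      targetTotal = targetTotal)
}

#' Read a coverage profile from TSV
#'
#' Expects a header line \code{species_id<TAB>coverage<TAB>tier}; the tier
#' column (LD/MD/HD) is optional.
#'
#' @param path Path to a tab-separated file.
#' @return data.frame suitable for \code{\link{scaleAbundances}}.
#' @export
readCoverageProfile <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  stopIfNot(all(c("species_id", "coverage") %in% names(df)),
            sprintf("'%s' lacks species_id/coverage columns", path))
  stopIfNot(nrow(df) > 0L, sprintf("'%s' contains no species", path))
  stopIfNot(all(df$coverage > 0), sprintf("'%s' has non-positive coverage", path))
  stopIfNot(!anyDuplicated(df$species_id), sprintf("'%s' has duplicate species ids", path))
  df
}

#' Write a population profile as TSV
#'
#' Emits \code{species_id<TAB>abundance} with a header.
#'
#' @param profile A \code{\linkS4class{PopulationProfile}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writePopulationProfile <- function(profile, path) {
  stopIfNot(is(profile, "PopulationProfile"), "profile must be a PopulationProfile")
  a <- abundances(profile)
  write.table(data.frame(species_id = names(a), abundance = unname(a)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
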