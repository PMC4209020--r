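---
title: "Simulating metatranscriptomes and scoring annotation accuracy with mtxsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating metatranscriptomes and scoring annotation accuracy with mtxsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxsim)
```

## The problem

Metatranscriptome data sets — hundreds of thousands of 454-style reads or
millions of short Illumina reads of community mRNA — are highly redundant,
and practitioners routinely reduce them (by clustering translated reads, or
by assembly into contigs plus leftover "debris") before protein-domain
annotation. Whether that reduction helps or harms the *accuracy* of the
resulting functional profile cannot be judged on real data, because the true
domain content of an environmental sample is unknown. mtxsim takes the
simulation route: it generates read sets from communities with fully known
composition, expression and per-read provenance, so any processing route
(all reads, clustered reads, contigs, debris, or combinations) can be scored
against exact ground truth.

## The community and expression model

A community is specified as a genome-coverage profile per diversity tier
(low/medium/high: LD/MD/HD, i.e. few dominant species through many evenly
covered species). `scaleAbundances()` converts coverage to discrete organism
counts summing to a target population of 1,000 organisms. Only an
approximate total is required by the study design; we use largest-remainder
(Hamilton) rounding with a floor of one copy per observed species, so the
total is exact whenever the species count allows it, scale-invariant in
the coverage units, and remainder ties break lexicographically for
determinism. The min-1 floor is a deliberate choice: a species observed in
the coverage profile should not vanish from the simulated sample merely
because of rounding.

Per-gene expression k (transcript copies per cell) follows the bounded
discrete power law

  P(k) = k^-r / sum_{j=1..kmax} j^-r,  k in {1, ..., kmax},

with defaults r = 1.69 (the E. coli microarray-calibrated exponent) and
kmax = 1000. Draws are i.i.d. per gene by exact inverse-CDF lookup on the
precomputed cumulative mass — no rejection step, so the sampler is exact and
cheap. Whether the original transcript simulator drew i.i.d. values or
assigned a deterministic rank profile is not documented; i.i.d. is our
choice and `fitExponent()` (bounded-support maximum likelihood, 1-D
numerical optimization) closes the loop by recovering r from samples to
within ±0.05 at n = 1e5. Each species gets its own RNG stream derived by
hashing (species id, root seed), so adding or removing one species never
perturbs the others' profiles.

The transcript pool multiplies expression by organism abundance:
copy_number(gene, species) = k(gene) x abundance(species). Copy numbers are
stored as weights on unique sequences — memory is O(genes), never O(copies).

## Read simulation and the surrogate error models

`sample454Reads()` draws source transcripts with probability proportional to
copy number, fragment lengths from a truncated normal (mean 200, sd 60,
bounds 40–400 bp, further truncated at the transcript length) and uniform
start positions. The platform literature fixes only the 400 bp cap and the
headline scale (250,000 reads ≈ 50 Mb); the length model's mean/sd are our
calibration to that printed scale and are exposed as parameters.
`sampleIlluminaReads()` draws fixed 100 bp single-end reads (default
7.5 million, ≈ 15x the 454 bases); transcripts shorter than the read length
are sampled whole and flagged, keeping pool weights honest. Both samplers
assume an unstranded library (strand probability 0.5) — the sources are
silent on strandedness, and six-frame ORF translation downstream makes
results strand-robust.

Sequencing errors are deliberately simple, pluggable surrogates rather than
flowgram- or quality-table-level platform emulators: the 454 model applies
per-base substitutions (default 0.1%) plus homopolymer-run indels with
probability base x factor^(run-1) (defaults 0.5%, 1.8, capped at 0.99),
gaining or losing one repeat unit; the Illumina model is substitution-only
with the rate ramping linearly 0.1% to 1.0% along the read, and FASTQ
qualities are emitted as Phred+33 values consistent with the realized
per-position error probability. Truth tables record pre-error sense-strand
coordinates (0-based, half-open), so evaluation never depends on the error
process.

## Longest-ORF translation

All nucleotide sequences entering clustering or annotation are translated
into their longest open reading frame: the maximal stop-free codon run over
all six frames, stop-to-stop, with *no* start-codon requirement — reads are
internal gene fragments, and demanding ATG would discard most true coding
signal. Partial terminal codons are ignored, N codons translate to X and are
treated as non-stop, frames are searched +1, +2, +3, -1, -2, -3 with the
first maximal run winning, and ORFs shorter than 10 amino acids (default)
are suppressed as noise. Internal translation deliberately disables
initiator-codon special-casing so CTG/TTG/GTG at a fragment boundary remain
Leu/Val.

## Data reduction

`greedyCluster()` is a reference longest-first greedy clusterer in the
CD-HIT mould: sequences sorted by length (ties by id), each joining the
first cluster whose representative it matches at identity ≥ C with aligned
fraction of representative ≥ aL and member ≥ aS, else founding a new
cluster. Identity is matching columns over global-alignment length
(Needleman–Wunsch, match +1 / mismatch −1 / gap −2, implemented in C++);
coverage of a sequence is the fraction of its residues aligned to residues.
A zero threshold means "no constraint", matching CD-HIT semantics, and a
shared amino-acid 3-mer prefilter skips hopeless pairs (its neutrality is
asserted against the unfiltered path on small sets). This is a
reference implementation, not a bit-compatible CD-HIT clone — external
CD-HIT output is ingested faithfully via `parseClstr()` when fidelity to the
real tool matters. `parameterGrid()` enumerates the canonical sweep:
C ∈ {40, 60, 80, 100} x aL, aS ∈ {0, 25, 50, 75, 100}, 100 parameter sets,
and `clusterSweep()` runs all of them from one precomputed pairwise-stats
cache. Assembly itself is out of scope: `parseSamMembership()` ingests a
read-to-contig SAM (primary alignments only; unmapped or absent reads become
debris), which is how assembler output enters the evaluation.

## Evaluation

The ground truth for a sample is its *full domain content*: each sampled
read credits every unique domain of its full-length source transcript with
weight one. Observed content counts each unique domain once per annotated
sequence, scaled by the sequence's weight — one for plain reads and debris,
cluster size for representatives, reads-mapped for contigs. The two vectors
are compared by Pearson correlation after zero-filling over the union of
domains (how absent domains are handled is unstated in the source material;
zero-filling is our declared choice).

Classification is per sequence and per domain against transcript-level
truth: predicted-and-true is a TP, predicted-and-absent an FP, true-but-
unpredicted a *potential* domain, and a sequence with neither predictions
nor true domains counts one TN. Judging TPs at the transcript level (rather
than requiring the read itself to overlap the domain) is intentional — the
whole point of annotation transfer is that members partially covering a
domain inherit a correct transcript-level call; the stricter fragment-level
truth is available via `readTruthDomains(mode = "fragment")`. A per-domain
TN over the whole domain universe would be meaningless, hence the
per-sequence definition. `selectBest()` picks the route with the largest
(TP − FP) gain over the all-reads baseline, ties broken by higher TP then
candidate order.

Contig chimerism is measured as Shannon entropy of read provenance: with
n_i member reads from source transcript i, H = −Σ (n_i/N) ln(n_i/N). We use
natural logarithm and gene-level (not copy-level) source identity; zero
entropy means a non-chimeric contig, and `zeroEntropyFraction()` summarizes
an assembly the way the contig-homogeneity percentages are quoted.

## Synthetic fixtures

Real benchmarks of this design need reference genomes and a domain
database. The fixtures module removes both dependencies: random amino-acid
motifs of 20–60 residues (mutually non-substring, so hits are unambiguous)
stand in for domain models, and synthetic CDSs are built from random
non-stop codons with motifs back-translated through a fixed one-codon-per-
amino-acid table — frame +1 translation reproduces each planted motif
exactly at its recorded coordinates, making every gene set self-annotating.
The toy scanner reports exact (or bounded-Hamming) motif occurrences, so the
"annotation" step is noiseless and evaluation logic is tested in isolation;
with 20-residue motifs the chance of a spurious exact hit in random sequence
is ~20^-20 per position, i.e. never observed. `makeDemo()` assembles
LD/MD/HD workspaces (6/12/20 species with geometric coverage decay 0.45/
0.75/0.97 — our realistic rendering of "few dominant" through "many even")
in the same file dialects the real pipeline consumes.

What the fixtures do *not* emulate: real codon usage, homologous gene
families across species (each synthetic gene is unrelated to the others, so
cross-species clustering structure is absent), HMM-style degenerate domain
models, rRNA contamination and realistic platform error spectra. Passing
tests therefore demonstrate the correctness of the accounting and the
samplers' distributional contracts, not biological realism of any particular
simulated data set.

## Numerical choices and problem sizes

Simulation-scale checks run at one tenth of the full configuration (25,000
454-style and 750,000 Illumina reads) and scale the totals back up; the
identities they verify (≈ 50 Mb per 454 data set, ≈ 15x Illumina/454 base
ratio) are linear in read count, so nothing is lost at the reduced size.
Exponent recovery uses 1e5 draws, where the MLE's sampling error is
comfortably inside ±0.05. The clustering sweep in the test suite runs all
100 parameter sets over ~70 translated reads with the shared alignment
cache. Degenerate inputs are handled explicitly: empty profiles, non-positive
coverage, ambiguity codes in gene FASTA, clusters without representatives
and duplicate primary SAM alignments all fail loudly rather than silently.

## Known limitations

The clusterer is a reference implementation whose identity definition
(global-alignment identity) only approximates CD-HIT's mode-dependent
definitions; paired-end reads, PCR duplicates and flowgram-level 454 error
structure are not modelled; assembly is consumed, never performed; and
correlated expression (e.g. elevated core-process transcripts) is left to
future refinement of the expression model.
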