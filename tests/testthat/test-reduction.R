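# Clustering sweep, greedy clusterer, external-format ingestion, transfer.

test_that("the parameter grid is the full 4 x 5 x 5 cross product", {
  g <- parameterGrid()
  expect_identical(nrow(g), 100L)
  expect_identical(nrow(unique(g)), 100L)
  expect_setequal(unique(g$C), c(40L, 60L, 80L, 100L))
  expect_setequal(unique(g$aL), c(0L, 25L, 50L, 75L, 100L))
  expect_true(any(g$C == 60 & g$aL == 25 & g$aS == 0))
  expect_true(any(g$C == 100 & g$aL == 100 & g$aS == 100))
  expect_true(any(g$C == 40 & g$aL == 0 & g$aS == 0))
  expect_identical(parameterGrid(), g)  # deterministic order
})

test_that("identical sequences cluster together at C = 100", {
  cl <- greedyCluster(c(a = "MKLVAHEWQPRSMKLV", b = "MKLVAHEWQPRSMKLV"), C = 100)
  expect_identical(length(representatives(cl)), 1L)
  expect_identical(unname(clusterSizes(cl)), 2L)
})

test_that("sequences sharing no k-mers stay apart", {
  cl <- greedyCluster(c(a = strrep("AC", 10), b = strrep("WY", 10)), C = 40)
  expect_identical(length(representatives(cl)), 2L)
})

test_that("identity and member-coverage thresholds act as documented", {
  seqs <- c(long = "AAAAAAAAAA", short = "AAAAAAAAVV")  # 80% identity, full coverage
  expect_identical(length(representatives(greedyCluster(seqs, C = 80, aS = 100))), 1L)
  expect_identical(length(representatives(greedyCluster(seqs, C = 90, aS = 100))), 2L)
  # a half-length perfect prefix: member coverage 100%, rep coverage 50%
  seqs2 <- c(whole = strrep("ARNDCQEGHI", 4), half = strrep("ARNDCQEGHI", 2))
  expect_identical(length(representatives(greedyCluster(seqs2, C = 40, aS = 100))), 1L)
  expect_identical(length(representatives(greedyCluster(seqs2, C = 40, aL = 75))), 2L)
})

test_that("clustering partitions the input and matches duplicate groups at strict parameters", {
  set.seed(51)
  base <- randomAa(12, 25:60)
  dup <- setNames(base[sample(12, 18, TRUE)], paste0("d", 1:18))
  seqs <- c(base, dup)
  cl <- greedyCluster(seqs, C = 100, aL = 100, aS = 100)
  m <- clusterMembers(cl)
  expect_setequal(m$member_id, names(seqs))
  expect_identical(sum(clusterSizes(cl)), length(seqs))
  # oracle: group by exact sequence string
  groups <- split(names(seqs), seqs)
  got <- split(m$member_id, m$representative_id)
  norm <- function(g) {
    sort(unname(vapply(g, function(x) paste(sort(x), collapse = ","), "")))
  }
  expect_identical(norm(got), norm(groups))
})

test_that("raising C never decreases the number of clusters on random fixtures", {
  for (seed in c(61, 62, 63)) {
    set.seed(seed)
    base <- randomAa(8, 30:60)
    # near-duplicates at graded divergence
    variants <- unlist(lapply(1:8, function(i) {
      v <- strsplit(base[[i]], "")[[1]]
      idx <- sample(length(v), max(1, length(v) %/% 10))
      v[idx] <- sample(AA_ALPHA, length(idx), TRUE)
      setNames(paste(v, collapse = ""), paste0("v", i))
    }))
    seqs <- c(base, variants)
    sizes <- vapply(c(40, 60, 80, 100), function(C) {
      length(representatives(greedyCluster(seqs, C)))
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("the k-mer prefilter does not change clustering on small sets", {
  set.seed(52)
  base <- randomAa(10, 30:60)
  seqs <- c(base, setNames(base[1:5], paste0("d", 1:5)))
  for (C in c(40, 80, 100)) {
    a <- clusterMembers(greedyCluster(seqs, C, kmerFilter = TRUE))
    b <- clusterMembers(greedyCluster(seqs, C, kmerFilter = FALSE))
    expect_identical(a, b)
  }
})

test_that("cached pairwise statistics reproduce direct clustering", {
  set.seed(53)
  seqs <- c(randomAa(15, 30:70), setNames(randomAa(5, 30:70)[1:5], paste0("x", 1:5)))
  cache <- pairAlignStats(seqs)
  g <- parameterGrid()[c(1, 27, 55, 100), ]
  for (i in seq_len(nrow(g))) {
    direct <- greedyCluster(seqs, g$C[i], g$aL[i], g$aS[i])
    cached <- greedyCluster(seqs, g$C[i], g$aL[i], g$aS[i], cache = cache)
    expect_identical(clusterMembers(direct), clusterMembers(cached))
  }
})

test_that("a CD-HIT .clstr file parses faithfully", {
  f <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(
    ">Cluster 0",
    "0\t120aa, >repA... *",
    "1\t95aa, >memB... at 97.50%",
    "2\t90aa, >memC... at 80.00%",
    ">Cluster 1",
    "0\t60aa, >solo... *"), f)
  cl <- parseClstr(f)
  m <- clusterMembers(cl)
  expect_identical(nrow(m), 4L)
  expect_identical(sort(unname(clusterSizes(cl))), c(1L, 3L))
  expect_equal(m$identity[m$member_id == "memB"], 0.975)
  expect_equal(m$identity[m$member_id == "repA"], 1)
  # nucleotide dialect with strand prefix
  writeLines(c(">Cluster 0", "0\t300nt, >n1... *", "1\t280nt, >n2... at +/95.00%"), f)
  expect_equal(clusterMembers(parseClstr(f))$identity[2], 0.95)
})

test_that("empty and malformed .clstr inputs behave as specified", {
  f <- withr::local_tempfile(fileext = ".clstr")
  writeLines(character(0), f)
  expect_identical(nrow(clusterMembers(parseClstr(f))), 0L)
  writeLines(c(">Cluster 0", "0\t120aa, >a... *", "garbage line"), f)
  expect_error(parseClstr(f), "line 3")
  writeLines(c(">Cluster 0", "0\t120aa, >a... at 90.00%"), f)
  expect_error(parseClstr(f), "no representative")
})

test_that("SAM membership keeps primary alignments and routes the rest to debris", {
  f <- withr::local_tempfile(fileext = ".sam")
  rows <- data.frame(
    qname = c("r1", "r2", "r3", "r4", "r3"),
    flag = c(0L, 0L, 0L, 4L, 256L),       # r4 unmapped, r3 has a secondary
    rname = c("c1", "c1", "c1", NA, "c2"),
    pos = c(1L, 5L, 9L, 0L, 1L))
  writeTinySam(rows, c("c1", "c2"), f)
  mem <- parseSamMembership(f, paste0("r", 1:6))  # r5, r6 absent from SAM
  expect_identical(sort(contigReads(mem)$c1), c("r1", "r2", "r3"))
  expect_setequal(debrisReads(mem), c("r4", "r5", "r6"))
})

test_that("header-only SAM sends every read to debris", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeTinySam(data.frame(qname = character(0), flag = integer(0),
                          rname = character(0), pos = integer(0)), "c1", f)
  mem <- parseSamMembership(f, c("a", "b"))
  expect_identical(length(contigReads(mem)), 0L)
  expect_setequal(debrisReads(mem), c("a", "b"))
})

test_that("duplicate primary alignments are rejected as corrupt", {
  f <- withr::local_tempfile(fileext = ".sam")
  rows <- data.frame(qname = c("r1", "r1"), flag = c(0L, 0L),
                     rname = c("c1", "c2"), pos = c(1L, 1L))
  writeTinySam(rows, c("c1", "c2"), f)
  expect_error(parseSamMembership(f, "r1"), "primary")
})

test_that("annotation transfer copies the representative set to every member", {
  cl <- new("ClusterSet", members = data.frame(
    member_id = c("R", "m1", "m2", "S", "n1"),
    representative_id = c("R", "R", "R", "S", "S"),
    identity = c(1, 0.9, 0.8, 1, 0.95)),
    parameters = c(C = 60, aL = 0, aS = 0))
  ann <- transferAnnotations(cl, list(R = c("PF_A"), S = character(0)))
  expect_identical(ann$m1, "PF_A")
  expect_identical(ann$m2, "PF_A")
  expect_identical(ann$n1, character(0))
  # partition property: union of member sets = union of representative sets
  expect_setequal(unique(unlist(ann)), "PF_A")
  expect_error(transferAnnotations(cl, list(R = "PF_A")), "S")
})
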