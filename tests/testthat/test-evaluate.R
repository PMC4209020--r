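# Domain-content vectors, classification, selection, entropy.

test_that("theoretical content credits each read with its gene's unique domains", {
  truth <- data.frame(read_id = paste0("r", 1:10), gene_id = "g1")
  dom <- data.frame(gene_id = "g1", domain_id = c("A", "B"),
                    aa_start = c(0L, 30L), aa_end = c(20L, 60L))
  expect_equal(theoreticalContent(truth, dom), c(A = 10, B = 10))
})

test_that("reads from domain-free genes contribute nothing", {
  truth <- data.frame(read_id = paste0("r", 1:5), gene_id = c(rep("g1", 3), rep("g0", 2)))
  dom <- data.frame(gene_id = "g1", domain_id = "A", aa_start = 0L, aa_end = 25L)
  expect_equal(theoreticalContent(truth, dom), c(A = 3))
})

test_that("theoretical content equals a brute-force per-read tally", {
  set.seed(71)
  genes <- paste0("g", 1:3)
  dom <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3"),
    domain_id = c("A", "B", "A", "B", "C", "C"),  # g3 carries C twice
    aa_start = c(0L, 30L, 5L, 0L, 40L, 90L), aa_end = c(20L, 55L, 30L, 25L, 70L, 120L))
  truth <- data.frame(read_id = paste0("r", 1:60),
                      gene_id = sample(genes, 60, TRUE))
  got <- theoreticalContent(truth, dom)
  oracle <- new.env()
  for (g in truth$gene_id) {
    for (d in unique(dom$domain_id[dom$gene_id == g])) {
      assign(d, mget(d, oracle, ifnotfound = 0)[[1]] + 1, envir = oracle)
    }
  }
  expect_equal(got[order(names(got))],
               unlist(as.list(oracle))[order(names(as.list(oracle)))])
})

test_that("observed content weights each unique domain once per sequence", {
  # a contig with 40 reads annotated {A} counts 40
  expect_equal(observedContent(list(c1 = "A"), c(c1 = 40)), c(A = 40))
  # duplicate hits within one sequence count once
  ann <- data.frame(seq_id = c("s1", "s1"), domain_id = c("A", "A"))
  expect_equal(observedContent(ann), c(A = 1))
  # additivity across routes: cluster of 5 with {A} plus a debris read with {A}
  expect_equal(observedContent(list(rep1 = "A", d1 = "A"), c(rep1 = 5, d1 = 1)),
               c(A = 6))
})

test_that("observed content is additive over a partition of sequences", {
  set.seed(72)
  ids <- paste0("s", 1:30)
  sets <- setNames(lapply(ids, function(i) {
    sample(LETTERS[1:6], sample(0:3, 1))
  }), ids)
  w <- setNames(sample(1:5, 30, TRUE), ids)
  whole <- observedContent(sets, w)
  part1 <- observedContent(sets[1:12], w)
  part2 <- observedContent(sets[13:30], w)
  merged <- tapply(c(part1, part2), c(names(part1), names(part2)), sum)
  expect_equal(whole[order(names(whole))],
               setNames(as.numeric(merged), names(merged))[order(names(merged))])
})

test_that("pearson matches hand-computed values and rejects degenerate input", {
  expect_equal(domainPearson(c(A = 1, B = 2, C = 3), c(A = 1, B = 2, C = 3)), 1)
  expect_equal(domainPearson(c(A = 1, B = 2, C = 3), c(A = 3, B = 2, C = 1)), -1)
  # covariance/sd by hand: r = sqrt(3)/2
  expect_equal(domainPearson(c(A = 2, B = 0, C = 1), c(A = 3, B = 1, C = 1)),
               0.866, tolerance = 1e-3)
  expect_error(domainPearson(c(A = 1, B = 1), c(A = 1, B = 2)), "variance")
})

test_that("classification covers the four definition cases", {
  truth <- list(s1 = "A", s2 = "A", s3 = c("A", "B"), s4 = character(0))
  pred <- list(s1 = "A", s2 = c("A", "B"))
  rep_ <- classifyAnnotations(pred, truth)
  expect_equal(unname(evalCounts(rep_)[c("TP", "FP", "TN", "potential")]),
               c(2, 1, 1, 2))
})

test_that("per-sequence accounting identities hold on random fixtures", {
  set.seed(73)
  ids <- paste0("s", 1:50)
  truth <- setNames(lapply(ids, function(i) sample(LETTERS[1:8], sample(0:3, 1))), ids)
  pred <- setNames(lapply(ids, function(i) sample(LETTERS[1:8], sample(0:3, 1))), ids)
  pred <- pred[sample(ids, 35)]  # some sequences unannotated
  rep_ <- classifyAnnotations(pred, truth)
  n_pred <- sum(lengths(lapply(pred, unique)))
  n_truth <- sum(lengths(lapply(truth, unique)))
  cnt <- evalCounts(rep_)
  expect_equal(unname(cnt["TP"] + cnt["FP"]), n_pred)
  expect_equal(unname(cnt["TP"] + cnt["potential"]), n_truth)
})

test_that("weighted classification scales counts by sequence weight", {
  truth <- list(rep1 = "A", rep2 = "B")
  pred <- list(rep1 = "A", rep2 = "C")
  w <- c(rep1 = 5, rep2 = 3)
  cnt <- evalCounts(classifyAnnotations(pred, truth, weights = w))
  expect_equal(unname(cnt["TP"]), 5)
  expect_equal(unname(cnt["FP"]), 3)
  expect_equal(unname(cnt["potential"]), 3)
})

test_that("fragment-mode truth restricts to domains the read overlaps", {
  dom <- data.frame(gene_id = "g1", domain_id = c("A", "B"),
                    aa_start = c(0L, 50L), aa_end = c(20L, 80L))
  # read covering nt 0-90 translates to aa 0-30: overlaps A only
  rt <- data.frame(read_id = "r1", gene_id = "g1", start = 0L, end = 90L)
  expect_identical(readTruthDomains(rt, dom, mode = "fragment")$r1, "A")
  expect_setequal(readTruthDomains(rt, dom, mode = "full")$r1, c("A", "B"))
})

test_that("selectBest maximizes the TP-FP gain with documented tie-breaks", {
  mk <- function(route, tp, fp) new("EvalReport", route = route, TP = tp, FP = fp,
                                    TN = 0, potential = 0, pearson = NA_real_)
  base <- mk("all", 100, 10)
  # B gains 45 > A's 40
  sel <- selectBest(list(mk("A", 150, 20), mk("B", 140, 5)), base)
  expect_identical(sel$route, "B")
  expect_equal(sel$gain, 45)
  # single candidate equal to baseline
  sel2 <- selectBest(list(mk("only", 100, 10)), base)
  expect_identical(sel2$route, "only")
  expect_equal(sel2$gain, 0)
  # tie on gain -> higher TP wins; full tie -> first candidate
  sel3 <- selectBest(list(mk("lowTP", 110, 20), mk("hiTP", 120, 30)), base)
  expect_identical(sel3$route, "hiTP")
  sel4 <- selectBest(list(mk("first", 110, 20), mk("second", 110, 20)), base)
  expect_identical(sel4$route, "first")
  expect_error(selectBest(list(), base), "at least one")
})

test_that("contig entropy matches closed forms and the formula oracle", {
  mem <- new("ContigMembership",
             contigs = list(c1 = paste0("r", 1:6), c2 = paste0("r", 7:10),
                            c3 = paste0("r", 11:14)),
             debris = character(0))
  truth <- data.frame(
    read_id = paste0("r", 1:14),
    gene_id = c(rep("g1", 6),               # homogeneous
                rep(c("g2", "g3"), 2),      # 50/50
                "g4", "g4", "g4", "g5"))    # 3:1
  H <- contigEntropy(mem, truth)
  expect_equal(unname(H["c1"]), 0)
  expect_equal(unname(H["c2"]), log(2))
  expect_equal(unname(H["c3"]), 0.5623, tolerance = 1e-4)
  # random memberships against the direct-formula oracle
  set.seed(74)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    src <- sample(paste0("g", 1:5), n, TRUE)
    m <- new("ContigMembership", contigs = list(x = paste0("q", 1:n)),
             debris = character(0))
    t2 <- data.frame(read_id = paste0("q", 1:n), gene_id = src)
    expect_equal(unname(contigEntropy(m, t2)), oracleEntropy(src))
    expect_lte(unname(contigEntropy(m, t2)), log(length(unique(src))) + 1e-12)
  }
})

test_that("zero-entropy fraction counts H = 0 contigs", {
  expect_equal(zeroEntropyFraction(c(0, 0, 0)), 1)
  expect_equal(zeroEntropyFraction(c(0, 0, 0, log(2))), 0.75)
  set.seed(75)
  h <- sample(c(0, 0.3, 0, 0.9, 0), 40, TRUE)
  expect_equal(zeroEntropyFraction(h), mean(h == 0))
  expect_error(zeroEntropyFraction(numeric(0)), "at least one")
})

test_that("cluster transfer of exact duplicates adds TPs but never FPs", {
  # 1 representative + 4 identical copies; rep annotated with its true domain
  truthSet <- c("A")
  ids <- c("R", paste0("c", 1:4))
  truth <- setNames(rep(list(truthSet), 5), ids)
  cl <- new("ClusterSet", members = data.frame(
    member_id = ids, representative_id = "R", identity = 1),
    parameters = c(C = 100, aL = 100, aS = 100))
  perRead <- classifyAnnotations(list(R = "A"), truth)      # only the rep annotated
  transferred <- classifyAnnotations(transferAnnotations(cl, list(R = "A")), truth)
  d <- evalCounts(transferred) - evalCounts(perRead)
  expect_equal(unname(d["FP"]), 0)
  expect_equal(unname(d["TP"]), 4)  # (cluster size - 1) x rep TP
})

test_that("evaluation reports serialize to TSV", {
  r1 <- new("EvalReport", route = "all", TP = 10, FP = 2, TN = 1, potential = 5,
            pearson = 0.9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEvalReports(list(r1), f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(df$route, "all")
  expect_equal(df$pearson, 0.9)
})
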