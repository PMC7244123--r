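small_setup <- function(nGroups = 3, perGroup = 3) {
  groups <- paste0("g", seq_len(nGroups))
  lt <- ladderTree(groups, perGroup = perGroup)
  list(groups = groups, tree = lt$tree,
       scheme = BranchScheme(groups, lt$species, groups[min(2, nGroups)]))
}

test_that("zero branch lengths propagate the root unchanged", {
  s <- small_setup()
  tr <- s$tree
  tr$edge.length[] <- 0
  aln <- simulateAlignment(tr, s$scheme, nCodons = 30, pocketColumns = 1:5,
                           schedule = scenarioSchedule("S1"), seed = 1)
  seqs <- alignmentSeqs(aln)
  expect_true(all(seqs == seqs[[1]]))
})

test_that("a pocket omega of zero freezes pocket amino acids", {
  s <- small_setup()
  sched <- rbind(pre = c(0, 1), appearance = c(0, 1), post = c(0, 1))
  aln <- simulateAlignment(s$tree, s$scheme, nCodons = 60, pocketColumns = 1:10,
                           schedule = sched, seed = 4)
  cm <- pocketevo:::.codonMatrix(alignmentSeqs(aln))
  aa <- matrix(pocketevo:::.translateCodons(cm), nrow(cm), ncol(cm))
  for (j in 1:10) expect_length(unique(aa[, j]), 1)
  # background evolved at omega 1: some amino-acid variation expected
  expect_gt(length(unique(as.vector(aa[, 11:60]))), 1)
})

test_that("the simulator emits neither stop codons nor indels, reproducibly", {
  s <- small_setup()
  a1 <- simulateAlignment(s$tree, s$scheme, nCodons = 50, pocketColumns = 1:5,
                          schedule = scenarioSchedule("S2"), seed = 11)
  a2 <- simulateAlignment(s$tree, s$scheme, nCodons = 50, pocketColumns = 1:5,
                          schedule = scenarioSchedule("S2"), seed = 11)
  expect_identical(alignmentSeqs(a1), alignmentSeqs(a2))
  a3 <- simulateAlignment(s$tree, s$scheme, nCodons = 50, pocketColumns = 1:5,
                          schedule = scenarioSchedule("S2"), seed = 12)
  expect_false(identical(alignmentSeqs(a1), alignmentSeqs(a3)))
  cm <- pocketevo:::.codonMatrix(alignmentSeqs(a1))
  expect_false(any(grepl("-", cm)))
  aa <- pocketevo:::.translateCodons(cm)
  expect_false(any(aa == "*"))
})

test_that("composition approaches the codon frequencies on a long branch", {
  tr <- ape::read.tree(text = "(a:10,b:10);")
  sch <- BranchScheme("g", list(g = c("a", "b")), "g")
  aln <- simulateAlignment(tr, sch, nCodons = 600, pocketColumns = 1:10,
                           schedule = scenarioSchedule("S1"), seed = 2)
  cm <- pocketevo:::.codonMatrix(alignmentSeqs(aln))
  tab <- table(factor(cm[1, 11:600], levels = senseCodons()))
  # loose uniformity check: every codon observed at plausible frequency
  expect_gt(min(tab), 0)
  expect_lt(max(tab) / 590, 4 / 61)
})

test_that("doubling branch lengths does not reduce observed substitutions", {
  s <- small_setup()
  count_subs <- function(scale, seed) {
    tr <- s$tree
    tr$edge.length <- tr$edge.length * scale
    aln <- simulateAlignment(tr, s$scheme, nCodons = 80, pocketColumns = 1:5,
                             schedule = scenarioSchedule("S2"), seed = seed)
    cm <- pocketevo:::.codonMatrix(alignmentSeqs(aln))
    sum(apply(cm, 2, function(x) length(unique(x)) - 1))
  }
  for (seed in 1:5) expect_lte(count_subs(1, seed), count_subs(2, seed) + 5)
})

test_that("generated cases have consistent species across artifacts", {
  case <- generateCase("S2", seed = 6, nCodons = 90, pocketSize = 6)
  sp <- names(alignmentSeqs(case$alignment))
  expect_setequal(sp, case$tree$tip.label)
  expect_setequal(sp, unlist(schemeSpecies(case$scheme), use.names = FALSE))
  expect_equal(case$trueLabel, "S2")
  expect_length(pocketPositions(case$pocket), 6)
  # determinism: same label and seed give byte-identical alignments
  case2 <- generateCase("S2", seed = 6, nCodons = 90, pocketSize = 6)
  expect_identical(alignmentSeqs(case$alignment), alignmentSeqs(case2$alignment))
})

test_that("scenario generators produce their defining index signatures", {
  case1 <- generateCase("S1", seed = 1)
  tab1 <- computeIndexTable(case1$alignment, case1$tree, case1$scheme, case1$pocket)
  expect_true(all(indexTable(tab1)$pct_id_pocket >= 40, na.rm = TRUE))
  case3 <- generateCase("S3", seed = 1)
  tab3 <- computeIndexTable(case3$alignment, case3$tree, case3$scheme, case3$pocket)
  tb3 <- indexTable(tab3)
  expect_gt(mean(tb3$n_nonsyn_pocket[!tb3$ligand_present]),
            mean(tb3$n_nonsyn_pocket[tb3$ligand_present]))
})

test_that("the recovery benchmark tabulates a 3 x 4 confusion matrix", {
  bm <- recoveryBenchmark(1, seed = 7, nCodons = 120, pocketSize = 8)
  expect_equal(dim(bm$confusion), c(3L, 4L))
  expect_equal(rownames(bm$confusion), c("S1", "S2", "S3"))
  expect_equal(colnames(bm$confusion), c("S1", "S2", "S3", "UNCLASSIFIED"))
  expect_equal(sum(bm$confusion), 3)
  expect_equal(nrow(bm$calls), 3)
})
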