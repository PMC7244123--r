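identity_fixture <- function() {
  # reference MKFG; sp_match identical; sp_three matches 3/4; sp_none shares
  # nothing; sp_gap gapped at two codons
  CodonAlignment(c(
    ref      = "ATGAAATTTGGA",
    sp_match = "ATGAAATTTGGA",
    sp_three = "ATGAAATTTCCA",
    sp_none  = "TGTCGTGCTCCA",
    sp_gap   = "ATG---TTT---"), reference = "ref")
}

test_that("pocket identity averages per-species matches against the reference", {
  aln <- identity_fixture()
  cols <- ColumnSet(1:4)
  sch <- BranchScheme(c("g1", "g2"),
                      list(g1 = c("sp_match", "sp_three"),
                           g2 = c("sp_none", "sp_gap")), "g1")
  r1 <- pctIdentityPocket(aln, cols, sch, "g1")
  expect_equal(unname(r1$perSpecies), c(100, 75))
  expect_equal(r1$value, 87.5)
  r2 <- pctIdentityPocket(aln, cols, sch, "g2")
  expect_equal(unname(r2$perSpecies["sp_none"]), 0)
  # gaps count as mismatches by default...
  expect_equal(unname(r2$perSpecies["sp_gap"]), 50)
  # ...but can be excluded from the denominator
  r2b <- pctIdentityPocket(aln, cols, sch, "g2", gapMode = "exclude")
  expect_equal(unname(r2b$perSpecies["sp_gap"]), 100)
})

test_that("whole-sequence identity behaves like the pocket identity over all columns", {
  aln <- identity_fixture()
  sch <- BranchScheme("g1", list(g1 = c("sp_match", "sp_three", "sp_none")), "g1")
  r <- pctIdentityWhole(aln, sch, "g1")
  expect_equal(unname(r$perSpecies), c(100, 75, 0))
  # a species identical to the reference scores 100 everywhere
  expect_equal(unname(r$perSpecies["sp_match"]), 100)
})

test_that("groups with no usable species yield the undefined sentinel", {
  aln <- CodonAlignment(c(ref = "ATGAAA", other = "------"), reference = "ref")
  sch <- BranchScheme(c("g1", "g2"), list(g1 = "other", g2 = "ref"), "g1")
  expect_warning(r <- pctIdentityPocket(aln, ColumnSet(1:2), sch, "g1"),
                 "no usable species")
  expect_true(is.na(r$value))
})

test_that("pocket-vs-whole comparison sets direction only under significance", {
  same <- stats::setNames(c(80, 81, 82), c("a", "b", "c"))
  expect_equal(comparePocketVsWhole(same, same), list(p = 1, direction = "none"))
  pocket <- stats::setNames(c(95, 96, 97, 98), letters[1:4])
  whole <- stats::setNames(c(60, 61, 62, 63), letters[1:4])
  r <- comparePocketVsWhole(pocket, whole)
  expect_lt(r$p, 0.05)
  expect_equal(r$direction, "pocket-higher")
  # Welch variant agrees with the hand-computed statistic
  rw <- comparePocketVsWhole(pocket, whole, method = "welch")
  se <- sqrt(stats::var(pocket) / 4 + stats::var(whole) / 4)
  tstat <- (mean(pocket) - mean(whole)) / se
  df <- se^4 / ((stats::var(pocket) / 4)^2 / 3 + (stats::var(whole) / 4)^2 / 3)
  expect_equal(rw$p, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(rw$direction, "pocket-higher")
  # fewer than two species: undefined sentinel
  expect_true(is.na(comparePocketVsWhole(c(a = 90), c(a = 50))$p))
})

test_that("within-branch N counts distinct residues minus one per column", {
  # columns: {K,R,R} -> 1; three monomorphic -> 0
  aln <- CodonAlignment(c(
    ref = "AAATTTGGAACA",
    s1  = "AAATTTGGAACA",
    s2  = "AGATTTGGAACA",
    s3  = "AGATTTGGAACA"), reference = "ref")
  sch <- BranchScheme("g", list(g = c("s1", "s2", "s3")), "g")
  expect_equal(countNonsynWithinBranch(aln, ColumnSet(1:4), sch, "g"), 1L)
  # 5 columns each with 3 distinct residues among 4 species -> 10
  codons <- c(K = "AAA", R = "AGA", T = "ACA", K2 = "AAG")
  rows <- c("AAA", "AGA", "ACA", "AAG")  # K, R, T, K: 3 distinct
  seqs <- vapply(rows, function(cd) strrep(cd, 5), character(1))
  names(seqs) <- paste0("t", 1:4)
  aln2 <- CodonAlignment(seqs, reference = "t1")
  sch2 <- BranchScheme("g", list(g = paste0("t", 1:4)), "g")
  expect_equal(countNonsynWithinBranch(aln2, ColumnSet(1:5), sch2, "g"), 10L)
  # upper bound and monomorphy equivalence
  expect_lte(10L, 5L * (4L - 1L))
  mono <- CodonAlignment(stats::setNames(rep(strrep("AAA", 5), 4), paste0("t", 1:4)),
                         reference = "t1")
  expect_equal(countNonsynWithinBranch(mono, ColumnSet(1:5), sch2, "g"), 0L)
})

test_that("indexes are invariant to permuting species within a group", {
  case <- generateCase("S1", seed = 5, nCodons = 90, pocketSize = 6)
  aln <- case$alignment
  cols <- mapPositionsToColumns(aln, case$pocket)
  sch <- case$scheme
  g <- schemeGroups(sch)[2]
  splist <- schemeSpecies(sch)
  splist[[g]] <- rev(splist[[g]])
  sch2 <- BranchScheme(schemeGroups(sch), splist, ligandGroup(sch))
  expect_equal(pctIdentityPocket(aln, cols, sch, g)$value,
               pctIdentityPocket(aln, cols, sch2, g)$value)
  expect_equal(countNonsynWithinBranch(aln, cols, sch, g),
               countNonsynWithinBranch(aln, cols, sch2, g))
})

test_that("computeIndexTable assembles bounded, complete per-group rows", {
  case <- generateCase("S1", seed = 3, nCodons = 120, pocketSize = 8)
  tab <- computeIndexTable(case$alignment, case$tree, case$scheme, case$pocket)
  tb <- indexTable(tab)
  expect_equal(tb$group, schemeGroups(case$scheme))
  expect_true(all(tb$pct_id_pocket >= 0 & tb$pct_id_pocket <= 100, na.rm = TRUE))
  expect_true(all(tb$p_pocket_vs_whole >= 0 & tb$p_pocket_vs_whole <= 1, na.rm = TRUE))
  expect_true(all(tb$n_nonsyn_pocket >= 0, na.rm = TRUE))
  expect_equal(tb$ligand_present,
               vapply(tb$group, function(g) ligandPresent(case$scheme, g), logical(1)),
               ignore_attr = TRUE)
  # writer emits TSV + JSON sidecar
  f <- withr::local_tempfile(fileext = ".tsv")
  writeIndexTable(tab, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.tsv$", ".json", f)))
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(tb))
})
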