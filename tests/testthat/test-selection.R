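test_that("site counts match neighbour enumeration and sum to 3", {
  expect_equal(countSites("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(countSites("ATG"), c(n = 3, s = 0))
  for (cd in senseCodons()) {
    sc <- countSites(cd)
    expect_equal(unname(sum(sc)), 3)
    expect_equal(sc, oracle_site_counts(cd))
  }
  expect_error(countSites("TAA"), "stop codon")
  expect_error(countSites("ANT"), "codon")
})

test_that("pathway counts average over stop-free shortest paths", {
  expect_equal(codonPathCounts("TTT", "TTC"), c(nd = 0, sd = 1))
  # AAA -> AGG: both orders give one synonymous and one non-synonymous step
  expect_equal(codonPathCounts("AAA", "AGG"), c(nd = 1, sd = 1))
  # AGA -> TGG: the path through TGA (stop) is excluded
  expect_equal(codonPathCounts("AGA", "TGG"), c(nd = 1, sd = 1))
  # single-position differences always split into exactly one step
  withr::local_seed(5)
  for (i in 1:50) {
    cd <- sample(senseCodons(), 1)
    ch <- strsplit(cd, "")[[1]]
    pos <- sample(3, 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    ch2 <- ch; ch2[pos] <- alt
    cd2 <- paste(ch2, collapse = "")
    if (!cd2 %in% senseCodons()) next
    pc <- codonPathCounts(cd, cd2)
    expect_equal(unname(pc["nd"] + pc["sd"]), 1)
  }
  # agreement with the explicit enumeration oracle over random pairs
  for (i in 1:100) {
    pair <- sample(senseCodons(), 2)
    expect_equal(codonPathCounts(pair[1], pair[2]),
                 oracle_path_counts(pair[1], pair[2]), tolerance = 1e-12)
  }
})

test_that("pairwiseOmega handles degenerate and hand-checkable inputs", {
  s <- random_codon_seq(25)
  est <- pairwiseOmega(s, s)
  expect_equal(est@nd, 0)
  expect_equal(est@sd, 0)
  expect_true(is.na(omegaValue(est)))
  # one synonymous third-position change: omega = 0
  s1 <- strrep("TTT", 25)
  s2 <- paste0("TTC", strrep("TTT", 24))
  est2 <- pairwiseOmega(s1, s2)
  expect_equal(est2@nd, 0)
  expect_equal(est2@sd, 1)
  expect_equal(est2@dn, 0)
  expect_gt(est2@ds, 0)
  expect_equal(omegaValue(est2), 0)
  expect_error(pairwiseOmega("ATGAAA", "ATG"), "length")
  # symmetry and gap skipping
  g1 <- "ATG---AAATTT"
  g2 <- "ATGCCCAAGTTT"
  ea <- pairwiseOmega(g1, g2)
  eb <- pairwiseOmega(g2, g1)
  expect_equal(ea@nd, eb@nd)
  expect_equal(ea@sd, eb@sd)
  expect_equal(ea@nSites, eb@nSites)
})

test_that("pairwiseOmega equals the brute-force oracle on random pairs", {
  withr::local_seed(7)
  for (i in 1:10) {
    s1 <- random_codon_seq(40)
    s2 <- random_codon_seq(40)
    est <- pairwiseOmega(s1, s2)
    oracle <- oracle_pairwise_omega(s1, s2)
    expect_equal(est@nd, oracle$nd, tolerance = 1e-9)
    expect_equal(est@sd, oracle$sd, tolerance = 1e-9)
    expect_equal(est@nSites, oracle$N, tolerance = 1e-9)
    expect_equal(est@sSites, oracle$S, tolerance = 1e-9)
  }
})

test_that("Fitch reconstruction scores and resolves deterministically", {
  t4 <- ape::read.tree(text = "((L1:1,L2:1):1,(L3:1,L4:1):1);")
  fit0 <- fitchReconstruct(t4, c(L1 = "A", L2 = "A", L3 = "A", L4 = "A"))
  expect_equal(fit0$score, 0)
  fit1 <- fitchReconstruct(t4, c(L1 = "A", L2 = "A", L3 = "B", L4 = "B"))
  expect_equal(fit1$score, 1)
  # wildcard tips match anything
  fitw <- fitchReconstruct(t4, c(L1 = "A", L2 = NA, L3 = "A", L4 = "A"),
                           alphabet = c("A", "B"))
  expect_equal(fitw$score, 0)
  # deterministic: repeated calls identical
  expect_identical(fit1, fitchReconstruct(t4, c(L1 = "A", L2 = "A",
                                                L3 = "B", L4 = "B")))
})

test_that("Fitch scores equal the exhaustive minimum on random small trees", {
  withr::local_seed(13)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:30) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    k <- sample(2:4, 1)
    st <- stats::setNames(sample(alphabet[1:k], n, replace = TRUE), tr$tip.label)
    got <- fitchReconstruct(tr, st, alphabet = alphabet[1:k])$score
    expect_equal(got, oracle_fitch_score(tr, st, alphabet[1:k]))
  }
})

test_that("branchOmega recovers a single synonymous change on a known edge", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  base <- strrep("TTT", 10)
  seqs <- c(a = base, b = base, c = base, d = base)
  # one synonymous change on d's pendant edge (TTT -> TTC at codon 4)
  substr(seqs["d"], 12, 12) <- "C"
  aln <- CodonAlignment(seqs, reference = "a")
  sch <- BranchScheme(c("left", "right"),
                      list(left = c("a", "b"), right = c("c", "d")), "right")
  part <- partitionEdges(tree, sch)
  cols <- ColumnSet(1:10)
  right <- branchOmega(part@tree, aln, cols, part, "right")
  expect_equal(right@sd, 1)
  expect_equal(right@nd, 0)
  expect_equal(omegaValue(right), 0)
  left <- branchOmega(part@tree, aln, cols, part, "left")
  expect_equal(left@sd + left@nd, 0)
  expect_true(is.na(omegaValue(left)))
})

test_that("per-group substitution counts sum to the whole-tree counts", {
  case <- generateCase("S2", seed = 9, nCodons = 120, pocketSize = 8)
  part <- partitionEdges(case$tree, case$scheme)
  cols <- mapPositionsToColumns(case$alignment, case$pocket)
  per <- lapply(schemeGroups(case$scheme), function(g)
    branchOmega(part@tree, case$alignment, cols, part, g))
  one <- BranchScheme("all", list(all = unlist(schemeSpecies(case$scheme),
                                               use.names = FALSE)), "all")
  pone <- partitionEdges(case$tree, one)
  whole <- branchOmega(pone@tree, case$alignment, cols, pone, "all")
  expect_equal(sum(vapply(per, function(x) x@nd, numeric(1))), whole@nd,
               tolerance = 1e-9)
  expect_equal(sum(vapply(per, function(x) x@sd, numeric(1))), whole@sd,
               tolerance = 1e-9)
})

test_that("site scan classifies constructed columns sensibly", {
  # 48 leaves in 24 cherries; column 2 alternates K/T within every cherry
  # (many non-synonymous changes, no synonymous ones); column 1 is monomorphic
  nwk <- paste0("(", paste(sprintf("(t%d:1,t%d:1):1", seq(1, 47, 2), seq(2, 48, 2)),
                           collapse = ","), ");")
  tree <- ape::compute.brlen(ape::multi2di(ape::read.tree(text = nwk)), 1)
  aa <- rep(c("AAA", "ACA"), 24)
  seqs <- stats::setNames(paste0("ATG", aa), paste0("t", 1:48))
  aln <- CodonAlignment(seqs, reference = "t1")
  scan <- siteSelectionScan(tree, aln, alpha = 0.05)
  expect_equal(scan$class[1], "uninformative")
  expect_equal(scan$sd[2], 0)  # every change is non-synonymous
  expect_gte(scan$nd[2], 20)
  # oracle: the exact binomial tail at the column's mean site fractions
  pnOracle <- mean(c(oracle_site_counts("AAA")["n"],
                     oracle_site_counts("ACA")["n"])) / 3
  ptail <- stats::binom.test(round(scan$nd[2]), round(scan$nd[2]),
                             pnOracle)$p.value
  expect_equal(scan$p[2], ptail)
  expect_equal(scan$class[2], "positive")
  expect_lt(scan$p[2], 0.05)
})

test_that("positive pocket-site intersection is reported faithfully", {
  call <- data.frame(column = c(10L, 55L), class = c("positive", "positive"))
  expect_equal(positiveSitesInPocket(call, ColumnSet(c(55L, 60L))),
               list(any = TRUE, sites = 55L))
  expect_equal(positiveSitesInPocket(call, ColumnSet(c(7L, 60L))),
               list(any = FALSE, sites = integer(0)))
  none <- data.frame(column = integer(0), class = character(0))
  expect_false(positiveSitesInPocket(none, ColumnSet(1:5))$any)
})
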