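## Codon sequence evolution with branch-group x site-class omega schedules.
## Evolution is an exact continuous-time codon process: single-nucleotide
## changes only, kappa-weighted mutation times target-codon frequency, scaled
## by omega for non-synonymous changes and zero into stop codons. Transition
## probabilities come from a spectral matrix exponential of the (reversible)
## 61 x 61 rate matrix, cached per (omega, kappa, branch length), so sampling
## is exact in distribution.

## unscaled rate matrix over sense codons for a given omega/kappa/frequencies
.codonRateMatrix <- function(omega, kappa, freqs) {
  sense <- senseCodons()
  code <- .geneticCode()
  ns <- length(sense)
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  chars <- strsplit(sense, "")
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      a <- chars[[i]]; b <- chars[[j]]
      d <- which(a != b)
      if (length(d) != 1) next
      rate <- freqs[j]
      if (.isTransition(a[d], b[d])) rate <- rate * kappa
      if (code[[sense[i]]] != code[[sense[j]]]) rate <- rate * omega
      Q[i, j] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## scaling constant: expected substitutions per codon under the NEUTRAL
## (omega = 1) process at equilibrium is 3 per unit branch length, i.e. branch
## lengths are expected nucleotide substitutions per site for neutral sites.
## The same constant is applied to every omega class, so purifying classes
## evolve slower and positively selected classes faster than neutral ones.
.rateScale <- function(kappa, freqs) {
  Qn <- .codonRateMatrix(1, kappa, freqs)
  3 / sum(freqs * -diag(Qn))
}

## transition probability matrix P = exp(Q * t), via symmetrization of the
## reversible Q; cached
.transitionMatrix <- function(omega, kappa, t, freqs) {
  key <- sprintf("P|%.10g|%.10g|%.10g", omega, kappa, t)
  cache <- .pkg_cache$simP
  if (is.null(cache)) cache <- .pkg_cache$simP <- new.env(parent = emptyenv())
  if (!identical(.pkg_cache$simFreqs, freqs)) {
    ## frequency set changed: drop cached decompositions
    rm(list = ls(cache), envir = cache)
    .pkg_cache$simFreqs <- freqs
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ekey <- sprintf("E|%.10g|%.10g", omega, kappa)
  eig <- cache[[ekey]]
  if (is.null(eig)) {
    Q <- .codonRateMatrix(omega, kappa, freqs) * .rateScale(kappa, freqs)
    sq <- sqrt(freqs)
    B <- Q * (sq %o% (1 / sq))       # symmetric for reversible Q
    B <- (B + t(B)) / 2              # guard numerical asymmetry
    e <- eigen(B, symmetric = TRUE)
    eig <- list(values = e$values,
                right = e$vectors / sq,       # D^{-1/2} U
                left = t(e$vectors * sq))     # U' D^{1/2}
    cache[[ekey]] <- eig
  }
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  cache[[key]] <- P
  P
}

## sample child codon indices given parent indices and a transition matrix
.evolveVector <- function(parent, P) {
  out <- integer(length(parent))
  for (u in unique(parent)) {
    idx <- which(parent == u)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE, prob = P[u, ])
  }
  out
}

#' Default omega schedule of a scenario
#'
#' Branch classes are `pre` (before ligand appearance), `appearance` (the
#' ligand-appearance group) and `post` (after appearance); site classes are
#' `pocket` and `background`.
#'
#' * S1 (pre-existing conserved pocket): pocket omega 0.02 on all branches,
#'   background 0.4.
#' * S2 (progressive acquisition): pocket omega 1.0 pre-ligand and 1.5 once
#'   the ligand is present, background 0.2.
#' * S3 (reshuffling at appearance): pocket omega 1.5 pre-ligand and at
#'   appearance, 0.02 afterwards, background 0.3.
#'
#' @param label "S1", "S2" or "S3".
#' @return 3 x 2 numeric matrix (rows pre/appearance/post, columns
#'   pocket/background).
#' @export
scenarioSchedule <- function(label) {
  m <- switch(label,
    S1 = rbind(pre = c(0.02, 0.4), appearance = c(0.02, 0.4), post = c(0.02, 0.4)),
    S2 = rbind(pre = c(1.0, 0.2), appearance = c(1.5, 0.2), post = c(1.5, 0.2)),
    S3 = rbind(pre = c(1.5, 0.3), appearance = c(1.5, 0.3), post = c(0.02, 0.3)),
    stop("unknown scenario label: ", label))
  colnames(m) <- c("pocket", "background")
  m
}

#' Simulate a codon alignment along a tree under a branch x site omega schedule
#'
#' The root sequence is drawn from the codon frequencies (sense codons only)
#' and evolved along every edge by the continuous-time codon process described
#' above; each edge's omega class is determined by its taxonomic group (via
#' [partitionEdges]) relative to the ligand-appearance group. The simulator
#' produces no indels and no stop codons. Reproducible from `seed`.
#'
#' @param tree Rooted binary `phylo` tree with branch lengths (expected
#'   nucleotide substitutions per site for neutral sites).
#' @param scheme A [BranchScheme-class] covering the tips.
#' @param nCodons Number of codons.
#' @param pocketColumns Integer vector of pocket codon columns (1-based).
#' @param schedule 3 x 2 omega matrix as returned by [scenarioSchedule].
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param codonFreqs Optional frequency vector over the 61 sense codons
#'   (default equal).
#' @param seed Integer seed.
#' @param reference Name of the reference record (default: last tip of the
#'   terminal group present in the tree).
#' @return A [CodonAlignment-class].
#' @export
simulateAlignment <- function(tree, scheme, nCodons, pocketColumns,
                              schedule, kappa = 2, codonFreqs = NULL,
                              seed = 1, reference = NULL) {
  .checkBinaryRooted(tree)
  stopifnot(all(pocketColumns >= 1), all(pocketColumns <= nCodons))
  sense <- senseCodons()
  if (is.null(codonFreqs)) codonFreqs <- rep(1 / length(sense), length(sense))
  stopifnot(length(codonFreqs) == length(sense),
            abs(sum(codonFreqs) - 1) < 1e-8)
  if (is.null(rownames(schedule))) rownames(schedule) <- c("pre", "appearance", "post")
  if (is.null(colnames(schedule))) colnames(schedule) <- c("pocket", "background")
  partition <- partitionEdges(tree, scheme)
  tree <- partition@tree
  eclass <- .edgeClasses(partition, scheme)
  isPocket <- seq_len(nCodons) %in% pocketColumns
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  states <- matrix(NA_integer_, nAll, nCodons)
  set.seed(seed)
  tr <- stats::reorder(tree, "postorder")
  root <- tr$edge[nrow(tr$edge), 1]
  states[root, ] <- sample.int(length(sense), nCodons, replace = TRUE,
                               prob = codonFreqs)
  ## parents before children: reverse postorder
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; chl <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    ## match this edge back to the partition's edge order for its class
    ei <- which(partition@tree$edge[, 1] == par & partition@tree$edge[, 2] == chl)
    cls <- eclass[ei[1]]
    child <- states[par, ]
    if (len > 0) {
      for (sc in c("pocket", "background")) {
        idx <- if (sc == "pocket") which(isPocket) else which(!isPocket)
        if (!length(idx)) next
        P <- .transitionMatrix(schedule[cls, sc], kappa, len, codonFreqs)
        child[idx] <- .evolveVector(states[par, idx], P)
      }
    }
    states[chl, ] <- child
  }
  seqs <- vapply(seq_len(nTip), function(i)
    paste(sense[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  if (is.null(reference)) {
    for (g in rev(schemeGroups(scheme))) {
      hit <- intersect(schemeSpecies(scheme, g), tree$tip.label)
      if (length(hit)) { reference <- hit[[1]]; break }
    }
  }
  CodonAlignment(seqs, reference = reference)
}

#' Build the default clade-ladder tree of ordered taxonomic groups
#'
#' A rooted ladder where each group is a clade hanging off the backbone in
#' ancestral-to-derived order. Group clades are ultrametric with leaf depth
#' `withinDepth` below the group ancestor: the first species diverges at the
#' clade root, the remaining species form a tight recent clade (pendant edges
#' `withinDepth/6`), mirroring typical ortholog panels that pair one deeper
#' lineage with a couple of close relatives. Backbone edges have length
#' `backboneLength`, so divergence between main branches is deep relative to
#' divergence within them.
#'
#' @param groups Ordered group names.
#' @param perGroup Species per group (default 3).
#' @param withinDepth Within-group leaf depth (default 0.09).
#' @param backboneLength Backbone edge length (default 0.35).
#' @return List with `tree` (a rooted binary `phylo`) and `scheme`-ready
#'   species list (named by group). Species are named `<group>_<i>`.
#' @export
ladderTree <- function(groups, perGroup = 3, withinDepth = 0.09,
                       backboneLength = 0.35) {
  cladeNewick <- function(tips, depth) {
    ## ultrametric clade at leaf depth `depth`: the first tip splits at the
    ## clade root, the rest form a tight recent clade at depth/6
    if (length(tips) == 2)
      return(sprintf("(%s:%g,%s:%g)", tips[1], depth, tips[2], depth))
    recent <- depth / 6
    tight <- function(tt, d) {
      if (length(tt) == 1) return(sprintf("%s:%g", tt, d))
      sprintf("(%s:%g,%s:%g):%g", tt[1], d / 2,
              sub(":[0-9.eE+-]+$", "", tight(tt[-1], d / 2)), d / 2, d / 2)
    }
    sub <- if (length(tips) == 3) {
      sprintf("(%s:%g,%s:%g)", tips[2], recent, tips[3], recent)
    } else {
      sub(":[0-9.eE+-]+$", "", tight(tips[-1], recent))
    }
    sprintf("(%s:%g,%s:%g)", tips[1], depth, sub, depth - recent)
  }
  species <- lapply(groups, function(g) paste0(g, "_", seq_len(perGroup)))
  names(species) <- groups
  clades <- vapply(seq_along(groups), function(i) {
    sp <- species[[i]]
    if (length(sp) == 1) sp[1] else cladeNewick(sp, withinDepth)
  }, character(1))
  ## assemble ladder from the most derived end
  n <- length(clades)
  nwk <- sprintf("%s:%g", clades[n], backboneLength)
  for (i in rev(seq_len(n - 1))) {
    nwk <- sprintf("(%s:%g,%s):%g", clades[i], backboneLength, nwk,
                   backboneLength)
  }
  nwk <- sub(":[0-9.eE+-]*$", ";", nwk)
  tree <- ape::read.tree(text = nwk)
  list(tree = tree, species = species)
}

#' Generate a synthetic receptor family under a known scenario
#'
#' Builds the default ten-group clade ladder (3 species per group), assigns
#' the ligand-appearance group (default the 4th), applies the scenario's omega
#' schedule ([scenarioSchedule]) and simulates a codon alignment. The pocket
#' is a fixed set of `pocketSize` evenly spaced codon columns. The terminal
#' group's first species is the mammalian reference.
#'
#' @param label True scenario, "S1", "S2" or "S3".
#' @param seed Integer seed.
#' @param nGroups,perGroup Tree shape (defaults 10 and 3).
#' @param nCodons Codons in the simulated receptor (default 500).
#' @param pocketSize Pocket codons (default 25).
#' @param ligandGroupIndex Index of the ligand-appearance group (default 4).
#' @param withinDepth,backboneLength Tree branch lengths (defaults 0.09, 0.35).
#' @param kappa Transition/transversion ratio (default 2).
#' @param schedule Optional omega schedule overriding the scenario default.
#' @return List of class `SyntheticCase`: `alignment`, `tree`, `scheme`,
#'   `pocket`, `trueLabel`.
#' @export
generateCase <- function(label, seed = 1, nGroups = 10, perGroup = 3,
                         nCodons = 500, pocketSize = 25,
                         ligandGroupIndex = 4, withinDepth = 0.09,
                         backboneLength = 0.35, kappa = 2, schedule = NULL) {
  stopifnot(label %in% c("S1", "S2", "S3"), ligandGroupIndex <= nGroups)
  groups <- defaultGroupTemplate()
  if (nGroups != length(groups)) groups <- paste0("group", seq_len(nGroups))
  lt <- ladderTree(groups, perGroup = perGroup, withinDepth = withinDepth,
                   backboneLength = backboneLength)
  scheme <- BranchScheme(groups, lt$species, groups[ligandGroupIndex])
  pocketCols <- unique(round(seq(3, nCodons - 2, length.out = pocketSize)))
  if (is.null(schedule)) schedule <- scenarioSchedule(label)
  reference <- lt$species[[groups[length(groups)]]][1]
  aln <- simulateAlignment(lt$tree, scheme, nCodons = nCodons,
                           pocketColumns = pocketCols, schedule = schedule,
                           kappa = kappa, seed = seed, reference = reference)
  pocket <- PocketDefinition(positions = pocketCols,
                             receptorId = paste0("synthetic_", label),
                             referenceSpecies = reference,
                             provenance = list(source = "simulation",
                                               scenario = label, seed = seed))
  structure(list(alignment = aln, tree = lt$tree, scheme = scheme,
                 pocket = pocket, trueLabel = label),
            class = "SyntheticCase")
}

#' Write a synthetic case to disk as standard artifacts
#'
#' FASTA alignment, newick tree, YAML branch scheme and pocket TSV, so that
#' generated cases are consumable by the file-based pipeline.
#'
#' @param case A `SyntheticCase` from [generateCase].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    alignment = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "tree.nwk"),
    scheme = file.path(dir, "scheme.yaml"),
    pocket = file.path(dir, "pocket.tsv"))
  writeCodonAlignment(case$alignment, paths$alignment)
  ape::write.tree(case$tree, paths$tree)
  writeBranchScheme(case$scheme, paths$scheme)
  writePocket(case$pocket, paths$pocket)
  invisible(paths)
}

#' Benchmark scenario recovery on synthetic cases
#'
#' Generates `nPerLabel` cases per scenario, runs the full pipeline (indexes,
#' selection, classification) on each, and tabulates true against called
#' labels. Deterministic given `seed`.
#'
#' @param nPerLabel Cases per scenario.
#' @param seed Master seed; per-case seeds are drawn from it.
#' @param swapSchedules If TRUE, the S1 and S3 omega schedules are swapped
#'   while the true labels are kept: a negative control under which S1
#'   recovery must collapse.
#' @param thresholds Classifier thresholds.
#' @param ... Passed on to [generateCase] (problem-size parameters).
#' @return List with `confusion` (3 x 4 matrix, rows true labels, columns
#'   S1/S2/S3/UNCLASSIFIED), `recovery` (overall fraction correct) and
#'   `calls` (per-case data.frame).
#' @export
recoveryBenchmark <- function(nPerLabel, seed = 42, swapSchedules = FALSE,
                              thresholds = scenarioThresholds(), ...) {
  stopifnot(nPerLabel >= 1)
  labels <- c("S1", "S2", "S3")
  set.seed(seed)
  caseSeeds <- matrix(sample.int(.Machine$integer.max %/% 2, 3 * nPerLabel),
                      nrow = 3, dimnames = list(labels, NULL))
  calls <- list()
  for (lab in labels) {
    sched <- if (swapSchedules && lab == "S1") scenarioSchedule("S3")
             else if (swapSchedules && lab == "S3") scenarioSchedule("S1")
             else NULL
    for (i in seq_len(nPerLabel)) {
      case <- generateCase(lab, seed = caseSeeds[lab, i], schedule = sched, ...)
      tab <- computeIndexTable(case$alignment, case$tree, case$scheme,
                               case$pocket)
      call <- classifyScenario(tab, thresholds)
      calls[[length(calls) + 1]] <- data.frame(
        true = lab, called = scenarioLabel(call),
        seed = caseSeeds[lab, i], stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  lev <- c("S1", "S2", "S3", "UNCLASSIFIED")
  confusion <- table(factor(calls$true, labels),
                     factor(calls$called, lev))
  recovery <- mean(calls$true == calls$called)
  list(confusion = unclass(confusion), recovery = recovery, calls = calls)
}
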