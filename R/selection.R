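## Counting-based selection estimators: pairwise dN/dS with pathway averaging
## and a Jukes-Cantor-style correction, per-branch dN/dS from Fitch ancestral
## reconstruction, and a per-site binomial selection scan.

## ---- Fitch parsimony -------------------------------------------------------

.checkBinaryRooted <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary (fully resolved)")
  invisible(tree)
}

## lowest set bit -> state index, for masks 1..(2^k - 1)
.lowBit <- function(mask) {
  out <- integer(length(mask))
  remaining <- mask
  bit <- 1L
  repeat {
    hit <- out == 0L & bitwAnd(remaining, bitwShiftL(1L, bit - 1L)) > 0L
    out[hit] <- bit
    if (all(out > 0L) || bit > 30L) break
    bit <- bit + 1L
  }
  out
}

## Fitch down-pass over a matrix of tip bitmasks (nTip x nCols).
## Returns per-column parsimony scores and the (nTip+nNode) x nCols mask matrix.
.fitchDown <- function(tree, tipMasks) {
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  nCols <- ncol(tipMasks)
  masks <- matrix(0L, nAll, nCols)
  masks[seq_len(nTip), ] <- tipMasks
  score <- numeric(nCols)
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chl <- tr$edge[e, 2]
    cur <- masks[par, ]
    child <- masks[chl, ]
    if (all(cur == 0L)) {
      masks[par, ] <- child
    } else {
      inter <- bitwAnd(cur, child)
      empty <- inter == 0L
      score <- score + empty
      inter[empty] <- bitwOr(cur, child)[empty]
      masks[par, ] <- inter
    }
  }
  list(score = score, masks = masks)
}

## deterministic up-pass: root takes the lexicographically smallest state in
## its set; a child keeps its parent's state when compatible, else its own
## smallest. Returns (nTip+nNode) x nCols matrix of state indices.
.fitchResolve <- function(tree, masks) {
  nAll <- nrow(masks)
  nCols <- ncol(masks)
  states <- matrix(0L, nAll, nCols)
  tr <- stats::reorder(tree, "postorder")
  root <- tr$edge[nrow(tr$edge), 1]
  states[root, ] <- .lowBit(masks[root, ])
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; chl <- tr$edge[e, 2]
    pbit <- bitwShiftL(1L, states[par, ] - 1L)
    keep <- bitwAnd(masks[chl, ], pbit) > 0L
    st <- .lowBit(masks[chl, ])
    st[keep] <- states[par, keep]
    states[chl, ] <- st
  }
  states
}

#' Fitch parsimony reconstruction of ancestral states
#'
#' Computes the minimal number of state changes on a rooted binary tree and,
#' per node, the Fitch state set plus a deterministically resolved state
#' (ties broken toward the lexicographically smallest state; a child keeps its
#' parent's state whenever its set allows). Tips with a missing (`NA`) state
#' are treated as wildcards that match anything.
#'
#' @param tree A rooted binary `phylo` tree.
#' @param states Named character vector of tip states (names = tip labels).
#' @param alphabet Optional state alphabet; defaults to the sorted unique
#'   observed states.
#' @return List with `score` (parsimony score), `sets` (list of candidate
#'   state vectors per node, tips first then internal nodes in `phylo` node
#'   numbering) and `states` (resolved state per node).
#' @export
fitchReconstruct <- function(tree, states, alphabet = NULL) {
  .checkBinaryRooted(tree)
  stopifnot(all(tree$tip.label %in% names(states) | is.na(states[tree$tip.label])))
  obs <- states[tree$tip.label]
  if (is.null(alphabet)) alphabet <- sort(unique(obs[!is.na(obs)]))
  if (length(alphabet) > 30) stop("alphabet too large for bitmask Fitch")
  if (any(!is.na(obs) & !obs %in% alphabet)) stop("state outside alphabet")
  full <- bitwShiftL(1L, length(alphabet)) - 1L
  tm <- matrix(ifelse(is.na(obs), full,
                      bitwShiftL(1L, match(obs, alphabet) - 1L)), ncol = 1)
  down <- .fitchDown(tree, tm)
  res <- .fitchResolve(tree, down$masks)
  sets <- lapply(seq_len(nrow(down$masks)), function(i) {
    m <- down$masks[i, 1]
    alphabet[bitwAnd(m, bitwShiftL(1L, seq_along(alphabet) - 1L)) > 0L]
  })
  list(score = down$score[1], sets = sets,
       states = alphabet[res[, 1]])
}

## ---- pairwise omega --------------------------------------------------------

.jcCorrect <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise dN/dS (omega) by pathway-averaged counting
#'
#' Nei-Gojobori-style estimator: synonymous and non-synonymous differences are
#' counted per differing codon pair, averaging multi-nucleotide differences
#' over all shortest mutational pathways that avoid stop codons; site totals
#' are averaged over the two sequences; proportions are corrected with the
#' Jukes-Cantor-style formula d = -(3/4) log(1 - 4p/3). Codon pairs where
#' either side is gapped, ambiguous or a stop codon are skipped.
#'
#' @param seq1,seq2 Equal-length in-frame nucleotide strings.
#' @return An [OmegaEstimate-class]. `omega` is `NA` when ds is 0 or a
#'   correction is undefined (p >= 3/4).
#' @export
pairwiseOmega <- function(seq1, seq2) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2)) stop("sequences differ in length")
  if (nchar(seq1) %% 3 != 0) stop("sequence length not a multiple of 3")
  c1 <- .codonMatrix(seq1)[1, ]; c2 <- .codonMatrix(seq2)[1, ]
  sense <- senseCodons()
  i1 <- match(c1, sense); i2 <- match(c2, sense)
  ok <- !is.na(i1) & !is.na(i2)
  sitesTab <- .siteCountTable()
  N <- (sum(sitesTab$nvec[c1[ok]]) + sum(sitesTab$nvec[c2[ok]])) / 2
  S <- (sum(sitesTab$svec[c1[ok]]) + sum(sitesTab$svec[c2[ok]])) / 2
  pm <- .pathCountMatrices()
  diff <- ok & c1 != c2
  nd <- sum(pm$nd[cbind(i1[diff], i2[diff])])
  sd <- sum(pm$sd[cbind(i1[diff], i2[diff])])
  pN <- if (N > 0) nd / N else 0
  pS <- if (S > 0) sd / S else 0
  dn <- .jcCorrect(pN); ds <- .jcCorrect(pS)
  omega <- if (is.na(dn) || is.na(ds) || ds == 0) NA_real_ else dn / ds
  OmegaEstimate(nd = nd, sd = sd, nSites = N, sSites = S,
                dn = dn, ds = ds, omega = omega)
}

## ---- shared reconstruction machinery --------------------------------------

## tip nucleotide bitmasks for the given protein columns, rows in tree tip
## order; gaps and ambiguity codes become wildcards (mask 15)
.tipNtMasks <- function(aln, tree, protCols) {
  seqs <- alignmentSeqs(aln)[tree$tip.label]
  ntIdx <- as.integer(rbind(3L * protCols - 2L, 3L * protCols - 1L, 3L * protCols))
  chm <- do.call(rbind, strsplit(seqs, ""))
  chm <- chm[, ntIdx, drop = FALSE]
  m <- matrix(15L, nrow(chm), ncol(chm))
  m[chm == "A"] <- 1L; m[chm == "C"] <- 2L
  m[chm == "G"] <- 4L; m[chm == "T"] <- 8L
  m
}

## reconstruct per-node codons at the given protein columns; returns a
## (nTip+nNode) x length(protCols) character matrix of codons
.reconstructCodons <- function(aln, tree, protCols) {
  tm <- .tipNtMasks(aln, tree, protCols)
  down <- .fitchDown(tree, tm)
  st <- .fitchResolve(tree, down$masks)
  nt <- matrix(.NUC[st], nrow(st), ncol(st))
  k <- length(protCols)
  cod <- matrix("", nrow(st), k)
  for (j in seq_len(k)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    cod[, j] <- paste0(nt[, cols[1]], nt[, cols[2]], nt[, cols[3]])
  }
  cod
}

## per-edge, per-column nd/sd from reconstructed parent -> child codon pairs.
## Returns list(nd, sd): nEdge x nCols matrices. Columns whose parent or child
## codon is a stop are skipped for that edge (counted in attr "skipped").
.edgeSubstCounts <- function(tree, codons) {
  sense <- senseCodons()
  pm <- .pathCountMatrices()
  nEdge <- nrow(tree$edge)
  nCols <- ncol(codons)
  ND <- SD <- matrix(0, nEdge, nCols)
  skipped <- 0L
  for (e in seq_len(nEdge)) {
    pc <- codons[tree$edge[e, 1], ]
    cc <- codons[tree$edge[e, 2], ]
    d <- which(pc != cc)
    if (!length(d)) next
    ip <- match(pc[d], sense); ic <- match(cc[d], sense)
    bad <- is.na(ip) | is.na(ic)
    skipped <- skipped + sum(bad)
    d <- d[!bad]; ip <- ip[!bad]; ic <- ic[!bad]
    if (length(d)) {
      ND[e, d] <- pm$nd[cbind(ip, ic)]
      SD[e, d] <- pm$sd[cbind(ip, ic)]
    }
  }
  structure(list(nd = ND, sd = SD), skipped = skipped)
}

## ---- branch omega ----------------------------------------------------------

#' Per-branch dN/dS of the binding pocket from ancestral reconstruction
#'
#' Ancestral codons at the pocket columns are inferred by per-nucleotide-site
#' Fitch parsimony; substitutions on the edges of the requested group are
#' classified synonymous / non-synonymous through the reconstructed
#' parent-to-child codon pair (multi-nucleotide differences pathway-averaged
#' as in [pairwiseOmega]). Site totals come from the reference's pocket
#' codons; dn = Nd/N and ds = Sd/S are uncorrected per-edge-sum proportions.
#'
#' @param tree Rooted binary `phylo` tree.
#' @param aln A [CodonAlignment-class].
#' @param cols Pocket [ColumnSet-class].
#' @param partition An [EdgePartition-class] for `tree`.
#' @param group Group name whose edges are counted.
#' @return An [OmegaEstimate-class]; `omega` is `NA` when Sd = 0.
#' @export
branchOmega <- function(tree, aln, cols, partition, group) {
  .checkBinaryRooted(tree)
  if (!group %in% edgeGroups(partition)) stop("group has no edges: ", group)
  p <- proteinColumns(cols)
  if (!length(p)) stop("empty pocket column set")
  codons <- .reconstructCodons(aln, tree, p)
  counts <- .edgeSubstCounts(tree, codons)
  sel <- edgeGroups(partition) == group
  nd <- sum(counts$nd[sel, , drop = FALSE])
  sd <- sum(counts$sd[sel, , drop = FALSE])
  ## site totals from the reference pocket codons
  refCod <- .codonMatrix(alignmentSeqs(aln)[referenceId(aln)])[1, p]
  sitesTab <- .siteCountTable()
  okRef <- refCod %in% senseCodons()
  N <- sum(sitesTab$nvec[refCod[okRef]])
  S <- sum(sitesTab$svec[refCod[okRef]])
  dn <- if (N > 0) nd / N else NA_real_
  ds <- if (S > 0) sd / S else NA_real_
  omega <- if (is.na(dn) || is.na(ds) || ds == 0) NA_real_ else dn / ds
  OmegaEstimate(nd = nd, sd = sd, nSites = N, sSites = S,
                dn = dn, ds = ds, omega = omega)
}

## ---- site selection scan ---------------------------------------------------

#' Per-site selection scan over the whole alignment
#'
#' For every protein column, synonymous and non-synonymous substitutions are
#' summed over all tree edges from Fitch reconstructions, and the observed
#' non-synonymous share is compared with the neutral expectation derived from
#' the column's codon site counts by a two-sided exact binomial test. A column
#' is `positive` when non-synonymous substitutions are in significant excess,
#' `purifying` on a significant deficit, `neutral` otherwise and
#' `uninformative` when no substitution was reconstructed.
#'
#' @param tree Rooted binary `phylo` tree.
#' @param aln A [CodonAlignment-class] with at least 3 records.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame (class `SiteSelectionCall`) with columns `column`,
#'   `nd`, `sd`, `score` (per-site dn - ds), `p`, `class`.
#' @export
siteSelectionScan <- function(tree, aln, alpha = 0.05) {
  .checkBinaryRooted(tree)
  if (length(tree$tip.label) < 3) stop("need >= 3 sequences")
  nCod <- codonColumns(aln)
  codons <- .reconstructCodons(aln, tree, seq_len(nCod))
  counts <- .edgeSubstCounts(tree, codons)
  ndCol <- colSums(counts$nd)
  sdCol <- colSums(counts$sd)
  ## neutral expectation from observed leaf codons per column
  cm <- .codonMatrix(alignmentSeqs(aln)[tree$tip.label])
  sitesTab <- .siteCountTable()
  nbar <- sbar <- pn <- numeric(nCod)
  for (j in seq_len(nCod)) {
    cd <- cm[, j]
    cd <- cd[cd %in% senseCodons()]
    if (length(cd)) {
      nbar[j] <- mean(sitesTab$nvec[cd])
      sbar[j] <- mean(sitesTab$svec[cd])
      pn[j] <- nbar[j] / (nbar[j] + sbar[j])
    } else {
      nbar[j] <- NA; sbar[j] <- NA; pn[j] <- NA
    }
  }
  tot <- ndCol + sdCol
  pval <- rep(NA_real_, nCod)
  cls <- rep("uninformative", nCod)
  inform <- tot > 0 & !is.na(pn)
  for (j in which(inform)) {
    x <- round(ndCol[j]); n <- round(tot[j])
    if (n < 1) { cls[j] <- "uninformative"; next }
    if (x > n) x <- n
    pval[j] <- stats::binom.test(x, n, pn[j])$p.value
    frac <- ndCol[j] / tot[j]
    if (pval[j] < alpha && frac > pn[j]) cls[j] <- "positive"
    else if (pval[j] < alpha && frac < pn[j]) cls[j] <- "purifying"
    else cls[j] <- "neutral"
  }
  score <- ifelse(!is.na(nbar) & nbar > 0, ndCol / nbar, NA) -
    ifelse(!is.na(sbar) & sbar > 0, sdCol / sbar, NA)
  out <- data.frame(column = seq_len(nCod), nd = ndCol, sd = sdCol,
                    score = score, p = pval, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("SiteSelectionCall", "data.frame")
  out
}

#' Positively selected sites falling inside the pocket
#'
#' @param call A `SiteSelectionCall` from [siteSelectionScan].
#' @param cols Pocket [ColumnSet-class].
#' @return List with `any` (logical: at least one positive pocket column) and
#'   `sites` (the intersection, as protein columns).
#' @export
positiveSitesInPocket <- function(call, cols) {
  pos <- call$column[call$class == "positive"]
  sites <- intersect(pos, proteinColumns(cols))
  list(any = length(sites) > 0, sites = sites)
}
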