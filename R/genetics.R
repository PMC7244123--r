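## Codon-level bookkeeping shared by the counting estimators and the simulator.
## All tables are built once from the standard genetic code and cached.

.pkg_cache <- new.env(parent = emptyenv())

.NUC <- c("A", "C", "G", "T")

#' Standard genetic code as a codon -> amino acid lookup
#'
#' Names are DNA codons (e.g. "ATG"), values one-letter amino acids with "*"
#' for stop codons.
#' @return Named character vector of length 64.
#' @keywords internal
.geneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  # drop alt-init attribute noise; keep plain named vector
  structure(as.character(gc), names = names(gc))
}

#' Sense codons of the standard genetic code
#' @return Character vector of 61 codons.
#' @export
senseCodons <- function() {
  if (is.null(.pkg_cache$sense)) {
    code <- .geneticCode()
    .pkg_cache$sense <- names(code)[code != "*"]
  }
  .pkg_cache$sense
}

.isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Expected synonymous and non-synonymous site counts of a codon
#'
#' For each of the three codon positions the fraction of the three possible
#' single-nucleotide changes that are synonymous contributes to the synonymous
#' site count; changes creating a stop codon count as non-synonymous. For any
#' sense codon the two counts sum to 3.
#'
#' @param codon A single sense codon, e.g. "TTT".
#' @return Named numeric vector with elements `n` (non-synonymous sites) and
#'   `s` (synonymous sites).
#' @examples
#' countSites("TTT")  # s = 1/3: only TTC is synonymous
#' countSites("ATG")  # s = 0: every neighbour changes the amino acid
#' @export
countSites <- function(codon) {
  codon <- toupper(codon)
  code <- .geneticCode()
  if (!codon %in% names(code)) stop("not a codon: ", codon)
  if (code[[codon]] == "*") stop("stop codon has no site counts: ", codon)
  if (grepl("[^ACGT]", codon)) stop("ambiguous codon: ", codon)
  tab <- .siteCountTable()
  c(n = tab$n[[codon]], s = tab$s[[codon]])
}

## site-count table over all sense codons, cached
.siteCountTable <- function() {
  if (!is.null(.pkg_cache$sites)) return(.pkg_cache$sites)
  code <- .geneticCode()
  sense <- senseCodons()
  s <- n <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    ch <- strsplit(cd, "")[[1]]
    aa <- code[[cd]]
    nsyn <- 0
    for (pos in 1:3) {
      for (alt in setdiff(.NUC, ch[pos])) {
        nb <- ch; nb[pos] <- alt
        nbc <- paste(nb, collapse = "")
        if (code[[nbc]] == aa) nsyn <- nsyn + 1  # stop neighbours are non-synonymous
      }
    }
    s[cd] <- nsyn / 3
    n[cd] <- 3 - s[cd]
  }
  .pkg_cache$sites <- list(n = as.list(n), s = as.list(s),
                           nvec = n, svec = s)
  .pkg_cache$sites
}

#' Pathway-averaged substitution counts between two sense codons
#'
#' Counts non-synonymous (`nd`) and synonymous (`sd`) steps between two codons,
#' averaged over all shortest mutational pathways that do not traverse a stop
#' codon. If every pathway passes through a stop, all steps are counted as
#' non-synonymous.
#'
#' @param codon1,codon2 Sense codons.
#' @return Named numeric vector `c(nd=, sd=)`; `nd + sd` equals the number of
#'   differing positions.
#' @export
codonPathCounts <- function(codon1, codon2) {
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  sense <- senseCodons()
  if (!codon1 %in% sense || !codon2 %in% sense)
    stop("codonPathCounts requires sense codons")
  m <- .pathCountMatrices()
  i <- match(codon1, sense); j <- match(codon2, sense)
  c(nd = m$nd[i, j], sd = m$sd[i, j])
}

## 61 x 61 nd/sd matrices, cached. Built by ordered enumeration of the
## differing positions (k! orders for k differing positions, k <= 3).
.pathCountMatrices <- function() {
  if (!is.null(.pkg_cache$paths)) return(.pkg_cache$paths)
  code <- .geneticCode()
  sense <- senseCodons()
  ns <- length(sense)
  ND <- SD <- matrix(0, ns, ns, dimnames = list(sense, sense))
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  chars <- strsplit(sense, "")
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i >= j) next
      a <- chars[[i]]; b <- chars[[j]]
      diffp <- which(a != b)
      k <- length(diffp)
      if (k == 0) next
      pm <- perms[[as.character(k)]]
      tot_nd <- 0; tot_sd <- 0; nvalid <- 0
      for (r in seq_len(nrow(pm))) {
        cur <- a; nd <- 0; sd <- 0; ok <- TRUE
        for (step in pm[r, ]) {
          pos <- diffp[step]
          nxt <- cur; nxt[pos] <- b[pos]
          nxtc <- paste(nxt, collapse = "")
          if (code[[nxtc]] == "*") { ok <- FALSE; break }
          if (code[[nxtc]] == code[[paste(cur, collapse = "")]]) sd <- sd + 1
          else nd <- nd + 1
          cur <- nxt
        }
        if (ok) { tot_nd <- tot_nd + nd; tot_sd <- tot_sd + sd; nvalid <- nvalid + 1 }
      }
      if (nvalid == 0) { ND[i, j] <- k; SD[i, j] <- 0 }
      else { ND[i, j] <- tot_nd / nvalid; SD[i, j] <- tot_sd / nvalid }
      ND[j, i] <- ND[i, j]; SD[j, i] <- SD[i, j]
    }
  }
  .pkg_cache$paths <- list(nd = ND, sd = SD)
  .pkg_cache$paths
}

## translate a vector of codon strings; "---" -> "-", anything ambiguous -> "X"
.translateCodons <- function(codons) {
  code <- .geneticCode()
  out <- unname(code[codons])
  out[codons == "---"] <- "-"
  out[is.na(out)] <- "X"
  out
}

## split aligned sequences (character vector) into a species x codon matrix
.codonMatrix <- function(seqs) {
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1, len %% 3 == 0)
  if (len == 0)
    return(matrix(character(0), nrow = length(seqs), ncol = 0,
                  dimnames = list(names(seqs), NULL)))
  ncod <- len / 3
  starts <- seq(1, len, by = 3)
  t(vapply(seqs, function(s) substring(s, starts, starts + 2), character(ncod)))
}
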