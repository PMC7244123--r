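## Per-branch conservation indexes: pocket and whole-sequence percent identity
## to the mammalian reference, their statistical comparison, and the
## within-branch non-synonymous count N.

## amino-acid matrix (species x protein columns) for an alignment
.aaMatrix <- function(aln) {
  cm <- .codonMatrix(alignmentSeqs(aln))
  m <- matrix(.translateCodons(cm), nrow(cm), ncol(cm),
              dimnames = dimnames(cm))
  m
}

## per-species percent identity to the reference over the given columns.
## Gaps (and ambiguous codons) count as mismatches; the denominator is the
## full column set. With gapMode = "exclude", columns where the species is
## gapped are dropped from that species' denominator instead.
.pctIdentity <- function(aln, protCols, species, gapMode = c("mismatch", "exclude")) {
  gapMode <- match.arg(gapMode)
  aa <- .aaMatrix(aln)
  ref <- aa[referenceId(aln), protCols]
  vals <- vapply(species, function(sp) {
    x <- aa[sp, protCols]
    if (gapMode == "exclude") {
      keep <- x != "-"
      if (!any(keep)) return(NA_real_)
      100 * sum(x[keep] == ref[keep] & ref[keep] != "-") / sum(keep)
    } else {
      100 * sum(x == ref & x != "-") / length(protCols)
    }
  }, numeric(1))
  vals
}

## species of a group usable for pocket statistics: present in the alignment,
## not the reference, and not all-gap at the pocket columns
.usableSpecies <- function(aln, protCols, scheme, group) {
  sp <- intersect(schemeSpecies(scheme, group), names(alignmentSeqs(aln)))
  sp <- setdiff(sp, referenceId(aln))
  if (!length(sp)) return(sp)
  aa <- .aaMatrix(aln)
  allGap <- vapply(sp, function(s) all(aa[s, protCols] == "-"), logical(1))
  if (any(allGap))
    message("excluded all-gap species in group ", group, ": ",
            paste(sp[allGap], collapse = ", "))
  sp[!allGap]
}

#' Percent identity of the binding pocket to the mammalian reference
#'
#' Per species: 100 x (pocket columns where the species' amino acid matches
#' the reference) / (number of pocket columns); a gap counts as a mismatch
#' (configurable). The branch value is the unweighted mean over the group's
#' species; the reference is excluded from its own group.
#'
#' @param aln A [CodonAlignment-class].
#' @param cols Pocket [ColumnSet-class].
#' @param scheme A [BranchScheme-class].
#' @param group Group name.
#' @param gapMode "mismatch" (default) or "exclude".
#' @return List with `value` (branch mean, `NA` when the group has no usable
#'   species) and `perSpecies` (named numeric vector).
#' @export
pctIdentityPocket <- function(aln, cols, scheme, group,
                              gapMode = c("mismatch", "exclude")) {
  p <- proteinColumns(cols)
  sp <- .usableSpecies(aln, p, scheme, group)
  if (!length(sp)) {
    warning("group '", group, "' has no usable species for pocket identity")
    return(list(value = NA_real_, perSpecies = numeric(0)))
  }
  v <- .pctIdentity(aln, p, sp, gapMode = match.arg(gapMode))
  list(value = mean(v, na.rm = TRUE), perSpecies = v)
}

#' Percent identity of the whole sequence to the mammalian reference
#'
#' As [pctIdentityPocket] but over all protein columns where the reference is
#' not gapped.
#'
#' @inheritParams pctIdentityPocket
#' @return List with `value` and `perSpecies`.
#' @export
pctIdentityWhole <- function(aln, scheme, group,
                             gapMode = c("mismatch", "exclude")) {
  aa <- .aaMatrix(aln)
  p <- which(aa[referenceId(aln), ] != "-")
  sp <- .usableSpecies(aln, p, scheme, group)
  if (!length(sp)) {
    warning("group '", group, "' has no usable species for whole-sequence identity")
    return(list(value = NA_real_, perSpecies = numeric(0)))
  }
  v <- .pctIdentity(aln, p, sp, gapMode = match.arg(gapMode))
  list(value = mean(v, na.rm = TRUE), perSpecies = v)
}

#' Compare pocket and whole-sequence identity within a branch
#'
#' The per-species pocket and whole-sequence identities are paired by species;
#' the default is a paired Student test on the per-species differences (the
#' two values are measured on the same species, and groups typically hold few
#' species). An unpaired Welch test is available via `method = "welch"`.
#' The direction is set by the sign of the mean difference when p < alpha,
#' else "none".
#'
#' @param pocketValues,wholeValues Named per-species percent identities.
#' @param alpha Significance level for calling a direction (default 0.05).
#' @param method "paired" (default) or "welch".
#' @return List with `p` (`NA` with fewer than 2 species) and `direction`
#'   (one of "pocket-higher", "whole-higher", "none").
#' @export
comparePocketVsWhole <- function(pocketValues, wholeValues, alpha = 0.05,
                                 method = c("paired", "welch")) {
  method <- match.arg(method)
  if (length(pocketValues) < 2 || length(wholeValues) < 2)
    return(list(p = NA_real_, direction = "none"))
  if (method == "paired") {
    common <- intersect(names(pocketValues), names(wholeValues))
    if (length(common) >= 2) {
      d <- pocketValues[common] - wholeValues[common]
    } else {
      d <- pocketValues - wholeValues  # positional pairing fallback
    }
    if (all(d == 0)) return(list(p = 1, direction = "none"))
    if (stats::sd(d) == 0) {
      ## identical nonzero differences: perfectly consistent shift
      p <- 0
    } else {
      p <- stats::t.test(d)$p.value
    }
    md <- mean(d)
  } else {
    if (stats::sd(pocketValues) == 0 && stats::sd(wholeValues) == 0) {
      md <- mean(pocketValues) - mean(wholeValues)
      p <- if (md == 0) 1 else 0
    } else {
      tt <- stats::t.test(pocketValues, wholeValues, var.equal = FALSE)
      p <- tt$p.value
      md <- mean(pocketValues) - mean(wholeValues)
    }
  }
  dir <- if (!is.na(p) && p < alpha) {
    if (md > 0) "pocket-higher" else "whole-higher"
  } else "none"
  list(p = p, direction = dir)
}

#' Within-branch non-synonymous substitution count N
#'
#' A minimum count of amino-acid-changing events among the species of one
#' group: over the pocket columns, the number of distinct amino acids observed
#' (gaps and ambiguous codons ignored) minus one, floored at zero, summed over
#' columns.
#'
#' @param aln A [CodonAlignment-class].
#' @param cols Pocket [ColumnSet-class].
#' @param scheme A [BranchScheme-class].
#' @param group Group name.
#' @return Integer count.
#' @export
countNonsynWithinBranch <- function(aln, cols, scheme, group) {
  p <- proteinColumns(cols)
  sp <- intersect(schemeSpecies(scheme, group), names(alignmentSeqs(aln)))
  if (!length(sp)) return(0L)
  aa <- .aaMatrix(aln)[sp, p, drop = FALSE]
  counts <- apply(aa, 2, function(col) {
    col <- col[!col %in% c("-", "X")]
    max(0L, length(unique(col)) - 1L)
  })
  as.integer(sum(counts))
}

#' Compute the full per-branch index table
#'
#' Runs pocket mapping, per-branch identities, the pocket-vs-whole comparison,
#' the within-branch non-synonymous count, the pocket-restricted per-branch
#' omega and the per-site selection scan, and assembles one row per group of
#' the scheme in ancestral-to-mammal order.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree Rooted binary `phylo` tree over the alignment species.
#' @param scheme A [BranchScheme-class].
#' @param pocket A [PocketDefinition-class] (positions on the reference).
#' @param alpha Significance level used in the comparison and the site scan.
#' @param gapMode Gap handling for identities ("mismatch" or "exclude").
#' @param compareMethod "paired" (default) or "welch" for the identity
#'   comparison.
#' @return An [IndexTable-class].
#' @export
computeIndexTable <- function(aln, tree, scheme, pocket, alpha = 0.05,
                              gapMode = "mismatch",
                              compareMethod = "paired") {
  .checkSchemeCoverage(scheme, names(alignmentSeqs(aln)))
  if (!setequal(tree$tip.label, names(alignmentSeqs(aln))))
    stop("tree tips and alignment species differ")
  cols <- mapPositionsToColumns(aln, pocket)
  partition <- partitionEdges(tree, scheme)
  tree <- partition@tree  # possibly rooted
  groups <- schemeGroups(scheme)
  scan <- siteSelectionScan(tree, aln, alpha = alpha)
  posSites <- as.integer(scan$column[scan$class == "positive"])
  perSpecies <- list()
  rows <- lapply(groups, function(g) {
    sp <- intersect(schemeSpecies(scheme, g), names(alignmentSeqs(aln)))
    sp <- setdiff(sp, referenceId(aln))
    if (!length(sp)) {
      return(data.frame(group = g, n_species = 0L, pct_id_pocket = NA_real_,
                        pct_id_whole = NA_real_, n_nonsyn_pocket = NA_integer_,
                        dn_pocket = NA_real_, omega_pocket = NA_real_,
                        p_pocket_vs_whole = NA_real_, direction = "none",
                        ligand_present = ligandPresent(scheme, g),
                        stringsAsFactors = FALSE))
    }
    pk <- suppressWarnings(pctIdentityPocket(aln, cols, scheme, g, gapMode = gapMode))
    wh <- suppressWarnings(pctIdentityWhole(aln, scheme, g, gapMode = gapMode))
    cmp <- comparePocketVsWhole(pk$perSpecies, wh$perSpecies, alpha = alpha,
                                method = compareMethod)
    om <- if (g %in% edgeGroups(partition)) {
      branchOmega(tree, aln, cols, partition, g)
    } else NULL
    perSpecies[[g]] <<- list(pocket = pk$perSpecies, whole = wh$perSpecies)
    data.frame(group = g, n_species = length(sp),
               pct_id_pocket = pk$value, pct_id_whole = wh$value,
               n_nonsyn_pocket = countNonsynWithinBranch(aln, cols, scheme, g),
               dn_pocket = if (is.null(om)) NA_real_ else om@dn,
               omega_pocket = if (is.null(om)) NA_real_ else om@omega,
               p_pocket_vs_whole = cmp$p, direction = cmp$direction,
               ligand_present = ligandPresent(scheme, g),
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  methods::new("IndexTable", table = tb, perSpecies = perSpecies,
               positiveSites = posSites, pocketColumns = cols,
               groups = groups, ligandGroup = ligandGroup(scheme))
}

#' Write an index table as TSV (plus a JSON sidecar)
#'
#' Columns follow the per-branch report layout: group, pct_id_pocket,
#' pct_id_whole, omega_pocket, dn_pocket, n_nonsyn_pocket, p-value, direction,
#' ligand_present. Undefined omegas are rendered as "NA".
#'
#' @param x An [IndexTable-class].
#' @param file Output TSV path; a `.json` sidecar is written next to it.
#' @return The TSV path, invisibly.
#' @export
writeIndexTable <- function(x, file) {
  ord <- c("group", "pct_id_pocket", "pct_id_whole", "omega_pocket",
           "dn_pocket", "n_nonsyn_pocket", "p_pocket_vs_whole", "direction",
           "ligand_present", "n_species")
  utils::write.table(indexTable(x)[, ord], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- sub("\\.tsv$", ".json", file)
  if (identical(json, file)) json <- paste0(file, ".json")
  jsonlite::write_json(
    list(table = indexTable(x)[, ord],
         positive_sites = x@positiveSites,
         pocket_columns = proteinColumns(x@pocketColumns)),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
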