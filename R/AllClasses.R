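## Central S4 containers. Validity checks enforce the frame/coordinate
## invariants the downstream estimators rely on.

setOldClass("phylo")

#' In-frame codon multiple sequence alignment with a designated reference
#'
#' Wraps a gapped nucleotide alignment whose records are whole-codon aligned:
#' equal widths, width divisible by 3, gaps only as whole-codon triples
#' ("---"), and no internal stop codon in the ungapped reference sequence.
#' The reference is the mammalian sequence against which pocket and
#' whole-sequence identities are computed.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of aligned coding sequences.
#' @slot reference Name of the reference record.
#' @export
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", reference = "character"))

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1) return("alignment has no records")
  nm <- names(s)
  if (is.null(nm) || anyDuplicated(nm)) return("records must have unique names")
  w <- unique(Biostrings::width(s))
  if (length(w) != 1) return("records differ in length")
  if (w %% 3 != 0) return("alignment width is not a multiple of 3")
  if (length(object@reference) != 1 || !object@reference %in% nm)
    return("reference must name one alignment record")
  chars <- as.character(s)
  cm <- .codonMatrix(chars)
  bad <- grepl("-", cm) & cm != "---"
  if (any(bad))
    return(sprintf("mid-codon gap in record(s): %s",
                   paste(unique(rownames(cm)[which(bad, arr.ind = TRUE)[, 1]]),
                         collapse = ", ")))
  refc <- cm[object@reference, ]
  refc <- refc[refc != "---"]
  if (length(refc) > 1) {
    aa <- .translateCodons(refc[-length(refc)])
    if (any(aa == "*")) return("reference has an internal stop codon")
  }
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param seqs Named character vector or `DNAStringSet` of aligned coding
#'   sequences (gaps as "-", whole codons only).
#' @param reference Name of the reference (mammalian) record.
#' @return A [CodonAlignment-class] object.
#' @export
CodonAlignment <- function(seqs, reference) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  methods::new("CodonAlignment", seqs = seqs, reference = reference)
}

#' @describeIn CodonAlignment-class Alignment records as a named character vector.
#' @param x A `CodonAlignment`.
#' @export
alignmentSeqs <- function(x) as.character(x@seqs)

#' @describeIn CodonAlignment-class Name of the reference record.
#' @export
referenceId <- function(x) x@reference

#' @describeIn CodonAlignment-class Number of codon (amino-acid) columns.
#' @export
codonColumns <- function(x) unique(Biostrings::width(x@seqs)) %/% 3L

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d records x %d codons (reference: %s)\n",
              length(object@seqs), codonColumns(object), object@reference))
})

#' Set of alignment columns at amino-acid resolution
#'
#' Ordered, strictly increasing 1-based codon column indices plus the
#' corresponding nucleotide columns.
#'
#' @slot proteinColumns Integer vector of 1-based codon column indices.
#' @slot nucleotideColumns Integer vector, 3 per protein column.
#' @export
setClass("ColumnSet",
  representation(proteinColumns = "integer", nucleotideColumns = "integer"))

setValidity("ColumnSet", function(object) {
  p <- object@proteinColumns
  if (length(p) && (any(p < 1) || is.unsorted(p, strictly = TRUE)))
    return("proteinColumns must be strictly increasing and >= 1")
  if (length(object@nucleotideColumns) != 3L * length(p))
    return("nucleotideColumns must hold 3 entries per protein column")
  TRUE
})

#' Construct a ColumnSet from protein (codon) column indices
#' @param proteinColumns 1-based codon column indices, strictly increasing.
#' @return A [ColumnSet-class].
#' @export
ColumnSet <- function(proteinColumns) {
  p <- as.integer(proteinColumns)
  nt <- as.integer(rbind(3L * p - 2L, 3L * p - 1L, 3L * p))
  methods::new("ColumnSet", proteinColumns = p, nucleotideColumns = nt)
}

#' @describeIn ColumnSet-class 1-based protein column indices.
#' @param x A `ColumnSet`.
#' @export
proteinColumns <- function(x) x@proteinColumns

setMethod("show", "ColumnSet", function(object) {
  cat(sprintf("ColumnSet: %d protein columns\n", length(object@proteinColumns)))
})

#' Ligand-binding pocket of the reference receptor
#'
#' Residue positions are 1-based ordinals over the reference protein's
#' ungapped sequence (not author numbering); the ordinal-to-author map is kept
#' in `residueMap` for traceability.
#'
#' @slot receptorId Receptor identifier.
#' @slot referenceSpecies Species of the reference sequence.
#' @slot positions Strictly increasing 1-based residue positions.
#' @slot provenance List: structure id, receptor/ligand chains, cutoff (Angstrom).
#' @slot residueMap data.frame with columns position, author_number, residue_name.
#' @export
setClass("PocketDefinition",
  representation(receptorId = "character", referenceSpecies = "character",
                 positions = "integer", provenance = "list",
                 residueMap = "data.frame"))

setValidity("PocketDefinition", function(object) {
  p <- object@positions
  if (length(p) && (any(p < 1) || is.unsorted(p, strictly = TRUE)))
    return("positions must be strictly increasing and >= 1")
  TRUE
})

#' Construct a PocketDefinition
#' @param positions 1-based residue positions in the reference protein.
#' @param receptorId,referenceSpecies Identifiers carried through to reports.
#' @param provenance List describing how the pocket was derived.
#' @param residueMap Optional ordinal-to-author-number map.
#' @return A [PocketDefinition-class].
#' @export
PocketDefinition <- function(positions, receptorId = "receptor",
                             referenceSpecies = "reference",
                             provenance = list(),
                             residueMap = data.frame()) {
  methods::new("PocketDefinition", receptorId = receptorId,
               referenceSpecies = referenceSpecies,
               positions = as.integer(positions), provenance = provenance,
               residueMap = residueMap)
}

#' @describeIn PocketDefinition-class Pocket residue positions.
#' @param x A `PocketDefinition`.
#' @export
pocketPositions <- function(x) x@positions

setMethod("show", "PocketDefinition", function(object) {
  cat(sprintf("PocketDefinition: %s, %d residues", object@receptorId,
              length(object@positions)))
  if (!is.null(object@provenance$cutoff))
    cat(sprintf(" (contact cutoff %.1f A)", object@provenance$cutoff))
  cat("\n")
})

#' Ordered taxonomic groups with species assignments and ligand appearance
#'
#' Groups are ordered most ancestral to mammals. The ligand group is the most
#' ancestral group in which the receptor's first ligand exists; that group and
#' all more derived groups count as ligand-present.
#'
#' @slot groups Ordered character vector of group names.
#' @slot species Named list (one entry per group) of species id vectors.
#' @slot ligandGroup Name of the ligand-appearance group.
#' @export
setClass("BranchScheme",
  representation(groups = "character", species = "list",
                 ligandGroup = "character"))

setValidity("BranchScheme", function(object) {
  g <- object@groups
  if (length(g) < 1 || anyDuplicated(g)) return("groups must be unique and non-empty")
  if (!identical(sort(names(object@species)), sort(g)))
    return("species list must have exactly one entry per group")
  sp <- unlist(object@species, use.names = FALSE)
  if (anyDuplicated(sp))
    return(sprintf("species assigned to more than one group: %s",
                   paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  if (length(object@ligandGroup) != 1 || !object@ligandGroup %in% g)
    return("ligandGroup must name one group")
  TRUE
})

#' Construct a BranchScheme
#' @param groups Group names, most ancestral first.
#' @param species Named list mapping each group to its species ids.
#' @param ligandGroup Group in which the first ligand appeared.
#' @return A [BranchScheme-class].
#' @export
BranchScheme <- function(groups, species, ligandGroup) {
  methods::new("BranchScheme", groups = as.character(groups),
               species = species[groups], ligandGroup = ligandGroup)
}

#' @describeIn BranchScheme-class Ordered group names.
#' @param x A `BranchScheme`.
#' @export
schemeGroups <- function(x) x@groups

#' @describeIn BranchScheme-class Species of one group (or all, as a list).
#' @param group Group name; if missing, the full list is returned.
#' @export
schemeSpecies <- function(x, group) {
  if (missing(group)) return(x@species)
  if (!group %in% x@groups) stop("unknown group: ", group)
  x@species[[group]]
}

#' @describeIn BranchScheme-class Name of the ligand-appearance group.
#' @export
ligandGroup <- function(x) x@ligandGroup

setMethod("show", "BranchScheme", function(object) {
  cat(sprintf("BranchScheme: %d groups (%s), ligand appears in '%s'\n",
              length(object@groups),
              paste(object@groups, collapse = " < "), object@ligandGroup))
})

#' Assignment of every tree edge to one taxonomic group
#'
#' @slot tree The rooted `phylo` tree the partition refers to.
#' @slot edgeGroups Character vector, one group name per row of `tree$edge`.
#' @export
setClass("EdgePartition",
  representation(tree = "phylo", edgeGroups = "character"))

setValidity("EdgePartition", function(object) {
  if (length(object@edgeGroups) != nrow(object@tree$edge))
    return("edgeGroups must label every edge exactly once")
  TRUE
})

#' @describeIn EdgePartition-class Group label per tree edge.
#' @param x An `EdgePartition`.
#' @export
edgeGroups <- function(x) x@edgeGroups

setMethod("show", "EdgePartition", function(object) {
  cat("EdgePartition:\n")
  print(table(object@edgeGroups))
})

#' Counting-based dN/dS estimate
#'
#' @slot nd,sd Pathway-averaged non-synonymous / synonymous difference counts.
#' @slot nSites,sSites Expected non-synonymous / synonymous site totals.
#' @slot dn,ds Rates (corrected for the pairwise estimator, per-edge-sum
#'   proportions for the branch estimator); `NA` when undefined.
#' @slot omega dn/ds, `NA` when ds is 0 or a correction is undefined.
#' @export
setClass("OmegaEstimate",
  representation(nd = "numeric", sd = "numeric", nSites = "numeric",
                 sSites = "numeric", dn = "numeric", ds = "numeric",
                 omega = "numeric"))

OmegaEstimate <- function(nd, sd, nSites, sSites, dn, ds, omega) {
  methods::new("OmegaEstimate", nd = nd, sd = sd, nSites = nSites,
               sSites = sSites, dn = dn, ds = ds, omega = omega)
}

#' @describeIn OmegaEstimate-class The omega (dN/dS) value, `NA` when undefined.
#' @param x An `OmegaEstimate`.
#' @export
omegaValue <- function(x) x@omega

setMethod("show", "OmegaEstimate", function(object) {
  cat(sprintf(
    "OmegaEstimate: nd=%.3f sd=%.3f N=%.2f S=%.2f dn=%s ds=%s omega=%s\n",
    object@nd, object@sd, object@nSites, object@sSites,
    format(object@dn, digits = 4), format(object@ds, digits = 4),
    ifelse(is.na(object@omega), "NA", format(object@omega, digits = 4))))
})

#' Per-branch conservation and selection indexes
#'
#' One row per taxonomic group with pocket and whole-sequence percent identity
#' to the reference, the within-branch non-synonymous count N, the pocket
#' restricted dN and omega, the pocket-vs-whole comparison, and the ligand
#' presence flag; plus table-level positively selected sites.
#'
#' @slot table data.frame of per-group indexes (see [computeIndexTable]).
#' @slot perSpecies List of per-group per-species identity values.
#' @slot positiveSites Integer protein columns called positively selected.
#' @slot pocketColumns The [ColumnSet-class] of pocket columns.
#' @slot groups Ordered group names.
#' @slot ligandGroup Ligand-appearance group.
#' @export
setClass("IndexTable",
  representation(table = "data.frame", perSpecies = "list",
                 positiveSites = "integer", pocketColumns = "ColumnSet",
                 groups = "character", ligandGroup = "character"))

setValidity("IndexTable", function(object) {
  tb <- object@table
  need <- c("group", "n_species", "pct_id_pocket", "pct_id_whole",
            "n_nonsyn_pocket", "dn_pocket", "omega_pocket",
            "p_pocket_vs_whole", "direction", "ligand_present")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  pct <- c(tb$pct_id_pocket, tb$pct_id_whole)
  if (any(!is.na(pct) & (pct < 0 | pct > 100))) return("percent identity out of [0,100]")
  p <- tb$p_pocket_vs_whole
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values out of [0,1]")
  TRUE
})

#' @describeIn IndexTable-class The per-group index table as a data.frame.
#' @param x An `IndexTable`.
#' @export
indexTable <- function(x) x@table

#' @describeIn IndexTable-class Positively selected protein columns.
#' @export
positiveSites <- function(x) x@positiveSites

setMethod("show", "IndexTable", function(object) {
  cat(sprintf("IndexTable: %d groups, pocket of %d columns, %d positively selected site(s)\n",
              nrow(object@table), length(object@pocketColumns@proteinColumns),
              length(object@positiveSites)))
  print(object@table, digits = 3, row.names = FALSE)
})

#' Scenario classification verdict with per-criterion evidence
#'
#' @slot label One of "S1", "S2", "S3", "UNCLASSIFIED".
#' @slot criteria data.frame with columns criterion, satisfied, detail.
#' @slot notes Free-text notes (e.g. precondition failures).
#' @export
setClass("ScenarioCall",
  representation(label = "character", criteria = "data.frame",
                 notes = "character"))

setValidity("ScenarioCall", function(object) {
  if (!object@label %in% c("S1", "S2", "S3", "UNCLASSIFIED"))
    return("label must be S1, S2, S3 or UNCLASSIFIED")
  TRUE
})

#' @describeIn ScenarioCall-class The scenario label.
#' @param x A `ScenarioCall`.
#' @export
scenarioLabel <- function(x) x@label

#' @describeIn ScenarioCall-class The per-criterion evidence trail.
#' @export
scenarioCriteria <- function(x) x@criteria

setMethod("show", "ScenarioCall", function(object) {
  cat(sprintf("ScenarioCall: %s\n", object@label))
  if (nzchar(object@notes)) cat("  note:", object@notes, "\n")
  print(object@criteria, row.names = FALSE)
})
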