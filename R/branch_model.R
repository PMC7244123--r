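## Ordered taxonomic groups ("main branches"), species and edge assignment,
## ligand presence.

#' Default ten-group template of the animal tree of life
#'
#' Ordered most ancestral to mammals, mirroring the major divergence branches
#' commonly used to slice receptor phylogenies. Species lists are empty and
#' must be supplied by the user (or the simulator).
#'
#' @return Character vector of ten group names.
#' @export
defaultGroupTemplate <- function() {
  c("metazoans", "bilaterians", "protostomians", "chordates", "vertebrates",
    "teleosts", "sarcopterygians", "amphibians", "sauropsids", "mammals")
}

#' Load a branch scheme from a YAML configuration
#'
#' The file lists `groups:` in ancestral-to-derived order, each with a
#' `species:` vector, plus a top-level `ligand_group:`.
#'
#' @param file Path to a YAML file.
#' @param alignmentSpecies Optional character vector; if given, every species
#'   must be assigned to a group (unassigned species are an error).
#' @return A [BranchScheme-class].
#' @export
loadBranchScheme <- function(file, alignmentSpecies = NULL) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$groups) || is.null(cfg$ligand_group))
    stop("scheme config needs 'groups' and 'ligand_group'")
  nms <- vapply(cfg$groups, function(g) g$name, character(1))
  sp <- lapply(cfg$groups, function(g) as.character(unlist(g$species)))
  names(sp) <- nms
  scheme <- BranchScheme(nms, sp, cfg$ligand_group)
  if (!is.null(alignmentSpecies)) .checkSchemeCoverage(scheme, alignmentSpecies)
  scheme
}

.checkSchemeCoverage <- function(scheme, species) {
  missing <- setdiff(species, unlist(scheme@species))
  if (length(missing))
    stop("alignment species not assigned to any group: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write a branch scheme as YAML
#' @param scheme A [BranchScheme-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeBranchScheme <- function(scheme, file) {
  cfg <- list(
    groups = lapply(schemeGroups(scheme), function(g)
      list(name = g, species = as.list(schemeSpecies(scheme, g)))),
    ligand_group = ligandGroup(scheme))
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Is the ligand present in a given group?
#'
#' The appearance group itself counts as ligand-present, as do all more
#' derived groups.
#'
#' @param scheme A [BranchScheme-class].
#' @param group Group name.
#' @return Logical flag.
#' @export
ligandPresent <- function(scheme, group) {
  g <- schemeGroups(scheme)
  if (!group %in% g) stop("unknown group: ", group)
  match(group, g) >= match(ligandGroup(scheme), g)
}

## root an unrooted tree on the split separating the most ancestral group
.rootForScheme <- function(tree, scheme) {
  if (ape::is.rooted(tree)) return(tree)
  og <- intersect(tree$tip.label, schemeSpecies(scheme, schemeGroups(scheme)[1]))
  if (!length(og)) stop("cannot root: no species of the most ancestral group in tree")
  tr <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  tr
}

#' Assign every tree edge to a taxonomic group
#'
#' Each edge is labelled with the most ancestral group among the groups of the
#' leaves descending from it: edges inside one group's clade get that group,
#' and backbone stem edges get the group diverging at that depth. Unrooted
#' trees are first rooted on the most ancestral group.
#'
#' @param tree A `phylo` tree whose tips are the alignment species.
#' @param scheme A [BranchScheme-class] covering all tips.
#' @return An [EdgePartition-class].
#' @export
partitionEdges <- function(tree, scheme) {
  .checkSchemeCoverage(scheme, tree$tip.label)
  tree <- .rootForScheme(tree, scheme)
  groups <- schemeGroups(scheme)
  tipGroup <- integer(length(tree$tip.label))
  for (gi in seq_along(groups)) {
    sp <- schemeSpecies(scheme, groups[gi])
    tipGroup[match(intersect(sp, tree$tip.label), tree$tip.label)] <- gi
  }
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  ## postorder sweep: most ancestral (minimum index) descendant group per node
  minG <- c(tipGroup, rep(NA_integer_, nNode))
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chl <- tr$edge[e, 2]
    minG[par] <- min(minG[par], minG[chl], na.rm = TRUE)
  }
  edgeG <- groups[minG[tree$edge[, 2]]]
  methods::new("EdgePartition", tree = tree, edgeGroups = edgeG)
}

#' Write an edge partition as TSV
#' @param partition An [EdgePartition-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeEdgePartition <- function(partition, file) {
  tr <- partition@tree
  lab <- c(tr$tip.label, paste0("node", seq_len(tr$Nnode) + length(tr$tip.label)))
  tb <- data.frame(parent = lab[tr$edge[, 1]], child = lab[tr$edge[, 2]],
                   length = if (is.null(tr$edge.length)) NA else tr$edge.length,
                   group = partition@edgeGroups)
  utils::write.table(tb, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## class of each edge relative to the ligand-appearance group:
## "pre", "appearance" or "post"
.edgeClasses <- function(partition, scheme) {
  groups <- schemeGroups(scheme)
  li <- match(ligandGroup(scheme), groups)
  gi <- match(partition@edgeGroups, groups)
  ifelse(gi < li, "pre", ifelse(gi == li, "appearance", "post"))
}
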