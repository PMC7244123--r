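## Binding-interface extraction from a receptor-ligand 3D complex (PDB).

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
.WATER <- c("HOH", "WAT", "DOD")

#' Read a receptor-ligand complex from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records, keeps heavy atoms (element != H)
#' of the two requested chains and resolves alternate locations to the
#' highest-occupancy conformer (ties to the first listed).
#'
#' @param file Path to a PDB file.
#' @param chains Chain identifiers to keep; default keeps all chains.
#' @return A data.frame of atoms with columns `chain`, `resno`, `insert`,
#'   `resid` (3-letter residue name), `elety` (atom name), `elesy` (element),
#'   `x`, `y`, `z`, and `type` (ATOM/HETATM), of class `c("ComplexStructure",
#'   "data.frame")`.
#' @export
readComplex <- function(file, chains = NULL) {
  if (!file.exists(file)) stop("PDB file not found: ", file)
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("unparseable PDB file: ", file,
                                           " (", conditionMessage(e), ")"))
  at <- pdb$atom
  have <- unique(at$chain)
  if (!is.null(chains)) {
    missing <- setdiff(chains, have)
    if (length(missing))
      stop(sprintf("chain(s) %s not in structure; available chains: {%s}",
                   paste(missing, collapse = ", "), paste(have, collapse = ", ")))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  ## heavy atoms only
  .element <- function(a) {
    e <- toupper(trimws(a$elesy))
    blank <- is.na(e) | e == ""
    e[blank] <- toupper(substr(gsub("[0-9]", "", trimws(a$elety[blank])), 1, 1))
    e
  }
  ele <- .element(at)
  at <- at[ele != "H" & ele != "D", , drop = FALSE]
  ## altloc resolution: within (chain, resno, insert, elety) keep highest
  ## occupancy, ties to first listed
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  out <- data.frame(chain = at$chain, resno = at$resno, insert = ins,
                    resid = at$resid, elety = at$elety, elesy = .element(at),
                    x = at$x, y = at$y, z = at$z, type = at$type,
                    stringsAsFactors = FALSE)
  class(out) <- c("ComplexStructure", "data.frame")
  out
}

## residues of a chain in file order, keyed by (resno, insert) as encountered
.chainResidues <- function(cs, chain, standardOnly = FALSE) {
  a <- cs[cs$chain == chain, , drop = FALSE]
  if (standardOnly) a <- a[a$resid %in% .STANDARD_AA, , drop = FALSE]
  key <- paste(a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  data.frame(key = key[first], resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], stringsAsFactors = FALSE)
}

#' Extract the ligand-binding interface residues of the receptor chain
#'
#' A receptor residue belongs to the pocket when at least one of its heavy
#' atoms lies within `cutoff` Angstrom of at least one heavy atom of the
#' ligand chain. Only standard amino-acid residues of the receptor chain are
#' eligible; waters are excluded from both chains, all other ligand-chain
#' heavy atoms count. Positions are reported as 1-based ordinals along the
#' receptor chain's resolved residues in file order (ordered by residue
#' number and insertion code as encountered), with the ordinal-to-author-number
#' map kept in the result for traceability.
#'
#' @param complex A `ComplexStructure` from [readComplex].
#' @param receptorChain,ligandChain Chain identifiers.
#' @param cutoff Heavy-atom contact distance in Angstrom (default 5.0).
#' @param receptorId Identifier stored in the result.
#' @return A [PocketDefinition-class]; empty (with a warning) when no residue
#'   is within the cutoff.
#' @export
extractInterface <- function(complex, receptorChain, ligandChain,
                             cutoff = 5.0, receptorId = "receptor") {
  stopifnot(inherits(complex, "ComplexStructure"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  have <- unique(complex$chain)
  for (ch in c(receptorChain, ligandChain))
    if (!ch %in% have)
      stop(sprintf("chain %s not in structure; available chains: {%s}",
                   ch, paste(have, collapse = ", ")))
  rec <- complex[complex$chain == receptorChain &
                   complex$resid %in% .STANDARD_AA, , drop = FALSE]
  lig <- complex[complex$chain == ligandChain &
                   !complex$resid %in% .WATER, , drop = FALSE]
  residues <- .chainResidues(complex, receptorChain, standardOnly = TRUE)
  hit <- character(0)
  if (nrow(rec) && nrow(lig)) {
    ## squared-distance test per receptor atom against all ligand atoms
    lx <- lig$x; ly <- lig$y; lz <- lig$z
    cut2 <- cutoff^2
    close <- vapply(seq_len(nrow(rec)), function(i) {
      d2 <- (lx - rec$x[i])^2 + (ly - rec$y[i])^2 + (lz - rec$z[i])^2
      any(d2 <= cut2)
    }, logical(1))
    hit <- unique(paste(rec$resno[close], rec$insert[close], sep = "|"))
  }
  ord <- which(residues$key %in% hit)
  if (!length(ord))
    warning("no receptor residue within ", cutoff,
            " A of the ligand chain: empty pocket")
  rmap <- data.frame(position = ord,
                     author_number = residues$resno[ord],
                     insert = residues$insert[ord],
                     residue_name = residues$resid[ord],
                     stringsAsFactors = FALSE)
  PocketDefinition(positions = ord, receptorId = receptorId,
                   provenance = list(receptor_chain = receptorChain,
                                     ligand_chain = ligandChain,
                                     cutoff = cutoff),
                   residueMap = rmap)
}

#' Write a pocket definition as TSV with a JSON provenance header
#'
#' @param pocket A [PocketDefinition-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writePocket <- function(pocket, file) {
  prov <- jsonlite::toJSON(pocket@provenance, auto_unbox = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", prov), con)
  rm <- pocket@residueMap
  if (!nrow(rm))
    rm <- data.frame(position = pocket@positions,
                     author_number = NA_integer_, insert = "",
                     residue_name = NA_character_)
  rm$receptor_id <- pocket@receptorId
  utils::write.table(rm[, c("receptor_id", "position", "author_number",
                            "residue_name")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a pocket definition written by [writePocket]
#' @param file Path to a pocket TSV.
#' @return A [PocketDefinition-class].
#' @export
readPocket <- function(file) {
  lines <- readLines(file)
  prov <- list()
  hdr <- grepl("^# provenance: ", lines)
  if (any(hdr))
    prov <- jsonlite::fromJSON(sub("^# provenance: ", "", lines[which(hdr)[1]]))
  tb <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  PocketDefinition(positions = sort(unique(tb$position)),
                   receptorId = if (nrow(tb)) tb$receptor_id[1] else "receptor",
                   provenance = as.list(prov), residueMap = tb)
}
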