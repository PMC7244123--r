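# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's internal tables and algorithms:
# the genetic code comes straight from Biostrings, pathway enumeration is
# written as explicit recursion, Fitch is checked by exhaustive labelling.

GC_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(GC_TABLE) <- names(Biostrings::GENETIC_CODE)
SENSE <- names(GC_TABLE)[GC_TABLE != "*"]

# --- brute-force pathway counts ------------------------------------------

# enumerate every ordering of the differing positions step by step
oracle_path_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffp <- which(a != b)
  if (!length(diffp)) return(c(nd = 0, sd = 0))
  paths <- list()
  walk <- function(cur, remaining, nd, sd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(nd = nd, sd = sd)
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      nxt[pos] <- b[pos]
      nxtc <- paste(nxt, collapse = "")
      if (GC_TABLE[[nxtc]] == "*") next
      syn <- GC_TABLE[[nxtc]] == GC_TABLE[[paste(cur, collapse = "")]]
      walk(nxt, remaining[-k], nd + !syn, sd + syn)
    }
  }
  walk(a, diffp, 0, 0)
  if (!length(paths)) return(c(nd = length(diffp), sd = 0))
  m <- do.call(rbind, paths)
  c(nd = mean(m[, "nd"]), sd = mean(m[, "sd"]))
}

# site counts by direct neighbour enumeration
oracle_site_counts <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- GC_TABLE[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      nb <- ch
      nb[pos] <- alt
      nbc <- paste(nb, collapse = "")
      if (GC_TABLE[[nbc]] == aa) syn <- syn + 1
    }
  }
  c(n = 3 - syn / 3, s = syn / 3)
}

# full pairwise omega re-implementation from the two oracles above
oracle_pairwise_omega <- function(s1, s2) {
  cod <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- cod(s1); c2 <- cod(s2)
  ok <- c1 %in% SENSE & c2 %in% SENSE
  nd <- sd <- 0
  N1 <- S1 <- N2 <- S2 <- 0
  for (i in which(ok)) {
    sc1 <- oracle_site_counts(c1[i]); sc2 <- oracle_site_counts(c2[i])
    N1 <- N1 + sc1["n"]; S1 <- S1 + sc1["s"]
    N2 <- N2 + sc2["n"]; S2 <- S2 + sc2["s"]
    if (c1[i] != c2[i]) {
      pc <- oracle_path_counts(c1[i], c2[i])
      nd <- nd + pc["nd"]; sd <- sd + pc["sd"]
    }
  }
  nd <- unname(nd); sd <- unname(sd)
  N <- unname((N1 + N2) / 2); S <- unname((S1 + S2) / 2)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dn <- jc(nd / N); ds <- jc(sd / S)
  list(nd = nd, sd = sd, N = N, S = S, dn = dn, ds = ds,
       omega = if (is.na(dn) || is.na(ds) || ds == 0) NA_real_ else dn / ds)
}

# --- brute-force Fitch parsimony -----------------------------------------

# minimum number of changes over all assignments of states to internal nodes
# (and to wildcard tips, which are free to take any state)
oracle_fitch_score <- function(tree, states, alphabet) {
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  tipState <- match(states[tree$tip.label], alphabet)
  free <- c(which(is.na(tipState)), nTip + seq_len(nInt))
  grid <- as.matrix(expand.grid(rep(list(seq_along(alphabet)), length(free))))
  par <- tree$edge[, 1]; chl <- tree$edge[, 2]
  best <- Inf
  assign <- c(tipState, rep(NA_integer_, nInt))
  for (r in seq_len(nrow(grid))) {
    assign[free] <- grid[r, ]
    best <- min(best, sum(assign[par] != assign[chl]))
  }
  best
}

# --- random sequences and structures -------------------------------------

random_codon_seq <- function(nCodons) {
  paste(sample(SENSE, nCodons, replace = TRUE), collapse = "")
}

# minimal fixed-column PDB writer for toy complexes
write_toy_pdb <- function(file, atoms) {
  # atoms: data.frame(chain, resno, resname, atom, element, x, y, z,
  #                    occ (optional), alt (optional))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(a$atom, 1, 4), a$alt, a$resname, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, 0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), file)
  file
}

# brute-force interface: all-pairs distance check at residue level
oracle_interface <- function(atoms, receptorChain, ligandChain, cutoff) {
  standard <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL")
  rec <- atoms[atoms$chain == receptorChain & atoms$resname %in% standard &
                 atoms$element != "H", ]
  lig <- atoms[atoms$chain == ligandChain & atoms$element != "H" &
                 !atoms$resname %in% c("HOH", "WAT"), ]
  resnos <- unique(atoms$resno[atoms$chain == receptorChain &
                                 atoms$resname %in% standard])
  resnos <- resnos[order(resnos)]
  hits <- integer(0)
  for (k in seq_along(resnos)) {
    ra <- rec[rec$resno == resnos[k], ]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                    (ra$z[i] - lig$z[j])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, k)
  }
  hits
}

random_toy_complex <- function(nRec = 8, nLig = 3, spread = 12) {
  aa3 <- c("ALA", "GLY", "LEU", "SER", "THR", "VAL", "PHE", "TYR")
  rec <- do.call(rbind, lapply(seq_len(nRec), function(r) {
    nat <- sample(1:3, 1)
    data.frame(chain = "A", resno = r, resname = sample(aa3, 1),
               atom = paste0("C", seq_len(nat)), element = "C",
               x = stats::runif(nat, 0, spread), y = stats::runif(nat, 0, spread),
               z = stats::runif(nat, 0, spread))
  }))
  lig <- data.frame(chain = "B", resno = 1, resname = "LIG",
                    atom = paste0("C", seq_len(nLig)), element = "C",
                    x = stats::runif(nLig, 0, spread), y = stats::runif(nLig, 0, spread),
                    z = stats::runif(nLig, 0, spread))
  rbind(rec, lig)
}

# small helper: build an IndexTable object directly from a data.frame
make_index_table <- function(tb, positiveSites = integer(0),
                             pocketCols = 1:4, ligand) {
  methods::new("IndexTable", table = tb, perSpecies = list(),
               positiveSites = as.integer(positiveSites),
               pocketColumns = ColumnSet(pocketCols),
               groups = tb$group, ligandGroup = ligand)
}
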