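test_that("readComplex round-trips a toy complex and filters hydrogens", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    chain = c("A", "A", "A", "B"), resno = c(1, 1, 2, 1),
    resname = c("ALA", "ALA", "GLY", "LIG"),
    atom = c("CA", "H", "CA", "C1"), element = c("C", "H", "C", "C"),
    x = c(0, 0.5, 3, 10), y = 0, z = 0)
  write_toy_pdb(f, atoms)
  cs <- readComplex(f)
  expect_s3_class(cs, "ComplexStructure")
  expect_setequal(unique(cs$chain), c("A", "B"))
  expect_false(any(cs$elesy == "H"))
  expect_equal(nrow(cs), 3)  # hydrogen dropped
})

test_that("requesting an absent chain errors naming the available chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, data.frame(chain = c("A", "B"), resno = 1,
                              resname = c("ALA", "LIG"), atom = "CA",
                              element = "C", x = c(0, 5), y = 0, z = 0))
  expect_error(readComplex(f, chains = c("A", "Z")), "available chains.*A.*B")
  cs <- readComplex(f)
  expect_error(extractInterface(cs, "Z", "B"), "available chains")
})

test_that("altlocs resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    chain = c("A", "A", "B"), resno = c(1, 1, 1),
    resname = c("ALA", "ALA", "LIG"),
    atom = c("CA", "CA", "C1"), element = "C",
    x = c(0, 100, 3), y = 0, z = 0,
    occ = c(0.4, 0.6, 1), alt = c("A", "B", ""))
  write_toy_pdb(f, atoms)
  cs <- readComplex(f)
  ca <- cs[cs$chain == "A", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 100)  # occupancy 0.6 conformer wins
})

test_that("interface membership follows the distance cutoff", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # residue 1 at 4 A from the ligand (inside 5 A), residue 2 at 12 A
  atoms <- data.frame(
    chain = c("A", "A", "B"), resno = c(7, 8, 1),
    resname = c("ALA", "GLY", "LIG"),
    atom = c("CA", "CA", "C1"), element = "C",
    x = c(0, 12, 0), y = c(0, 0, 4), z = 0)
  write_toy_pdb(f, atoms)
  cs <- readComplex(f)
  p <- extractInterface(cs, "A", "B", cutoff = 5)
  expect_equal(pocketPositions(p), 1L)  # ordinal of residue 7
  expect_equal(p@residueMap$author_number, 7)
  # far-apart structure: empty pocket with a warning, not an error
  atoms$y[3] <- 100
  write_toy_pdb(f, atoms)
  cs2 <- readComplex(f)
  expect_warning(p2 <- extractInterface(cs2, "A", "B", cutoff = 5), "empty pocket")
  expect_length(pocketPositions(p2), 0)
})

test_that("extraction matches the all-pairs oracle on random structures", {
  withr::local_seed(11)
  for (rep in 1:20) {
    atoms <- random_toy_complex()
    f <- withr::local_tempfile(fileext = ".pdb")
    write_toy_pdb(f, atoms)
    cs <- readComplex(f)
    cutoff <- stats::runif(1, 3, 8)
    got <- suppressWarnings(
      pocketPositions(extractInterface(cs, "A", "B", cutoff = cutoff)))
    expect_equal(got, oracle_interface(atoms, "A", "B", cutoff),
                 ignore_attr = TRUE)
  }
})

test_that("pocket grows monotonically with the cutoff and is rigid-motion invariant", {
  withr::local_seed(21)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 11)
  for (rep in 1:15) {
    atoms <- random_toy_complex()
    f <- withr::local_tempfile(fileext = ".pdb")
    write_toy_pdb(f, atoms)
    cs <- readComplex(f)
    pockets <- lapply(c(3, 5, 7), function(cut)
      suppressWarnings(pocketPositions(extractInterface(cs, "A", "B", cutoff = cut))))
    expect_true(all(pockets[[1]] %in% pockets[[2]]))
    expect_true(all(pockets[[2]] %in% pockets[[3]]))
    xyz <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")])) + shift)
    rot <- atoms; rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
    f2 <- withr::local_tempfile(fileext = ".pdb")
    write_toy_pdb(f2, rot)
    cs2 <- readComplex(f2)
    expect_equal(
      suppressWarnings(pocketPositions(extractInterface(cs2, "A", "B", cutoff = 5))),
      pockets[[2]])
  }
})

test_that("pocket files round-trip through TSV", {
  p <- PocketDefinition(c(3L, 9L, 17L), receptorId = "rec1",
                        provenance = list(receptor_chain = "A",
                                          ligand_chain = "B", cutoff = 5),
                        residueMap = data.frame(position = c(3L, 9L, 17L),
                                                author_number = c(13L, 19L, 27L),
                                                insert = "",
                                                residue_name = c("ALA", "GLY", "SER")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePocket(p, f)
  p2 <- readPocket(f)
  expect_equal(pocketPositions(p2), pocketPositions(p))
  expect_equal(p2@provenance$cutoff, 5)
})
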