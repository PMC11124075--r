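test_that("hand-written PDB atoms are parsed field-for-field", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "O1", "LIG", 1, 1.234, -2.5, 3.75, "O"),
    pdb_atom_line(2, "C1", "LIG", 1, 0.0, 0.0, 0.0, "C"),
    pdb_atom_line(3, "P1", "LIG", 1, 10.0, 20.0, -30.0, "P"),
    "END"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$atoms$serial, 1:3)
  expect_equal(st$atoms$name, c("O1", "C1", "P1"))
  expect_equal(st$atoms$element, c("O", "C", "P"))
  expect_equal(st$atoms$x, c(1.234, 0, 10))
  expect_equal(st$atoms$y, c(-2.5, 0, 20))
  expect_equal(st$atoms$z, c(3.75, 0, -30))
})

test_that("write/read round-trip preserves atoms and coordinates to PDB precision", {
  sizes <- c(1, 3, 100)
  set.seed(42)
  for (n in sizes) {
    st <- mol_structure(data.frame(
      serial = seq_len(n), name = paste0("C", seq_len(n) %% 100),
      resname = "MOL", resid = 1L, element = "C",
      x = round(runif(n, -50, 50), 3),
      y = round(runif(n, -50, 50), 3),
      z = round(runif(n, -50, 50), 3)))
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(st, f)
    re <- read_structure(f)
    expect_equal(re$atoms$serial, st$atoms$serial)
    expect_equal(re$atoms$name, st$atoms$name)
    expect_equal(as.matrix(re$atoms[, c("x", "y", "z")]),
                 as.matrix(st$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("synthetic hosts survive a PDB round-trip into topology detection", {
  for (n in c(6, 7, 8)) {
    cd <- build_cd(n_units = n)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(cd$structure, f)
    topo <- detect_cd_topology(read_structure(f))
    expect_equal(topo$n_units, n)
    expect_equal(length(topo$glycosidic), n)
  }
})

test_that("malformed and empty PDB files raise parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bad <- pdb_atom_line(1, "C1", "LIG", 1, 0, 0, 0, "C")
  substr(bad, 32, 38) <- "abcdefg"
  writeLines(c(pdb_atom_line(2, "O1", "LIG", 1, 1, 1, 1, "O"), bad), f)
  expect_error(read_structure(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_structure(f), "empty")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("single-model trajectory equals the single-structure read", {
  cd <- build_cd(7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cd$structure, f)
  tr <- read_trajectory(f)
  expect_length(tr, 1)
  expect_equal(tr$frames[[1]]$atoms, read_structure(f)$atoms)
})

test_that("multi-model files become trajectories with uniform timestamps", {
  cd <- build_cd(6)
  g <- build_guest()
  frames <- lapply(seq(-2, 2), function(d)
    place_guest(cd, g, d, theta = 45)$structure)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(trajectory(frames), f)
  tr <- read_trajectory(f, dt_ps = 10)
  expect_length(tr, 5)
  expect_equal(tr$times, (0:4) * 10)
})

test_that("inconsistent MODEL blocks are rejected", {
  l1 <- pdb_atom_line(1, "C1", "LIG", 1, 0, 0, 0, "C")
  l2 <- pdb_atom_line(2, "O1", "LIG", 1, 1, 0, 0, "O")
  f <- withr::local_tempfile(fileext = ".pdb")
  # differing atom counts
  writeLines(c("MODEL        1", l1, l2, "ENDMDL",
               "MODEL        2", l1, "ENDMDL", "END"), f)
  expect_error(read_trajectory(f), "differing atom counts")
  # shuffled atom order in the second model
  writeLines(c("MODEL        1", l1, l2, "ENDMDL",
               "MODEL        2", l2, l1, "ENDMDL", "END"), f)
  expect_error(read_trajectory(f), "ordering")
})

test_that("XYZ files are read with element-derived names", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "toy molecule",
               "O 0.0 0.0 0.0", "H 0.96 0.0 0.0", "H -0.24 0.93 0.0"), f)
  st <- read_structure(f)
  expect_equal(st$atoms$element, c("O", "H", "H"))
  expect_equal(st$atoms$x, c(0, 0.96, -0.24))
  writeLines(c("5", "truncated", "O 0 0 0"), f)
  expect_error(read_structure(f), "truncated")
})

test_that("structure invariants are enforced", {
  a <- data.frame(serial = c(1, 1), name = "C1", resname = "LIG", resid = 1L,
                  element = "C", x = 0, y = 0, z = c(0, 1))
  expect_error(mol_structure(a), "unique")
  a$serial <- 1:2
  a$x[1] <- NaN
  expect_error(mol_structure(a), "finite")
  a$x[1] <- 0
  expect_error(mol_structure(a, bonds = cbind(1, 9)), "existing atom serials")
  st <- mol_structure(a)
  expect_error(atom_masses(mol_structure(transform(a, element = "Qq"))),
               "unknown element")
  expect_error(trajectory(list(st), times = c(0, 1)), "match")
})

test_that("topology hints are honoured verbatim", {
  cd <- build_cd(7)
  hints <- list(glycosidic = cd$topology$glycosidic,
                pyran_rings = cd$topology$pyran_rings,
                prim_rim = cd$topology$prim_rim,
                sec_rim = cd$topology$sec_rim)
  # scramble the unit order: hints must pass through untouched
  perm <- c(3, 4, 5, 6, 7, 1, 2)
  hints <- list(glycosidic = hints$glycosidic[perm],
                pyran_rings = hints$pyran_rings[perm],
                prim_rim = hints$prim_rim[perm],
                sec_rim = hints$sec_rim[perm])
  topo <- detect_cd_topology(cd$structure, hints = hints)
  expect_equal(topo$glycosidic, hints$glycosidic)
  expect_equal(topo$pyran_rings, lapply(hints$pyran_rings, as.integer))
})

test_that("detection recovers the generator's serial lists exactly", {
  for (n in c(6, 7, 8)) {
    cd <- build_cd(n_units = n)
    topo <- detect_cd_topology(cd$structure)
    expect_identical(topo$glycosidic, cd$topology$glycosidic)
    expect_identical(topo$pyran_rings, cd$topology$pyran_rings)
    expect_identical(topo$prim_rim, cd$topology$prim_rim)
    expect_identical(topo$sec_rim, cd$topology$sec_rim)
  }
})

test_that("non-cyclodextrin unit counts are rejected without hints", {
  g <- build_guest()
  expect_error(detect_cd_topology(g$structure), "hints")
})
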