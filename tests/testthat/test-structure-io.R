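# Structure/trajectory reading and writing, BW maps, selections.

make_two_model_pdb <- function(path) {
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C", "N", "C", "C", "O", "C"),
    resno = rep(1:2, each = 5), resname = "ALA", chain = "A",
    stringsAsFactors = FALSE
  )
  xyz1 <- matrix(round(rnorm(30), 3), 10, 3)
  s1 <- or_structure(atoms, xyz1, "m1")
  s2 <- or_structure(atoms, xyz1 + 1, "m2")
  write_structures(list(s1, s2), path, box = c(100, 100, 120))
  list(s1 = s1, s2 = s2)
}

test_that("multi-model PDB round-trips the atom table and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  made <- make_two_model_pdb(path)
  got <- read_structures(path)
  expect_length(got, 2)
  expect_equal(vapply(got, function(s) nrow(s$atoms), integer(1)), c(10L, 10L))
  for (col in c("atom_name", "element", "resno", "resname", "chain")) {
    expect_identical(got[[1]]$atoms[[col]], made$s1$atoms[[col]])
  }
  expect_equal(got[[1]]$xyz, made$s1$xyz, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(got[[2]]$xyz, made$s2$xyz, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(attr(got, "box"), c(100, 100, 120))
})

test_that("HETATM waters and ions are retained and classified by residue name", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  120.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.000   2.500   3.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       3.500   3.500   3.000  1.00  0.00           O",
    "HETATM    5  O   HOH W 101      10.000  10.000  10.000  1.00  0.00           O",
    "HETATM    6  O   HOH W 102      12.000  10.000  10.000  1.00  0.00           O",
    "HETATM    7 NA    NA I 201      20.000  20.000  20.000  1.00  0.00          NA",
    "END"
  ), path)
  s <- read_structures(path)[[1]]
  expect_equal(nrow(s$atoms), 7)
  expect_equal(sum(is_water_atom(s)), 2)
  expect_equal(sum(is_ion_atom(s)), 1)
  expect_equal(sum(is_protein_atom(s)), 4)
  expect_equal(s$atoms$resno[is_ion_atom(s)], 201L)
})

test_that("malformed and empty PDB inputs raise errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), path)
  expect_error(read_structures(path))
  expect_error(read_structures(file.path(tempdir(), "no-such-file.pdb")),
               "no such file")
})

test_that("triclinic boxes are rejected with a clear error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  120.000  90.00  95.00  90.00 P 1           1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"
  ), path)
  expect_error(read_structures(path), "orthorhombic")
})

test_that("plain-text frame dialect round-trips a trajectory", {
  b <- small_bundle(n_helices = 2, residues_per_helix = 8)
  tr <- make_trajectory(b, event_schedule(noise_sigma = 0.2, seed = 3),
                        n_frames = 4, dt_ns = 0.5)
  path <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(tr, path, dialect = "frames")
  got <- read_trajectory(path, dialect = "frames")
  expect_equal(length(got$frames), 4)
  expect_equal(got$times, tr$times)
  expect_equal(got$box, tr$box, ignore_attr = TRUE)
  for (f in 1:4) {
    expect_equal(got$frames[[f]], tr$frames[[f]], tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("trajectory invariants are enforced", {
  s <- ca_structure(matrix(rnorm(30), 10, 3))
  f <- list(s$xyz, s$xyz)
  expect_error(or_trajectory(s, f, c(100, 100, 120), times = c(1, 1)),
               "increasing")
  expect_error(or_trajectory(s, f, c(100, 100, -5), times = c(0, 1)),
               "positive")
  expect_error(or_trajectory(s, list(s$xyz, s$xyz[-1, ]), c(100, 100, 120),
                             times = c(0, 1)), "atom count")
})

test_that("BW lookup inverts the residue map (hOR51E2 anchors)", {
  # the receptor's sodium-pocket anchors: D69 at 2.50, E110 at 3.39
  hor <- bw_map(c(69L, 110L, 96L, 178L, 246L, 279L),
                c("2.50", "3.39", "3.25", "45.50", "6.43", "7.40"))
  expect_equal(bw_lookup(hor, "2.50"), 69L)
  expect_equal(bw_lookup(hor, "3.39"), 110L)
  expect_equal(bw_lookup(hor, "45.50"), 178L)
  expect_error(bw_lookup(hor, "1.50"), "1\\.50")
  expect_equal(bw_lookup(bw_map(10L, "1.50"), "1.50"), 10L)
  # forward map then lookup is the identity on all mapped residues
  for (r in hor$resno) expect_equal(bw_lookup(hor, bw_label(hor, r)), r)
})

test_that("BW maps round-trip through TSV and reject bad labels", {
  m <- bw_map(c(5L, 9L), c("1.50", "2.50"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bw_map(m, path)
  expect_equal(read_bw_map(path), m, ignore_attr = TRUE)
  expect_error(bw_map(1L, "helix2"), "parse")
  expect_error(bw_map(c(1L, 2L), c("2.50", "2.50")), "injective")
})

test_that("backbone selection returns exactly N, CA, C, O per residue", {
  atoms <- do.call(rbind, lapply(1:10, function(r) {
    data.frame(atom_name = c("N", "CA", "C", "O", "CB"),
               element = c("N", "C", "C", "O", "C"),
               resno = r, resname = "ALA", chain = "A",
               stringsAsFactors = FALSE)
  }))
  s <- or_structure(atoms, matrix(rnorm(150), 50, 3))
  idx <- resolve_selection(s, selection_spec("backbone"))
  expect_length(idx, 40)
  expect_true(all(s$atoms$atom_name[idx] %in% c("N", "CA", "C", "O")))
  # idempotent and order-stable
  expect_identical(idx, resolve_selection(s, selection_spec("backbone")))
  expect_identical(idx, sort(idx))
})

test_that("heavy selection excludes hydrogens, counts 8 of 13 atoms", {
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE",
                  "H", "HA", "HB1", "HB2", "HB3"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C",
                "H", "H", "H", "H", "H"),
    resno = 1, resname = "LYS", chain = "A", stringsAsFactors = FALSE
  )
  s <- or_structure(atoms, matrix(rnorm(39), 13, 3))
  expect_length(resolve_selection(s, selection_spec("heavy")), 8)
})

test_that("TM-restricted selection excludes every loop residue", {
  b <- small_bundle(n_helices = 3, residues_per_helix = 10)
  s <- b$structure
  idx <- resolve_selection(s, selection_spec("heavy", helices = names(b$helices)),
                           b$helices)
  tm_resnos <- unlist(lapply(b$helices, function(r) seq(r[1], r[2])))
  expect_true(all(s$atoms$resno[idx] %in% tm_resnos))
  loop_resnos <- setdiff(unique(s$atoms$resno), tm_resnos)
  expect_gt(length(loop_resnos), 0) # generator does create loop residues
  expect_false(any(s$atoms$resno[idx] %in% loop_resnos))
  expect_error(resolve_selection(s, selection_spec("heavy", residues = 99999L)),
               "zero atoms")
})

test_that("helix sets validate ranges and read/write YAML", {
  expect_error(helix_set(list(TM1 = c(1, 3))), "shorter")
  expect_error(helix_set(list(TM1 = c(1, 10), TM2 = c(8, 20))), "overlap")
  hs <- helix_set(list(TM1 = c(1, 10), TM2 = c(15, 25)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_helix_set(hs, path)
  expect_equal(read_helix_set(path), hs, ignore_attr = TRUE)
})
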