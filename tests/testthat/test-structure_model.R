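test_that("a minimal one-atom PDB file reads back at the written coordinates", {
  p <- write_pdb_lines(pdb_atom_line(1, "CA", "ALA", "A", 7, 1.234, -5.678, 9.012))
  m <- read_structure(p)
  expect_equal(n_atoms(m), 1)
  expect_equal(unname(coords(m)[1, ]), c(1.234, -5.678, 9.012))
  expect_equal(m$atoms$residue_index, 7L)
  expect_equal(m$atoms$chain_id, "A")
})

test_that("PDB and mmCIF round trips preserve atoms, order, numbering and coordinates", {
  model <- small_subunit
  for (fmt in c("pdb", "mmcif")) {
    path <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(model, path, format = fmt)
    back <- read_structure(path, format = fmt)
    expect_equal(n_atoms(back), n_atoms(model))
    expect_identical(back$atoms$residue_index, model$atoms$residue_index)
    expect_identical(back$atoms$chain_id, model$atoms$chain_id)
    expect_identical(back$atoms$atom_name, model$atoms$atom_name)
    tol <- if (fmt == "pdb") 5e-4 else 5e-5  # format precision: 3 / 4 decimals
    expect_lt(max(abs(coords(back) - coords(model))), tol)
  }
})

test_that("our mmCIF output is readable by an independent mmCIF parser", {
  path <- tempfile(fileext = ".cif")
  write_structure(small_subunit, path)
  ref <- suppressWarnings(bio3d::read.cif(path))
  expect_equal(nrow(ref$atom), n_atoms(small_subunit))
  expect_equal(unname(ref$atom$x), small_subunit$atoms$x, tolerance = 1e-3)
})

test_that("multi-character chain ids round trip through mmCIF (and are refused by PDB)", {
  ring <- build_cn_ring(place_at_radius(small_upright, 30), 5, tier_name = "inner")
  path <- tempfile(fileext = ".cif")
  write_structure(ring$model, path)
  back <- read_structure(path)
  expect_identical(chain_ids(back), sprintf("I%02d", 0:4))
  expect_error(write_structure(ring$model, tempfile(fileext = ".pdb")),
               "chain ids")
})

test_that("alternate locations resolve to highest occupancy, first on ties", {
  p <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "CB", "SER", "A", 1, 1, 1, 1, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "CB", "SER", "A", 1, 8, 8, 8, occ = 0.5, alt = "B")))
  m <- read_structure(p)
  expect_equal(n_atoms(m), 2)
  expect_equal(unname(coords(m)[m$atoms$atom_name == "CA", ]), c(9, 9, 9))  # occ 0.6 wins
  expect_equal(unname(coords(m)[m$atoms$atom_name == "CB", ]), c(1, 1, 1))  # tie: first
})

test_that("select_atoms subsets by chain, residue range and atom class without mutating", {
  d1 <- select_atoms(small_subunit, residues = small_ann$D1, atoms = "CA")
  expect_equal(n_atoms(d1), small_ann$D1$residue_end - small_ann$D1$residue_start + 1)
  expect_true(all(d1$atoms$atom_name == "CA"))
  expect_equal(n_atoms(small_subunit), (12 + 16 + 1) * 2)  # original untouched
  d1_only <- select_atoms(small_subunit, residues = small_ann$D1)
  expect_error(select_atoms(d1_only, residues = small_ann$D2), "empty selection")
})

test_that("domain annotations convert between Aa and St numbering by +2", {
  d1 <- domain_annotation("D1", 58, 122, scheme = "Aa")
  st <- convert_annotation(d1, "St")
  expect_equal(c(st$residue_start, st$residue_end), c(60, 124))
  expect_equal(convert_annotation(st, "Aa")$residue_start, 58)
})

test_that("thread_sequence relabels without moving the backbone", {
  # template: toy subunit (all ALA); thread an equal-length different sequence
  template <- small_subunit
  n_res <- length(unique(template$atoms$residue_index))
  target <- paste(rep(c("G", "V", "A", "L"), length.out = n_res), collapse = "")

  threaded <- thread_sequence(template, target, offset = 2L)
  # numbering shifted by +2
  expect_equal(min(threaded$atoms$residue_index),
               min(template$atoms$residue_index) + 2L)
  # backbone (here CA) coordinates copied verbatim: RMSD exactly 0
  ca_t <- coords(select_atoms(template, atoms = "CA"))
  ca_h <- coords(select_atoms(threaded, atoms = "CA"))
  expect_identical(ca_t, ca_h)
  # glycine positions lost their CB; alanine positions kept it
  gly <- threaded$atoms$residue_name == "GLY"
  expect_true(all(threaded$atoms$atom_name[gly] == "CA"))
  ala <- threaded$atoms$residue_name == "ALA"
  expect_true(any(threaded$atoms$atom_name[ala] == "CB"))

  # identity threading returns the input unchanged
  same <- thread_sequence(template, paste(rep("A", n_res), collapse = ""), 0L)
  expect_equal(same$atoms[names(same$atoms) != "residue_name"],
               template$atoms[names(template$atoms) != "residue_name"])

  expect_error(thread_sequence(template, "AAA", 0L), "gapless")
  expect_error(suppressWarnings(
    thread_sequence(template, paste(rep("B", n_res), collapse = ""), 0L)),
    "non-standard")
})

test_that("gapless identity matches hand counts, is symmetric, and rejects unequal lengths", {
  expect_equal(gapless_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(gapless_identity("ACDE", "WYHR"), 0)
  # 22 matching positions out of 50 = 44.0%
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(c(rep("A", 22), rep("G", 28)), collapse = "")
  expect_equal(gapless_identity(a, b), 44.0)
  expect_equal(gapless_identity(b, a), gapless_identity(a, b))
  expect_error(gapless_identity("ACD", "ACDE"), "undefined")
})

test_that("FASTA sequences read through the standard parser", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "ACDEFG", ">seq2", "ACD-FG"), path)
  seqs <- read_fasta_sequences(path)
  expect_equal(unname(seqs["seq1"]), "ACDEFG")
  expect_equal(unname(seqs["seq2"]), "ACDFG")  # gaps removed
})
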