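test_that("PDB parsing echoes chains, residues and header metadata", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    2.50 ANGSTROMS.",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      13.500   7.000  -3.000  1.00  0.00           C",
    "ATOM      4  CA  CYS A   3      15.500   7.200  -3.100  1.00  0.00           C",
    "ATOM      5  CA  ALA B   1       1.000   1.000   1.000  1.00  0.00           C",
    "ATOM      6  CA  GLY B   2       4.000   1.000   1.000  1.00  0.00           C",
    "END"
  ), pdb)
  m <- read_structure(pdb, "pdb", structure_id = "toy1")
  expect_s3_class(m, "epi_structure")
  expect_equal(sort(unique(m$residues$chain)), c("A", "B"))
  expect_equal(m$resolution, 2.5)
  expect_equal(m$method, "X-RAY DIFFRACTION")
  expect_true(is.na(m$r_free))
  expect_equal(chain_sequence(m, "A"), "AGC")
  expect_equal(m$residues$seq_index[m$residues$chain == "A"], 0:2)
  # same file parsed twice -> identical model
  expect_identical(m, read_structure(pdb, "pdb", structure_id = "toy1"))
})

test_that("missing resolution record yields NA resolution", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "EXPDTA    SOLUTION NMR",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), pdb)
  m <- read_structure(pdb, "pdb")
  expect_true(is.na(m$resolution))
  expect_equal(m$method, "SOLUTION NMR")
})

test_that("mmCIF refine block populates R-free and resolution", {
  rec <- mk_abag("cif1", resolution = 2.1)
  rec$structure$r_free <- 0.28
  path <- tempfile(fileext = ".cif")
  write_structure(rec$structure, path, "mmcif")
  m <- read_structure(path, "mmcif")
  expect_equal(m$r_free, 0.28)
  expect_equal(m$resolution, 2.1)
})

test_that("hydrogens are discarded and altlocs collapse to one conformer", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.500   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.100   0.000  0.60  0.00           C",
    "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       3.100   0.100   0.000  0.50  0.00           C",
    "ATOM      6  H   ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
    "END"
  ), pdb)
  m <- read_structure(pdb, "pdb")
  a <- m$atoms
  expect_false("H" %in% a$elesy)
  # highest occupancy wins (CA: B at 0.60) ...
  expect_equal(a$x[a$elety == "CA"], 1.6)
  # ... ties go to altloc 'A' (CB both 0.50)
  expect_equal(a$x[a$elety == "CB"], 3.0)
  # exactly one conformer per atom name, never more atoms than on file
  expect_equal(anyDuplicated(a$elety[a$seq_index == 0]), 0L)
  expect_equal(nrow(a), 3L)
})

test_that("chain_sequence skips non-standard residues and empties on ligands", {
  atoms <- rbind(
    mk_chain("A", "AG", c(0, 0, 0)),
    epibench:::.make_ligand_atoms("B", c(30, 0, 0)),
    # a heme-like hetero group spliced between two standard residues
    epibench:::.atoms_df("C", 1L, "ALA", c("N", "CA", "C"), c("N", "C", "C"),
                         serp(3, origin = c(0, 0, 30))),
    epibench:::.atoms_df("C", 2L, "HEM", "FE", "FE",
                         matrix(c(50, 0, 30), 1)),
    epibench:::.atoms_df("C", 3L, "GLY", c("N", "CA", "C"), c("N", "C", "C"),
                         serp(3, origin = c(60, 0, 30)))
  )
  m <- mk_model(atoms)
  expect_equal(chain_sequence(m, "C"), "AG")
  expect_equal(chain_sequence(m, "B"), "")
  expect_equal(molecule_kind(m, "B"), "non-peptidic")
  expect_equal(molecule_kind(m, "A"), "peptide")
})

test_that("antigen classification keys on any standard amino-acid content", {
  pep <- mk_pmhc("p1", contact_idx = 1:9)
  expect_equal(classify_antigen(pep), "peptidic")

  # glycan-only ligand -> non-peptidic
  atoms <- rbind(epibench:::.make_ligand_atoms("X", c(5, 5, 0)),
                 mk_chain("M", "DEKRH", c(0, 0, 24)))
  rec <- complex_record(mk_model(atoms), "MHC_LIGAND", c(M = "mhc_a"), "X")
  expect_equal(classify_antigen(rec), "non_peptidic")
  expect_false(rec$antigen_is_peptidic)

  # hybrid chain: three amino acids plus a sugar ring -> >= 1 standard
  # residue, hence peptidic
  hybrid <- rbind(mk_chain("X", "AGC", c(0, 0, 0)),
                  epibench:::.atoms_df("X", 4L, "NAG",
                                       c("C1", "C2"), c("C", "C"),
                                       rbind(c(20, 0, 0), c(21.5, 0, 0))))
  atoms <- rbind(hybrid, mk_chain("M", "DEKRH", c(0, 0, 24)))
  rec <- complex_record(mk_model(atoms), "MHC_LIGAND", c(M = "mhc_a"), "X")
  expect_equal(classify_antigen(rec), "peptidic")
})

test_that("write/parse round-trips both dialects", {
  rec <- mk_abag("rt01", resolution = 2.35)
  rec$structure$r_free <- 0.245
  for (dialect in c("pdb", "mmcif")) {
    path <- tempfile(fileext = if (dialect == "pdb") ".pdb" else ".cif")
    write_structure(rec$structure, path, dialect)
    back <- read_structure(path, dialect, structure_id = "rt01")
    expect_identical(back$residues$resid, rec$structure$residues$resid)
    expect_identical(back$residues$seq_index, rec$structure$residues$seq_index)
    expect_identical(back$atoms$elety, rec$structure$atoms$elety)
    expect_lt(max(abs(back$atoms$x - rec$structure$atoms$x)), 1e-3)
    expect_lt(max(abs(back$atoms$y - rec$structure$atoms$y)), 1e-3)
    expect_lt(max(abs(back$atoms$z - rec$structure$atoms$z)), 1e-3)
    expect_equal(back$resolution, 2.35)
    expect_equal(back$r_free, 0.245)
  }
})

test_that("malformed or missing files raise parse errors", {
  expect_error(read_structure(tempfile(), "pdb"), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines("REMARK just a header, no coordinates", bad)
  expect_error(read_structure(bad, "pdb"))
})

test_that("complex_record validates roles against the complex type", {
  rec <- mk_abag()
  m <- rec$structure
  expect_error(complex_record(m, "TCR_PMHC", c(H = "heavy"), "G"),
               "inconsistent")
  expect_error(complex_record(m, "AB_AG", c(H = "heavy"), "H"), "disjoint")
  expect_error(complex_record(m, "AB_AG", c(H = "paratope"), "G"),
               "unknown chain role")
  expect_error(complex_record(m, "AB_AG", c(Z = "heavy"), "G"), "absent")
})
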