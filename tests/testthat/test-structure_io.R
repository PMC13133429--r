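test_that("read_chain echoes coordinates and enforces its error contract", {
  pdb <- tempfile(fileext = ".pdb")
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  write_chain_pdb(protein_chain("toy_A", xyz), pdb)
  ch <- read_chain(pdb, "A")
  expect_s3_class(ch, "protein_chain")
  expect_equal(length(ch), 3)
  expect_equal(unname(ch$xyz), xyz, tolerance = 1e-3)
  expect_true(all(ch$ss3 == "C"))
  expect_error(read_chain(pdb, "B"), "chain not found")
})

test_that("residues lacking a C-alpha are dropped with a warning", {
  pdb <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   ALA A   3       7.600   0.000   0.000  1.00  0.00           N",
    "END")
  writeLines(lines, pdb)
  expect_warning(ch <- read_chain(pdb, "A"), "without C-alpha")
  expect_equal(length(ch), 2)
})

test_that("PDB round-trip preserves coordinates and residue order", {
  ch <- make_random_chain(21, 6)
  pdb <- tempfile(fileext = ".pdb")
  write_chain_pdb(ch, pdb, renumber = TRUE)
  back <- read_chain(pdb, "A")
  expect_equal(length(back), length(ch))
  expect_equal(unname(back$xyz), unname(ch$xyz), tolerance = 1e-3)
  expect_equal(back$resno, seq_len(length(ch)))
})

test_that("DSSP letters reduce to 3 states by the standard table", {
  # helix family collapses to H, bridge/strand to E, the rest to coil
  cases <- list(list(ss8 = c("H", "H", "H", "H", "H"),
                     ss3 = c("H", "H", "H", "H", "H")),
                list(ss8 = c("G", "G", "G"), ss3 = c("H", "H", "H")),
                list(ss8 = c("I", "I", "I"), ss3 = c("H", "H", "H")),
                list(ss8 = c("T", "T", "S", "S"),
                     ss3 = c("C", "C", "C", "C")),
                list(ss8 = c("E", "B", "E"), ss3 = c("E", "E", "E")),
                list(ss8 = c(" ", "P", "H"), ss3 = c("C", "C", "H")))
  for (cs in cases) {
    n <- length(cs$ss8)
    ch <- protein_chain("x_A", matrix(rnorm(n * 3), ncol = 3))
    dssp <- tempfile(fileext = ".dssp")
    write_fake_dssp(dssp, seq_len(n), "A", cs$ss8)
    out <- apply_dssp_assignment(ch, dssp)
    expect_equal(out$ss3, cs$ss3)
    # assignment never touches coordinates or length
    expect_identical(out$xyz, ch$xyz)
    expect_equal(length(out), length(ch))
  }
})

test_that("DSSP assignment errors when the chain is absent and keeps coil
           for residues missing from the record", {
  ch <- protein_chain("x_A", matrix(rnorm(15), ncol = 3))
  dssp <- tempfile(fileext = ".dssp")
  write_fake_dssp(dssp, 1:5, "B", rep("H", 5))
  expect_error(apply_dssp_assignment(ch, dssp, chain_letter = "A"),
               "assignment not found")
  dssp2 <- tempfile(fileext = ".dssp")
  write_fake_dssp(dssp2, 1:3, "A", rep("H", 3))     # residues 4,5 absent
  out <- apply_dssp_assignment(ch, dssp2)
  expect_equal(out$ss3, c("H", "H", "H", "C", "C"))
})

test_that("ss3 sidecars round-trip and validate length", {
  ch <- make_random_chain(5, 6)
  path <- tempfile(fileext = ".ss3")
  write_ss3_sidecar(ch, path)
  s <- read_ss3_sidecar(path, ch$chain_id)
  expect_equal(nchar(s), length(ch))
  expect_identical(apply_ss3_string(ch, s)$ss3, ch$ss3)
  expect_error(apply_ss3_string(ch, "HEC"), "does not match")
  expect_error(read_ss3_sidecar(path, "nope_Z"), "not found")
})

test_that("geometric assigner labels ideal elements and guards short chains", {
  helix <- protein_chain("h_A", ssesym:::ideal_helix(12))
  out <- assign_ss_geometric(helix)
  expect_gte(sum(out$ss3 == "H"), 8)
  expect_false(any(out$ss3 == "E"))

  strand <- protein_chain("e_A", ssesym:::ideal_strand(8))
  out <- assign_ss_geometric(strand)
  expect_gte(sum(out$ss3 == "E"), 4)
  expect_false(any(out$ss3 == "H"))

  short <- protein_chain("s_A", matrix(rnorm(12), ncol = 3))
  expect_warning(out <- assign_ss_geometric(short), "shorter than 5")
  expect_equal(out$ss3, rep("C", 4))
})
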