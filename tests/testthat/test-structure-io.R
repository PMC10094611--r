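# PDB / ensemble reading, writing, alt-loc policy, chromophore identification

test_that("PDB write/read round-trip preserves every atom field", {
  toy <- toyShellStructure()$structure
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(toy, f)
  back <- readPDB(f)
  a0 <- atoms(toy); a1 <- atoms(back)
  expect_equal(nrow(a1), nrow(a0))
  for (col in c("name", "res_name", "chain_id", "res_seq"))
    expect_identical(a1[[col]], a0[[col]])
  # coordinates to printed precision (%8.3f)
  expect_equal(a1$x, round(a0$x, 3), tolerance = 1e-9)
  expect_equal(a1$y, round(a0$y, 3), tolerance = 1e-9)
  expect_equal(a1$z, round(a0$z, 3), tolerance = 1e-9)
  expect_equal(a1$occupancy, a0$occupancy)
  expect_identical(a1$is_het, a0$is_het)
})

test_that("a minimal one-atom record parses with coordinates echoed exactly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00 10.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_equal(nAtoms(s), 1L)
  expect_equal(as.numeric(coords(s)), c(11.104, 6.134, -6.504))
  expect_identical(atoms(s)$name, "CA")
})

test_that("alt-loc policy keeps the highest-occupancy conformer, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       3.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  s <- readPDB(f)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 1.000)     # higher occupancy wins
  expect_equal(a$x[a$name == "CB"], 2.000)     # tie resolved toward A
  expect_identical(metadata(s)$alt_loc_policy, "highest")
  expect_equal(nrow(atoms(readPDB(f, altLoc = "keep"))), 4L)
})

test_that("model selection works and absent models are an error", {
  toy <- toyShellStructure()$structure
  f <- withr::local_tempfile(fileext = ".pdb")
  spec <- ensembleSpec(nFrames = 5, seed = 3, sigma = 0.1)
  ens <- makeEnsemble(toy, spec)$ensemble
  # write a multi-MODEL file by concatenating single-frame records
  out <- character(0)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  for (i in 1:5) {
    writePDB(frameStructure(ens, i), tmp)
    recs <- grep("^(ATOM|HETATM)", readLines(tmp), value = TRUE)
    out <- c(out, sprintf("MODEL     %4d", i), recs, "ENDMDL")
  }
  writeLines(c(out, "END"), f)
  s2 <- readPDB(f, model = 2)
  expect_equal(coords(s2), round(ens@coords[, , 2], 3), ignore_attr = TRUE)
  expect_length(readPDB(f, model = "all"), 5L)
  expect_error(readPDB(f, model = 9), "not found")
  e2 <- readEnsemble(f, dt = 50)
  expect_equal(nFrames(e2), 5L)
  expect_equal(frameDt(e2), 50)
  expect_equal(e2@coords, round(ens@coords, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("malformed fixed-column records fail with the offending line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CB  ALA A   1       xx.000   0.000  0.000  1.00 10.00           C"),
    f)
  expect_error(readPDB(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(readPDB(f2), "no ATOM/HETATM")
})

test_that("XYZ ensembles round-trip and enforce the atom count", {
  toy <- toyShellStructure()$structure
  gen <- makeEnsemble(toy, ensembleSpec(nFrames = 4, seed = 11, sigma = 0.2))
  f <- withr::local_tempfile(fileext = ".xyz")
  writeEnsembleXYZ(gen$ensemble, f)
  back <- readEnsemble(f, topology = toy)
  expect_equal(nFrames(back), 4L)
  expect_equal(frameDt(back), 100)
  expect_equal(back@coords, gen$ensemble@coords, tolerance = 1e-5,
               ignore_attr = TRUE)
  # wrong topology size
  small <- newStructure(atoms(toy)[1:5, c("name", "res_name", "chain_id",
                                          "res_seq", "x", "y", "z")])
  expect_error(readEnsemble(f, topology = small), "atom count")
  # truncated frame names the frame
  lines <- readLines(f)
  writeLines(lines[1:(1 + nAtoms(toy) + 3)], f)
  expect_error(readEnsemble(f, topology = toy), "frame 2")
})

test_that("chromophore identification matches the generator manifest", {
  toy <- toyShellStructure()
  chrom <- identifyChromophore(toy$structure, "A")
  a <- atoms(toy$structure)
  expect_identical(a$name[chrom@cg2], "CG2")
  expect_identical(a$name[chrom@cz], "CZ")
  expect_identical(a$name[chrom@oh], "OH")
  expect_identical(a$name[chrom@carbonylO], "O2")
  expect_setequal(a$name[chrom@imidazolinone], c("C1", "N2", "N3", "C2", "CA2"))
  expect_setequal(a$name[chrom@phenolRing],
                  c("CG2", "CD1", "CD2", "CE1", "CE2", "CZ"))
  expect_true(all(a$res_name[chromophoreAtoms(chrom)] == "CRO"))
  # deterministic: same input, same refs
  chrom2 <- identifyChromophore(toy$structure, "A")
  expect_identical(chromophoreAtoms(chrom2), chromophoreAtoms(chrom))
})

test_that("absent or incomplete chromophores are errors, not guesses", {
  toy <- toyShellStructure()$structure
  a <- atoms(toy)
  noChrom <- newStructure(a[a$res_name != "CRO", ])
  expect_error(identifyChromophore(noChrom, "A"), "no chromophore")
  broken <- newStructure(a[a$name != "CZ" | a$res_name != "CRO", ])
  expect_error(identifyChromophore(broken, "A"), "CZ")
})
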