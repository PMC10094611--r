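# Static contact detectors: H-bonds, water bridges, hydrophobic contacts,
# shell census; checked against exhaustive enumeration oracles.

toy <- toyShellStructure()
s <- toy$structure
chrom <- toy$chromophore

test_that("H-bond detection matches exhaustive pairwise enumeration", {
  chromIdx <- selectAtoms(s, chain = "A", resSeq = 66)
  allProt <- selectAtoms(s, water = FALSE)
  hb <- findHBonds(s, chromIdx, allProt, cutoff = 3.3)
  # reconstruct pair keys from the records
  a <- atoms(s)
  got <- vapply(seq_len(nrow(hb)), function(r) {
    i <- which(a$chain_id == hb$chain_a[r] & a$res_seq == hb$res_seq_a[r] &
                 a$name == hb$atom_a[r])
    j <- which(a$chain_id == hb$chain_b[r] & a$res_seq == hb$res_seq_b[r] &
                 a$name == hb$atom_b[r])
    paste(min(i, j), max(i, j))
  }, character(1))
  expect_setequal(got, bruteHBondPairs(s, chromIdx, allProt, 3.3))
  # sorted by distance, all metrics within cutoff, re-measured to 0.01 A
  expect_false(is.unsorted(hb$metric))
  expect_true(all(hb$metric <= 3.3))
  for (r in seq_len(nrow(hb))) {
    i <- which(a$chain_id == hb$chain_a[r] & a$res_seq == hb$res_seq_a[r] &
                 a$name == hb$atom_a[r])
    j <- which(a$chain_id == hb$chain_b[r] & a$res_seq == hb$res_seq_b[r] &
                 a$name == hb$atom_b[r])
    expect_equal(atomDist(s, i, j), hb$metric[r], tolerance = 0.01)
  }
})

test_that("the toy pocket yields its constructed direct H-bond partners", {
  hb <- findHBonds(s, selectAtoms(s, chain = "A", resSeq = 66),
                   selectAtoms(s, water = FALSE), cutoff = 3.3)
  partners <- unique(hb$res_seq_b)
  expected <- toy$manifest$placements$res_seq[
    toy$manifest$placements$class == "hbond"]
  expect_setequal(partners, expected)
  # constructed distances come back exactly
  expect_equal(sort(hb$metric),
               sort(toy$manifest$placements$target_dist[
                 toy$manifest$placements$class == "hbond"]),
               tolerance = 1e-6)
})

test_that("H-bond search is symmetric and monotone in the cutoff", {
  chromIdx <- selectAtoms(s, chain = "A", resSeq = 66)
  allProt <- selectAtoms(s, water = FALSE)
  ab <- findHBonds(s, chromIdx, allProt, cutoff = 3.3)
  ba <- findHBonds(s, allProt, chromIdx, cutoff = 3.3)
  key <- function(df) sort(paste(pmin(paste0(df$chain_a, df$res_seq_a, df$atom_a),
                                      paste0(df$chain_b, df$res_seq_b, df$atom_b)),
                                 pmax(paste0(df$chain_a, df$res_seq_a, df$atom_a),
                                      paste0(df$chain_b, df$res_seq_b, df$atom_b))))
  expect_identical(key(ab), key(ba))
  for (cut in c(2.9, 3.1, 3.3, 3.6)) {
    sub <- findHBonds(s, chromIdx, allProt, cutoff = cut)
    sup <- findHBonds(s, chromIdx, allProt, cutoff = cut + 0.3)
    expect_true(all(key(sub) %in% key(sup)))
  }
})

test_that("out-of-range and apolar selections give empty results", {
  mk <- function(chain, res_seq, name, res_name, x)
    data.frame(name = name, res_name = res_name, chain_id = chain,
               res_seq = res_seq, x = x, y = 0, z = 0)
  far <- newStructure(rbind(mk("A", 1, "N", "ALA", 0),
                            mk("A", 1, "O", "ALA", 1.2),
                            mk("B", 2, "N", "ALA", 10),
                            mk("B", 2, "O", "ALA", 11.2)))
  expect_equal(nrow(findHBonds(far, 1:2, 3:4, cutoff = 3.3)), 0L)
  apolar <- newStructure(rbind(mk("A", 1, "CB", "ALA", 0),
                               mk("B", 2, "CB", "ALA", 3)))
  expect_warning(out <- findHBonds(apolar, 1, 2, cutoff = 3.3), "no polar")
  expect_equal(nrow(out), 0L)
})

test_that("a constructed O...N pair at 2.80 A is found with that metric", {
  mk <- function(chain, res_seq, name, res_name, x)
    data.frame(name = name, res_name = res_name, chain_id = chain,
               res_seq = res_seq, x = x, y = 0, z = 0)
  pair <- newStructure(rbind(mk("A", 1, "OG", "SER", 0),
                             mk("B", 2, "NZ", "LYS", 2.80)))
  hb <- findHBonds(pair, 1, 2, cutoff = 3.3)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$metric, 2.80)
})

test_that("water bridges match exhaustive triple enumeration", {
  wm <- findWaterMediated(s, chrom, cutoff = 3.3)
  brute <- bruteWaterBridges(s, chrom, 3.3)
  a <- atoms(s)
  expect_equal(nrow(wm), nrow(brute))
  expect_setequal(unique(wm$water_res_seq), unique(a$res_seq[brute$water]))
  expect_setequal(unique(wm$res_seq_b), unique(a$res_seq[brute$resAtom]))
  # the constructed pocket: 2 bridging waters, 6 bridged residues
  expect_length(unique(wm$water_res_seq), 2L)
  expect_length(unique(wm$res_seq_b),
                toy$manifest$expected_counts[["water_mediated"]])
})

test_that("stripping waters empties the water-mediated list", {
  a <- atoms(s)
  dry <- newStructure(a[a$res_name != "HOH", ])
  chromDry <- identifyChromophore(dry, "A")
  expect_equal(nrow(findWaterMediated(dry, chromDry, 3.3)), 0L)
})

test_that("hydrophobic contacts report the constructed residues only", {
  hp <- findHydrophobic(s, chrom, cutoff = 4.0)
  expected <- toy$manifest$placements$res_seq[
    toy$manifest$placements$class == "hydrophobic"]
  expect_setequal(hp$res_seq_b, expected)
  expect_equal(nrow(hp), toy$manifest$expected_counts[["hydrophobic"]])
  expect_true(all(hp$metric <= 4.0))
  # a single Leu CD at 3.8 A from a chromophore carbon is reported
  one <- toyShellStructure(hbondDists = numeric(0),
                           waterLegs = list(), plainDists = numeric(0),
                           hydrophobicDists = 3.8)
  hp1 <- findHydrophobic(one$structure, one$chromophore, cutoff = 4.0)
  expect_equal(nrow(hp1), 1L)
  expect_equal(hp1$metric, 3.8, tolerance = 1e-6)
  # a polar-only neighbour contributes nothing
  pol <- toyShellStructure(hbondDists = 3.0, waterLegs = list(),
                           plainDists = numeric(0),
                           hydrophobicDists = numeric(0))
  expect_equal(nrow(findHydrophobic(pol$structure, pol$chromophore, 4.0)), 0L)
})

test_that("shell census matches brute-force minimum distances and the manifest", {
  cen <- shellCensus(s, chrom, radius = 4.0)
  brute <- bruteShellDistances(s, chrom)
  expect_setequal(paste(cen$shell_residues$chain, cen$shell_residues$res_seq),
                  names(brute)[brute <= 4.0])
  m <- match(paste(cen$shell_residues$chain, cen$shell_residues$res_seq),
             names(brute))
  expect_equal(cen$shell_residues$min_dist, as.numeric(brute[m]),
               tolerance = 0.02)
  expect_equal(nrow(cen$shell_residues),
               as.integer(toy$manifest$expected_counts[["shell_at_4A"]]))
  expect_length(cen$direct_hbond,
                as.integer(toy$manifest$expected_counts[["direct_hbond"]]))
  expect_length(cen$water_mediated,
                as.integer(toy$manifest$expected_counts[["water_mediated"]]))
  expect_length(cen$hydrophobic,
                as.integer(toy$manifest$expected_counts[["hydrophobic"]]))
  # classified subsets are subsets of the shell; unclassified are reported
  allLab <- paste0(cen$shell_residues$res_name, cen$shell_residues$chain,
                   cen$shell_residues$res_seq)
  expect_true(all(cen$direct_hbond %in% allLab))
  expect_true(all(cen$water_mediated %in% allLab))
  expect_true(all(cen$hydrophobic %in% allLab))
  expect_length(cen$unclassified, 1L)
})

test_that("census honours the radius: graded targets in, tiny radius empty", {
  graded <- toyShellStructure(hbondDists = numeric(0), waterLegs = list(),
                              hydrophobicDists = numeric(0),
                              plainDists = c(3.5, 3.9, 4.5))
  cen <- shellCensus(graded$structure, graded$chromophore, radius = 4.0)
  expect_equal(nrow(cen$shell_residues), 2L)
  tiny <- shellCensus(s, chrom, radius = 0.1)
  expect_equal(nrow(tiny$shell_residues), 0L)
  # monotonicity: growing the radius never loses a member
  r1 <- shellCensus(s, chrom, radius = 3.5)$shell_residues
  r2 <- shellCensus(s, chrom, radius = 4.5)$shell_residues
  expect_true(all(paste(r1$chain, r1$res_seq) %in% paste(r2$chain, r2$res_seq)))
})
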