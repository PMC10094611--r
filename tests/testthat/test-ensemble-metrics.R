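# RMSF, contact occupancy/lifetimes, pi-pi stacking.

toy <- toyShellStructure(withHydroxylH = TRUE)
s <- toy$structure
chrom <- toy$chromophore

test_that("a static ensemble has zero RMSF everywhere", {
  co <- array(coords(s), dim = c(nAtoms(s), 3, 5))
  e <- new("FPEnsemble", topology = s, coords = co, dt = 100)
  prof <- rmsf(e, equilFraction = 0)
  expect_true(all(prof$rmsf < 1e-10))
  expect_equal(nrow(prof), length(unique(paste(atoms(s)$chain_id,
                                               atoms(s)$res_seq))))
})

test_that("isotropic Gaussian noise recovers sigma * sqrt(3)", {
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 5000, seed = 42, sigma = 0.30))
  prof <- rmsf(gen$ensemble, fitSelection = seq_len(nAtoms(s)),
               atomScope = "all", equilFraction = 0)
  perAtom <- attr(prof, "per_atom")
  expect_equal(mean(perAtom), 0.30 * sqrt(3), tolerance = 0.02)
  # and against the manifest's per-atom expectation
  expect_equal(mean(perAtom / gen$manifest$expected_rmsf_per_atom), 1,
               tolerance = 0.02)
})

test_that("RMSF is invariant under a global rigid transform of every frame", {
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 200, seed = 9, sigma = 0.25))
  e <- gen$ensemble
  t <- 40 * pi / 180
  R <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  co2 <- e@coords
  for (i in seq_len(nFrames(e)))
    co2[, , i] <- sweep(co2[, , i] %*% t(R), 2, c(5, -3, 11), "+")
  e2 <- new("FPEnsemble", topology = s, coords = co2, dt = e@dt)
  p1 <- attr(rmsf(e, equilFraction = 0), "per_atom")
  p2 <- attr(rmsf(e2, equilFraction = 0), "per_atom")
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("equilibration trimming drops the requested initial fraction", {
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 100, seed = 2, sigma = 0.1))
  prof <- rmsf(gen$ensemble, equilFraction = 0.25)
  expect_equal(attr(prof, "n_frames_used"), 75L)
  co <- array(coords(s), dim = c(nAtoms(s), 3, 2))
  e2 <- new("FPEnsemble", topology = s, coords = co, dt = 100)
  expect_error(rmsf(e2, equilFraction = 0.6), "fewer than 2")
})

test_that("an always-present contact has occupancy 1 and one event", {
  co <- array(coords(s), dim = c(nAtoms(s), 3, 10))
  e <- new("FPEnsemble", topology = s, coords = co, dt = 100)
  og <- selectAtoms(s, resSeq = 10, atomNames = "OG")
  occ <- contactOccupancy(e, data.frame(label = "OH-OG", donor = chrom@oh,
                                        acceptor = og))
  expect_equal(occ$series$pr_oc, 1.0)
  expect_equal(occ$series$n_events, 1L)
  expect_equal(occ$series$mean_lifetime_ps, 10 * 100)
})

test_that("Markov-switched contacts: analysis equals the generated state
           sequence, occupancy and dwell are recovered", {
  og <- selectAtoms(s, resSeq = 10, atomNames = "OG")
  spec <- ensembleSpec(
    nFrames = 20000, seed = 1234, sigma = 0.30,
    contacts = list(list(donor = chrom@oh, acceptor = og,
                         occupancy = 0.30, dwellOn = 10)))
  gen <- makeEnsemble(s, spec)
  occ <- contactOccupancy(gen$ensemble,
                          data.frame(label = "c1", donor = chrom@oh,
                                     acceptor = og))
  # per-frame detection identical to the generator's state labels
  expect_identical(unname(occ$presence[, 1]),
                   unname(gen$manifest$contact_states[, 1]))
  # pr_oc is the exact fraction of present frames
  expect_identical(occ$series$pr_oc, mean(gen$manifest$contact_states[, 1]))
  # parameter recovery at the spec'd tolerances
  expect_equal(occ$series$pr_oc, 0.30, tolerance = 0.02 / 0.30)
  expect_equal(occ$series$mean_lifetime_ps, 10 * 100,
               tolerance = 0.10)
  # lifetime bookkeeping conserves mass
  expect_identical(occ$series$total_on_frames, sum(occ$presence[, 1]))
  expect_equal(occ$series$mean_lifetime_ps * occ$series$n_events,
               occ$series$total_on_frames * 100)
})

test_that("hydrogen-aware criterion applies the angle bound", {
  # donor-acceptor at 3.0: present when H is on the axis, absent when the
  # H-donor-acceptor angle exceeds 30 degrees
  base <- data.frame(name = c("OG", "HG", "OD1"),
                     res_name = c("SER", "SER", "ASN"),
                     chain_id = c("A", "A", "B"), res_seq = c(1, 1, 2),
                     x = c(0, 0.96, 3.0), y = 0, z = 0)
  topo <- newStructure(base)
  aligned <- as.matrix(base[, c("x", "y", "z")])
  bent <- aligned
  bent[2, ] <- c(0.96 * cos(50 * pi / 180), 0.96 * sin(50 * pi / 180), 0)
  e <- ensembleFromFrames(topo, list(aligned, bent, aligned))
  occ <- contactOccupancy(e, data.frame(label = "h", donor = 1, acceptor = 3,
                                        hydrogen = 2))
  expect_equal(unname(occ$presence[, 1]), c(TRUE, FALSE, TRUE))
  expect_error(contactOccupancy(e, data.frame(label = "bad", donor = 1,
                                              acceptor = 99)),
               "missing atoms")
})

test_that("pi-pi occupancy: parallel stacked rings always, oscillation 40%", {
  hexA <- 1.4 * cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6), 0)
  mkTopo <- function() newStructure(data.frame(
    name = paste0("C", 1:12), res_name = c(rep("PHE", 6), rep("TYR", 6)),
    chain_id = "A", res_seq = rep(1:2, each = 6),
    x = c(hexA[, 1], hexA[, 1]), y = c(hexA[, 2], hexA[, 2]),
    z = c(hexA[, 3], hexA[, 3] + 3.8)))
  topo <- mkTopo()
  stacked <- coords(topo)
  e <- ensembleFromFrames(topo, list(stacked, stacked, stacked))
  occ <- pipiOccupancy(e, ringA = 1:6, ringB = 7:12)
  expect_equal(occ$series$pr_oc, 1.0)
  # separation oscillates: 2 of 5 frames within the 5.5 A criterion
  frames <- lapply(c(3.8, 7.5, 3.9, 8.0, 9.0), function(z) {
    f <- stacked; f[7:12, 3] <- f[7:12, 3] - 3.8 + z; f
  })
  e2 <- ensembleFromFrames(topo, frames)
  occ2 <- pipiOccupancy(e2, 1:6, 7:12)
  expect_equal(occ2$series$pr_oc, 0.40)
  # a tilted far ring fails the angle criterion even when close
  tilt <- stacked
  t <- 50 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  tilt[7:12, ] <- sweep(sweep(tilt[7:12, ], 2, colMeans(tilt[7:12, ])) %*% t(R),
                        2, colMeans(tilt[7:12, ]), "+")
  e3 <- ensembleFromFrames(topo, list(tilt))
  expect_equal(pipiOccupancy(e3, 1:6, 7:12)$series$pr_oc, 0)
  # sensitivity report is attached
  expect_named(occ2$sensitivity, c("minus_0.5", "plus_0.5"))
})
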