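# Fragment dipole moment, cis/trans state classification, 2D state density.

toy <- toyShellStructure(withHydroxylH = TRUE)
s <- toy$structure
chrom <- setCharges(toy$chromophore, neutralCharges())

staticEnsemble <- function(structure, n = 1) {
  new("FPEnsemble", topology = structure,
      coords = array(coords(structure), dim = c(nAtoms(structure), 3, n)),
      dt = 100)
}

test_that("two opposite unit charges 1 A apart give 4.8032 D along the axis", {
  pair <- newStructure(data.frame(
    name = c("Q1", "Q2"), res_name = "XXX", chain_id = "A", res_seq = 1,
    x = c(0, 1), y = 0, z = 0, element = "C"))
  # hand calculation: |q| * d = 1 e * 1 A = 4.8032 D, direction +x
  q <- c(Q1 = -1, Q2 = 1)
  xyz <- coords(pair)
  ref <- colMeans(xyz)
  dm <- colSums(q * sweep(xyz, 2, ref)) * 4.8032
  expect_equal(sqrt(sum(dm^2)), 4.8032, tolerance = 1e-12)
  expect_equal(unname(dm / sqrt(sum(dm^2))), c(1, 0, 0), tolerance = 1e-12)
})

test_that("zero charges give zero dipole in every frame", {
  zero <- chrom
  zero@charges[] <- 0
  d <- dipoleSeries(staticEnsemble(s, 3), zero)
  expect_equal(d$dm_modulus, rep(0, 3))
})

test_that("missing charges fail naming the atoms", {
  partial <- setCharges(toy$chromophore, c(OH = -0.4))
  expect_error(dipoleSeries(staticEnsemble(s), partial), "CG2")
})

test_that("a neutral fragment's dipole is independent of the reference point", {
  d0 <- dipoleSeries(staticEnsemble(s), chrom)
  d1 <- dipoleSeries(staticEnsemble(s), chrom, referencePoint = c(100, -50, 3))
  expect_equal(d0$dm_modulus, d1$dm_modulus, tolerance = 1e-9)
  expect_equal(d0$axis_angle, d1$axis_angle, tolerance = 1e-9)
  # a charged fragment is origin-dependent, and the reference is reported
  an <- setCharges(toy$chromophore, anionCharges())
  a0 <- dipoleSeries(staticEnsemble(s), an)
  a1 <- dipoleSeries(staticEnsemble(s), an, referencePoint = c(100, -50, 3))
  expect_gt(abs(a0$dm_modulus - a1$dm_modulus), 1)
  expect_match(attr(a0, "reference_point"), "centroid")
  expect_equal(attr(a0, "net_charge"), -1, tolerance = 1e-9)
})

test_that("axis angle uses the CG2 -> CZ vector convention in [0, 180]", {
  d <- dipoleSeries(staticEnsemble(s), chrom)
  expect_true(all(d$axis_angle >= 0 & d$axis_angle <= 180))
  expect_equal(d$dm_modulus, sqrt(d$dm_x^2 + d$dm_y^2 + d$dm_z^2))
})

test_that("an all-trans ensemble classifies as pure major state", {
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 50, seed = 5, sigma = 0.2,
                                      dipole = list(transFraction = 1)),
                      chrom = chrom)
  d <- dipoleSeries(gen$ensemble, chrom)
  st <- classifyStates(d, gen$ensemble, chrom)
  expect_equal(nrow(st$summary), 1L)
  expect_identical(st$summary$state, "major_trans")
  expect_equal(st$summary$population, 1.0)
})

test_that("a 70/30 trans/cis mixture is recovered and matches the labels", {
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 10000, seed = 77, sigma = 0.2,
                                      dipole = list(transFraction = 0.70)),
                      chrom = chrom)
  d <- dipoleSeries(gen$ensemble, chrom)
  st <- classifyStates(d, gen$ensemble, chrom)
  # frame-by-frame agreement with the generator's labels
  expect_identical(st$series$state, gen$manifest$dipole_labels)
  pops <- st$summary$population
  names(pops) <- st$summary$state
  expect_equal(sum(pops), 1.0)
  expect_equal(unname(pops["major_trans"]), 0.70, tolerance = 0.02 / 0.70)
  expect_equal(unname(pops["major_trans"]),
               gen$manifest$trans_fraction_realized)
})

test_that("classification without a hydroxyl hydrogen is an error", {
  noH <- toyShellStructure(withHydroxylH = FALSE)
  chromNoH <- setCharges(noH$chromophore, neutralCharges())
  d <- dipoleSeries(staticEnsemble(noH$structure), chromNoH)
  e <- staticEnsemble(noH$structure)
  expect_error(classifyStates(d, e, chromNoH), "hydroxyl hydrogen")
})

test_that("density2d integrates to 1 and refining bins preserves that", {
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 2000, seed = 13, sigma = 0.2,
                                      dipole = list(transFraction = 0.7)),
                      chrom = chrom)
  d <- dipoleSeries(gen$ensemble, chrom)
  for (nb in c(10L, 40L, 80L)) {
    dn <- density2d(d, modBreaks = nb, angleBreaks = nb)
    area <- outer(diff(dn$mod_edges), diff(dn$angle_edges))
    expect_equal(sum(dn$density * area), 1, tolerance = 1e-9)
  }
  expect_error(density2d(d, modBreaks = 0L), "degenerate")
  expect_error(density2d(d, modBreaks = c(3, 2, 1)), "degenerate")
})

test_that("a single repeated frame occupies one bin with unit integral", {
  d <- dipoleSeries(staticEnsemble(s, 4), chrom)
  dn <- density2d(d, modBreaks = 5L, angleBreaks = 5L)
  expect_equal(sum(dn$counts > 0), 1L)
  area <- outer(diff(dn$mod_edges), diff(dn$angle_edges))
  expect_equal(sum(dn$density * area), 1, tolerance = 1e-9)
})

test_that("a two-state mixture puts its density modes at the generator's
           state centers", {
  # low positional noise so the two geometric states stay well separated in
  # (modulus, angle) space and the mode locations are sharply defined
  gen <- makeEnsemble(s, ensembleSpec(nFrames = 8000, seed = 21, sigma = 0.03,
                                      dipole = list(transFraction = 0.65)),
                      chrom = chrom)
  d <- dipoleSeries(gen$ensemble, chrom)
  st <- classifyStates(d, gen$ensemble, chrom)
  centers <- gen$manifest$dipole_state_centers
  expect_equal(nrow(centers), 2L)
  for (state in centers$state) {
    sub <- st$series[st$series$state == state, ]
    expect_equal(mean(sub$dm_modulus),
                 centers$dm_modulus[centers$state == state],
                 tolerance = 0.05)
    expect_equal(mean(sub$axis_angle),
                 centers$axis_angle[centers$state == state],
                 tolerance = 0.05)
  }
  # each state's density mode sits in the bin containing its center: split
  # the modulus axis at the midpoint between the two centers and take the
  # top bin in each half
  dn <- density2d(d, modBreaks = 25L, angleBreaks = 25L)
  binOf <- function(m, a) {
    mi <- findInterval(m, dn$mod_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ai <- findInterval(a, dn$angle_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    c(mi, ai)
  }
  mids <- (dn$mod_edges[-1] + dn$mod_edges[-length(dn$mod_edges)]) / 2
  cutpoint <- mean(centers$dm_modulus)
  for (k in seq_len(2)) {
    half <- if (centers$dm_modulus[k] < cutpoint) mids < cutpoint
            else mids >= cutpoint
    sub <- dn$density[half, , drop = FALSE]
    top <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    want <- binOf(centers$dm_modulus[k], centers$axis_angle[k])
    expect_equal(unname(which(half)[top[1]]), want[1])
    expect_equal(unname(top[2]), want[2])
  }
})

test_that("uniform samples over a rectangle give a flat density", {
  n <- 20000
  set.seed(99)
  d <- data.frame(frame = 1:n, dm_x = 0, dm_y = 0, dm_z = 0,
                  dm_modulus = runif(n, 2, 6),
                  axis_angle = runif(n, 20, 80))
  class(d) <- c("DipoleSeries", "data.frame")
  dn <- density2d(d, modBreaks = c(2, 3, 4, 5, 6),
                  angleBreaks = c(20, 35, 50, 65, 80))
  # chi-square against uniform bin counts
  expected <- dn$n / length(dn$counts)
  chi2 <- sum((dn$counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = length(dn$counts) - 1))
})
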