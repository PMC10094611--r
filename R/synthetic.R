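# Synthetic structures and ensembles with known ground truth.  The toy
# structure is a beta-barrel-free mini-protein: a CRO-named chromophore with
# shell residues placed at exact target distances, so the construction
# itself is the oracle for every static detector.  Ensembles add Gaussian
# positional noise, two-state Markov switching of individual contacts, and
# an i.i.d. cis/trans hydroxyl mixture, with every realized label recorded
# in a manifest.

#' Build an FPStructure from an atom table
#'
#' Low-level constructor used by the generator and handy in tests.  Missing
#' optional columns are filled with defaults (occupancy 1, b_factor 0,
#' element from the atom name's first letter).
#'
#' @param atoms data.frame with at least \code{name}, \code{res_name},
#'   \code{chain_id}, \code{res_seq}, \code{x}, \code{y}, \code{z}.
#' @param modelId model number.
#' @param metadata metadata list.
#' @return an [FPStructure-class].
#' @export
newStructure <- function(atoms, modelId = 1L, metadata = list()) {
  n <- nrow(atoms)
  defaults <- list(serial = seq_len(n), alt_loc = "", i_code = "",
                   occupancy = 1, b_factor = 0, is_het = FALSE)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[0-9']", "", atoms$name), 1, 1)
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  new("FPStructure", atoms = atoms, modelId = as.integer(modelId),
      metadata = metadata)
}

.rotZ <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# rotate points about an arbitrary axis (unit vector) through `origin`
.rotAbout <- function(xyz, axis, deg, origin) {
  t <- deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

.unit <- function(v) v / sqrt(sum(v^2))

# CRO-style chromophore template: phenol ring in the z = 0 plane, hydroxyl
# at +x, imidazolinone ring tilted by `tilt` degrees about an in-plane axis.
.croTemplate <- function(tilt = 7, withH = FALSE, hydroxylState = "trans") {
  hex <- 1.39 * cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  phen <- rbind(CZ = hex[1, ], CE1 = hex[2, ], CD1 = hex[3, ],
                CG2 = hex[4, ], CD2 = hex[5, ], CE2 = hex[6, ])
  OH <- c(2.75, 0, 0)
  CB2 <- c(-2.65, 0.60, 0)
  u <- .unit(CB2 - phen["CG2", ])
  CA2 <- CB2 + 1.38 * u
  cen <- CA2 + 1.17 * u                      # pentagon centre
  vert <- function(deg) cen + 1.17 * as.numeric(.rotZ(deg) %*% (CA2 - cen))
  C2 <- vert(72); N3 <- vert(144); C1 <- vert(216); N2 <- vert(288)
  O2 <- C2 + 1.23 * .unit(C2 - cen)
  CA1 <- C1 + 1.49 * .unit(C1 - cen) + c(0, 0, -0.55)
  N1 <- CA1 + 1.47 * .unit(CA1 - C1) + c(0, 0, -0.35)
  CA3 <- N3 + 1.47 * .unit(N3 - cen) + c(0, 0, 0.55)
  C3 <- CA3 + 1.52 * .unit(CA3 - N3)
  O3 <- C3 + 1.23 * c(0, 0.30, 0.95) / sqrt(0.30^2 + 0.95^2)
  imid <- rbind(C1 = C1, N2 = N2, N3 = N3, C2 = C2, O2 = O2,
                CA1 = CA1, N1 = N1, CA3 = CA3, C3 = C3, O3 = O3)
  if (tilt != 0) {
    axis <- c(-u[2], u[1], 0)                # in-plane, perpendicular to u
    imid <- .rotAbout(imid, axis, tilt, CA2)
  }
  coordsTab <- rbind(phen, OH = OH, CB2 = CB2, CA2 = CA2, imid)
  if (withH) {
    H <- .hydroxylPosition(coordsTab, hydroxylState)
    coordsTab <- rbind(coordsTab, HOH1 = H)
  }
  el <- substr(gsub("[0-9]", "", rownames(coordsTab)), 1, 1)
  data.frame(name = rownames(coordsTab), element = el,
             x = coordsTab[, 1], y = coordsTab[, 2], z = coordsTab[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

# the two in-plane hydroxyl rotamers: the O-H bond makes ~109.5 deg with
# O-CZ; "cis" leans toward the carbonyl-oxygen side of the CZ-OH axis,
# "trans" away from it
.hydroxylPosition <- function(tab, state) {
  OH <- tab["OH", ]; CZ <- tab["CZ", ]; O2 <- tab["O2", ]
  axis <- .unit(OH - CZ)
  perp <- (O2 - OH) - sum((O2 - OH) * axis) * axis
  perp <- .unit(perp)
  sgn <- if (state == "cis") 1 else -1
  ang <- (180 - 109.5) * pi / 180            # angle of O->H from the +axis
  as.numeric(OH + 0.96 * (cos(ang) * axis + sgn * sin(ang) * perp))
}

# string a residue's remaining atoms outward from its contact atom
.residueAtoms <- function(resName, contactName, contactPos, dir) {
  lat <- .unit(if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(1, 0, 0))
  at <- function(name, along, side = 0)
    c(name = name, as.list(contactPos + along * dir + side * lat))
  rows <- switch(resName,
    SER = list(at("OG", 0), at("CB", 1.43), at("CA", 2.70, 0.6),
               at("N", 3.60, 1.5), at("C", 3.90, -0.6), at("O", 5.00, -1.0)),
    LEU = list(at("CD1", 0), at("CG", 1.53), at("CD2", 2.20, 1.3),
               at("CB", 2.90, -0.6), at("CA", 4.20, -0.9),
               at("N", 5.20, 0.2), at("C", 5.30, -1.9), at("O", 6.40, -2.2)),
    GLY = list(at("CA", 0), at("N", 1.45, 0.5), at("C", 1.50, -1.0),
               at("O", 2.60, -1.4)),
    stop("unsupported toy residue type: ", resName))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, x = r$x, y = r$y, z = r$z,
               stringsAsFactors = FALSE)))
  df$name[df$name == contactName][1] <- contactName
  df
}

#' Generate a toy chromophore-shell structure with known ground truth
#'
#' Builds a mini-protein on chain A: a CRO-named chromophore (residue 66)
#' plus shell residues placed so that each one's minimum heavy-atom distance
#' to the chromophore equals its target to 0.01 Angstrom.  Four placement
#' classes mirror the census structure of a GFP chromophore pocket:
#' \describe{
#'   \item{hbond}{serines whose OG sits at the target distance from a
#'     chromophore polar atom (direct H-bond partners).}
#'   \item{water}{bridging waters at \code{leg1} from a chromophore polar
#'     atom, each surrounded by serines whose OG sits at \code{leg2} from
#'     the water (water-mediated partners; their realized chromophore
#'     distance, ~\code{shellDist}, keeps them inside the shell).}
#'   \item{hydrophobic}{leucines whose CD1 sits at the target distance from
#'     a chromophore apolar carbon.}
#'   \item{plain}{glycines whose CA (neither polar nor apolar by the
#'     capability tables) sits at the target distance: shell members with no
#'     interaction class.}
#' }
#' The defaults realize the canonical pocket composition: 5 direct
#' H-bond partners, 2 waters bridging 6 residues, 7 hydrophobic residues and
#' 1 unclassified shell member (19 shell residues at 4 Angstrom).
#'
#' @param hbondDists target distances for direct H-bond serines (max 5,
#'   anchored at OH, O2, N2-adjacent polar atoms).
#' @param waterLegs list with one numeric vector c(leg1, leg2...) per water:
#'   first element is the chromophore-water leg, the rest are water-residue
#'   legs (one bridged serine each).  At most 2 waters.
#' @param waterShellDist realized chromophore distance aimed for the
#'   bridged serines' OG (default 3.9; must exceed the H-bond cutoff and
#'   stay within the shell radius).
#' @param hydrophobicDists target distances for leucines (max 7).
#' @param plainDists target distances for unclassified glycines.
#' @param ringTilt angle in degrees between the imidazolinone and phenol
#'   ring planes (default 7).
#' @param withHydroxylH include the phenolic hydroxyl hydrogen (needed for
#'   ensemble dipole-state work).
#' @param hydroxylState \code{"trans"} or \code{"cis"} starting rotamer.
#' @return list with \code{structure} ([FPStructure-class]),
#'   \code{chromophore} ([Chromophore-class]) and \code{manifest} (ground
#'   truth: placements data.frame with class/anchor/target/realized
#'   distances, expected census counts, ring tilt).
#' @examples
#' toy <- toyShellStructure()
#' toy$manifest$expected_counts
#' @export
toyShellStructure <- function(hbondDists = c(2.80, 2.90, 3.00, 3.10, 3.20),
                              waterLegs = list(c(2.80, 2.85, 2.85, 2.85),
                                               c(2.80, 2.85, 2.85, 2.85)),
                              waterShellDist = 3.9,
                              hydrophobicDists = rep(3.80, 7),
                              plainDists = 3.70,
                              ringTilt = 7,
                              withHydroxylH = FALSE,
                              hydroxylState = c("trans", "cis")) {
  hydroxylState <- match.arg(hydroxylState)
  stopifnot(length(hbondDists) <= 5, length(waterLegs) <= 2,
            length(hydrophobicDists) <= 7)
  cro <- .croTemplate(tilt = ringTilt, withH = withHydroxylH,
                      hydroxylState = hydroxylState)
  pos <- as.matrix(cro[, c("x", "y", "z")])
  rownames(pos) <- cro$name
  heavyMask <- cro$element != "H"
  centroid <- colMeans(pos[heavyMask, , drop = FALSE])
  phenCen <- colMeans(pos[c("CZ", "CE1", "CD1", "CG2", "CD2", "CE2"), ])

  atomsList <- list(data.frame(name = cro$name, element = cro$element,
                               res_name = "CRO", chain_id = "A",
                               res_seq = 66L, x = pos[, 1], y = pos[, 2],
                               z = pos[, 3], is_het = TRUE,
                               stringsAsFactors = FALSE))
  placements <- list()
  nextRes <- 10L

  addResidue <- function(resName, contactName, contactPos, dir, class,
                         anchor, target) {
    df <- .residueAtoms(resName, contactName, contactPos, dir)
    df$element <- substr(df$name, 1, 1)
    df$res_name <- resName; df$chain_id <- "A"; df$res_seq <- nextRes
    df$is_het <- FALSE
    atomsList[[length(atomsList) + 1]] <<- df
    placements[[length(placements) + 1]] <<- data.frame(
      res_seq = nextRes, res_name = resName, class = class,
      anchor_atom = anchor, contact_atom = contactName,
      target_dist = target, stringsAsFactors = FALSE)
    nextRes <<- nextRes + 10L
  }

  pentCen <- colMeans(pos[c("C1", "N2", "N3", "C2", "CA2"), ])

  # --- direct H-bond serines: anchors are terminal polar atoms ------------
  # directions chosen to clear the rest of the chromophore (the N2 partner
  # leaves radially from the pentagon; the OH partner leaves at +70 degrees
  # so the hydroxyl end can also host the bridging waters)
  hbAnchors <- list(
    OH = .unit(as.numeric(.rotZ(70) %*% c(1, 0, 0))),
    O2 = .unit(pos["O2", ] - pos["C2", ]),
    N2 = .unit(pos["N2", ] - pentCen),
    N1 = .unit(pos["N1", ] - pos["CA1", ]),
    O3 = .unit(pos["O3", ] - pos["C3", ]))
  for (k in seq_along(hbondDists)) {
    anchor <- names(hbAnchors)[k]
    dir <- hbAnchors[[k]]
    addResidue("SER", "OG", pos[anchor, ] + hbondDists[k] * dir, dir,
               "hbond", anchor, hbondDists[k])
  }

  # --- bridging waters and their serines ----------------------------------
  # both waters sit off the roomy hydroxyl end (below and above the ring
  # plane); their serines fan out on an orthonormal frame perpendicular to
  # the chromophore-water axis, tilted so the OG lands at waterShellDist
  # from the anchor atom
  waterAnchors <- list(
    OH = .unit(as.numeric(.rotZ(-50) %*% c(1, 0, 0))),
    OH = .unit(c(1, 0, -1.2)))
  waterRows <- list()
  for (w in seq_along(waterLegs)) {
    legs <- waterLegs[[w]]
    stopifnot(length(legs) >= 2, length(legs) <= 4)
    anchor <- names(waterAnchors)[w]
    u <- waterAnchors[[w]]
    wPos <- pos[anchor, ] + legs[1] * u
    waterRows[[w]] <- data.frame(name = "O", element = "O",
                                 res_name = "HOH", chain_id = "W",
                                 res_seq = 200L + w, x = wPos[1],
                                 y = wPos[2], z = wPos[3], is_het = TRUE,
                                 stringsAsFactors = FALSE)
    b1 <- .unit(c(u[2], -u[1], 0))
    if (sum(b1 * (centroid - wPos)) > 0) b1 <- -b1   # point away from bulk
    b2 <- c(u[2] * b1[3] - u[3] * b1[2],
            u[3] * b1[1] - u[1] * b1[3],
            u[1] * b1[2] - u[2] * b1[1])
    fan <- list(b2, -b2, b1)
    cu <- (waterShellDist^2 - legs[1]^2 -
             mean(legs[-1])^2) / (2 * legs[1] * mean(legs[-1]))
    cu <- max(-0.9, min(0.9, cu))
    for (j in seq_along(legs[-1])) {
      v <- .unit(cu * u + sqrt(1 - cu^2) * fan[[j]])
      addResidue("SER", "OG", wPos + legs[1 + j] * v, v,
                 "water", anchor, legs[1 + j])
    }
  }

  # --- hydrophobic leucines: anchors on apolar ring/bridge carbons --------
  # (phenol-side anchors only; the imidazolinone side is crowded by the
  # carbonyl and the backbone arms)
  zfan <- function(p, zoff) .unit(.unit(p - phenCen) + c(0, 0, zoff))
  hpAnchors <- list(
    CE1 = zfan(pos["CE1", ], 0.45), CE1 = zfan(pos["CE1", ], -0.45),
    CD2 = zfan(pos["CD2", ], 0.45), CD2 = zfan(pos["CD2", ], -0.45),
    CE2 = zfan(pos["CE2", ], 0.45),
    CB2 = c(0, 0, 1), CB2 = c(0, 0, -1))
  for (k in seq_along(hydrophobicDists)) {
    anchor <- names(hpAnchors)[k]
    dir <- hpAnchors[[k]]
    addResidue("LEU", "CD1", pos[anchor, ] + hydrophobicDists[k] * dir, dir,
               "hydrophobic", anchor, hydrophobicDists[k])
  }

  # --- unclassified glycines ----------------------------------------------
  plainAnchors <- list(O3 = .unit(c(0.2, -0.4, 1)),
                       N1 = .unit(c(-0.3, -1, -0.4)),
                       OH = .unit(as.numeric(.rotZ(130) %*% c(0, 0, 1) +
                                               c(0.3, 0.8, 0.7))))
  for (k in seq_along(plainDists)) {
    anchor <- names(plainAnchors)[((k - 1) %% 3) + 1]
    dir <- plainAnchors[[((k - 1) %% 3) + 1]]
    addResidue("GLY", "CA", pos[anchor, ] + plainDists[k] * dir, dir,
               "plain", anchor, plainDists[k])
  }

  allAtoms <- do.call(rbind, c(atomsList, waterRows))
  s <- newStructure(allAtoms, metadata = list(generator = "toyShellStructure"))

  # realized minimum heavy-atom distance of every placed residue to the
  # chromophore; construction is the oracle, so targets must be realized
  plc <- if (length(placements)) do.call(rbind, placements) else
    data.frame(res_seq = integer(0), res_name = character(0),
               class = character(0), anchor_atom = character(0),
               contact_atom = character(0), target_dist = numeric(0))
  a <- s@atoms
  chromIdx <- which(a$res_seq == 66L & a$element != "H")
  cxyz <- as.matrix(a[chromIdx, c("x", "y", "z")])
  plc$realized_min_dist <- vapply(seq_len(nrow(plc)), function(i) {
    ri <- which(a$res_seq == plc$res_seq[i] & a$chain_id == "A")
    min(.pairDistMatrix(as.matrix(a[ri, c("x", "y", "z")]), cxyz))
  }, numeric(1))
  strict <- plc$class %in% c("hbond", "hydrophobic", "plain")
  off <- strict & abs(plc$realized_min_dist - plc$target_dist) > 0.01
  if (any(off))
    stop("infeasible placement: residue(s) ",
         paste(plc$res_seq[off], collapse = ", "),
         " realized min distance != target")

  chrom <- identifyChromophore(s, "A")
  manifest <- list(
    placements = plc,
    expected_counts = c(
      direct_hbond = length(hbondDists),
      waters = length(waterLegs),
      water_mediated = sum(lengths(waterLegs) - 1L),
      hydrophobic = length(hydrophobicDists),
      shell_at_4A = sum(plc$realized_min_dist <= 4.0)),
    ring_tilt = ringTilt,
    hydroxyl_state = if (withHydroxylH) hydroxylState else NA_character_,
    chromophore_atoms = a$name[chromIdx])
  list(structure = s, chromophore = chrom, manifest = manifest)
}

#' Specification for a synthetic ensemble
#'
#' @param nFrames number of frames (>= 1).
#' @param dt frame spacing, ps (default 100).
#' @param seed RNG seed; the same seed reproduces the ensemble and manifest
#'   bit for bit.
#' @param sigma default isotropic per-coordinate Gaussian amplitude,
#'   Angstrom (default 0.30).
#' @param perAtomSigma optional named numeric: per-atom sigma overrides,
#'   named by atom index.
#' @param contacts list of Markov-switched contacts, each a list with
#'   \code{donor}, \code{acceptor} (atom indices), \code{occupancy}
#'   (stationary on-fraction), \code{dwellOn} (mean on-dwell, frames), and
#'   optional \code{onDist} (2.9), \code{offDist} (4.5).  The acceptor atom
#'   is displaced along the donor-acceptor axis between the two distances;
#'   donor/acceptor atoms get sigma 0 unless overridden so switching is the
#'   only source of variation for that distance.
#' @param dipole optional list \code{list(transFraction =)} enabling i.i.d.
#'   two-state hydroxyl switching (topology must carry the hydroxyl H).
#' @return a list of class \code{"EnsembleSpec"}.
#' @export
ensembleSpec <- function(nFrames, dt = 100, seed = 1L, sigma = 0.30,
                         perAtomSigma = NULL, contacts = list(),
                         dipole = NULL) {
  stopifnot(nFrames >= 1, dt > 0, sigma >= 0)
  for (ct in contacts)
    stopifnot(ct$occupancy >= 0, ct$occupancy <= 1, ct$dwellOn >= 1)
  if (!is.null(dipole))
    stopifnot(dipole$transFraction >= 0, dipole$transFraction <= 1)
  structure(list(nFrames = as.integer(nFrames), dt = dt,
                 seed = as.integer(seed), sigma = sigma,
                 perAtomSigma = perAtomSigma, contacts = contacts,
                 dipole = dipole),
            class = "EnsembleSpec")
}

# two-state Markov chain with stationary on-fraction p and mean on-dwell
# `dwellOn` frames; returns logical vector
.markovChain <- function(n, p, dwellOn) {
  kOff <- 1 / dwellOn                        # on -> off rate per frame
  kOn <- if (p >= 1) 1 else kOff * p / (1 - p)
  if (kOn > 1) stop("infeasible Markov spec: occupancy ", p,
                    " with on-dwell ", dwellOn, " needs off-dwell < 1 frame")
  s <- logical(n)
  s[1] <- stats::runif(1) < p
  u <- stats::runif(n - 1)
  for (i in 2:n) s[i] <- if (s[i - 1]) u[i - 1] >= kOff else u[i - 1] < kOn
  s
}

#' Generate a synthetic ensemble with a ground-truth manifest
#'
#' Frame i is the base coordinates plus independent per-atom Gaussian noise;
#' contacts listed in the spec are toggled by two-state Markov chains
#' (displacing only the acceptor atom along the donor-acceptor axis between
#' the on and off distances); when a dipole spec is present the hydroxyl
#' hydrogen is switched i.i.d. between its trans and cis rotamer positions.
#' The manifest records every realized per-frame label, so analysis output
#' can be checked against ground truth without rerunning the generator.
#'
#' @param base an [FPStructure-class] (e.g. from [toyShellStructure()]).
#' @param spec an [ensembleSpec()].
#' @param chrom a [Chromophore-class]; required when \code{spec$dipole} is
#'   set.
#' @return list with \code{ensemble} ([FPEnsemble-class]) and
#'   \code{manifest}: per-atom sigma and expected RMSF (sigma * sqrt(3)),
#'   per-contact state matrix with specified and realized occupancy/dwell,
#'   per-frame dipole state labels with specified and realized trans
#'   fraction, and the seed.
#' @export
makeEnsemble <- function(base, spec, chrom = NULL) {
  stopifnot(is(base, "FPStructure"), inherits(spec, "EnsembleSpec"))
  n <- nAtoms(base)
  nf <- spec$nFrames
  sig <- rep(spec$sigma, n)
  for (ct in spec$contacts) sig[c(ct$donor, ct$acceptor)] <- 0
  if (!is.null(spec$dipole)) {
    if (is.null(chrom)) stop("dipole spec needs a Chromophore")
    if (!length(chrom@hydroxylH))
      stop("dipole switching needs a hydroxyl hydrogen in the topology")
    sig[c(chrom@hydroxylH, chrom@oh, chrom@cz, chrom@carbonylO)] <- 0
  }
  if (!is.null(spec$perAtomSigma))
    sig[as.integer(names(spec$perAtomSigma))] <- spec$perAtomSigma

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(spec$seed)

  b <- coords(base)
  co <- array(stats::rnorm(n * 3 * nf, sd = rep(sig, 3 * nf)),
              dim = c(n, 3, nf)) + array(b, dim = c(n, 3, nf))

  contactStates <- NULL
  contactSummary <- NULL
  if (length(spec$contacts)) {
    contactStates <- matrix(FALSE, nf, length(spec$contacts))
    rows <- list()
    for (k in seq_along(spec$contacts)) {
      ct <- spec$contacts[[k]]
      onD <- if (is.null(ct$onDist)) 2.9 else ct$onDist
      offD <- if (is.null(ct$offDist)) 4.5 else ct$offDist
      st <- .markovChain(nf, ct$occupancy, ct$dwellOn)
      contactStates[, k] <- st
      axis <- .unit(b[ct$acceptor, ] - b[ct$donor, ])
      dist <- ifelse(st, onD, offD)
      for (dim in 1:3)
        co[ct$acceptor, dim, ] <- b[ct$donor, dim] + dist * axis[dim]
      r <- rle(st)
      onRuns <- r$lengths[r$values]
      rows[[k]] <- data.frame(
        donor = ct$donor, acceptor = ct$acceptor,
        occupancy_spec = ct$occupancy, dwell_spec = ct$dwellOn,
        on_dist = onD, off_dist = offD,
        occupancy_realized = mean(st),
        dwell_realized = if (length(onRuns)) mean(onRuns) else NA_real_)
    }
    contactSummary <- do.call(rbind, rows)
  }

  dipoleLabels <- NULL
  transFrac <- NA_real_
  stateCenters <- NULL
  if (!is.null(spec$dipole)) {
    a <- base@atoms
    tab <- coords(base)
    rownames(tab) <- a$name   # chromophore atom names are unique in the toy
    croRows <- which(a$res_seq == chrom@resSeq & a$chain_id == chrom@chain)
    ctab <- tab[croRows, , drop = FALSE]
    hTrans <- .hydroxylPosition(ctab, "trans")
    hCis <- .hydroxylPosition(ctab, "cis")
    isTrans <- stats::runif(nf) < spec$dipole$transFraction
    hIdx <- chrom@hydroxylH
    for (dim in 1:3)
      co[hIdx, dim, ] <- ifelse(isTrans, hTrans[dim], hCis[dim])
    dipoleLabels <- ifelse(isTrans, "major_trans", "minor_cis")
    transFrac <- mean(isTrans)
    # noise-free dipole state centers from the two rotamer geometries
    if (length(chrom@charges)) {
      stateCenters <- do.call(rbind, lapply(
        list(major_trans = hTrans, minor_cis = hCis), function(h) {
          b2 <- b; b2[hIdx, ] <- h
          e1 <- new("FPEnsemble", topology = base,
                    coords = array(b2, dim = c(n, 3, 1)), dt = spec$dt)
          d1 <- dipoleSeries(e1, chrom)
          data.frame(dm_modulus = d1$dm_modulus, axis_angle = d1$axis_angle)
        }))
      stateCenters$state <- rownames(stateCenters)
      rownames(stateCenters) <- NULL
    }
  }

  ens <- new("FPEnsemble", topology = base, coords = co, dt = spec$dt,
             originLabel = sprintf("synthetic seed %d", spec$seed))
  manifest <- list(
    seed = spec$seed, n_frames = nf, dt = spec$dt,
    sigma_per_atom = sig,
    expected_rmsf_per_atom = sig * sqrt(3),
    contact_states = contactStates,
    contacts = contactSummary,
    dipole_labels = dipoleLabels,
    trans_fraction_spec = if (is.null(spec$dipole)) NA_real_
                          else spec$dipole$transFraction,
    trans_fraction_realized = transFrac,
    dipole_state_centers = stateCenters)
  list(ensemble = ens, manifest = manifest)
}
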