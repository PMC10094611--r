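# Solvent-accessible surface area by Shrake-Rupley sphere-point sampling,
# and the dimer-interface report built on it.

# deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)   # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling on each atom's solvent-expanded sphere
#' (radius + probe) against all neighbouring expanded spheres, with an
#' element-based van der Waals radii table (C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80 Angstrom; unknown elements fall back to 1.70 with a
#' warning).
#'
#' @param x an [FPStructure-class], or an n-by-3 coordinate matrix (then
#'   \code{elements} must be given).
#' @param probe probe radius in Angstroms (default 1.4, water).
#' @param nPoints sphere sample points per atom (>= 92; default 240).
#' @param elements element symbols when \code{x} is a bare matrix.
#' @param subset optional atom indices restricting which atoms are scored
#'   (all atoms still occlude).
#' @return numeric vector of per-atom areas in square Angstroms (named by
#'   atom index when subset is used); \code{sum()} gives the total SASA.
#' @examples
#' # a lone carbon: closed form 4*pi*(1.7+1.4)^2
#' sasa(matrix(0, 1, 3), elements = "C")
#' @export
sasa <- function(x, probe = 1.4, nPoints = 240L, elements = NULL,
                 subset = NULL) {
  stopifnot(probe > 0, nPoints >= 92L)
  if (is(x, "FPStructure")) {
    xyz <- coords(x)
    elements <- x@atoms$element
  } else {
    xyz <- as.matrix(x)
    if (is.null(elements)) stop("elements required for bare coordinates")
  }
  n <- nrow(xyz)
  radii <- .vdwRadius(elements) + probe
  pts <- .spherePoints(as.integer(nPoints))
  score <- if (is.null(subset)) seq_len(n) else as.integer(subset)
  areas <- numeric(length(score))
  maxR <- max(radii)
  for (k in seq_along(score)) {
    i <- score[k]
    ri <- radii[i]
    # neighbours whose expanded spheres can occlude atom i's surface
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (!length(nb)) { areas[k] <- 4 * pi * ri^2; next }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (sp[exposed, 1] - xyz[j, 1])^2 + (sp[exposed, 2] - xyz[j, 2])^2 +
        (sp[exposed, 3] - xyz[j, 3])^2
      exposed[exposed] <- dj2 > radii[j]^2
    }
    areas[k] <- 4 * pi * ri^2 * sum(exposed) / nrow(sp)
  }
  if (!is.null(subset)) names(areas) <- as.character(score)
  areas
}

.structureSubset <- function(x, idx) {
  a <- x@atoms[idx, , drop = FALSE]
  rownames(a) <- NULL
  new("FPStructure", atoms = a, modelId = x@modelId, metadata = x@metadata)
}

#' Buried surface area between two chain sets
#'
#' Total solvent-accessible area buried on complex formation,
#' SASA(A alone) + SASA(B alone) - SASA(A union B), waters excluded.  This
#' is the sum over both subunits (about twice the single-subunit interface
#' footprint); \code{halfArea = TRUE} returns half of it.
#'
#' @param x an [FPStructure-class].
#' @param chainsA,chainsB disjoint, non-empty chain-id sets.
#' @param probe probe radius (Angstrom).
#' @param nPoints sphere sample points per atom.
#' @param halfArea report the one-sided interface area instead of the
#'   two-subunit total.
#' @return buried area in square Angstroms (>= 0).
#' @export
buriedArea <- function(x, chainsA, chainsB, probe = 1.4, nPoints = 240L,
                       halfArea = FALSE) {
  stopifnot(is(x, "FPStructure"))
  if (!length(chainsA) || !length(chainsB)) stop("empty chain selection")
  if (length(intersect(chainsA, chainsB)))
    stop("chain sets must be disjoint: both contain ",
         paste(intersect(chainsA, chainsB), collapse = ","))
  ia <- selectAtoms(x, chain = chainsA, water = FALSE)
  ib <- selectAtoms(x, chain = chainsB, water = FALSE)
  if (!length(ia) || !length(ib)) stop("empty atom selection for given chains")
  sa <- sum(sasa(.structureSubset(x, ia), probe, nPoints))
  sb <- sum(sasa(.structureSubset(x, ib), probe, nPoints))
  sab <- sum(sasa(.structureSubset(x, c(ia, ib)), probe, nPoints))
  ba <- max(0, sa + sb - sab)
  if (halfArea) ba / 2 else ba
}

#' Dimer-interface report: H-bonds, symmetry doubling, hydrophobic cluster
#'
#' Detects cross-chain hydrogen bonds with [findHBonds()] and the
#' cross-chain apolar-carbon cluster, and applies the crystallographic
#' two-fold counting convention when \code{doubling = TRUE}: detected bonds
#' are reduced to unique residue/atom-pair labels (chain identity ignored);
#' each non-self-symmetric label counts twice, a label symmetric under
#' swapping its two sides (same residue number and the swapped atom pair)
#' counts once.  Doubling is a reporting convention, not re-detection.
#'
#' @param x an [FPStructure-class].
#' @param chainsA,chainsB disjoint chain sets.
#' @param cutoff H-bond distance cutoff in Angstroms (default 3.7; interface
#'   tabulations conventionally admit long polar contacts near 3.6).
#' @param doubling apply the two-fold symmetry counting convention.
#' @param probe,nPoints passed to [buriedArea()]; set
#'   \code{computeArea = FALSE} to skip the SASA step.
#' @param computeArea include buried area in the report.
#' @param hydrophobicCutoff apolar carbon-carbon cutoff (default 4.0).
#' @return an object of class \code{"InterfaceReport"}: list with
#'   \code{chains_a}, \code{chains_b}, \code{buried_area}, \code{hbonds}
#'   (unique-label records), \code{hbond_count_total},
#'   \code{hydrophobic_cluster} (per-subunit residue labels),
#'   \code{doubling_applied}, \code{params}.
#' @export
interfaceHBonds <- function(x, chainsA, chainsB, cutoff = 3.7,
                            doubling = TRUE, probe = 1.4, nPoints = 240L,
                            computeArea = FALSE, hydrophobicCutoff = 4.0) {
  stopifnot(is(x, "FPStructure"))
  if (length(intersect(chainsA, chainsB)))
    stop("chain sets must be disjoint")
  ia <- selectAtoms(x, chain = chainsA, water = FALSE)
  ib <- selectAtoms(x, chain = chainsB, water = FALSE)
  hb <- suppressWarnings(findHBonds(x, ia, ib, cutoff = cutoff))
  # unique unordered residue/atom-pair labels, chain identity ignored
  if (nrow(hb)) {
    sideA <- paste0(hb$res_name_a, hb$res_seq_a, ":", hb$atom_a)
    sideB <- paste0(hb$res_name_b, hb$res_seq_b, ":", hb$atom_b)
    lab <- ifelse(sideA < sideB, paste(sideA, sideB, sep = "--"),
                  paste(sideB, sideA, sep = "--"))
    keep <- !duplicated(lab)
    uniq <- hb[keep, , drop = FALSE]
    uniqLab <- lab[keep]
    selfSym <- uniq$res_seq_a == uniq$res_seq_b &
      uniq$res_name_a == uniq$res_name_b
    total <- if (doubling) sum(ifelse(selfSym, 1L, 2L)) else nrow(uniq)
    uniq$label <- uniqLab
    uniq$self_symmetric <- selfSym
  } else {
    uniq <- hb
    total <- 0L
  }
  # hydrophobic cluster: cross-chain apolar carbon pairs, per-subunit residues
  a <- x@atoms
  apol <- .isApolarCarbon(a)
  pa <- ia[apol[ia]]; pb <- ib[apol[ib]]
  cluster <- character(0)
  if (length(pa) && length(pb)) {
    D <- .pairDistMatrix(as.matrix(a[pa, c("x", "y", "z")]),
                         as.matrix(a[pb, c("x", "y", "z")]))
    hit <- which(D <= hydrophobicCutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      resLabs <- c(paste0(a$res_name[pa[hit[, 1]]], a$res_seq[pa[hit[, 1]]]),
                   paste0(a$res_name[pb[hit[, 2]]], a$res_seq[pb[hit[, 2]]]))
      cluster <- sort(unique(resLabs))
    }
  }
  ba <- if (computeArea) buriedArea(x, chainsA, chainsB, probe, nPoints) else NA_real_
  structure(list(
    chains_a = chainsA, chains_b = chainsB,
    buried_area = ba,
    hbonds = uniq,
    hbond_count_total = total,
    hydrophobic_cluster = cluster,
    doubling_applied = doubling,
    params = list(cutoff = cutoff, probe = probe, n_points = nPoints,
                  hydrophobic_cutoff = hydrophobicCutoff)
  ), class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("Interface %s | %s\n", paste(x$chains_a, collapse = ","),
              paste(x$chains_b, collapse = ",")))
  if (!is.na(x$buried_area))
    cat(sprintf("  buried area: %.0f A^2 (probe %.1f A)\n",
                x$buried_area, x$params$probe))
  cat(sprintf("  H-bonds: %d unique pair(s), total %d%s\n",
              nrow(x$hbonds), x$hbond_count_total,
              if (x$doubling_applied) " after symmetry doubling" else ""))
  if (nrow(x$hbonds))
    for (i in seq_len(nrow(x$hbonds)))
      cat(sprintf("    %s  %.2f A\n", x$hbonds$label[i], x$hbonds$metric[i]))
  cat("  hydrophobic cluster:", paste(x$hydrophobic_cluster, collapse = " + "), "\n")
  invisible(x)
}
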