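# Rigid-body superposition (Kabsch), least-squares ring planes, and the
# chromophore-geometry measurements built on them.

# optimal rotation/translation mapping mobile onto reference (both n x 3)
.kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.numeric(cr - R %*% cm)
  fitted <- sweep(P %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

.applyTransform <- function(xyz, rotation, translation)
  sweep(xyz %*% t(rotation), 2, translation, "+")

# pair fit-selection atoms 1:1 across two structures by (res_seq, name);
# chromophore atom-name aliases are normalized first so CRO naming variants
# pair up
.pairSelections <- function(mobile, reference, fitSelection) {
  canon <- function(s, idx) {
    a <- s@atoms
    nm <- a$name[idx]
    alias <- .CRO_ALIASES[nm]
    nm[!is.na(alias)] <- alias[!is.na(alias)]
    paste(a$res_seq[idx], nm)
  }
  if (is.list(fitSelection)) {
    im <- fitSelection$mobile; ir <- fitSelection$reference
  } else {
    im <- fitSelection; ir <- fitSelection
  }
  km <- canon(mobile, im); kr <- canon(reference, ir)
  shared <- intersect(km, kr)
  if (!length(shared)) stop("no atoms pair up between the two selections")
  missM <- setdiff(kr, km); missR <- setdiff(km, kr)
  if (length(missM) || length(missR))
    message("superpose: dropping unpaired atoms (",
            length(missM) + length(missR), ")")
  list(mobile = im[match(shared, km)], reference = ir[match(shared, kr)])
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Fits \code{mobile} onto \code{reference} over a selection paired 1:1 by
#' (residue number, atom name).  Returns the optimal rotation (det +1),
#' translation and the RMSD over the fit atoms.
#'
#' @param mobile,reference [FPStructure-class] objects.
#' @param fitSelection integer atom indices used in both structures, or a
#'   list \code{list(mobile =, reference =)} of per-structure indices.
#'   Default: all C-alpha atoms.
#' @return an object of class \code{"Superposition"}: list with
#'   \code{rotation} (3x3), \code{translation} (length 3, Angstrom),
#'   \code{rmsd} (Angstrom), \code{n_fit_atoms}.
#' @examples
#' toy <- toyShellStructure()$structure
#' sup <- superpose(toy, toy)
#' sup$rmsd   # 0
#' @export
superpose <- function(mobile, reference,
                      fitSelection = selectAtoms(mobile, atomNames = "CA")) {
  stopifnot(is(mobile, "FPStructure"), is(reference, "FPStructure"))
  pr <- .pairSelections(mobile, reference, fitSelection)
  if (length(pr$mobile) < 3L) stop("need at least 3 paired atoms to fit")
  M <- coords(mobile)[pr$mobile, , drop = FALSE]
  Rf <- coords(reference)[pr$reference, , drop = FALSE]
  # collinearity check: rank of the centred reference coordinates
  sv <- svd(sweep(Rf, 2, colMeans(Rf)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate geometry: fit atoms are collinear")
  k <- .kabsch(M, Rf)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, n_fit_atoms = length(pr$mobile)),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: rmsd %.3f A\n",
              x$n_fit_atoms, x$rmsd))
  invisible(x)
}

#' Displacement of a probe atom after superposition
#'
#' Superposes \code{mobile} onto \code{reference} over \code{fitSelection}
#' (default: shared C-alpha atoms) and returns the Euclidean distance
#' between the probe atom's fitted position and its reference position.
#' Used e.g. to quantify the shift of the chromophore hydroxyl between a
#' mutant and its precursor after a whole-monomer backbone fit.
#'
#' @param mobile,reference [FPStructure-class] objects.
#' @param probeAtom list \code{list(mobile = i, reference = j)} of atom
#'   indices, or a single index valid in both.
#' @param fitSelection as in [superpose()].
#' @return displacement in Angstroms.
#' @export
atomShift <- function(mobile, reference, probeAtom,
                      fitSelection = selectAtoms(mobile, atomNames = "CA")) {
  if (!is.list(probeAtom)) probeAtom <- list(mobile = probeAtom,
                                             reference = probeAtom)
  if (is.na(probeAtom$mobile) || is.na(probeAtom$reference) ||
      !length(probeAtom$mobile) || !length(probeAtom$reference))
    stop("probe atom not found in one of the structures")
  sup <- superpose(mobile, reference, fitSelection)
  pm <- .applyTransform(coords(mobile)[probeAtom$mobile, , drop = FALSE],
                        sup$rotation, sup$translation)
  pr <- coords(reference)[probeAtom$reference, , drop = FALSE]
  sqrt(sum((pm - pr)^2))
}

#' Least-squares plane through a set of atoms
#'
#' Centroid plus the smallest principal direction of the centred
#' coordinates.  The normal's hemisphere is arbitrary; [planeAngle()] uses
#' the acute-angle convention so this does not matter downstream.
#'
#' @param xyz n-by-3 coordinate matrix (n >= 3, non-collinear), or an
#'   [FPStructure-class] with \code{idx} giving the atom indices.
#' @param idx atom indices when \code{xyz} is a structure.
#' @return an object of class \code{"RingPlane"}: list with \code{centroid},
#'   unit \code{normal}, and \code{planarity_rms} (Angstrom, RMS
#'   out-of-plane deviation).
#' @examples
#' hexagon <- cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6), 0)
#' ringPlane(hexagon)$normal   # (0, 0, +-1)
#' @export
ringPlane <- function(xyz, idx = NULL) {
  if (is(xyz, "FPStructure")) {
    stopifnot(!is.null(idx))
    xyz <- coords(xyz)[idx, , drop = FALSE]
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop("need at least 3 atoms for a plane")
  centroid <- colMeans(xyz)
  C <- sweep(xyz, 2, centroid)
  s <- svd(C)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate geometry: atoms are collinear")
  normal <- s$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  structure(list(centroid = centroid, normal = normal,
                 planarity_rms = sqrt(mean((C %*% normal)^2))),
            class = "RingPlane")
}

#' @export
print.RingPlane <- function(x, ...) {
  cat(sprintf("RingPlane: centroid (%.2f, %.2f, %.2f), planarity rms %.3f A\n",
              x$centroid[1], x$centroid[2], x$centroid[3], x$planarity_rms))
  invisible(x)
}

#' Acute angle between two planes
#'
#' @param p,q \code{"RingPlane"} objects (see [ringPlane()]).
#' @return angle in degrees, in [0, 90].
#' @export
planeAngle <- function(p, q) {
  cosang <- abs(sum(p$normal * q$normal))
  acos(min(1, cosang)) * 180 / pi
}

# angle between two vectors in degrees, [0, 180]
.vectorAngle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Minimum distance between two named atom sets
#'
#' The paper-style "side chain to hydroxyl" measurement: minimum pairwise
#' distance between atom set A of residue A and atom set B of residue B.
#' The histidine default is \{ND1, NE2\} (the paper names no atom), probed
#' against the chromophore hydroxyl.
#'
#' @param x an [FPStructure-class].
#' @param chainA,resA,atomsA first residue: chain, residue number, atom
#'   names.
#' @param chainB,resB,atomsB second residue.
#' @return minimum distance in Angstroms.
#' @export
minSidechainDistance <- function(x, chainA, resA, atomsA = c("ND1", "NE2"),
                                 chainB, resB, atomsB = "OH") {
  ia <- selectAtoms(x, chain = chainA, resSeq = resA, atomNames = atomsA)
  ib <- selectAtoms(x, chain = chainB, resSeq = resB, atomNames = atomsB)
  if (!length(ia)) stop("no atoms ", paste(atomsA, collapse = "/"),
                        " in residue ", chainA, resA)
  if (!length(ib)) stop("no atoms ", paste(atomsB, collapse = "/"),
                        " in residue ", chainB, resB)
  min(.pairDistMatrix(coords(x)[ia, , drop = FALSE],
                      coords(x)[ib, , drop = FALSE]))
}
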