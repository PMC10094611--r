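# Geometric interaction detectors around the chromophore.  All static-mode
# criteria are heavy-atom based: deposited crystal structures carry no
# hydrogens, so donor/acceptor capability comes from a lookup table and no
# donor-angle term is applied (documented limitation).

.pairDistMatrix <- function(A, B) {
  # dense Euclidean distance matrix between two coordinate sets
  out <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) out <- out + outer(A[, k], B[, k], "-")^2
  sqrt(out)
}

.resLabel <- function(a, idx)
  paste0(a$res_name[idx], a$chain_id[idx], a$res_seq[idx])

# TRUE where a pair must be excluded from H-bonding: same residue, or
# backbone atoms of sequence-adjacent residues on one chain (covalent link
# and 1-3 neighbours across the peptide bond; the chromophore's N1/O3
# termini behave as backbone at its splice points)
.excludedPair <- function(a, i, j) {
  sameRes <- a$chain_id[i] == a$chain_id[j] & a$res_seq[i] == a$res_seq[j] &
    a$i_code[i] == a$i_code[j]
  bb <- c("N", "O", "C", "OXT", "N1", "O3", "C3", "CA")
  adj <- a$chain_id[i] == a$chain_id[j] &
    abs(a$res_seq[i] - a$res_seq[j]) == 1L &
    a$name[i] %in% bb & a$name[j] %in% bb
  sameRes | adj
}

.emptyContacts <- function() {
  data.frame(kind = character(0),
             chain_a = character(0), res_seq_a = integer(0),
             res_name_a = character(0), atom_a = character(0),
             chain_b = character(0), res_seq_b = integer(0),
             res_name_b = character(0), atom_b = character(0),
             metric = numeric(0), donor_side = character(0),
             water_res_seq = integer(0), stringsAsFactors = FALSE)
}

.contactRows <- function(a, i, j, d, kind, donorSide = NA_character_,
                         waterRes = NA_integer_) {
  data.frame(kind = kind,
             chain_a = a$chain_id[i], res_seq_a = a$res_seq[i],
             res_name_a = a$res_name[i], atom_a = a$name[i],
             chain_b = a$chain_id[j], res_seq_b = a$res_seq[j],
             res_name_b = a$res_name[j], atom_b = a$name[j],
             metric = d, donor_side = donorSide,
             water_res_seq = waterRes, stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds between two atom selections
#'
#' Heavy-atom geometric criterion: one record per donor/acceptor pair with
#' distance at or below \code{cutoff}, where donor and acceptor capability is
#' taken from the polar-atom table (backbone N donates, backbone O accepts,
#' hydroxyls/His ring nitrogens/waters are ambivalent).  Covalently bonded
#' and same-residue pairs are excluded.  Records are sorted by distance.
#'
#' @param x an [FPStructure-class].
#' @param selA,selB integer atom indices (see [selectAtoms()]).
#' @param cutoff donor-acceptor distance cutoff in Angstroms (default 3.3,
#'   the conventional chromophore-shell criterion).
#' @param includeWeak treat S of Cys/Met as a weak acceptor.
#' @return data.frame of contact records (columns \code{kind}, partner
#'   chain/residue/atom fields, \code{metric} in Angstroms,
#'   \code{donor_side} "a"/"b" when capability makes the direction
#'   unambiguous, else NA).
#' @examples
#' toy <- toyShellStructure()
#' chrom <- identifyChromophore(toy$structure, "A")
#' hb <- findHBonds(toy$structure, chromophoreAtoms(chrom),
#'                  selectAtoms(toy$structure, water = FALSE))
#' @export
findHBonds <- function(x, selA, selB, cutoff = 3.3, includeWeak = FALSE) {
  stopifnot(is(x, "FPStructure"), cutoff > 0)
  if (!length(selA) || !length(selB)) stop("empty selection")
  a <- x@atoms
  pol <- .polarClass(a, includeWeak = includeWeak)
  pa <- selA[pol[selA] != ""]
  pb <- selB[pol[selB] != ""]
  if (!length(pa) || !length(pb)) {
    warning("no polar atoms in selection; returning no H-bonds")
    return(.emptyContacts())
  }
  D <- .pairDistMatrix(as.matrix(a[pa, c("x", "y", "z")]),
                       as.matrix(a[pb, c("x", "y", "z")]))
  hit <- which(D <= cutoff & D > 0, arr.ind = TRUE)
  if (!nrow(hit)) return(.emptyContacts())
  i <- pa[hit[, 1]]; j <- pb[hit[, 2]]
  canDon <- function(k) pol[k] %in% c("D", "B")
  canAcc <- function(k) pol[k] %in% c("A", "B")
  ok <- (canDon(i) & canAcc(j)) | (canAcc(i) & canDon(j))
  ok <- ok & !.excludedPair(a, i, j)
  i <- i[ok]; j <- j[ok]; d <- D[hit][ok]
  if (!length(i)) return(.emptyContacts())
  # de-duplicate unordered pairs (selections may overlap)
  key <- paste(pmin(i, j), pmax(i, j))
  keep <- !duplicated(key)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  donorSide <- ifelse(canDon(i) & !canAcc(i), "a",
               ifelse(canDon(j) & !canAcc(j), "b",
               ifelse(canAcc(i) & !canDon(i), "b",
               ifelse(canAcc(j) & !canDon(j), "a", NA_character_))))
  out <- .contactRows(a, i, j, d, "hbond", donorSide)
  out[order(out$metric), , drop = FALSE]
}

#' Detect water-mediated hydrogen bonds to the chromophore
#'
#' Finds every (chromophore polar atom, water oxygen, residue polar atom)
#' bridge where both legs satisfy the H-bond distance criterion.
#'
#' @param x an [FPStructure-class] with waters (residue name HOH).
#' @param chrom a [Chromophore-class].
#' @param cutoff leg distance cutoff in Angstroms.
#' @return data.frame of contact records (\code{kind} "water_mediated";
#'   partner a = chromophore atom, partner b = bridged residue atom;
#'   \code{metric} = chromophore-water leg + water-residue leg summed;
#'   \code{water_res_seq} identifies the bridging water).
#' @export
findWaterMediated <- function(x, chrom, cutoff = 3.3) {
  stopifnot(is(x, "FPStructure"), is(chrom, "Chromophore"), cutoff > 0)
  a <- x@atoms
  pol <- .polarClass(a)
  chromIdx <- which(a$chain_id == chrom@chain & a$res_seq == chrom@resSeq)
  chromPolar <- chromIdx[pol[chromIdx] != ""]
  waterO <- which(a$res_name == "HOH" & toupper(trimws(a$element)) == "O")
  resPolar <- which(pol != "" & a$res_name != "HOH" &
                      !(a$chain_id == chrom@chain & a$res_seq == chrom@resSeq))
  if (!length(waterO) || !length(chromPolar)) return(.emptyContacts())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  leg1 <- .pairDistMatrix(xyz[chromPolar, , drop = FALSE],
                          xyz[waterO, , drop = FALSE])
  leg2 <- .pairDistMatrix(xyz[waterO, , drop = FALSE],
                          xyz[resPolar, , drop = FALSE])
  recs <- .emptyContacts()
  for (w in seq_along(waterO)) {
    ci <- which(leg1[, w] <= cutoff)
    rj <- which(leg2[w, ] <= cutoff)
    if (!length(ci) || !length(rj)) next
    for (ii in ci) for (jj in rj) {
      i <- chromPolar[ii]; j <- resPolar[jj]
      if (.excludedPair(a, i, j)) next
      recs <- rbind(recs, .contactRows(a, i, j, leg1[ii, w] + leg2[w, jj],
                                       "water_mediated",
                                       waterRes = a$res_seq[waterO[w]]))
    }
  }
  if (nrow(recs)) recs <- recs[order(recs$metric), , drop = FALSE]
  recs
}

#' Detect hydrophobic contacts to the chromophore
#'
#' Apolar-carbon pairs (chromophore carbon vs residue carbon not bonded to
#' N/O) within \code{cutoff}, aggregated per residue: one record per
#' contacting residue with \code{metric} the minimum pair distance and
#' \code{n_pairs} the number of qualifying pairs.
#'
#' @param x an [FPStructure-class].
#' @param chrom a [Chromophore-class].
#' @param cutoff apolar carbon-carbon distance cutoff in Angstroms (default
#'   4.0, a conventional van der Waals contact distance).
#' @return data.frame with columns \code{kind}, residue fields, \code{metric},
#'   \code{n_pairs}.
#' @export
findHydrophobic <- function(x, chrom, cutoff = 4.0) {
  stopifnot(is(x, "FPStructure"), is(chrom, "Chromophore"), cutoff > 0)
  a <- x@atoms
  apol <- .isApolarCarbon(a)
  chromIdx <- which(a$chain_id == chrom@chain & a$res_seq == chrom@resSeq & apol)
  otherIdx <- which(apol & !(a$chain_id == chrom@chain & a$res_seq == chrom@resSeq))
  if (!length(chromIdx) || !length(otherIdx))
    return(cbind(.emptyContacts(), n_pairs = integer(0)))
  D <- .pairDistMatrix(as.matrix(a[chromIdx, c("x", "y", "z")]),
                       as.matrix(a[otherIdx, c("x", "y", "z")]))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(cbind(.emptyContacts(), n_pairs = integer(0)))
  j <- otherIdx[hit[, 2]]
  resKey <- paste(a$chain_id[j], a$res_seq[j])
  out <- do.call(rbind, lapply(split(seq_len(nrow(hit)), resKey), function(rows) {
    dmin <- min(D[hit[rows, , drop = FALSE]])
    r <- rows[which.min(D[hit[rows, , drop = FALSE]])]
    cbind(.contactRows(a, chromIdx[hit[r, 1]], j[r], dmin, "hydrophobic"),
          n_pairs = length(rows))
  }))
  rownames(out) <- NULL
  out[order(out$metric), , drop = FALSE]
}

#' Census of the chromophore's nearest residue shell
#'
#' Lists every residue (waters and the chromophore itself excluded) with any
#' heavy atom within \code{radius} of any chromophore heavy atom, and
#' classifies shell members as direct H-bond partners, water-mediated
#' partners, and hydrophobic contacts using the three detectors.  A residue
#' may carry more than one class; members matching no class are reported as
#' unclassified rather than being forced into one.
#'
#' For the chromophore's covalent neighbours (the preceding and following
#' residues in chain), the backbone atoms forming or flanking the splice
#' (C, O of the predecessor; N of the successor) are ignored when testing
#' shell membership, so these residues enter the shell only through
#' genuinely non-bonded proximity; the rule applied is recorded in the
#' report.
#'
#' @param x an [FPStructure-class].
#' @param chrom a [Chromophore-class].
#' @param radius shell radius in Angstroms (default 4.0).
#' @param hbondCutoff H-bond leg cutoff (default 3.3).
#' @param hydrophobicCutoff apolar contact cutoff (default 4.0).
#' @return an object of class \code{"ShellReport"}: a list with
#'   \code{shell_residues} (data.frame chain/res_seq/res_name/min_dist),
#'   \code{direct_hbond}, \code{water_mediated}, \code{hydrophobic},
#'   \code{unclassified} (residue labels), \code{contacts} (all records),
#'   \code{params}.
#' @export
shellCensus <- function(x, chrom, radius = 4.0, hbondCutoff = 3.3,
                        hydrophobicCutoff = 4.0) {
  stopifnot(is(x, "FPStructure"), is(chrom, "Chromophore"), radius > 0)
  a <- x@atoms
  heavy <- toupper(trimws(a$element)) != "H"
  isChrom <- a$chain_id == chrom@chain & a$res_seq == chrom@resSeq
  chromIdx <- which(isChrom & heavy)
  cand <- which(heavy & !isChrom & a$res_name != "HOH")
  # splice-neighbour backbone atoms never count toward shell membership
  pred <- a$chain_id == chrom@chain & a$res_seq == chrom@resSeq - 1L &
    a$name %in% c("C", "O")
  succ <- a$chain_id == chrom@chain & a$res_seq == chrom@resSeq + 1L &
    a$name == "N"
  cand <- cand[!(pred[cand] | succ[cand])]
  shell <- data.frame(chain = character(0), res_seq = integer(0),
                      res_name = character(0), min_dist = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cand)) {
    D <- .pairDistMatrix(as.matrix(a[chromIdx, c("x", "y", "z")]),
                         as.matrix(a[cand, c("x", "y", "z")]))
    dmin <- apply(D, 2, min)
    resKey <- paste(a$chain_id[cand], a$res_seq[cand])
    agg <- tapply(dmin, resKey, min)
    first <- cand[!duplicated(resKey)]
    names(first) <- resKey[!duplicated(resKey)]
    inShell <- names(agg)[agg <= radius]
    if (length(inShell)) {
      fi <- first[inShell]
      shell <- data.frame(chain = a$chain_id[fi], res_seq = a$res_seq[fi],
                          res_name = a$res_name[fi],
                          min_dist = as.numeric(agg[inShell]),
                          stringsAsFactors = FALSE)
      shell <- shell[order(shell$min_dist), , drop = FALSE]
      rownames(shell) <- NULL
    }
  }
  shellKey <- paste(shell$chain, shell$res_seq)
  labelOf <- function(ch, rs, rn) paste0(rn, ch, rs)

  hb <- suppressWarnings(
    findHBonds(x, chromIdx, selectAtoms(x, water = FALSE), cutoff = hbondCutoff))
  hbRes <- unique(paste(hb$chain_b, hb$res_seq_b))
  wm <- findWaterMediated(x, chrom, cutoff = hbondCutoff)
  wmRes <- unique(paste(wm$chain_b, wm$res_seq_b))
  hp <- findHydrophobic(x, chrom, cutoff = hydrophobicCutoff)
  hpRes <- unique(paste(hp$chain_b, hp$res_seq_b))

  sub <- function(keys) {
    k <- intersect(keys, shellKey)
    m <- match(k, shellKey)
    labelOf(shell$chain[m], shell$res_seq[m], shell$res_name[m])
  }
  allLab <- labelOf(shell$chain, shell$res_seq, shell$res_name)
  classified <- unique(c(sub(hbRes), sub(wmRes), sub(hpRes)))
  structure(list(
    shell_residues = shell,
    direct_hbond = sub(hbRes),
    water_mediated = sub(wmRes),
    hydrophobic = sub(hpRes),
    unclassified = setdiff(allLab, classified),
    contacts = list(hbond = hb, water_mediated = wm, hydrophobic = hp),
    params = list(radius = radius, hbond_cutoff = hbondCutoff,
                  hydrophobic_cutoff = hydrophobicCutoff,
                  splice_neighbour_rule = "predecessor C/O and successor N excluded")
  ), class = "ShellReport")
}

#' @export
print.ShellReport <- function(x, ...) {
  cat(sprintf("Chromophore shell census (radius %.1f A)\n", x$params$radius))
  cat(sprintf("  %d shell residues\n", nrow(x$shell_residues)))
  cat(sprintf("  direct H-bond partners (%.1f A): %s\n", x$params$hbond_cutoff,
              paste(x$direct_hbond, collapse = ", ")))
  cat(sprintf("  water-mediated partners: %s\n",
              paste(x$water_mediated, collapse = ", ")))
  cat(sprintf("  hydrophobic (%.1f A): %s\n", x$params$hydrophobic_cutoff,
              paste(x$hydrophobic, collapse = ", ")))
  if (length(x$unclassified))
    cat("  unclassified:", paste(x$unclassified, collapse = ", "), "\n")
  invisible(x)
}

#' Write contact records as TSV
#'
#' One record per line with a reproducibility header (commented lines
#' recording the generating parameters).
#'
#' @param contacts contact data.frame from the detectors.
#' @param file output path.
#' @param params named list echoed into the header.
#' @return invisibly, \code{file}.
#' @export
writeContactsTSV <- function(contacts, file, params = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fpchrom contacts v%s",
                     as.character(utils::packageVersion("fpchrom"))), con)
  for (nm in names(params))
    writeLines(sprintf("# %s = %s", nm, paste(params[[nm]], collapse = " ")), con)
  utils::write.table(contacts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
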