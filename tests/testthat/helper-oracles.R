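# Independent brute-force oracles and small fixture builders.  These
# deliberately use plain double loops over raw coordinates so they share no
# code path with the package's detectors.

atomDist <- function(s, i, j) {
  a <- atoms(s)
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

# exhaustive O(n^2) H-bond enumeration (same capability table, independent
# pair logic); returns sorted "i-j" keys with i < j
bruteHBondPairs <- function(s, selA, selB, cutoff, includeWeak = FALSE) {
  a <- atoms(s)
  pol <- fpchrom:::.polarClass(a, includeWeak = includeWeak)
  bb <- c("N", "O", "C", "OXT", "N1", "O3", "C3", "CA")
  keys <- character(0)
  for (i in selA) for (j in selB) {
    if (i == j) next
    if (pol[i] == "" || pol[j] == "") next
    don_i <- pol[i] %in% c("D", "B"); acc_i <- pol[i] %in% c("A", "B")
    don_j <- pol[j] %in% c("D", "B"); acc_j <- pol[j] %in% c("A", "B")
    if (!((don_i && acc_j) || (acc_i && don_j))) next
    sameRes <- a$chain_id[i] == a$chain_id[j] && a$res_seq[i] == a$res_seq[j] &&
      a$i_code[i] == a$i_code[j]
    adj <- a$chain_id[i] == a$chain_id[j] &&
      abs(a$res_seq[i] - a$res_seq[j]) == 1 &&
      a$name[i] %in% bb && a$name[j] %in% bb
    if (sameRes || adj) next
    if (atomDist(s, i, j) > cutoff) next
    keys <- c(keys, paste(min(i, j), max(i, j)))
  }
  sort(unique(keys))
}

# exhaustive O(n^3) water-bridge enumeration: (chrom polar, water O, residue
# polar) triples with both legs <= cutoff
bruteWaterBridges <- function(s, chrom, cutoff) {
  a <- atoms(s)
  pol <- fpchrom:::.polarClass(a)
  isChrom <- a$chain_id == chrom@chain & a$res_seq == chrom@resSeq
  ci <- which(isChrom & pol != "")
  wi <- which(a$res_name == "HOH" & a$element == "O")
  ri <- which(pol != "" & a$res_name != "HOH" & !isChrom)
  out <- data.frame(chromAtom = integer(0), water = integer(0),
                    resAtom = integer(0))
  for (i in ci) for (w in wi) for (j in ri) {
    if (atomDist(s, i, w) <= cutoff && atomDist(s, w, j) <= cutoff)
      out <- rbind(out, data.frame(chromAtom = i, water = w, resAtom = j))
  }
  out
}

# minimum heavy-atom distance of every non-water residue to the chromophore
bruteShellDistances <- function(s, chrom) {
  a <- atoms(s)
  heavy <- a$element != "H"
  isChrom <- a$chain_id == chrom@chain & a$res_seq == chrom@resSeq
  ci <- which(isChrom & heavy)
  keys <- unique(paste(a$chain_id, a$res_seq)[!isChrom & a$res_name != "HOH"])
  dmin <- numeric(length(keys))
  names(dmin) <- keys
  for (k in keys) {
    ri <- which(paste(a$chain_id, a$res_seq) == k & heavy)
    best <- Inf
    for (i in ri) for (j in ci) best <- min(best, atomDist(s, i, j))
    dmin[k] <- best
  }
  dmin
}

# a two-chain structure with exactly 5 unique cross-chain donor/acceptor
# pair labels at 2.9 A, one of which is self-symmetric (same residue, the
# swapped atom pair on the partner chain) -- the two-fold counting fixture
symmetricDimer <- function() {
  mk <- function(chain, res_seq, res_name, name, x, y) {
    data.frame(name = name, res_name = res_name, chain_id = chain,
               res_seq = res_seq, x = x, y = y, z = 0,
               stringsAsFactors = FALSE)
  }
  newStructure(rbind(
    mk("A", 10, "SER", "OG", 0, 0),   mk("B", 20, "ASN", "OD1", 2.9, 0),
    mk("A", 30, "THR", "OG1", 0, 8),  mk("B", 40, "SER", "OG", 2.9, 8),
    mk("A", 50, "LYS", "NZ", 0, 16),  mk("B", 60, "GLU", "OE1", 2.9, 16),
    mk("A", 70, "TYR", "OH", 0, 24),  mk("B", 80, "ASN", "ND2", 2.9, 24),
    mk("A", 146, "ASN", "ND2", 0, 32), mk("A", 146, "ASN", "OD1", 0, 35.5),
    mk("B", 146, "ASN", "OD1", 2.9, 32), mk("B", 146, "ASN", "ND2", 2.9, 35.5)))
}

# build a static ensemble from a list of coordinate matrices
ensembleFromFrames <- function(topology, frames, dt = 100) {
  co <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (i in seq_along(frames)) co[, , i] <- frames[[i]]
  new("FPEnsemble", topology = topology, coords = co, dt = dt,
      originLabel = "test")
}

neutralCharges <- function()
  readChargeTable(system.file("extdata", "charges_synthetic_neutral.txt",
                              package = "fpchrom"))

anionCharges <- function()
  readChargeTable(system.file("extdata", "charges_synthetic_anion.txt",
                              package = "fpchrom"))
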