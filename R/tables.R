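# Chemistry lookup tables used by the contact detectors and SASA.
# Heavy-atom donor/acceptor capabilities follow common contact-map practice
# for hydrogen-free crystal structures: backbone N donates, backbone O
# accepts, His ND1/NE2 and hydroxyls are ambivalent, waters are ambivalent.

# per-residue polar atoms: D = donor, A = acceptor, B = both (ambivalent),
# W = weak acceptor (S of Cys/Met; off by default)
.SIDECHAIN_POLAR <- list(
  SER = c(OG  = "B"),
  THR = c(OG1 = "B"),
  TYR = c(OH  = "B"),
  CYS = c(SG  = "W"),
  MET = c(SD  = "W"),
  ASN = c(OD1 = "A", ND2 = "D"),
  GLN = c(OE1 = "A", NE2 = "D"),
  ASP = c(OD1 = "A", OD2 = "A"),
  GLU = c(OE1 = "A", OE2 = "A"),
  LYS = c(NZ  = "D"),
  ARG = c(NE  = "D", NH1 = "D", NH2 = "D"),
  HIS = c(ND1 = "B", NE2 = "B"),
  TRP = c(NE1 = "D"),
  HOH = c(O   = "B"),
  # GFP-type chromophore, CRO-style atom naming: N1 backbone-like amine,
  # N2 imine acceptor, N3 ring amide nitrogen, O2 carbonyl, O3 backbone
  # carbonyl, OH phenolic hydroxyl, OG1 when a Thr-derived CB1-OG1 survives.
  CRO = c(N1 = "D", N2 = "A", N3 = "B", O2 = "A", O3 = "A", OH = "B", OG1 = "B")
)

.STD_AA <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

# apolar carbons (not covalently bonded to N or O) per residue; used for
# hydrophobic-contact detection.  Backbone C and CA are never apolar (bonded
# to O and N respectively).
.APOLAR_CARBONS <- list(
  ALA = "CB",
  VAL = c("CB","CG1","CG2"),
  LEU = c("CB","CG","CD1","CD2"),
  ILE = c("CB","CG1","CG2","CD1"),
  PHE = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
  MET = c("CB","CG","CE"),
  PRO = c("CB","CG"),
  TRP = c("CB","CG","CD2","CE3","CZ2","CZ3","CH2"),
  TYR = c("CB","CG","CD1","CD2","CE1","CE2"),
  CYS = "CB",
  GLY = character(0),
  SER = character(0),
  THR = "CG2",
  ASN = "CB",
  ASP = "CB",
  GLN = c("CB","CG"),
  GLU = c("CB","CG"),
  LYS = c("CB","CG","CD"),
  ARG = c("CB","CG"),
  HIS = "CB",
  # chromophore: bridge methine and phenol ring carbons except CZ (bonded to
  # OH); ring carbons of the imidazolinone are all bonded to N or O.
  CRO = c("CB2","CG2","CD1","CD2","CE1","CE2")
)

# van der Waals radii (Angstrom) for SASA; Bondi-style element values.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.VDW_FALLBACK <- 1.70

# chromophore atom-name aliases across deposition dialects (CRO/CR2/GYS...):
# maps observed name -> canonical CRO-style name used internally.
.CRO_ALIASES <- c(
  "OH2" = "OH", "O2'" = "OH",        # phenolic hydroxyl variants
  "CZ'" = "CZ", "C2'" = "CB2",
  "HO"  = "HOH1", "HOH" = "HOH1", "HO2" = "HOH1", "H20" = "HOH1"
)

# chromophore residue names commonly used for GYG/TYG-derived fluorophores
.CRO_RESNAMES <- c("CRO","CR2","CR8","CSY","GYS","CFY","CRQ","CRU","NRQ")

# canonical CRO-style chromophore topology
.CRO_IMIDAZOLINONE <- c("C1", "N2", "N3", "C2", "CA2")
.CRO_BRIDGE        <- c("CA2", "CB2")
.CRO_PHENOL        <- c("CG2", "CD1", "CD2", "CE1", "CE2", "CZ")

.vdwRadius <- function(element) {
  element <- toupper(trimws(element))
  r <- .VDW_RADII[element]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using fallback radius ", .VDW_FALLBACK, " A", call. = FALSE)
    r[unknown] <- .VDW_FALLBACK
  }
  unname(r)
}

# polar capability of every atom in an atom table; returns character vector
# "D"/"A"/"B"/"" per row.  includeWeak turns the S of Cys/Met into acceptors.
.polarClass <- function(a, includeWeak = FALSE) {
  cls <- character(nrow(a))
  std <- a$res_name %in% c(.STD_AA, "HOH") | a$res_name %in% .CRO_RESNAMES
  # backbone of amino-acid residues (and the chromophore's terminal O3/N1
  # handled via the side-chain table)
  isAA <- a$res_name %in% .STD_AA
  cls[isAA & a$name == "N" & a$res_name != "PRO"] <- "D"
  cls[isAA & a$name %in% c("O", "OXT")] <- "A"
  for (i in seq_len(nrow(a))) {
    rn <- a$res_name[i]
    key <- if (rn %in% .CRO_RESNAMES) "CRO" else rn
    tab <- .SIDECHAIN_POLAR[[key]]
    if (is.null(tab)) {
      # unknown hetero residue: generic element rule (O accepts, N ambivalent)
      if (!std[i]) {
        el <- toupper(trimws(a$element[i]))
        if (el == "O") cls[i] <- "A" else if (el == "N") cls[i] <- "B"
      }
      next
    }
    v <- tab[a$name[i]]
    if (!is.na(v)) {
      if (v == "W") { if (includeWeak) cls[i] <- "A" } else cls[i] <- v
    }
  }
  cls
}

# TRUE for atoms classed apolar carbon
.isApolarCarbon <- function(a) {
  out <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    rn <- a$res_name[i]
    key <- if (rn %in% .CRO_RESNAMES) "CRO" else rn
    tab <- .APOLAR_CARBONS[[key]]
    if (is.null(tab)) next
    out[i] <- a$name[i] %in% tab
  }
  out
}
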