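#' Identify the chromophore in a structure
#'
#' Locates the tripeptide-derived chromophore on a chain, either as a single
#' hetero residue with CRO-style atom naming (residue names CRO, CR2, GYS,
#' ...) or, when \code{resSeq} flags the first residue of an uncyclized
#' Gly/Thr-Tyr-Gly triad, by mapping the tyrosine's ring atoms onto the
#' chromophore convention (CG -> CG2, etc.).  Ring membership is assigned by
#' atom-name convention; the function fails rather than guessing when ring
#' atoms are missing.
#'
#' @param x an [FPStructure-class].
#' @param chain chain id to search.
#' @param resSeq optional residue number of the first triad residue when the
#'   chromophore is modelled as three standard residues.
#' @return a [Chromophore-class] whose atom references resolve into
#'   \code{atoms(x)}.
#' @examples
#' toy <- toyShellStructure()
#' chrom <- identifyChromophore(toy$structure, chain = "A")
#' chrom
#' @export
identifyChromophore <- function(x, chain, resSeq = NULL) {
  stopifnot(is(x, "FPStructure"))
  a <- x@atoms
  if (!is.null(resSeq)) return(.chromFromTriad(x, chain, as.integer(resSeq)))
  cand <- which(a$chain_id == chain & a$res_name %in% .CRO_RESNAMES)
  if (!length(cand))
    stop("no chromophore residue (", paste(.CRO_RESNAMES[1:3], collapse = "/"),
         " ...) found on chain ", chain)
  rs <- unique(a$res_seq[cand])
  if (length(rs) > 1L)
    stop("multiple chromophore residues on chain ", chain, ": ",
         paste(rs, collapse = ", "))
  .chromFromNames(x, chain, rs, cand)
}

# resolve CRO-style atom names (with alias normalization) to a Chromophore
.chromFromNames <- function(x, chain, rs, idx) {
  a <- x@atoms
  nm <- a$name[idx]
  alias <- .CRO_ALIASES[nm]
  nm[!is.na(alias)] <- alias[!is.na(alias)]
  find1 <- function(name) idx[match(name, nm)]
  need <- unique(c(.CRO_IMIDAZOLINONE, .CRO_BRIDGE, .CRO_PHENOL, "OH", "O2"))
  missing <- need[is.na(match(need, nm))]
  if (length(missing))
    stop("chromophore at ", chain, rs, " is incomplete; missing atom(s): ",
         paste(missing, collapse = ", "))
  hIdx <- find1("HOH1")
  new("Chromophore",
      chain = chain, resSeq = as.integer(rs), resName = a$res_name[idx[1]],
      imidazolinone = vapply(.CRO_IMIDAZOLINONE, find1, integer(1)),
      bridge = vapply(.CRO_BRIDGE, find1, integer(1)),
      phenolRing = vapply(.CRO_PHENOL, find1, integer(1)),
      oh = find1("OH"),
      cg2 = find1("CG2"), cz = find1("CZ"), carbonylO = find1("O2"),
      hydroxylH = if (is.na(hIdx)) integer(0) else hIdx,
      charges = numeric(0))
}

# map an uncyclized X-Tyr-Gly triad (caller-flagged) onto chromophore roles
.chromFromTriad <- function(x, chain, first) {
  a <- x@atoms
  tyr <- which(a$chain_id == chain & a$res_seq == first + 1L)
  if (!length(tyr) || a$res_name[tyr[1]] != "TYR")
    stop("no TYR at ", chain, first + 1L, "; cannot map triad chromophore")
  nm <- a$name[tyr]
  find1 <- function(name) tyr[match(name, nm)]
  phenNames <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  missing <- c(phenNames, "OH")[is.na(match(c(phenNames, "OH"), nm))]
  if (length(missing))
    stop("triad tyrosine ring incomplete; missing atom(s): ",
         paste(missing, collapse = ", "))
  # uncyclized triad: no imidazolinone exists; the five ring roles are the
  # atoms that would cyclize (Tyr N/CA/C, Gly67 N, and the Tyr carbonyl C is
  # shared) -- for analysis purposes we only support this mapping when those
  # backbone atoms are present.
  g3 <- which(a$chain_id == chain & a$res_seq == first + 2L)
  req <- c(find1("N"), find1("CA"), find1("C"),
           g3[match("N", a$name[g3])], g3[match("CA", a$name[g3])])
  if (anyNA(req))
    stop("triad backbone atoms needed for the imidazolinone mapping are missing")
  oIdx <- find1("O")
  if (is.na(oIdx)) stop("triad tyrosine carbonyl O missing")
  new("Chromophore",
      chain = chain, resSeq = first + 1L, resName = "TYR",
      imidazolinone = as.integer(req),
      bridge = as.integer(c(find1("CB"), find1("CG"))),
      phenolRing = vapply(phenNames, find1, integer(1)),
      oh = find1("OH"),
      cg2 = find1("CG"), cz = find1("CZ"), carbonylO = oIdx,
      hydroxylH = integer(0), charges = numeric(0))
}

#' All heavy-atom indices of the chromophore fragment
#'
#' The fragment used for dipole analysis: imidazolinone ring, aryl-alkene
#' bridge, phenol ring, the imidazolinone carbonyl oxygen and the phenolic
#' hydroxyl oxygen (plus the hydroxyl hydrogen when present and
#' \code{withH = TRUE}).
#'
#' @param chrom a [Chromophore-class].
#' @param withH include the hydroxyl hydrogen if present.
#' @return integer atom indices (unique, sorted).
#' @export
chromophoreAtoms <- function(chrom, withH = TRUE) {
  idx <- c(chrom@imidazolinone, chrom@bridge, chrom@phenolRing,
           chrom@oh, chrom@carbonylO,
           if (withH) chrom@hydroxylH)
  sort(unique(idx))
}

#' Attach partial charges to a chromophore
#'
#' @param chrom a [Chromophore-class].
#' @param charges named numeric vector (atom name -> charge, elementary
#'   charge units), e.g. from [readChargeTable()].
#' @return the chromophore with charges attached.
#' @export
setCharges <- function(chrom, charges) {
  stopifnot(is(chrom, "Chromophore"), is.numeric(charges),
            !is.null(names(charges)))
  chrom@charges <- charges
  chrom
}

#' Read a two-column partial-charge table
#'
#' Plain text, one \code{"atom_name charge_e"} pair per line; lines starting
#' with \code{#} are comments.
#'
#' @param file path.
#' @return named numeric vector of charges.
#' @export
readChargeTable <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed charge-table line: '", lines[bad[1]], "'")
  q <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(q)) stop("non-numeric charge in table")
  names(q) <- vapply(parts, `[`, character(1), 1)
  q
}
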