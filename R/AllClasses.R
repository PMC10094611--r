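#' @import methods
NULL

#' FPStructure: a single-model macromolecular structure
#'
#' Hierarchical atom container (chains, residues, atoms) holding one model of
#' a PDB-format structure.  Coordinates are orthogonal Angstroms as deposited;
#' no symmetry expansion is performed.  Atoms are kept in file order; the
#' alternate-location policy applied at read time is recorded in
#' \code{metadata(x)$alt_loc_policy}.
#'
#' @slot atoms data.frame with one row per atom and columns \code{serial},
#'   \code{name}, \code{alt_loc}, \code{res_name}, \code{chain_id},
#'   \code{res_seq}, \code{i_code}, \code{x}, \code{y}, \code{z},
#'   \code{occupancy}, \code{b_factor}, \code{element}, \code{is_het}.
#' @slot modelId integer MODEL number the atoms came from (1 for single-model
#'   files).
#' @slot metadata free-form list (alt-loc policy, CRYST1 cell if present,
#'   source file).
#'
#' @seealso [readPDB()], [writePDB()], [atoms()], [coords()]
#' @export
setClass("FPStructure",
  representation(atoms = "data.frame", modelId = "integer", metadata = "list"),
  prototype(atoms = data.frame(), modelId = 1L, metadata = list())
)

.ATOM_COLS <- c("serial", "name", "alt_loc", "res_name", "chain_id",
                "res_seq", "i_code", "x", "y", "z", "occupancy",
                "b_factor", "element", "is_het")

setValidity("FPStructure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(TRUE)
  missing_cols <- setdiff(.ATOM_COLS, names(a))
  if (length(missing_cols))
    return(paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    return("non-finite coordinates")
  if (any(!is.na(a$occupancy) & (a$occupancy < 0 | a$occupancy > 1)))
    return("occupancy outside [0, 1]")
  if (any(!nzchar(a$name)))
    return("empty atom name")
  key <- paste(a$chain_id, a$res_seq, a$i_code, a$name, a$alt_loc)
  if (anyDuplicated(key))
    return("duplicate (chain, res_seq, i_code, name, alt_loc) atom key")
  TRUE
})

#' Chromophore: atom bookkeeping for a GFP-type chromophore
#'
#' References (row indices into the parent FPStructure atom table) for the
#' three moieties of the tripeptide-derived chromophore: the imidazolinone
#' five-ring, the aryl-alkene bridge, and the phenolic six-ring with its
#' hydroxyl.  CG2 (the phenol carbon bonded to the bridge) and CZ (the para
#' carbon carrying the hydroxyl) are resolved explicitly because the
#' CG2-to-CZ vector is the reference axis for dipole-orientation analysis.
#' Optional partial charges (elementary-charge units, named by atom name)
#' enable dipole-moment calculations.
#'
#' @slot chain chain identifier of the chromophore residue.
#' @slot resSeq residue sequence number.
#' @slot resName residue name in the file (e.g. "CRO").
#' @slot imidazolinone indices of the 5 imidazolinone ring atoms.
#' @slot bridge indices of the aryl-alkene linkage atoms (CA2, CB2).
#' @slot phenolRing indices of the 6 phenol ring carbons.
#' @slot oh index of the phenolic hydroxyl oxygen.
#' @slot cg2,cz indices of the CG2 and CZ ring carbons (members of
#'   \code{phenolRing}).
#' @slot carbonylO index of the imidazolinone carbonyl oxygen.
#' @slot hydroxylH index of the hydroxyl hydrogen, or \code{integer(0)} when
#'   hydrogens are absent (crystal structures).
#' @slot charges named numeric vector of partial charges (e) keyed by atom
#'   name; may be empty until [setCharges()] is used.
#'
#' @seealso [identifyChromophore()], [dipoleSeries()]
#' @export
setClass("Chromophore",
  representation(chain = "character", resSeq = "integer", resName = "character",
                 imidazolinone = "integer", bridge = "integer",
                 phenolRing = "integer", oh = "integer",
                 cg2 = "integer", cz = "integer", carbonylO = "integer",
                 hydroxylH = "integer", charges = "numeric"),
  prototype(hydroxylH = integer(0), charges = numeric(0))
)

setValidity("Chromophore", function(object) {
  if (length(object@phenolRing) != 6L)
    return("phenol ring must have 6 carbon members")
  if (length(object@imidazolinone) != 5L)
    return("imidazolinone ring must have 5 members")
  if (!(object@cg2 %in% object@phenolRing))
    return("CG2 must be a member of the phenol ring")
  if (!(object@cz %in% object@phenolRing))
    return("CZ must be a member of the phenol ring")
  TRUE
})

#' FPEnsemble: an ordered conformational ensemble over one topology
#'
#' Frames of coordinates (one per ensemble member / trajectory snapshot)
#' sharing a single topology, with a fixed frame spacing \code{dt} in
#' picoseconds.
#'
#' @slot topology an [FPStructure-class] describing every atom.
#' @slot coords numeric array of dimension (n_atoms, 3, n_frames), Angstroms.
#' @slot dt frame spacing in ps (> 0).
#' @slot originLabel free-form provenance label.
#'
#' @seealso [readEnsemble()], [rmsf()], [contactOccupancy()]
#' @export
setClass("FPEnsemble",
  representation(topology = "FPStructure", coords = "array",
                 dt = "numeric", originLabel = "character"),
  prototype(dt = 1, originLabel = "")
)

setValidity("FPEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an (n_atoms, 3, n_frames) array")
  if (d[1] != nrow(object@topology@atoms))
    return(sprintf("frame atom count (%d) != topology atom count (%d)",
                   d[1], nrow(object@topology@atoms)))
  if (!is.finite(object@dt) || object@dt <= 0)
    return("dt must be positive")
  TRUE
})
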