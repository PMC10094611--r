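#' Accessors for structure and ensemble objects
#'
#' @param x an [FPStructure-class] or [FPEnsemble-class] object.
#' @param ... unused.
#' @return \code{atoms()} the atom data.frame; \code{coords()} an
#'   n_atoms-by-3 matrix (structures) or (n_atoms, 3, n_frames) array
#'   (ensembles); \code{nAtoms()}, \code{nFrames()} integer counts;
#'   \code{frameDt()} the frame spacing in ps; \code{chainIds()} the unique
#'   chain identifiers in file order; \code{metadata()} the metadata list.
#' @name accessors
#' @aliases atoms coords nAtoms nFrames frameDt chainIds metadata
#' @examples
#' s <- toyShellStructure()$structure
#' nAtoms(s)
#' head(atoms(s))
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x, ...) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameDt", function(x, ...) standardGeneric("frameDt"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x, ...) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("metadata", function(x, ...) standardGeneric("metadata"))

#' @rdname accessors
#' @export
setMethod("atoms", "FPStructure", function(x, ...) x@atoms)

#' @rdname accessors
#' @export
setMethod("coords", "FPStructure", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
})

#' @rdname accessors
#' @export
setMethod("nAtoms", "FPStructure", function(x, ...) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("chainIds", "FPStructure", function(x, ...) unique(x@atoms$chain_id))

#' @rdname accessors
#' @export
setMethod("metadata", "FPStructure", function(x, ...) x@metadata)

#' @rdname accessors
#' @export
setMethod("atoms", "FPEnsemble", function(x, ...) x@topology@atoms)

#' @rdname accessors
#' @export
setMethod("coords", "FPEnsemble", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setMethod("nAtoms", "FPEnsemble", function(x, ...) dim(x@coords)[1])

#' @rdname accessors
#' @export
setMethod("nFrames", "FPEnsemble", function(x, ...) dim(x@coords)[3])

#' @rdname accessors
#' @export
setMethod("frameDt", "FPEnsemble", function(x, ...) x@dt)

#' Extract a frame of an ensemble as an FPStructure
#'
#' @param x an [FPEnsemble-class].
#' @param i frame index (1-based).
#' @return an [FPStructure-class] with the topology's atom table and frame
#'   \code{i}'s coordinates.
#' @export
frameStructure <- function(x, i) {
  stopifnot(is(x, "FPEnsemble"))
  i <- as.integer(i)
  if (i < 1L || i > nFrames(x))
    stop("frame index ", i, " out of range 1..", nFrames(x))
  s <- x@topology
  s@atoms[, c("x", "y", "z")] <- x@coords[, , i]
  s
}

setMethod("show", "FPStructure", function(object) {
  a <- object@atoms
  resKey <- unique(paste(a$chain_id, a$res_seq, a$i_code))
  cat(sprintf("FPStructure: %d atoms, %d residues, chains [%s], model %d\n",
              nrow(a), length(resKey),
              paste(unique(a$chain_id), collapse = ","), object@modelId))
  nw <- sum(a$res_name == "HOH")
  if (nw) cat(sprintf("  %d water atoms retained\n", nw))
  if (!is.null(object@metadata$alt_loc_policy))
    cat("  alt-loc policy:", object@metadata$alt_loc_policy, "\n")
})

setMethod("show", "Chromophore", function(object) {
  cat(sprintf("Chromophore %s %s%d: imidazolinone(5) + bridge(%d) + phenol(6) + OH\n",
              object@resName, object@chain, object@resSeq, length(object@bridge)))
  cat(sprintf("  hydroxyl H %s; %d partial charges attached\n",
              if (length(object@hydroxylH)) "present" else "absent",
              length(object@charges)))
})

setMethod("show", "FPEnsemble", function(object) {
  d <- dim(object@coords)
  cat(sprintf("FPEnsemble: %d frames x %d atoms, dt = %g ps (%s)\n",
              d[3], d[1], object@dt,
              if (nzchar(object@originLabel)) object@originLabel else "unlabelled"))
})
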