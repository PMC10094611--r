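#' Read a PDB-format structure
#'
#' Parses fixed-column ATOM/HETATM records into an [FPStructure-class].
#' Waters are retained as residues named HOH.  Coordinates are taken verbatim
#' (orthogonal Angstroms); the CRYST1 record, when present, is stored in
#' metadata but not used (no symmetry expansion).  Residue numbering follows
#' the file.
#'
#' Alternate locations: with \code{altLoc = "highest"} (default) only the
#' highest-occupancy conformer of each atom is kept, ties resolved in favour
#' of blank/'A' indicators, so that downstream geometry sees a single
#' conformer; \code{altLoc = "keep"} retains all conformers.
#'
#' @param file path to a PDB file.
#' @param model integer MODEL number to extract, or \code{"all"} to get a
#'   list of structures (one per model).
#' @param altLoc \code{"highest"} or \code{"keep"}.
#' @return an [FPStructure-class], or a list of them when
#'   \code{model = "all"}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(toyShellStructure()$structure, pdb)
#' s <- readPDB(pdb)
#' nAtoms(s)
#' @export
readPDB <- function(file, model = 1L, altLoc = c("highest", "keep")) {
  altLoc <- match.arg(altLoc)
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  .checkPdbRecords(lines)
  nModels <- max(1L, sum(startsWith(lines, "MODEL")))
  cryst1 <- grep("^CRYST1", lines, value = TRUE)

  p <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  if (identical(model, "all")) {
    return(lapply(seq_len(nModels), function(m)
      .bio3dToStructure(p, m, altLoc, file, cryst1)))
  }
  model <- as.integer(model)
  if (model < 1L || model > nModels)
    stop("model ", model, " not found (file has ", nModels, " model(s))")
  .bio3dToStructure(p, model, altLoc, file, cryst1)
}

# minimal fixed-column sanity scan so malformed records fail with a line number
.checkPdbRecords <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  if (!length(idx)) stop("no ATOM/HETATM records found")
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": shorter than coordinate field")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

.bio3dToStructure <- function(p, model, altLoc, file, cryst1) {
  a <- p$atom
  xyz <- p$xyz[model, ]
  n <- nrow(a)
  blank <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    alt_loc = blank(a$alt),
    res_name = as.character(a$resid),
    chain_id = blank(a$chain),
    res_seq = as.integer(a$resno),
    i_code = blank(a$insert),
    x = xyz[seq(1, 3 * n, 3)],
    y = xyz[seq(2, 3 * n, 3)],
    z = xyz[seq(3, 3 * n, 3)],
    occupancy = as.numeric(a$o),
    b_factor = as.numeric(a$b),
    element = blank(a$elesy),
    is_het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  # infer missing element symbols from the atom name (first non-digit char)
  noel <- !nzchar(atoms$element)
  if (any(noel))
    atoms$element[noel] <- substr(gsub("[0-9']", "", atoms$name[noel]), 1, 1)
  if (altLoc == "highest") atoms <- .filterAltLoc(atoms)
  rownames(atoms) <- NULL
  meta <- list(source = file, alt_loc_policy = altLoc)
  if (length(cryst1)) meta$cryst1 <- cryst1[1]
  new("FPStructure", atoms = atoms, modelId = as.integer(model), metadata = meta)
}

# keep the highest-occupancy alternate conformer per atom; ties go to the
# blank/'A' indicator so the choice is deterministic
.filterAltLoc <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code, atoms$name)
  if (!anyDuplicated(key)) return(atoms)
  occ <- ifelse(is.na(atoms$occupancy), 1, atoms$occupancy)
  pref <- match(atoms$alt_loc, c("", LETTERS))      # blank first, then A, B...
  ord <- order(key, -occ, pref)
  keep <- !duplicated(key[ord])
  atoms[sort(seq_len(nrow(atoms))[ord][keep]), , drop = FALSE]
}

#' Write an FPStructure as a PDB file
#'
#' Fields round-trip through [readPDB()] to printed precision (coordinates
#' \%8.3f, occupancy/B \%6.2f).
#'
#' @param x an [FPStructure-class].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writePDB <- function(x, file) {
  stopifnot(is(x, "FPStructure"))
  a <- x@atoms
  na_if_blank <- function(v) ifelse(nzchar(v), v, NA)
  bio3d::write.pdb(
    file = file,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_het, "HETATM", "ATOM"),
    eleno = a$serial, elety = a$name, alt = na_if_blank(a$alt_loc),
    resid = a$res_name, chain = na_if_blank(a$chain_id), resno = a$res_seq,
    insert = na_if_blank(a$i_code),
    o = ifelse(is.na(a$occupancy), 1, a$occupancy), b = a$b_factor,
    elesy = a$element, end = TRUE
  )
  invisible(file)
}

#' Select atom indices by hierarchy fields
#'
#' Convenience selector returning row indices into \code{atoms(x)}.  All
#' arguments are optional filters combined with AND; \code{NULL} means "any".
#'
#' @param x an [FPStructure-class].
#' @param chain chain id(s).
#' @param resSeq residue number(s).
#' @param atomNames atom name(s).
#' @param resName residue name(s).
#' @param element element symbol(s).
#' @param het \code{NA} (any, default), \code{TRUE} (HETATM only) or
#'   \code{FALSE} (ATOM only).
#' @param water \code{NA} (any, default), \code{TRUE}/\code{FALSE} to
#'   keep/drop waters (res_name HOH).
#' @return integer vector of atom row indices.
#' @export
selectAtoms <- function(x, chain = NULL, resSeq = NULL, atomNames = NULL,
                        resName = NULL, element = NULL, het = NA, water = NA) {
  stopifnot(is(x, "FPStructure"))
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))     keep <- keep & a$chain_id %in% chain
  if (!is.null(resSeq))    keep <- keep & a$res_seq %in% resSeq
  if (!is.null(atomNames)) keep <- keep & a$name %in% atomNames
  if (!is.null(resName))   keep <- keep & a$res_name %in% resName
  if (!is.null(element))   keep <- keep & toupper(trimws(a$element)) %in% toupper(element)
  if (!is.na(het))         keep <- keep & (a$is_het == het)
  if (!is.na(water))       keep <- keep & ((a$res_name == "HOH") == water)
  which(keep)
}

#' Read a multi-frame coordinate ensemble
#'
#' Two dialects are supported: multi-MODEL PDB (each MODEL is one frame) and
#' a whitespace-separated per-frame XYZ dialect with a single header line
#' \code{"natoms dt_ps"} followed by \code{natoms} lines of
#' \code{"name x y z"} per frame.
#'
#' @param file path to the ensemble file.
#' @param topology optional [FPStructure-class]; required for XYZ input,
#'   optional for PDB (defaults to the file's own first model).  Frame atom
#'   counts must match the topology.
#' @param format \code{"auto"} (by extension/sniffing), \code{"pdb"} or
#'   \code{"xyz"}.
#' @param dt frame spacing in ps.  For XYZ input, defaults to the header
#'   value; for PDB input it must be supplied (default 100 ps, the
#'   conventional analysis stride).
#' @param originLabel provenance string stored on the ensemble.
#' @return an [FPEnsemble-class]; frames are in file order.
#' @export
readEnsemble <- function(file, topology = NULL, format = c("auto", "pdb", "xyz"),
                         dt = NULL, originLabel = basename(file)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", file, ignore.case = TRUE)) "pdb" else {
      first <- readLines(file, n = 1L)
      if (grepl("^(ATOM|HETATM|MODEL|CRYST1|REMARK|HEADER)", first)) "pdb" else "xyz"
    }
  }
  if (format == "pdb") {
    models <- readPDB(file, model = "all")
    if (is.null(topology)) topology <- models[[1]]
    n <- nAtoms(topology)
    co <- array(NA_real_, dim = c(n, 3, length(models)))
    for (i in seq_along(models)) {
      if (nAtoms(models[[i]]) != n)
        stop("frame ", i, " has ", nAtoms(models[[i]]),
             " atoms; topology has ", n)
      co[, , i] <- coords(models[[i]])
    }
    if (is.null(dt)) dt <- 100
    return(new("FPEnsemble", topology = topology, coords = co,
               dt = as.numeric(dt), originLabel = originLabel))
  }
  # XYZ dialect
  if (is.null(topology)) stop("XYZ ensembles need an explicit topology")
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  natoms <- as.integer(hdr[1])
  hdrDt <- if (length(hdr) >= 2) as.numeric(hdr[2]) else NA_real_
  if (is.na(natoms) || natoms < 1L) stop("bad XYZ header: ", lines[1])
  if (natoms != nAtoms(topology))
    stop("XYZ atom count (", natoms, ") != topology atom count (",
         nAtoms(topology), ")")
  body <- lines[-1]
  if (length(body) %% natoms != 0L)
    stop("truncated XYZ frame: ", length(body), " atom lines is not a ",
         "multiple of ", natoms, " (frame ", length(body) %/% natoms + 1, ")")
  nf <- length(body) %/% natoms
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) stop("malformed XYZ atom line ", bad[1] + 1L)
  m <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:4))), ncol = 3, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric coordinates in XYZ body")
  co <- array(NA_real_, dim = c(natoms, 3, nf))
  for (i in seq_len(nf)) co[, , i] <- m[((i - 1) * natoms + 1):(i * natoms), ]
  if (is.null(dt)) dt <- if (!is.na(hdrDt)) hdrDt else 100
  new("FPEnsemble", topology = topology, coords = co, dt = as.numeric(dt),
      originLabel = originLabel)
}

#' Write an ensemble in the XYZ-per-frame dialect
#'
#' Header line \code{"natoms dt_ps"}, then per frame one \code{"name x y z"}
#' line per atom.  Coordinates are written with enough digits (\%.6f) to
#' round-trip through [readEnsemble()] far below analysis precision.
#'
#' @param e an [FPEnsemble-class].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeEnsembleXYZ <- function(e, file) {
  stopifnot(is(e, "FPEnsemble"))
  nm <- e@topology@atoms$name
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %g", nAtoms(e), e@dt), con)
  for (i in seq_len(nFrames(e))) {
    f <- e@coords[, , i]
    writeLines(sprintf("%s %.6f %.6f %.6f", nm, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(file)
}
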