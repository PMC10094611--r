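# Dynamic observables on conformational ensembles: per-residue RMSF after
# least-squares fitting, contact occupancy/lifetime bookkeeping, and pi-pi
# stacking occupancy.

.trimEquil <- function(e, equilFraction) {
  nf <- nFrames(e)
  drop <- floor(nf * equilFraction)
  if (nf - drop < 2L) stop("fewer than 2 frames after equilibration trimming")
  seq.int(drop + 1L, nf)
}

#' Per-residue RMSF over an ensemble
#'
#' Frames are least-squares fitted (Kabsch) on \code{fitSelection} to the
#' ensemble-average structure (two fitting passes: first to the initial
#' frame, then to the resulting mean).  Per-atom RMSF is
#' sqrt(mean over frames of the squared deviation from the mean position);
#' the per-residue value is the unweighted mean over the atoms in
#' \code{atomScope}.
#'
#' @param e an [FPEnsemble-class].
#' @param fitSelection atom indices for the rigid fit (default: C-alpha
#'   atoms).
#' @param atomScope \code{"sidechain"} (default; side-chain heavy atoms,
#'   falling back to all heavy atoms for glycine-like residues),
#'   \code{"heavy"}, \code{"all"}, or explicit atom indices.
#' @param equilFraction fraction of initial frames discarded as
#'   equilibration (default 0.25: the final 75 percent of frames are
#'   analysed).
#' @return data.frame with one row per residue (\code{chain},
#'   \code{res_seq}, \code{res_name}, \code{rmsf} in Angstroms) and
#'   attributes \code{per_atom} (named per-atom RMSF), \code{fit_selection}
#'   and \code{atom_scope} labels.
#' @examples
#' toy <- toyShellStructure()
#' ens <- makeEnsemble(toy$structure, ensembleSpec(nFrames = 50, seed = 1))
#' prof <- rmsf(ens$ensemble, equilFraction = 0)
#' head(prof)
#' @export
rmsf <- function(e, fitSelection = selectAtoms(e@topology, atomNames = "CA"),
                 atomScope = "sidechain", equilFraction = 0.25) {
  stopifnot(is(e, "FPEnsemble"))
  frames <- .trimEquil(e, equilFraction)
  co <- e@coords[, , frames, drop = FALSE]
  n <- dim(co)[1]; nf <- dim(co)[3]
  if (length(fitSelection) < 3L) stop("need >= 3 fit atoms")
  ref <- co[, , 1]
  for (pass in 1:2) {
    for (i in seq_len(nf)) {
      k <- .kabsch(co[fitSelection, , i, drop = FALSE][, , 1],
                   ref[fitSelection, , drop = FALSE])
      co[, , i] <- .applyTransform(co[, , i], k$rotation, k$translation)
    }
    ref <- apply(co, c(1, 2), mean)
  }
  dev2 <- (co - array(ref, dim = dim(co)))^2
  perAtom <- sqrt(apply(dev2, 1, sum) / nf)

  a <- e@topology@atoms
  heavy <- toupper(trimws(a$element)) != "H"
  bb <- a$name %in% c("N", "CA", "C", "O", "OXT")
  scopeIdx <- if (is.numeric(atomScope)) {
    as.integer(atomScope)
  } else {
    switch(atomScope,
           sidechain = which(heavy & !bb),
           heavy = which(heavy),
           all = seq_len(n),
           stop("unknown atomScope: ", atomScope))
  }
  resKey <- paste(a$chain_id, a$res_seq)
  resKeys <- unique(resKey)
  rows <- lapply(resKeys, function(k) {
    ri <- which(resKey == k)
    sc <- intersect(ri, scopeIdx)
    if (!length(sc) && !is.numeric(atomScope) && atomScope == "sidechain")
      sc <- ri[heavy[ri]]          # glycine fallback: all heavy atoms
    if (!length(sc)) return(NULL)
    data.frame(chain = a$chain_id[ri[1]], res_seq = a$res_seq[ri[1]],
               res_name = a$res_name[ri[1]], rmsf = mean(perAtom[sc]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_atom") <- perAtom
  attr(out, "fit_selection") <- paste0(length(fitSelection), " atoms")
  attr(out, "atom_scope") <- if (is.numeric(atomScope)) "custom" else atomScope
  attr(out, "n_frames_used") <- nf
  out
}

# run-length statistics of a logical presence vector
.lifetimeStats <- function(present, dt) {
  r <- rle(present)
  onRuns <- r$lengths[r$values]
  list(pr_oc = mean(present),
       n_events = length(onRuns),
       mean_lifetime = if (length(onRuns)) mean(onRuns) * dt else NA_real_,
       total_on_frames = sum(onRuns))
}

#' Contact occupancy and lifetime statistics over an ensemble
#'
#' Evaluates each contact criterion in every frame and summarizes the
#' per-frame boolean series: probability of occurrence (PrOc, exact fraction
#' of present frames), number of events (maximal runs of consecutive
#' presence), and mean lifetime (mean run length times the frame spacing).
#' The group-level mean count per frame (average number of simultaneously
#' present contacts) is reported alongside.
#'
#' Criterion: with a hydrogen given, donor-acceptor distance at most
#' \code{distCutoffH} and hydrogen-donor-acceptor angle at most
#' \code{angleMax} degrees; without hydrogens, heavy-atom distance at most
#' \code{distCutoff}.
#'
#' @param e an [FPEnsemble-class].
#' @param contacts data.frame (or list coercible to one) with columns
#'   \code{label}, \code{donor}, \code{acceptor} (atom indices) and optional
#'   \code{hydrogen} (index or NA).
#' @param distCutoff heavy-atom criterion distance, Angstrom (default 3.3).
#' @param distCutoffH donor-acceptor distance when a hydrogen is available
#'   (default 3.5).
#' @param angleMax H-donor-acceptor angle bound in degrees (default 30).
#' @param equilFraction initial fraction of frames discarded (default 0).
#' @return object of class \code{"OccupancySummary"}: list with
#'   \code{series} (per-contact data.frame: label, pr_oc, n_events,
#'   mean_lifetime_ps, total_on_frames), \code{mean_count_per_frame},
#'   \code{presence} (frames x contacts logical matrix), \code{dt}.
#' @export
contactOccupancy <- function(e, contacts, distCutoff = 3.3,
                             distCutoffH = 3.5, angleMax = 30,
                             equilFraction = 0) {
  stopifnot(is(e, "FPEnsemble"))
  contacts <- as.data.frame(contacts)
  if (is.null(contacts$hydrogen)) contacts$hydrogen <- NA_integer_
  n <- nAtoms(e)
  refIdx <- c(contacts$donor, contacts$acceptor,
              contacts$hydrogen[!is.na(contacts$hydrogen)])
  bad <- refIdx[refIdx < 1 | refIdx > n]
  if (length(bad))
    stop("contact criterion references missing atoms: index ",
         paste(unique(bad), collapse = ", "))
  frames <- if (equilFraction > 0) .trimEquil(e, equilFraction) else seq_len(nFrames(e))
  nf <- length(frames)
  presence <- matrix(FALSE, nf, nrow(contacts),
                     dimnames = list(NULL, contacts$label))
  for (ci in seq_len(nrow(contacts))) {
    d <- contacts$donor[ci]; acc <- contacts$acceptor[ci]
    h <- contacts$hydrogen[ci]
    dv <- e@coords[d, , frames] - e@coords[acc, , frames]   # 3 x nf
    dist <- sqrt(colSums(dv^2))
    if (!is.na(h)) {
      hv <- e@coords[h, , frames] - e@coords[d, , frames]
      av <- -dv                                             # donor -> acceptor
      cosang <- colSums(hv * av) / sqrt(colSums(hv^2) * colSums(av^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      presence[, ci] <- dist <= distCutoffH & ang <= angleMax
    } else {
      presence[, ci] <- dist <= distCutoff
    }
  }
  series <- do.call(rbind, lapply(seq_len(nrow(contacts)), function(ci) {
    st <- .lifetimeStats(presence[, ci], e@dt)
    data.frame(label = contacts$label[ci], pr_oc = st$pr_oc,
               n_events = st$n_events, mean_lifetime_ps = st$mean_lifetime,
               total_on_frames = st$total_on_frames, stringsAsFactors = FALSE)
  }))
  structure(list(series = series,
                 mean_count_per_frame = mean(rowSums(presence)),
                 presence = presence, dt = e@dt,
                 params = list(dist_cutoff = distCutoff,
                               dist_cutoff_h = distCutoffH,
                               angle_max = angleMax)),
            class = "OccupancySummary")
}

#' @export
print.OccupancySummary <- function(x, ...) {
  cat(sprintf("Contact occupancy over %d frames (dt %g ps)\n",
              nrow(x$presence), x$dt))
  cat(sprintf("  mean count per frame: %.2f\n", x$mean_count_per_frame))
  print(x$series, row.names = FALSE)
  invisible(x)
}

#' Pi-pi stacking occupancy between two rings
#'
#' Per-frame presence when the ring-centroid distance is at most \code{dMax}
#' and the acute inter-plane angle is at most \code{angleMax}.  A
#' sensitivity report (PrOc at distance cutoffs +-0.5 Angstrom) is attached
#' because stacking criteria are conventional, not physical constants.
#'
#' @param e an [FPEnsemble-class].
#' @param ringA,ringB atom-index vectors of the two rings (>= 3 atoms each).
#' @param dMax centroid-distance cutoff, Angstrom (default 5.5).
#' @param angleMax inter-plane angle cutoff, degrees (default 30).
#' @param equilFraction initial fraction of frames discarded (default 0).
#' @return object of class \code{"OccupancySummary"} with a single series
#'   row and an extra \code{sensitivity} element (PrOc at dMax - 0.5 and
#'   dMax + 0.5).
#' @export
pipiOccupancy <- function(e, ringA, ringB, dMax = 5.5, angleMax = 30,
                          equilFraction = 0) {
  stopifnot(is(e, "FPEnsemble"), length(ringA) >= 3L, length(ringB) >= 3L)
  frames <- if (equilFraction > 0) .trimEquil(e, equilFraction) else seq_len(nFrames(e))
  nf <- length(frames)
  dcen <- numeric(nf); ang <- numeric(nf)
  for (k in seq_len(nf)) {
    f <- e@coords[, , frames[k]]
    pa <- ringPlane(f[ringA, , drop = FALSE])
    pb <- ringPlane(f[ringB, , drop = FALSE])
    dcen[k] <- sqrt(sum((pa$centroid - pb$centroid)^2))
    ang[k] <- planeAngle(pa, pb)
  }
  present <- dcen <= dMax & ang <= angleMax
  st <- .lifetimeStats(present, e@dt)
  series <- data.frame(label = "pi_pi", pr_oc = st$pr_oc,
                       n_events = st$n_events,
                       mean_lifetime_ps = st$mean_lifetime,
                       total_on_frames = st$total_on_frames,
                       stringsAsFactors = FALSE)
  structure(list(series = series,
                 mean_count_per_frame = mean(present),
                 presence = matrix(present, ncol = 1,
                                   dimnames = list(NULL, "pi_pi")),
                 dt = e@dt,
                 sensitivity = c(minus_0.5 = mean(dcen <= dMax - 0.5 & ang <= angleMax),
                                 plus_0.5 = mean(dcen <= dMax + 0.5 & ang <= angleMax)),
                 params = list(d_max = dMax, angle_max = angleMax)),
            class = "OccupancySummary")
}
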