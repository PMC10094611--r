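# Chromophore-fragment dipole moment from partial charges, two-state
# (cis/trans hydroxyl) classification, and the 2D state-density histogram.

.EA_TO_DEBYE <- 4.8032   # 1 e*Angstrom in Debye

#' Per-frame dipole moment of the chromophore fragment
#'
#' For every frame, DM = sum over fragment atoms of q_i (r_i - r_ref),
#' converted by 1 e.Angstrom = 4.8032 D.  The fragment is the imidazolinone
#' ring, aryl-alkene bridge and phenol ring with the carbonyl and hydroxyl
#' oxygens (plus the hydroxyl hydrogen when present and charged).  Because
#' the fragment may carry net charge - making the dipole origin-dependent -
#' the reference point is part of the contract: the default is the
#' fragment's heavy-atom centroid (recomputed per frame) and the choice is
#' recorded on the result.  The orientation angle is measured against the
#' CG2-to-CZ axis of the phenolic ring, in the vector convention [0, 180]
#' degrees.
#'
#' @param e an [FPEnsemble-class].
#' @param chrom a [Chromophore-class] with charges attached (see
#'   [setCharges()]); every fragment atom must have a charge.
#' @param referencePoint \code{"centroid"} (heavy-atom centroid, default) or
#'   a fixed numeric length-3 point in Angstroms.
#' @param equilFraction initial fraction of frames discarded (default 0).
#' @return object of class \code{"DipoleSeries"}: data.frame with one row
#'   per frame (\code{frame}, \code{dm_x}, \code{dm_y}, \code{dm_z},
#'   \code{dm_modulus} in Debye, \code{axis_angle} in degrees) and
#'   attributes \code{reference_point}, \code{net_charge}.
#' @export
dipoleSeries <- function(e, chrom, referencePoint = "centroid",
                         equilFraction = 0) {
  stopifnot(is(e, "FPEnsemble"), is(chrom, "Chromophore"))
  a <- e@topology@atoms
  idx <- chromophoreAtoms(chrom, withH = TRUE)
  nm <- a$name[idx]
  if (!length(chrom@charges)) stop("chromophore has no charges attached")
  q <- chrom@charges[nm]
  missing <- nm[is.na(q)]
  if (length(missing))
    stop("missing partial charge for chromophore atom(s): ",
         paste(unique(missing), collapse = ", "))
  heavyIdx <- chromophoreAtoms(chrom, withH = FALSE)
  heavyPos <- match(heavyIdx, idx)
  frames <- if (equilFraction > 0) .trimEquil(e, equilFraction) else seq_len(nFrames(e))
  nf <- length(frames)
  dm <- matrix(NA_real_, nf, 3)
  axisAngle <- numeric(nf)
  for (k in seq_len(nf)) {
    f <- e@coords[, , frames[k]]
    r <- f[idx, , drop = FALSE]
    rref <- if (identical(referencePoint, "centroid"))
      colMeans(r[heavyPos, , drop = FALSE]) else as.numeric(referencePoint)
    dm[k, ] <- colSums(q * sweep(r, 2, rref)) * .EA_TO_DEBYE
    axis <- f[chrom@cz, ] - f[chrom@cg2, ]
    axisAngle[k] <- .vectorAngle(dm[k, ], axis)
  }
  out <- data.frame(frame = frames, dm_x = dm[, 1], dm_y = dm[, 2],
                    dm_z = dm[, 3],
                    dm_modulus = sqrt(rowSums(dm^2)),
                    axis_angle = axisAngle)
  attr(out, "reference_point") <- if (identical(referencePoint, "centroid"))
    "heavy-atom centroid (per frame)" else paste(referencePoint, collapse = ",")
  attr(out, "net_charge") <- sum(q)
  class(out) <- c("DipoleSeries", "data.frame")
  out
}

#' Classify frames into cis/trans hydroxyl dipole states
#'
#' The phenolic hydroxyl proton sits either trans (major state) or cis
#' (minor state) with respect to the imidazolinone carbonyl oxygen.  The
#' classification uses the orientation of the O-H bond relative to the
#' carbonyl: the angle between the hydroxyl O-to-H vector and the hydroxyl
#' O-to-carbonyl-O vector, binarized at 90 degrees (below: cis, the proton
#' leans toward the carbonyl; above: trans).  Frames cannot be classified
#' without a hydroxyl hydrogen in the topology - there is no silent proxy.
#'
#' @param d a \code{"DipoleSeries"} from [dipoleSeries()].
#' @param e the [FPEnsemble-class] the series came from.
#' @param chrom the [Chromophore-class]; must carry \code{hydroxylH}.
#' @return list of class \code{"DipoleStates"}: \code{series} (the input
#'   with a \code{state} column, \code{"major_trans"}/\code{"minor_cis"})
#'   and \code{summary} (per-state population, mean and sd of modulus and
#'   axis angle).  Populations sum to 1.
#' @export
classifyStates <- function(d, e, chrom) {
  stopifnot(inherits(d, "DipoleSeries"), is(e, "FPEnsemble"),
            is(chrom, "Chromophore"))
  if (!length(chrom@hydroxylH))
    stop("no hydroxyl hydrogen in topology; cis/trans states cannot be ",
         "classified (no proxy is substituted)")
  h <- chrom@hydroxylH; o <- chrom@oh; co <- chrom@carbonylO
  ang <- vapply(d$frame, function(fr) {
    f <- e@coords[, , fr]
    .vectorAngle(f[h, ] - f[o, ], f[co, ] - f[o, ])
  }, numeric(1))
  d$state <- ifelse(ang < 90, "minor_cis", "major_trans")
  summ <- do.call(rbind, lapply(split(d, d$state), function(g) {
    data.frame(state = g$state[1], population = nrow(g) / nrow(d),
               dm_mean = mean(g$dm_modulus), dm_sd = stats::sd(g$dm_modulus),
               angle_mean = mean(g$axis_angle),
               angle_sd = stats::sd(g$axis_angle),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(series = d, summary = summ), class = "DipoleStates")
}

#' @export
print.DipoleStates <- function(x, ...) {
  cat("Dipole-moment states (cis/trans hydroxyl)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' 2D probability density over (dipole modulus, axis angle)
#'
#' Normalized 2D histogram: the density integrates to 1 over the binned
#' domain (sum of density times bin area = 1).
#'
#' @param d a \code{"DipoleSeries"}.
#' @param modBreaks,angleBreaks either a single bin count or explicit,
#'   strictly increasing break vectors; default 40 bins spanning the data.
#' @return object of class \code{"Density2D"}: list with \code{mod_edges},
#'   \code{angle_edges}, \code{density} (matrix, rows = modulus bins),
#'   \code{counts}, \code{n}.
#' @export
density2d <- function(d, modBreaks = 40L, angleBreaks = 40L) {
  stopifnot(inherits(d, "DipoleSeries"), nrow(d) >= 1L)
  mkEdges <- function(v, breaks) {
    if (length(breaks) == 1L) {
      breaks <- as.integer(breaks)
      if (breaks < 1L) stop("degenerate bin specification")
      rng <- range(v)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      seq(rng[1], rng[2], length.out = breaks + 1L)
    } else {
      if (length(breaks) < 2L || any(diff(breaks) <= 0))
        stop("degenerate bin specification: edges must be increasing")
      breaks
    }
  }
  me <- mkEdges(d$dm_modulus, modBreaks)
  ae <- mkEdges(d$axis_angle, angleBreaks)
  mi <- findInterval(d$dm_modulus, me, rightmost.closed = TRUE, all.inside = TRUE)
  ai <- findInterval(d$axis_angle, ae, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(me) - 1L, length(ae) - 1L)
  for (k in seq_len(nrow(d))) counts[mi[k], ai[k]] <- counts[mi[k], ai[k]] + 1L
  area <- outer(diff(me), diff(ae))
  density <- counts / (sum(counts) * area)
  structure(list(mod_edges = me, angle_edges = ae, density = density,
                 counts = counts, n = nrow(d)), class = "Density2D")
}

#' @export
print.Density2D <- function(x, ...) {
  cat(sprintf("Density2D: %d x %d bins over modulus [%.2f, %.2f] D, angle [%.1f, %.1f] deg, n = %d\n",
              nrow(x$density), ncol(x$density),
              min(x$mod_edges), max(x$mod_edges),
              min(x$angle_edges), max(x$angle_edges), x$n))
  invisible(x)
}
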