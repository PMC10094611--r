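# Photophysics arithmetic and the config-driven report runner.

#' Construct a spectral-property record
#'
#' @param name protein name.
#' @param lambdaEx,lambdaEm excitation/emission maxima, nm.
#' @param ec molar extinction coefficient, 1/(M cm) (> 0).
#' @param fqy fluorescence quantum yield, in [0, 1].
#' @param fl fluorescence lifetime, ns (> 0), optional.
#' @return a list of class \code{"SpectralRecord"}.
#' @examples
#' egfp <- spectralRecord("EGFP", 489, 509, ec = 55000, fqy = 0.60, fl = 2.83)
#' @export
spectralRecord <- function(name, lambdaEx = NA, lambdaEm = NA, ec, fqy,
                           fl = NA) {
  stopifnot(ec > 0, fqy >= 0, fqy <= 1, is.na(fl) || fl > 0)
  structure(list(name = name, lambda_ex = lambdaEx, lambda_em = lambdaEm,
                 ec = ec, fqy = fqy, fl = fl), class = "SpectralRecord")
}

#' Relative brightness of a fluorophore vs a reference
#'
#' Brightness is the product of molar extinction coefficient and
#' fluorescence quantum yield; the relative value is
#' 100 * (ec * fqy) / (ec_ref * fqy_ref), reported rounded to integer
#' percent.
#'
#' @param x,reference \code{"SpectralRecord"} objects (see
#'   [spectralRecord()]).
#' @param digits rounding for the reported percentage (default 0).
#' @return percentage (numeric).
#' @examples
#' egfp <- spectralRecord("EGFP", ec = 55000, fqy = 0.60)
#' bruslee <- spectralRecord("BrUSLEE", ec = 86000, fqy = 0.30)
#' relativeBrightness(bruslee, egfp)   # 78
#' @export
relativeBrightness <- function(x, reference, digits = 0) {
  stopifnot(inherits(x, "SpectralRecord"), inherits(reference, "SpectralRecord"))
  denom <- reference$ec * reference$fqy
  if (!is.finite(denom) || denom <= 0)
    stop("reference brightness (ec * fqy) must be positive")
  round(100 * (x$ec * x$fqy) / denom, digits)
}

.reportHeader <- function(params, seed = NULL) {
  c(sprintf("# fpchrom %s", as.character(utils::packageVersion("fpchrom"))),
    if (!is.null(seed)) sprintf("# seed = %s", seed),
    vapply(names(params), function(nm)
      sprintf("# %s = %s", nm, paste(params[[nm]], collapse = " ")),
      character(1)))
}

#' Run a configured set of analyses and write report files
#'
#' Executes the analysis blocks named in \code{config} and writes one TSV or
#' JSON file per block under \code{outDir}, each carrying a reproducibility
#' header (package version, seed, cutoffs).  Re-running with an identical
#' config yields byte-identical file bodies.
#'
#' Recognized blocks:
#' \describe{
#'   \item{shell}{\code{pdb}, \code{chain}, optional \code{radius},
#'     \code{hbond_cutoff} -> shell census TSV.}
#'   \item{interface}{\code{pdb}, \code{chains_a}, \code{chains_b},
#'     optional \code{cutoff}, \code{double}, \code{area} -> JSON report.}
#'   \item{brightness}{\code{ec}, \code{fqy}, \code{ref_ec}, \code{ref_fqy}
#'     -> JSON with the relative-brightness percentage.}
#'   \item{simulate}{\code{n_frames}, optional \code{seed}, \code{sigma} ->
#'     toy ensemble written as topology PDB + XYZ frames + manifest JSON.}
#' }
#'
#' @param config named list of blocks (e.g. parsed from a JSON file with
#'   \code{jsonlite::fromJSON}).
#' @param outDir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return invisibly, character vector of files written.
#' @export
runReport <- function(config, outDir = ".", quiet = FALSE) {
  if (!length(config) || is.null(names(config)) || any(!nzchar(names(config))))
    stop("empty or unnamed config; nothing to run")
  known <- c("shell", "interface", "brightness", "simulate")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  written <- character(0)

  writeTSV <- function(df, path, params, seed = NULL) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.reportHeader(params, seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeJSON <- function(x, path, params, seed = NULL) {
    x$reproducibility <- c(list(
      fpchrom_version = as.character(utils::packageVersion("fpchrom"))),
      if (!is.null(seed)) list(seed = seed), params)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (!is.null(cfg <- config$shell)) {
    say("shell census: ", cfg$pdb, " chain ", cfg$chain)
    s <- readPDB(cfg$pdb)
    chrom <- identifyChromophore(s, cfg$chain)
    radius <- if (is.null(cfg$radius)) 4.0 else cfg$radius
    hcut <- if (is.null(cfg$hbond_cutoff)) 3.3 else cfg$hbond_cutoff
    rep <- shellCensus(s, chrom, radius = radius, hbondCutoff = hcut)
    df <- rep$shell_residues
    df$classes <- vapply(seq_len(nrow(df)), function(i) {
      lab <- paste0(df$res_name[i], df$chain[i], df$res_seq[i])
      paste(c(if (lab %in% rep$direct_hbond) "hbond",
              if (lab %in% rep$water_mediated) "water_mediated",
              if (lab %in% rep$hydrophobic) "hydrophobic"), collapse = ",")
    }, character(1))
    path <- file.path(outDir, "shell.tsv")
    writeTSV(df, path, rep$params)
    written <- c(written, path)
  }

  if (!is.null(cfg <- config$interface)) {
    say("interface: ", cfg$pdb, " ", cfg$chains_a, " vs ", cfg$chains_b)
    s <- readPDB(cfg$pdb)
    rep <- interfaceHBonds(
      s, cfg$chains_a, cfg$chains_b,
      cutoff = if (is.null(cfg$cutoff)) 3.7 else cfg$cutoff,
      doubling = if (is.null(cfg$double)) TRUE else isTRUE(cfg$double),
      computeArea = isTRUE(cfg$area))
    path <- file.path(outDir, "interface.json")
    writeJSON(list(chains_a = rep$chains_a, chains_b = rep$chains_b,
                   buried_area = rep$buried_area,
                   hbond_count_total = rep$hbond_count_total,
                   hbonds = rep$hbonds,
                   hydrophobic_cluster = rep$hydrophobic_cluster,
                   doubling_applied = rep$doubling_applied),
              path, rep$params)
    written <- c(written, path)
  }

  if (!is.null(cfg <- config$brightness)) {
    x <- spectralRecord("query", ec = cfg$ec, fqy = cfg$fqy)
    ref <- spectralRecord("reference", ec = cfg$ref_ec, fqy = cfg$ref_fqy)
    path <- file.path(outDir, "brightness.json")
    writeJSON(list(relative_brightness_percent = relativeBrightness(x, ref)),
              path, cfg)
    written <- c(written, path)
  }

  if (!is.null(cfg <- config$simulate)) {
    seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    sigma <- if (is.null(cfg$sigma)) 0.30 else cfg$sigma
    toy <- toyShellStructure(withHydroxylH = TRUE)
    spec <- ensembleSpec(nFrames = cfg$n_frames, seed = seed, sigma = sigma)
    gen <- makeEnsemble(toy$structure, spec, toy$chromophore)
    p1 <- file.path(outDir, "toy_topology.pdb")
    p2 <- file.path(outDir, "toy_frames.xyz")
    p3 <- file.path(outDir, "toy_manifest.json")
    writePDB(toy$structure, p1)
    writeEnsembleXYZ(gen$ensemble, p2)
    writeJSON(list(seed = seed, n_frames = cfg$n_frames, sigma = sigma,
                   expected_rmsf = sigma * sqrt(3),
                   placements = toy$manifest$placements),
              p3, list())
    written <- c(written, p1, p2, p3)
  }
  say("wrote ", length(written), " file(s)")
  invisible(written)
}
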