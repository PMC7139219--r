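## Simulation-system specification: membrane compositions and lipid counts,
## run-parameter defaults, umbrella-window planning and restraint selection.
## Nothing here executes an MD engine; it produces counts, manifests and
## run-parameter files.

#' Construct a MembraneSpec
#'
#' @param lower,upper named numeric vectors of mole fractions per leaflet,
#'   e.g. \code{c(POPE = 0.8, POPG = 0.2)}; each must sum to 1
#' @param areaPerLipid named nm^2-per-lipid overrides (default LPS = 1.7)
#' @param boxDim optional box dimensions in nm
#' @return a \linkS4class{MembraneSpec}
#' @export
membraneSpec <- function(lower, upper = lower,
                         areaPerLipid = c(LPS = 1.7),
                         boxDim = rep(NA_real_, 3)) {
  toDF <- function(v) data.frame(lipid = names(v), fraction = unname(v),
                                 stringsAsFactors = FALSE)
  new("MembraneSpec", lower = toDF(lower), upper = toDF(upper),
      areaPerLipid = areaPerLipid, boxDim = boxDim)
}

#' Per-leaflet lipid counts for a membrane specification
#'
#' Counts are proportional to the leaflet mole fractions and rounded by the
#' largest-remainder rule so they sum exactly to the leaflet total.
#' Area-occupying lipids with a per-lipid area override (LPS at 1.7 nm^2 by
#' default) are counted as \code{floor(area / areaPerLipid)} instead.
#'
#' @param spec a \linkS4class{MembraneSpec}
#' @param leafletArea leaflet area in nm^2, used with \code{areaPerLipid}
#'   (nm^2 per ordinary phospholipid) to set the leaflet total; alternatively
#'   give \code{nLipids} directly
#' @param nLipids total ordinary lipids per leaflet (overrides area-based
#'   count when given)
#' @param areaPerLipid nm^2 per ordinary phospholipid (default 0.65)
#' @return named list with one integer count vector per leaflet
#' @export
lipidCounts <- function(spec, leafletArea = NULL, nLipids = NULL,
                        areaPerLipid = 0.65) {
  stopifnot(is(spec, "MembraneSpec"))
  if (is.null(nLipids)) {
    .stopifnotScalarPositive(leafletArea, "leafletArea")
    nLipids <- floor(leafletArea / areaPerLipid)
  }
  lapply(stats::setNames(c("lower", "upper"), c("lower", "upper")),
         function(side) {
    lf <- slot(spec, side)
    if (!nrow(lf)) return(integer(0))
    special <- lf$lipid %in% names(spec@areaPerLipid)
    counts <- integer(nrow(lf))
    if (any(special)) {
      if (is.null(leafletArea))
        stop("leafletArea required when the leaflet contains an ",
             "area-per-lipid species", call. = FALSE)
      for (s in which(special))
        counts[s] <- as.integer(floor(
          leafletArea * lf$fraction[s] / sum(lf$fraction[special]) /
            spec@areaPerLipid[[lf$lipid[s]]]))
    }
    ordinary <- which(!special)
    if (length(ordinary)) {
      if (nLipids < 1)
        stop("leaflet area too small for a single lipid", call. = FALSE)
      counts[ordinary] <- .largestRemainder(lf$fraction[ordinary], nLipids)
    }
    stats::setNames(counts, lf$lipid)
  })
}

#' Default run configuration for a simulation stage
#'
#' Production: 20 fs timestep, 323 K, 1 bar, 1.1 nm nonbonded cutoff,
#' neighbour update every 20 steps, thermostat/barostat coupling 1.0/12.0 ps,
#' 0.15 M NaCl. Umbrella sampling runs at 310 K but is otherwise identical.
#' Assembly uses the production settings.
#'
#' @param stage one of "assembly", "production", "umbrella"
#' @param ... named overrides of any \linkS4class{RunConfig} slot
#'   (timestep, temperature, pressure, tauT, tauP, cutoff, nstlist, salt)
#' @return a \linkS4class{RunConfig}
#' @export
defaultRunConfig <- function(stage = c("assembly", "production", "umbrella"),
                             ...) {
  if (!is.character(stage) || !stage[1] %in% c("assembly", "production",
                                               "umbrella"))
    stop("unknown stage: ", stage[1], call. = FALSE)
  stage <- stage[1]
  cfg <- list(timestep = 20, temperature = if (stage == "umbrella") 310
              else 323, pressure = 1, tauT = 1.0, tauP = 12.0,
              cutoff = 1.1, nstlist = 20, salt = 0.15)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown run parameter: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  new("RunConfig", stage = stage, timestep = cfg$timestep,
      temperature = cfg$temperature, pressure = cfg$pressure,
      tauT = cfg$tauT, tauP = cfg$tauP, cutoff = cfg$cutoff,
      nstlist = cfg$nstlist, salt = cfg$salt)
}

#' Write a run configuration in mdp dialect (key = value lines)
#'
#' @param config a \linkS4class{RunConfig}
#' @param path output file
#' @export
writeMDP <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  lines <- c(
    sprintf("; LipoCG %s run parameters", config@stage),
    sprintf("dt                  = %.4f", config@timestep / 1000),  # ps
    "integrator          = md",
    sprintf("nstlist             = %d", as.integer(config@nstlist)),
    "cutoff-scheme       = Verlet",
    sprintf("rvdw                = %.3f", config@cutoff),
    sprintf("rcoulomb            = %.3f", config@cutoff),
    "vdw-modifier        = Potential-shift-verlet",
    "coulomb-modifier    = Potential-shift-verlet",
    "tcoupl              = v-rescale",
    sprintf("ref-t               = %.2f", config@temperature),
    sprintf("tau-t               = %.2f", config@tauT),
    "pcoupl              = parrinello-rahman",
    sprintf("ref-p               = %.2f", config@pressure),
    sprintf("tau-p               = %.2f", config@tauP),
    sprintf("; salt              = %.3f M NaCl", config@salt))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a LipoCG mdp file into a RunConfig
#'
#' Inverse of \code{\link{writeMDP}} for round-trip checking.
#'
#' @param path mdp file written by \code{\link{writeMDP}}
#' @return a \linkS4class{RunConfig}
#' @export
readMDP <- function(path) {
  lines <- readLines(path)
  stage <- sub("^; LipoCG (\\w+) run parameters$", "\\1", lines[1])
  val <- function(key, comment = FALSE) {
    pat <- if (comment) paste0("^; ", key, "\\s*=\\s*") else
      paste0("^", key, "\\s*=\\s*")
    ln <- grep(pat, lines, value = TRUE)[1]
    as.numeric(strsplit(sub(pat, "", ln), "\\s+")[[1]][1])
  }
  defaultRunConfig(stage, timestep = val("dt") * 1000,
                   temperature = val("ref-t"), pressure = val("ref-p"),
                   tauT = val("tau-t"), tauP = val("tau-p"),
                   cutoff = val("rvdw"), nstlist = val("nstlist"),
                   salt = val("salt", comment = TRUE))
}

#' Plan umbrella windows from a pull trace
#'
#' Selects, for every 0.1 nm target along the pulled reaction coordinate,
#' the trace frame whose distance is nearest the target (earlier frame on
#' ties), producing the window manifest for umbrella sampling. Errors when a
#' target has no frame within half a spacing (a gap in the trace).
#'
#' @param pullTrace data.frame with columns distance (nm) and frame
#' @param spacing window spacing in nm (default 0.1)
#' @param forceConstant bias force constant (default 1000 kJ mol^-1 nm^-2)
#' @param temperature sampling temperature (default 310 K)
#' @param range optional reaction-coordinate range c(min, max); defaults to
#'   0 to the maximum traced distance
#' @return an \linkS4class{UmbrellaSetup}; a warning reports window counts
#'   outside the conventional 50-80 band
#' @export
planUmbrellaWindows <- function(pullTrace, spacing = 0.1,
                                forceConstant = 1000, temperature = 310,
                                range = NULL) {
  .stopifnotScalarPositive(spacing, "spacing")
  stopifnot(all(c("distance", "frame") %in% names(pullTrace)))
  if (is.null(range)) range <- c(0, max(pullTrace$distance))
  nW <- floor((range[2] - range[1]) / spacing + 1e-6)
  centers <- range[1] + spacing * (0:nW)
  frames <- integer(length(centers))
  for (w in seq_along(centers)) {
    dev <- abs(pullTrace$distance - centers[w])
    best <- which.min(dev)  # which.min takes the earlier frame on ties
    if (dev[best] > spacing / 2 + 1e-9)
      stop(sprintf("no trace frame within %.3f nm of window target %.3f nm",
                   spacing / 2, centers[w]), call. = FALSE)
    frames[w] <- as.integer(pullTrace$frame[best])
  }
  inRange <- length(centers) >= 50L && length(centers) <= 80L
  if (!inRange)
    warning("window count ", length(centers),
            " is outside the conventional 50-80 band", call. = FALSE)
  new("UmbrellaSetup", forceConstant = forceConstant, spacing = spacing,
      centers = centers, frames = frames, temperature = temperature,
      countInRange = inRange)
}

#' Write / read an umbrella-window manifest
#'
#' Plain-text manifest: window id, center (nm), force constant, source frame.
#'
#' @param setup an \linkS4class{UmbrellaSetup}
#' @param path manifest TSV path
#' @export
writeWindowManifest <- function(setup, path) {
  stopifnot(is(setup, "UmbrellaSetup"))
  df <- data.frame(window = seq_along(setup@centers),
                   center_nm = setup@centers,
                   force_constant = setup@forceConstant,
                   source_frame = setup@frames,
                   temperature_K = setup@temperature)
  utils::write.table(format(df, digits = 12), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowManifest
#' @export
readWindowManifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  centers <- df$center_nm
  n <- length(centers)
  new("UmbrellaSetup", forceConstant = df$force_constant[1],
      spacing = if (n > 1) stats::median(diff(centers)) else NA_real_,
      centers = centers, frames = as.integer(df$source_frame),
      temperature = df$temperature_K[1],
      countInRange = n >= 50L && n <= 80L)
}

#' Select three low-mobility backbone beads forming a restraint triangle
#'
#' Picks, among the backbone beads in the base region of the protein (by
#' default the 20 percent of beads with lowest z), the three with the lowest
#' positional fluctuation whose triangle is non-degenerate; when the lowest
#' three are (near) collinear the next combination by fluctuation sum is
#' taken. These beads receive the position restraints that hold a carrier
#' protein in place during umbrella sampling.
#'
#' @param positions n x 3 matrix of mean backbone bead positions (Angstrom)
#' @param fluctuations per-bead root-mean-square fluctuation (same order)
#' @param baseFraction fraction of lowest-z beads forming the base region
#'   (ignored when baseRegion given)
#' @param baseRegion optional explicit z-range c(zmin, zmax) of the base
#' @param minArea minimum triangle area (Angstrom^2) for non-collinearity
#' @return integer vector of three bead indices (into \code{positions})
#' @export
selectRestraintTriangle <- function(positions, fluctuations,
                                    baseFraction = 0.2, baseRegion = NULL,
                                    minArea = 1.0) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(fluctuations))
  if (is.null(baseRegion)) {
    zcut <- stats::quantile(positions[, 3], baseFraction)
    cand <- which(positions[, 3] <= zcut)
  } else {
    cand <- which(positions[, 3] >= baseRegion[1] &
                  positions[, 3] <= baseRegion[2])
  }
  if (length(cand) < 3L)
    stop("fewer than 3 backbone beads in the base region", call. = FALSE)
  combs <- utils::combn(cand, 3L)
  sums <- colSums(matrix(fluctuations[combs], nrow = 3L))
  ## deterministic order: fluctuation sum, then lexicographic indices
  ord <- order(sums, combs[1, ], combs[2, ], combs[3, ])
  area <- function(idx) {
    a <- positions[idx[2], ] - positions[idx[1], ]
    b <- positions[idx[3], ] - positions[idx[1], ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    sqrt(sum(cr^2)) / 2
  }
  for (cix in ord) {
    idx <- combs[, cix]
    if (area(idx) >= minArea) return(sort(idx))
  }
  stop("all candidate triangles are degenerate (collinear beads)",
       call. = FALSE)
}
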