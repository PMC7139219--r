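## Synthetic-data generators with known ground truth. They emit the same
## formats the analysis modules read, so every estimator can be tested
## without running molecular dynamics. The generators encode only the
## statistical and geometric structure each analysis assumes, not membrane
## physics.

#' Generate a toy lipoprotein structure and sequence
#'
#' Builds a compact helix-bundle-like coarse-grained core whose first
#' residues are present in the sequence but absent from the coordinates, with
#' a lipobox planted so the scan and tether-building paths are exercised.
#' The precursor sequence has the lipobox cysteine at \code{cysPosition};
#' \code{missingNTerminal} linker residues between the cysteine and the
#' first resolved core residue are missing from the coordinates (so the
#' tether builder's linker length resolves to exactly
#' \code{missingNTerminal}).
#'
#' @param nResidues total precursor length
#' @param missingNTerminal unresolved linker residues between cysteine and
#'   core
#' @param cysPosition 1-based position of the lipobox cysteine (>= 4)
#' @param seed RNG seed; identical seeds give identical output
#' @param dir optional directory: writes core.pdb, precursor.fasta and
#'   ground_truth.json
#' @return list: atoms (resolved core), sequence, match (the planted lipobox
#'   match), nLinker, coreStart
#' @export
makeToyStructure <- function(nResidues = 30L, missingNTerminal = 5L,
                             cysPosition = 4L, seed = 1L, dir = NULL) {
  stopifnot(nResidues >= 2L, cysPosition >= 4L, missingNTerminal >= 0L)
  coreStart <- cysPosition + missingNTerminal + 1L
  if (coreStart + 1L > nResidues)
    stop("no room for a resolved core: reduce missingNTerminal",
         call. = FALSE)
  ## alphabet free of lipobox-forming letters, so the planted motif is the
  ## only match
  alphabet <- c("K", "E", "D", "R", "N", "Q", "M", "F", "W", "Y", "H", "P")
  out <- .withSeed(seed, {
    chars <- sample(alphabet, nResidues, replace = TRUE)
    chars[(cysPosition - 3L):cysPosition] <- c("L", "A", "G", "C")
    sequence <- paste(chars, collapse = "")
    nCore <- nResidues - coreStart + 1L
    ## three antiparallel ideal helices side by side
    segs <- split(seq_len(nCore), ceiling(3 * seq_len(nCore) / nCore))
    coords <- matrix(0, nCore, 3)
    for (s in seq_along(segs)) {
      idx <- segs[[s]]
      h <- buildHelix(length(idx))
      xyz <- as.matrix(h[, c("x", "y", "z")])
      if (s %% 2L == 0L) xyz[, 3] <- max(xyz[, 3]) - xyz[, 3]  # antiparallel
      xyz[, 1] <- xyz[, 1] + 9 * (s - 1L)
      coords[idx, ] <- xyz
    }
    coords <- coords + matrix(stats::runif(3 * nCore, -0.2, 0.2), nCore, 3)
    atoms <- data.frame(chain = "A",
                        resno = coreStart - 1L + seq_len(nCore),
                        resname = unname(.AA3[chars[coreStart - 1L +
                                                      seq_len(nCore)]]),
                        elety = "BB",
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        stringsAsFactors = FALSE)
    list(atoms = atoms, sequence = sequence)
  })
  match <- scanLipobox(out$sequence, id = "toy")
  match <- match[match$cys_position == cysPosition, , drop = FALSE]
  res <- list(atoms = out$atoms, sequence = out$sequence, match = match,
              nLinker = missingNTerminal, coreStart = coreStart)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeStructurePDB(out$atoms, file.path(dir, "core.pdb"))
    writeProteinFasta(c(toy = out$sequence),
                      file.path(dir, "precursor.fasta"))
    jsonlite::write_json(
      list(nResidues = nResidues, missingNTerminal = missingNTerminal,
           cysPosition = cysPosition, coreStart = coreStart, seed = seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  }
  res
}

.CLASS_BEADNAME <- c("GL0" = "GL0", "NH3" = "NH3", "PO4" = "PO4",
                     "GL1:2" = "GL1", "Tail" = "C1A")
.CLASS_RESNAME <- c("GL0" = "POPG", "NH3" = "POPE", "PO4" = "POPE",
                    "GL1:2" = "POPG", "Tail" = "POPE")

#' Generate a membrane trajectory with known contact ground truth
#'
#' Builds a planar two-leaflet bead membrane plus a row of protein residues,
#' and places dedicated lipid beads so the 6 Angstrom contact count of each
#' residue equals the requested per-frame ground truth (contact beads sit at
#' 5 Angstrom; everything else is kept beyond 14 Angstrom, so the +/- 0.3
#' Angstrom frame jitter never changes a count).
#'
#' @param groundTruth data.frame with columns resid, class, count: per-frame
#'   contact counts to realise (accumulated counts are count * nFrames)
#' @param nResidues number of protein residues
#' @param resnames optional residue names (three-letter), length nResidues
#' @param nFrames frames to emit
#' @param seed jitter seed
#' @param dir optional directory: writes traj.gro and ground_truth.json
#' @return list: trajectory (\linkS4class{CGTrajectory}), expectedCounts
#'   (residues x classes matrix of accumulated counts)
#' @export
makeMembraneTrajectory <- function(groundTruth, nResidues = 10L,
                                   resnames = NULL, nFrames = 3L,
                                   seed = 1L, dir = NULL) {
  classes <- .LIPID_BEAD_CLASSES
  if (nrow(groundTruth)) {
    if (!all(groundTruth$class %in% classes))
      stop("unknown lipid bead class in ground truth", call. = FALSE)
    if (!all(groundTruth$resid %in% seq_len(nResidues)))
      stop("ground-truth residue outside the protein", call. = FALSE)
    if (any(groundTruth$count < 0) || any(groundTruth$count > 64))
      stop("unrealizable contact request (counts must be in 0..64)",
           call. = FALSE)
  }
  if (is.null(resnames)) resnames <- rep("ALA", nResidues)
  stopifnot(length(resnames) == nResidues)
  boxx <- 20 * (nResidues + 1) + 20
  box <- c(boxx, 100, 90)
  ## protein row, high above the membrane
  prot <- data.frame(name = "BB", resid = seq_len(nResidues),
                     resname = resnames, segment = "protein",
                     class = NA_character_, stringsAsFactors = FALSE)
  protXYZ <- cbind(20 * seq_len(nResidues), 50, 30)
  ## background membrane grid at z = +/- 11
  gx <- seq(4, boxx - 4, by = 8); gy <- seq(4, 96, by = 8)
  bg <- expand.grid(x = gx, y = gy)
  bgClasses <- rep(classes, length.out = 2L * nrow(bg))
  bgXYZ <- rbind(cbind(bg$x, bg$y, 11), cbind(bg$x, bg$y, -11))
  lipid <- data.frame(name = unname(.CLASS_BEADNAME[bgClasses]),
                      resid = nResidues + seq_along(bgClasses),
                      resname = unname(.CLASS_RESNAME[bgClasses]),
                      segment = "lipid", class = bgClasses,
                      stringsAsFactors = FALSE)
  ## dedicated contact beads at 5 Angstrom from their residue bead
  cbXYZ <- NULL; cbMeta <- NULL
  if (nrow(groundTruth)) for (r in seq_len(nrow(groundTruth))) {
    m <- groundTruth$count[r]
    if (m == 0) next
    p <- protXYZ[groundTruth$resid[r], ]
    kseq <- seq_len(m)
    phi <- 2 * pi * (kseq - 0.5) / 64 +
      2 * pi * match(groundTruth$class[r], classes) / 5.3
    u <- cbind(cos(phi) * 0.8, sin(phi) * 0.8, 0.6)
    u <- u / sqrt(rowSums(u^2))
    cbXYZ <- rbind(cbXYZ, sweep(5.0 * u, 2, p, "+"))
    cls <- groundTruth$class[r]
    cbMeta <- rbind(cbMeta, data.frame(
      name = unname(.CLASS_BEADNAME[cls]), resid = 0L,
      resname = unname(.CLASS_RESNAME[cls]), segment = "lipid",
      class = cls, stringsAsFactors = FALSE)[rep(1L, m), ])
  }
  if (!is.null(cbMeta))
    cbMeta$resid <- nResidues + nrow(lipid) + seq_len(nrow(cbMeta))
  atoms <- rbind(prot, lipid, cbMeta)
  base <- rbind(protXYZ, bgXYZ, cbXYZ)
  coords <- .withSeed(seed, lapply(seq_len(nFrames), function(f)
    base + matrix(stats::runif(3 * nrow(base), -0.3, 0.3), nrow(base), 3)))
  traj <- newCGTrajectory(coords, box, atoms)
  expected <- matrix(0L, nResidues, length(classes),
                     dimnames = list(seq_len(nResidues), classes))
  if (nrow(groundTruth)) for (r in seq_len(nrow(groundTruth)))
    expected[groundTruth$resid[r], groundTruth$class[r]] <-
      expected[groundTruth$resid[r], groundTruth$class[r]] +
      as.integer(groundTruth$count[r]) * nFrames
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTrajectoryGRO(traj, file.path(dir, "traj.gro"))
    jsonlite::write_json(list(expectedCounts = expected, seed = seed,
                              nFrames = nFrames),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, expectedCounts = expected)
}

#' Generate umbrella-window samples from a known potential
#'
#' Draws exact independent samples from each window's biased Boltzmann
#' density exp(-(U + w_i)/kT) by rejection against a dominating Gaussian
#' matched to the density's mode (support truncated at +/- 6 bias standard
#' deviations around the window center, where the density is negligible).
#' Because samples are independent, estimator tests are free of
#' autocorrelation confounds. The closed-form unbiased profile is returned
#' for comparison.
#'
#' Potentials: harmonic \code{U = kappa xi^2 / 2}; double well
#' \code{U = a (xi^2 - b^2)^2}; bounded extraction well
#' \code{U = depth (1 - exp(-alpha xi))^2} (minimum at 0, plateau at
#' \code{depth}).
#'
#' @param potential "harmonic", "double_well" or "extraction_well"
#' @param centers window centers (nm)
#' @param forceConstant bias force constant (kJ mol^-1 nm^-2)
#' @param nPerWindow samples per window
#' @param temperature K
#' @param kappa harmonic constant (kJ mol^-1 nm^-2)
#' @param a,b double-well parameters (barrier a b^4 between minima at -b, b)
#' @param depth,alpha extraction-well depth (kJ/mol) and steepness (nm^-1)
#' @param seed RNG seed
#' @param minAcceptance rejection-efficiency floor; below it the generator
#'   errors and suggests a tighter envelope
#' @param dir optional directory: window files + manifest
#'   (\code{\link{writeUmbrellaWindows}}) and ground_truth.json
#' @return list: windows (list of \linkS4class{UmbrellaWindow}), U (the
#'   potential function), analyticG (function: anchored true profile over a
#'   query grid)
#' @export
makeUmbrellaSamples <- function(potential = c("harmonic", "double_well",
                                              "extraction_well"),
                                centers = seq(-1.5, 1.5, by = 0.1),
                                forceConstant = 1000, nPerWindow = 1e4,
                                temperature = 310, kappa = 10, a = 160,
                                b = 0.5, depth = 115, alpha = 3, seed = 1L,
                                minAcceptance = 1e-4, dir = NULL) {
  potential <- match.arg(potential)
  U <- switch(potential,
              harmonic = function(x) 0.5 * kappa * x^2,
              double_well = function(x) a * (x^2 - b^2)^2,
              extraction_well = function(x) depth * (1 - exp(-alpha * x))^2)
  kT <- .kT(temperature)
  sigmaB <- sqrt(kT / forceConstant)
  windows <- .withSeed(seed, lapply(centers, function(cc) {
    logTarget <- function(x) -(U(x) + 0.5 * forceConstant * (x - cc)^2) / kT
    lo <- cc - 6 * sigmaB; hi <- cc + 6 * sigmaB
    grid <- seq(lo, hi, length.out = 1201L)
    lt <- logTarget(grid)
    i0 <- which.max(lt)
    h <- grid[2] - grid[1]
    d2 <- if (i0 > 1L && i0 < length(grid))
      (lt[i0 - 1L] - 2 * lt[i0] + lt[i0 + 1L]) / h^2 else -1 / sigmaB^2
    sLap <- 1 / sqrt(max(-d2, 1e-12))
    s <- min(max(1.3 * sLap, 0.5 * sigmaB), 6 * sigmaB)
    mode <- grid[i0]
    logM <- max(lt - stats::dnorm(grid, mode, s, log = TRUE)) + 1e-3
    got <- numeric(0)
    proposed <- 0
    batch <- max(2L * nPerWindow, 1000L)
    while (length(got) < nPerWindow) {
      x <- stats::rnorm(batch, mode, s)
      proposed <- proposed + batch
      x <- x[x >= lo & x <= hi]
      keep <- log(stats::runif(length(x))) <
        logTarget(x) - stats::dnorm(x, mode, s, log = TRUE) - logM
      got <- c(got, x[keep])
      if (proposed >= nPerWindow / minAcceptance && length(got) < nPerWindow)
        stop("rejection efficiency below ", minAcceptance,
             ": tighten the dominating envelope", call. = FALSE)
    }
    umbrellaWindow(cc, forceConstant, got[seq_len(nPerWindow)], temperature)
  }))
  ## anchor the true profile at the potential minimum over the sampled range
  dense <- seq(min(centers) - 6 * sigmaB, max(centers) + 6 * sigmaB,
               length.out = 4001L)
  U0 <- min(U(dense))
  analyticG <- function(xi) U(xi) - U0
  if (!is.null(dir)) {
    writeUmbrellaWindows(windows, dir)
    jsonlite::write_json(
      list(potential = potential, centers = centers,
           forceConstant = forceConstant, temperature = temperature,
           parameters = switch(potential,
                               harmonic = list(kappa = kappa),
                               double_well = list(a = a, b = b),
                               extraction_well = list(depth = depth,
                                                      alpha = alpha)),
           seed = seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(windows = windows, U = U, analyticG = analyticG)
}

#' Generate a phosphate trajectory over a known membrane height field
#'
#' Scatters phosphate beads on the two leaflet sheets defined by the height
#' field (z of the upper and lower phosphate layers, Angstrom), plus
#' Gaussian noise, so \code{\link{deformationSurface}} must recover the
#' field within half a bin.
#'
#' @param upper,lower constants or functions of (x, y) giving the leaflet
#'   phosphate z (Angstrom); e.g. 11 and -11 for a flat 22 Angstrom bulk
#'   membrane
#' @param nFrames frames to emit
#' @param box box dimensions (Angstrom)
#' @param spacing phosphate grid spacing (Angstrom)
#' @param noise Gaussian positional noise sd (Angstrom)
#' @param seed RNG seed
#' @param dir optional directory: traj.gro + ground_truth.json
#' @return list: trajectory (\linkS4class{CGTrajectory}), truth (list of
#'   evaluated height-field matrices and grid)
#' @export
makeDeformedMembrane <- function(upper = 11, lower = -11, nFrames = 5L,
                                 box = c(200, 200, 140), spacing = 4,
                                 noise = 0.5, seed = 1L, dir = NULL) {
  fUp <- if (is.function(upper)) upper else function(x, y) upper + 0 * x
  fLo <- if (is.function(lower)) lower else function(x, y) lower + 0 * x
  gx <- seq(spacing / 2, box[1] - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, box[2] - spacing / 2, by = spacing)
  g <- expand.grid(x = gx, y = gy)
  zu <- fUp(g$x, g$y); zl <- fLo(g$x, g$y)
  n <- nrow(g)
  atoms <- data.frame(name = "PO4", resid = seq_len(2L * n),
                      resname = rep(c("POPE"), 2L * n), segment = "lipid",
                      class = "PO4", stringsAsFactors = FALSE)
  base <- rbind(cbind(g$x, g$y, zu), cbind(g$x, g$y, zl))
  coords <- .withSeed(seed, lapply(seq_len(nFrames), function(f)
    base + cbind(stats::rnorm(2L * n, 0, noise / 4),
                 stats::rnorm(2L * n, 0, noise / 4),
                 stats::rnorm(2L * n, 0, noise))))
  traj <- newCGTrajectory(coords, box, atoms)
  truth <- list(x = gx, y = gy,
                upper = matrix(zu, length(gx)),
                lower = matrix(zl, length(gx)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTrajectoryGRO(traj, file.path(dir, "traj.gro"))
    jsonlite::write_json(list(maxUpper = max(zu), minLower = min(zl),
                              bulkThickness = stats::median(zu) -
                                stats::median(zl), seed = seed),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, truth = truth)
}
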