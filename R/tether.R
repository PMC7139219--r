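## Reorientation of core domains and construction of N-terminal tethers
## (signal-peptide helix, disordered linker) for the four maturation states.

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

## Martini-style side-chain bead counts per residue type.
.SC_BEADS <- c(GLY = 0L, ALA = 0L, CYS = 1L, VAL = 1L, LEU = 1L, ILE = 1L,
               MET = 1L, PRO = 1L, SER = 1L, THR = 1L, ASN = 1L, GLN = 1L,
               ASP = 1L, GLU = 1L, LYS = 2L, ARG = 2L, HIS = 3L, PHE = 3L,
               TYR = 3L, TRP = 4L)

.BACKBONE_NAMES <- c("BB", "CA")

## Backbone-bead table of an atom data.frame: one row per residue.
.backbone <- function(atoms) {
  bb <- atoms[atoms$elety %in% .BACKBONE_NAMES, , drop = FALSE]
  bb[!duplicated(paste(bb$chain, bb$resno)), , drop = FALSE]
}

#' Reorient a core domain for membrane insertion
#'
#' Applies the rigid-body transform (rotation with determinant +1 plus
#' translation) that places the backbone positions of the first and second
#' residues on the z-axis, with the first residue at lower z than the core
#' centroid. The N terminus then points toward the membrane and the folded
#' core sits above it.
#'
#' @param atoms atom data.frame (chain, resno, resname, elety, x, y, z) with
#'   backbone beads named BB or CA
#' @param tol tolerance below which the first two backbone positions are
#'   considered coincident (degenerate axis)
#' @return the transformed atom data.frame
#' @export
orientStructure <- function(atoms, tol = 1e-6) {
  v <- .validAtoms(atoms)
  if (!isTRUE(v)) stop(v, call. = FALSE)
  bb <- .backbone(atoms)
  if (nrow(bb) < 2L)
    stop("orientation requires at least 2 residues with backbone positions",
         call. = FALSE)
  p1 <- as.numeric(bb[1L, c("x", "y", "z")])
  p2 <- as.numeric(bb[2L, c("x", "y", "z")])
  axis <- p2 - p1
  if (sqrt(sum(axis^2)) < tol)
    stop("first two backbone positions coincide: degenerate axis",
         call. = FALSE)
  R <- .rotationBetween(axis, c(0, 0, 1))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, p1) %*% t(R)
  ## first residue must lie below the core centroid; flip by a proper
  ## rotation (diag(1,-1,-1)) if needed so chirality is preserved
  cz <- mean(xyz[atoms$elety %in% .BACKBONE_NAMES, 3])
  if (cz < 0) xyz <- xyz %*% diag(c(1, -1, -1))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Build an ideal alpha-helix backbone
#'
#' Canonical geometry: 1.5 Angstrom rise and 100 degrees twist per residue,
#' 2.3 Angstrom radius, axis along z (residue 1 at z = 0, subsequent
#' residues above it).
#'
#' @param sequence one-letter residues of the span (length >= 1), or an
#'   integer residue count (residue names then default to ALA)
#' @param startResno residue number of the first residue
#' @param chain chain id
#' @param rise per-residue rise (Angstrom)
#' @param twist per-residue twist (degrees)
#' @param radius helix radius (Angstrom)
#' @return atom data.frame of backbone beads
#' @export
buildHelix <- function(sequence, startResno = 1L, chain = "A",
                       rise = 1.5, twist = 100, radius = 2.3) {
  if (is.numeric(sequence)) {
    n <- as.integer(sequence)
    resnames <- rep("ALA", n)
  } else {
    chars <- .checkResidues(sequence)
    n <- length(chars)
    resnames <- unname(.AA3[chars])
  }
  if (n < 1L) stop("helix span must contain at least one residue",
                   call. = FALSE)
  i <- seq_len(n) - 1L
  theta <- i * twist * pi / 180
  data.frame(chain = chain, resno = startResno + i, resname = resnames,
             elety = "BB",
             x = radius * cos(theta), y = radius * sin(theta),
             z = i * rise, stringsAsFactors = FALSE)
}

## Place n linker beads between two fixed endpoints with seeded jitter and
## push-apart relaxation: all backbone pairs (linker-linker and linker-core)
## must end >= minSep apart, consecutive chain neighbours <= maxBond.
.placeLinker <- function(from, to, n, coreBB, seed = 1L,
                         minSep = 3.0, maxBond = 4.2) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  span <- sqrt(sum((to - from)^2))
  if (span > (n + 1) * maxBond)
    stop("linker span of ", round(span, 1), " A exceeds the reach of ",
         n + 1, " peptide segments", call. = FALSE)
  frac <- seq_len(n) / (n + 1)
  straight <- t(vapply(frac, function(f) from + f * (to - from), numeric(3)))
  chainPts <- function(p) rbind(from, p, to)
  clear <- function(pos) {
    pts <- chainPts(pos)
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    for (a in seq_len(nrow(pts) - 1L)) d[a, a + 1L] <- d[a + 1L, a] <- Inf
    min(d) >= minSep - 1e-6 &&
      (!nrow(coreBB) || min(.pbcDistance(pos, coreBB, NULL)) >=
         minSep - 1e-6)
  }
  ## restart with a growing lateral bow when the straight corridor is
  ## blocked by the core; each attempt re-jitters from the derived seed
  for (attempt in seq_len(25L)) {
    ang <- 2 * pi * (attempt - 1L) / 8
    amp <- 0.9 * (attempt - 1L)
    bow <- amp * sin(pi * frac)
    pos <- straight
    pos[, 1] <- pos[, 1] + bow * cos(ang)
    pos[, 2] <- pos[, 2] + bow * sin(ang)
    jit <- .withSeed(seed + 7919L * (attempt - 1L),
                     matrix(stats::runif(2L * n, -1.5, 1.5), n, 2L))
    pos[, 1] <- pos[, 1] + jit[, 1]
    pos[, 2] <- pos[, 2] + jit[, 2]
    fixed <- rbind(coreBB, from, to)
    for (iter in seq_len(300L)) {
      moved <- FALSE
      ## self-avoidance among linker beads
      if (n > 1L) {
        d <- as.matrix(stats::dist(pos))
        for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
          if (d[a, b] < minSep) {
            dir <- pos[a, ] - pos[b, ]
            nrm <- sqrt(sum(dir^2))
            dir <- if (nrm < 1e-9) c(1, 0, 0) else dir / nrm
            push <- (minSep - d[a, b]) / 2 + 0.05
            pos[a, ] <- pos[a, ] + dir * push
            pos[b, ] <- pos[b, ] - dir * push
            moved <- TRUE
          }
        }
      }
      ## clash avoidance against every nearby fixed bead (core + endpoints)
      dc <- .pbcDistance(pos, fixed, box = NULL)
      for (a in seq_len(n)) {
        for (b in which(dc[a, ] < minSep)) {
          dir <- pos[a, ] - fixed[b, ]
          nrm <- sqrt(sum(dir^2))
          dir <- if (nrm < 1e-9) c(cos(ang), sin(ang), 0) else dir / nrm
          pos[a, ] <- pos[a, ] + dir * (minSep - dc[a, b] + 0.05)
          moved <- TRUE
        }
      }
      ## keep consecutive neighbours within a peptide-bond reach (damped
      ## pull, to avoid oscillating against the pushes above)
      pts <- chainPts(pos)
      for (a in seq_len(nrow(pts) - 1L)) {
        dab <- sqrt(sum((pts[a + 1L, ] - pts[a, ])^2))
        if (dab > maxBond) {
          mid <- (pts[a + 1L, ] + pts[a, ]) / 2
          for (idx in c(a, a + 1L)) {
            li <- idx - 1L  # index into pos (0 = from, n+1 = to)
            if (li >= 1L && li <= n) {
              pos[li, ] <- pos[li, ] + (mid - pos[li, ]) *
                (0.6 * (dab - maxBond) / dab)
              moved <- TRUE
            }
          }
          pts <- chainPts(pos)
        }
      }
      if (!moved) break
    }
    if (clear(pos)) return(pos)
  }
  stop("linker relaxation failed to remove steric clashes", call. = FALSE)
}

#' Build the disordered linker between the cysteine and the core domain
#'
#' Places the anchored cysteine \code{nLinker * perResidueExtension}
#' Angstrom below the first resolved core residue along -z (the disordered
#' length rule of 3.5 Angstrom per missing residue), with the missing
#' residues laid on an extended, self-avoiding path between the two
#' endpoints. With zero missing residues the cysteine sits one peptide-unit
#' spacing (3.5 Angstrom) below the core.
#'
#' @param core oriented core atom data.frame (first residue near the origin)
#' @param nLinker number of residues modelled between the cysteine and the
#'   first resolved core residue
#' @param linkerSeq optional one-letter residues of the linker
#'   (length nLinker)
#' @param cysResno residue number given to the cysteine
#' @param perResidueExtension Angstrom of extension per disordered residue
#' @param seed seed for the jittered self-avoiding placement
#' @return list with elements \code{tether} (atom data.frame: cysteine plus
#'   linker backbone beads) and \code{cysPosition} (xyz of the cysteine BB)
#' @export
buildLinker <- function(core, nLinker, linkerSeq = NULL,
                        cysResno = 1L, perResidueExtension = 3.5,
                        seed = 1L) {
  stopifnot(nLinker >= 0)
  .stopifnotScalarPositive(perResidueExtension, "perResidueExtension")
  bb <- .backbone(core)
  if (!nrow(bb)) stop("core has no backbone beads", call. = FALSE)
  p0 <- as.numeric(bb[1L, c("x", "y", "z")])
  dist <- if (nLinker == 0L) 3.5 else nLinker * perResidueExtension
  cysPos <- p0 - c(0, 0, dist)
  coreBB <- as.matrix(bb[, c("x", "y", "z")])
  linkXYZ <- .placeLinker(cysPos, p0, nLinker, coreBB, seed = seed)
  resnames <- if (is.null(linkerSeq)) rep("GLY", nLinker)
              else unname(.AA3[.checkResidues(linkerSeq)])
  if (length(resnames) != nLinker)
    stop("linkerSeq length must equal nLinker", call. = FALSE)
  tether <- rbind(
    data.frame(chain = bb$chain[1L], resno = cysResno, resname = "CYS",
               elety = "BB", x = cysPos[1], y = cysPos[2], z = cysPos[3],
               stringsAsFactors = FALSE),
    if (nLinker > 0L)
      data.frame(chain = bb$chain[1L], resno = cysResno + seq_len(nLinker),
                 resname = resnames, elety = "BB",
                 x = linkXYZ[, 1], y = linkXYZ[, 2], z = linkXYZ[, 3],
                 stringsAsFactors = FALSE))
  list(tether = tether, cysPosition = cysPos)
}

## Add template side-chain beads to tether backbone beads (radial offsets).
.addSideChains <- function(bbAtoms) {
  out <- list()
  for (r in seq_len(nrow(bbAtoms))) {
    row <- bbAtoms[r, , drop = FALSE]
    out[[length(out) + 1L]] <- row
    nsc <- .SC_BEADS[[row$resname]]
    if (is.null(nsc) || is.na(nsc)) nsc <- 0L
    if (nsc > 0L) {
      radial <- c(row$x, row$y)
      nrm <- sqrt(sum(radial^2))
      dir <- if (nrm < 1e-6) c(1, 0) else radial / nrm
      for (k in seq_len(nsc)) {
        sc <- row
        sc$elety <- paste0("SC", k)
        sc$x <- row$x + dir[1] * (2.0 + 1.2 * k)
        sc$y <- row$y + dir[2] * (2.0 + 1.2 * k)
        out[[length(out) + 1L]] <- sc
      }
    }
  }
  do.call(rbind, out)
}

#' Assemble a maturation-state model from a core structure and lipobox match
#'
#' Composes, per state: SP / SP_DI = signal-peptide helix (residue 1 to the
#' lipobox cysteine, vertical along z) + disordered linker + core;
#' DI / TRI = cysteine + linker + core, with the lipid attachment flag set
#' (diacyl for SP_DI/DI, triacyl for TRI); UNTETHERED = the core alone. A
#' warning is recorded when the linker exceeds 35 residues.
#'
#' @param core core-domain atom data.frame (oriented with
#'   \code{\link{orientStructure}} unless \code{orient = TRUE}, the default,
#'   which applies it here)
#' @param match single lipobox match row (see \code{\link{scanLipobox}})
#' @param state maturation state
#' @param sequence full precursor sequence (one-letter); used for tether
#'   residue names and numbering
#' @param perResidueExtension Angstrom per disordered linker residue
#' @param seed linker placement seed
#' @param orient orient the core first (default TRUE)
#' @return a \linkS4class{LipoproteinModel}
#' @export
assembleState <- function(core, match, state, sequence,
                          perResidueExtension = 3.5, seed = 1L,
                          orient = TRUE) {
  state <- match.arg(state, .MATURATION_STATES)
  if (orient) core <- orientStructure(core)
  if (state == "UNTETHERED") {
    return(new("LipoproteinModel", atoms = core, state = state,
               cysIndex = NA_integer_, anchor = "none",
               tetherResnos = integer(0)))
  }
  .checkResidues(sequence)
  cys <- as.integer(match$cys_position[1])
  bb <- .backbone(core)
  firstCore <- bb$resno[1L]
  nLinker <- firstCore - cys - 1L
  if (nLinker < 0L)
    stop("core residues overlap the modelled tether: core starts at ",
         firstCore, " but the lipobox cysteine is residue ", cys,
         call. = FALSE)
  if (nLinker > 35L)
    warning("linker of ", nLinker, " residues exceeds the 35-residue ",
            "initial-modelling threshold", call. = FALSE)
  linkerSeq <- if (nLinker > 0L) substring(sequence, cys + 1L,
                                           cys + nLinker) else NULL
  lk <- buildLinker(core, nLinker, linkerSeq = linkerSeq, cysResno = cys,
                    perResidueExtension = perResidueExtension, seed = seed)
  tether <- lk$tether
  if (state %in% c("SP", "SP_DI")) {
    spSeq <- substring(sequence, 1L, cys)
    helix <- buildHelix(spSeq, startResno = 1L, chain = bb$chain[1L])
    ## place the helix below the membrane-proximal cysteine: its last
    ## residue (the cysteine) lands on the linker's cysteine anchor
    top <- as.numeric(helix[nrow(helix), c("x", "y", "z")])
    shift <- lk$cysPosition - top
    helix$x <- helix$x + shift[1]
    helix$y <- helix$y + shift[2]
    helix$z <- helix$z + shift[3]
    tether <- rbind(helix, tether[-1L, , drop = FALSE])
  }
  if (any(tether$resno %in% bb$resno))
    stop("core residues overlap the modelled tether residue numbers",
         call. = FALSE)
  tether <- .addSideChains(tether)
  atoms <- rbind(tether, core)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  new("LipoproteinModel", atoms = atoms, state = state,
      cysIndex = cys, anchor = .stateAnchor(state),
      tetherResnos = sort(unique(tether$resno)))
}
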