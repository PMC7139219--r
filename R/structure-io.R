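## Structure and trajectory I/O: PDB (via bio3d) and GRO (GROMACS dialect).
## Coordinates are Angstrom everywhere inside the package; GRO files are
## written/read in nm per the GROMACS convention.

#' Read a structure from a PDB file
#'
#' Thin wrapper around \code{bio3d::read.pdb} returning the package's atom
#' table (author residue numbering preserved).
#'
#' @param path PDB file (ATOM/HETATM records)
#' @return data.frame with columns chain, resno, resname, elety, x, y, z
#' @export
readStructurePDB <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  data.frame(chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             resno = as.integer(a$resno), resname = a$resid,
             elety = a$elety, x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

#' Write a model or atom table to PDB
#'
#' @param x a \linkS4class{LipoproteinModel} or an atom data.frame
#' @param path output file
#' @export
writeStructurePDB <- function(x, path) {
  atoms <- if (is(x, "LipoproteinModel")) atomRecords(x) else x
  v <- .validAtoms(atoms)
  if (!isTRUE(v)) stop(v, call. = FALSE)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain)
  invisible(path)
}

#' Write a model or atom table as a GRO file
#'
#' Coordinates are converted from Angstrom to nm on write.
#'
#' @param x a \linkS4class{LipoproteinModel} or an atom data.frame
#' @param path output file
#' @param box box dimensions in Angstrom (length 3); defaults to the
#'   coordinate extent plus 20 A padding
#' @param title title line
#' @export
writeStructureGRO <- function(x, path, box = NULL, title = "LipoCG model") {
  atoms <- if (is(x, "LipoproteinModel")) atomRecords(x) else x
  v <- .validAtoms(atoms)
  if (!isTRUE(v)) stop(v, call. = FALSE)
  if (is.null(box)) {
    span <- apply(atoms[, c("x", "y", "z")], 2, function(v) diff(range(v)))
    box <- span + 20
  }
  con <- file(path, "w")
  on.exit(close(con))
  .writeGROFrame(con, atoms$resno, atoms$resname, atoms$elety,
                 as.matrix(atoms[, c("x", "y", "z")]), box, title)
  invisible(path)
}

.writeGROFrame <- function(con, resno, resname, name, xyz, box, title) {
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(xyz)), con)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   resno %% 100000L, substr(resname, 1, 5),
                   substr(name, 1, 5),
                   seq_along(resno) %% 100000L,
                   xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                     box[3] / 10), con)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj a \linkS4class{CGTrajectory}
#' @param path output file
#' @export
writeTrajectoryGRO <- function(traj, path) {
  stopifnot(is(traj, "CGTrajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj@atoms
  for (f in seq_along(traj@coords)) {
    box <- traj@box[f, ]
    if (any(!is.finite(box))) {
      span <- apply(traj@coords[[f]], 2, function(v) diff(range(v)))
      box <- span + 20
    }
    .writeGROFrame(con, a$resid, a$resname, a$name, traj@coords[[f]],
                   box, sprintf("frame %d", f))
  }
  invisible(path)
}

#' Read one or more GRO frames into a trajectory
#'
#' All frames must share the same atom list. Coordinates are converted from
#' nm to Angstrom. Bead metadata (protein/lipid segment and lipid bead
#' class) is derived from residue and atom names via
#' \code{\link{classifyLipidBeads}}.
#'
#' @param path GRO file, possibly with several concatenated frames
#' @return a \linkS4class{CGTrajectory}
#' @export
readTrajectoryGRO <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i + 1L]))
    rec <- lines[(i + 2L):(i + 1L + n)]
    resid <- as.integer(substr(rec, 1, 5))
    resname <- trimws(substr(rec, 6, 10))
    name <- trimws(substr(rec, 11, 15))
    xyz <- cbind(as.numeric(substr(rec, 21, 28)),
                 as.numeric(substr(rec, 29, 36)),
                 as.numeric(substr(rec, 37, 44))) * 10
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3] * 10
    if (is.null(atoms)) {
      atoms <- data.frame(name = name, resid = resid, resname = resname,
                          stringsAsFactors = FALSE)
    } else if (nrow(atoms) != n) {
      stop("frames differ in atom count", call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- box
    i <- i + 3L + n
  }
  atoms <- classifyLipidBeads(atoms)
  newCGTrajectory(frames, do.call(rbind, boxes), atoms)
}

.LIPID_RESNAMES <- c("POPE", "POPG", "POPC", "CDL", "CL", "LPS", "DPG")

#' Assign segment and lipid bead class to trajectory atoms
#'
#' Lipid beads are grouped into the five classes used for contact
#' fingerprints: GL0 (POPG glycerol headgroup), NH3 (POPE ethanolamine),
#' PO4 (phosphates), GL1:2 (ester glycerols) and Tail (acyl tail beads).
#'
#' @param atoms data.frame with at least name and resname columns
#' @return the data.frame with segment and class columns added
#' @export
classifyLipidBeads <- function(atoms) {
  isLipid <- atoms$resname %in% .LIPID_RESNAMES
  atoms$segment <- ifelse(isLipid, "lipid", "protein")
  cls <- rep(NA_character_, nrow(atoms))
  nm <- atoms$name
  cls[isLipid & nm == "GL0"] <- "GL0"
  cls[isLipid & nm %in% c("NH3", "NC3")] <- "NH3"
  cls[isLipid & nm == "PO4"] <- "PO4"
  cls[isLipid & nm %in% c("GL1", "GL2")] <- "GL1:2"
  cls[isLipid & grepl("^[CD][0-9][AB]$", nm)] <- "Tail"
  atoms$class <- cls
  atoms
}

#' Construct a CGTrajectory
#'
#' @param coords list of n_atoms x 3 matrices (Angstrom)
#' @param box nFrames x 3 matrix (Angstrom) or a single length-3 vector
#'   recycled over frames
#' @param atoms data.frame with name, resid, resname and optionally segment,
#'   class (filled by \code{\link{classifyLipidBeads}} when absent)
#' @return a \linkS4class{CGTrajectory}
#' @export
newCGTrajectory <- function(coords, box, atoms) {
  if (is.null(dim(box))) box <- matrix(box, nrow = length(coords), ncol = 3,
                                       byrow = TRUE)
  if (!all(c("segment", "class") %in% names(atoms)))
    atoms <- classifyLipidBeads(atoms)
  new("CGTrajectory", coords = lapply(coords, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  }), box = box, atoms = atoms)
}
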