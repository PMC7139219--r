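## Grafting lipid fragments onto cysteine to form the diacyl- and
## triacylcysteine post-translational modifications, and elastic-network
## generation for folded cores.

## Subset a topology to the beads at `keep` (indices into beads), remapping
## bonded terms and discarding any term that references a dropped bead.
.subsetTopology <- function(top, keep) {
  map <- rep(NA_integer_, nrow(top@beads))
  map[keep] <- seq_along(keep)
  remap <- function(df, cols) {
    if (!nrow(df)) return(df)
    idx <- as.matrix(df[, cols, drop = FALSE])
    ok <- apply(idx, 1L, function(r) all(!is.na(map[r])))
    df <- df[ok, , drop = FALSE]
    for (cl in cols) df[[cl]] <- map[df[[cl]]]
    rownames(df) <- NULL
    df
  }
  list(beads = {
    b <- top@beads[keep, , drop = FALSE]; rownames(b) <- NULL; b
  },
  bonds = remap(top@bonds, c("i", "j")),
  constraints = remap(top@constraints, c("i", "j")),
  angles = remap(top@angles, c("i", "j", "k")))
}

## First bond in `top` joining a bead of roleA to a bead of roleB
## (either direction); NULL if none.
.bondBetweenRoles <- function(top, roleA, roleB) {
  roles <- top@beads$role
  for (r in seq_len(nrow(top@bonds))) {
    ri <- roles[top@bonds$i[r]]; rj <- roles[top@bonds$j[r]]
    if ((identical(ri, roleA) && identical(rj, roleB)) ||
        (identical(ri, roleB) && identical(rj, roleA)))
      return(top@bonds[r, , drop = FALSE])
  }
  NULL
}

#' Graft a diacylglyceryl moiety onto cysteine
#'
#' Creates the diacylcysteine topology by taking the glycerol and both acyl
#' tails of a phospholipid template (the headgroup and phosphate beads are
#' discarded) and bonding the first glycerol bead to the cysteine side-chain
#' bead, mirroring the enzymatic transfer of the sn-1,2-diacylglyceryl group
#' from phosphatidylglycerol. All bonded terms among retained template beads
#' are preserved verbatim.
#'
#' @param cys cysteine \linkS4class{CGTopology} (backbone + side-chain beads)
#' @param lipidTemplate phospholipid template with fragment-role annotations
#'   (see \code{\link{templateTopology}})
#' @param molecule name of the grafted molecule
#' @return a \linkS4class{CGTopology}
#' @export
graftDiacyl <- function(cys, lipidTemplate, molecule = "CYSD") {
  stopifnot(is(cys, "CGTopology"), is(lipidTemplate, "CGTopology"))
  if (!any(cys@beads$role == "sidechain", na.rm = TRUE))
    stop("cysteine topology lacks a side-chain bead", call. = FALSE)
  if (!any(lipidTemplate@beads$role == "glycerol", na.rm = TRUE))
    stop("lipid template lacks an annotated glycerol fragment",
         call. = FALSE)
  keep <- which(lipidTemplate@beads$role %in% c("glycerol", "tail"))
  frag <- .subsetTopology(lipidTemplate, keep)
  nCys <- nrow(cys@beads)
  shift <- function(df, cols) {
    for (cl in cols) df[[cl]] <- df[[cl]] + nCys
    df
  }
  scIdx <- which(cys@beads$role == "sidechain")[1]
  glyIdx <- nCys + which(frag$beads$role == "glycerol")[1]
  ## bonded parameters for the new cross-fragment bond default to the
  ## template's analogous phosphate-glycerol (headgroup-side) bond
  ref <- .bondBetweenRoles(lipidTemplate, "phosphate", "glycerol")
  if (is.null(ref)) ref <- .bondBetweenRoles(lipidTemplate, "glycerol", "tail")
  newBond <- data.frame(i = scIdx, j = glyIdx, funct = 1L,
                        length = ref$length, k = ref$k,
                        comment = "cysteine sidechain - glycerol graft",
                        stringsAsFactors = FALSE)
  newCGTopology(
    molecule,
    rbind(cys@beads, frag$beads),
    rbind(cys@bonds, newBond, shift(frag$bonds, c("i", "j"))),
    rbind(cys@constraints, shift(frag$constraints, c("i", "j"))),
    rbind(cys@angles, shift(frag$angles, c("i", "j", "k"))),
    header = sprintf("diacylcysteine: %s glycerol + tails grafted onto %s",
                     lipidTemplate@molecule, cys@molecule))
}

## TRUE when the fragment's bond graph is a simple path (linear tail).
.isLinearFragment <- function(top) {
  n <- nrow(top@beads)
  if (n == 1L) return(TRUE)
  deg <- tabulate(c(top@bonds$i, top@bonds$j, top@constraints$i,
                    top@constraints$j), nbins = n)
  sum(deg == 1L) == 2L && all(deg <= 2L) && .isConnectedTopology(top)
}

#' Graft an amide-linked palmitoyl tail onto diacylcysteine
#'
#' Creates the triacylcysteine topology by bonding a linear palmitoyl tail
#' fragment to the cysteine backbone bead (the N-acylation carried out by
#' Lnt). Errors if the backbone attachment is already occupied or the
#' fragment branches.
#'
#' @param diacyl diacylcysteine topology from \code{\link{graftDiacyl}}
#' @param palmitoylFragment linear tail fragment topology
#' @param molecule name of the grafted molecule
#' @return a \linkS4class{CGTopology}
#' @export
graftTriacyl <- function(diacyl, palmitoylFragment, molecule = "CYST") {
  stopifnot(is(diacyl, "CGTopology"), is(palmitoylFragment, "CGTopology"))
  bbIdx <- which(diacyl@beads$role == "backbone")[1]
  if (is.na(bbIdx))
    stop("diacyl topology lacks a backbone bead", call. = FALSE)
  if (!.isLinearFragment(palmitoylFragment))
    stop("palmitoyl fragment must be a linear (unbranched) tail",
         call. = FALSE)
  ## backbone attachment occupied = backbone already bonded to a tail bead
  tails <- which(diacyl@beads$role == "tail")
  occupied <- any((diacyl@bonds$i == bbIdx & diacyl@bonds$j %in% tails) |
                  (diacyl@bonds$j == bbIdx & diacyl@bonds$i %in% tails))
  if (occupied)
    stop("backbone attachment occupied: topology is already triacylated",
         call. = FALSE)
  n0 <- nrow(diacyl@beads)
  frag <- .subsetTopology(palmitoylFragment,
                          seq_len(nrow(palmitoylFragment@beads)))
  shift <- function(df, cols) {
    for (cl in cols) df[[cl]] <- df[[cl]] + n0
    df
  }
  ref <- .bondBetweenRoles(diacyl, "glycerol", "tail")
  if (is.null(ref)) ref <- .bondBetweenRoles(palmitoylFragment, "tail", "tail")
  newBond <- data.frame(i = bbIdx, j = n0 + 1L, funct = 1L,
                        length = ref$length, k = ref$k,
                        comment = "cysteine backbone - palmitoyl graft",
                        stringsAsFactors = FALSE)
  newCGTopology(
    molecule,
    rbind(diacyl@beads, frag$beads),
    rbind(diacyl@bonds, newBond, shift(frag$bonds, c("i", "j"))),
    rbind(diacyl@constraints, shift(frag$constraints, c("i", "j"))),
    rbind(diacyl@angles, shift(frag$angles, c("i", "j", "k"))),
    header = "triacylcysteine: palmitoyl tail on the cysteine backbone")
}

#' Build an elastic network over a folded core
#'
#' Harmonic restraints between all backbone-bead pairs within the cutoff,
#' preserving secondary and tertiary structure during coarse-grained
#' simulation. Tether residues modelled as disordered are excluded so the
#' linker stays unstructured and dynamic.
#'
#' @param model a \linkS4class{LipoproteinModel} or atom data.frame
#' @param cutoff inclusion cutoff in nm (default 0.7)
#' @param forceConstant spring constant in kJ mol^-1 nm^-2 (default 500, the
#'   conventional Martini elastic-network value)
#' @return an \linkS4class{ElasticNetwork} with pair distances in nm
#' @export
buildElasticNetwork <- function(model, cutoff = 0.7, forceConstant = 500) {
  .stopifnotScalarPositive(cutoff, "cutoff")
  .stopifnotScalarPositive(forceConstant, "forceConstant")
  if (is(model, "LipoproteinModel")) {
    atoms <- atomRecords(model)
    atoms <- atoms[!atoms$resno %in% model@tetherResnos, , drop = FALSE]
  } else atoms <- model
  bb <- .backbone(atoms)
  pairs <- if (nrow(bb) >= 2L) {
    xyz <- as.matrix(bb[, c("x", "y", "z")]) / 10  # Angstrom -> nm
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    data.frame(i = bb$resno[idx[, 1]], j = bb$resno[idx[, 2]],
               distance = d[idx], stringsAsFactors = FALSE)
  } else data.frame(i = integer(), j = integer(), distance = numeric())
  if (nrow(pairs)) {
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  new("ElasticNetwork", pairs = pairs, cutoff = cutoff,
      forceConstant = forceConstant)
}

#' Write an elastic network as itp [bonds] lines
#'
#' @param enm an \linkS4class{ElasticNetwork}
#' @param path output file
#' @export
writeElasticNetworkITP <- function(enm, path) {
  stopifnot(is(enm, "ElasticNetwork"))
  out <- c(sprintf("; elastic network: cutoff %.3f nm, k %.1f kJ mol-1 nm-2",
                   enm@cutoff, enm@forceConstant),
           "[ bonds ]", "; i j funct length fc")
  p <- enm@pairs
  out <- c(out, sprintf("%5d %5d 1 %8.4f %10.2f", p$i, p$j, p$distance,
                        rep(enm@forceConstant, nrow(p))))
  writeLines(out, path)
  invisible(path)
}
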