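## S4 classes for the central data objects.

.MATURATION_STATES <- c("SP", "SP_DI", "DI", "TRI", "UNTETHERED")
.ANCHOR_TYPES <- c("none", "diacyl", "triacyl")
.LIPID_BEAD_CLASSES <- c("GL0", "NH3", "PO4", "GL1:2", "Tail")
.FRAGMENT_ROLES <- c("backbone", "sidechain", "headgroup", "phosphate",
                     "glycerol", "tail")

## Expected anchor for each maturation state.
.stateAnchor <- function(state) {
  switch(state,
         SP = "none", SP_DI = "diacyl", DI = "diacyl",
         TRI = "triacyl", UNTETHERED = "none",
         stop("unknown maturation state: ", state, call. = FALSE))
}

.validAtoms <- function(atoms) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  if (!is.data.frame(atoms)) return("atoms must be a data.frame")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) return(paste("atoms lacks columns:",
                                 paste(miss, collapse = ", ")))
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r)) return(paste0("residue numbers not non-decreasing ",
                                      "within chain ", ch))
  }
  TRUE
}

#' LipoproteinModel: a structure in one of the four maturation states
#'
#' Holds the coarse-grained coordinates of a lipoprotein (folded core plus
#' any modelled N-terminal tether), its maturation state, the residue number
#' of the lipid-anchored cysteine, and the lipid attachment implied by the
#' state (none, diacyl or triacyl).
#'
#' @slot atoms data.frame with columns chain, resno, resname, elety, x, y, z
#'   (coordinates in Angstrom; one backbone bead "BB" per residue, optional
#'   side-chain beads "SC1"...)
#' @slot state maturation state, one of SP, SP_DI, DI, TRI, UNTETHERED
#' @slot cysIndex residue number of the anchored cysteine (NA for UNTETHERED)
#' @slot anchor lipid attachment: none, diacyl or triacyl
#' @slot tetherResnos residue numbers that were modelled (helix/linker) rather
#'   than experimentally resolved
#' @exportClass LipoproteinModel
setClass("LipoproteinModel",
         representation(atoms = "data.frame", state = "character",
                        cysIndex = "integer", anchor = "character",
                        tetherResnos = "integer"))

setValidity("LipoproteinModel", function(object) {
  msgs <- character()
  v <- .validAtoms(object@atoms)
  if (!isTRUE(v)) msgs <- c(msgs, v)
  if (!object@state %in% .MATURATION_STATES)
    msgs <- c(msgs, "invalid maturation state")
  if (!object@anchor %in% .ANCHOR_TYPES)
    msgs <- c(msgs, "invalid anchor type")
  if (object@state %in% .MATURATION_STATES &&
      object@anchor %in% .ANCHOR_TYPES &&
      object@anchor != .stateAnchor(object@state))
    msgs <- c(msgs, sprintf("state %s requires anchor '%s'", object@state,
                            .stateAnchor(object@state)))
  if (object@state %in% c("DI", "TRI") && nrow(object@atoms)) {
    first <- object@atoms$resname[which.min(object@atoms$resno)]
    if (first != "CYS")
      msgs <- c(msgs, "first residue must be the cysteine for DI/TRI")
  }
  if (length(msgs)) msgs else TRUE
})

#' CGTopology: beads and bonded terms of a coarse-grained molecule
#'
#' @slot molecule molecule name, as written to the itp [moleculetype]
#' @slot beads data.frame: name, type, charge, role (fragment role, one of
#'   backbone/sidechain/headgroup/phosphate/glycerol/tail), comment
#' @slot bonds data.frame: i, j (1-based bead indices), length (nm),
#'   k (kJ mol^-1 nm^-2)
#' @slot constraints data.frame: i, j, length (nm)
#' @slot angles data.frame: i, j, k (indices), angle (degrees),
#'   force (kJ mol^-1)
#' @slot header free-text comment lines preserved from/for the itp file
#' @exportClass CGTopology
setClass("CGTopology",
         representation(molecule = "character", beads = "data.frame",
                        bonds = "data.frame", constraints = "data.frame",
                        angles = "data.frame", header = "character"))

setValidity("CGTopology", function(object) {
  msgs <- character()
  b <- object@beads
  if (anyDuplicated(b$name))
    msgs <- c(msgs, "bead names must be unique within a molecule")
  bad <- setdiff(b$role[!is.na(b$role)], .FRAGMENT_ROLES)
  if (length(bad))
    msgs <- c(msgs, paste("unknown fragment role:", paste(bad, collapse = ",")))
  n <- nrow(b)
  idx <- c(object@bonds$i, object@bonds$j, object@constraints$i,
           object@constraints$j, object@angles$i, object@angles$j,
           object@angles$k)
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    msgs <- c(msgs, "bonded term references a nonexistent bead")
  if (n > 1 && !.isConnectedTopology(object))
    msgs <- c(msgs, "bead connectivity graph is not connected")
  if (length(msgs)) msgs else TRUE
})

## Connectivity over bonds + constraints (angles add no new edges in
## Martini-style topologies but are included for robustness).
.isConnectedTopology <- function(top) {
  n <- nrow(top@beads)
  if (n <= 1L) return(TRUE)
  edges <- rbind(
    cbind(top@bonds$i, top@bonds$j),
    cbind(top@constraints$i, top@constraints$j),
    cbind(top@angles$i, top@angles$j),
    cbind(top@angles$j, top@angles$k))
  if (is.null(edges) || nrow(edges) == 0L) return(FALSE)
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- c(edges[edges[, 1] %in% frontier, 2],
            edges[edges[, 2] %in% frontier, 1])
    nb <- unique(nb[!seen[nb]])
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' ElasticNetwork: harmonic restraints preserving a folded core
#'
#' @slot pairs data.frame: i, j (residue numbers, i < j), distance (nm)
#' @slot cutoff inclusion cutoff (nm)
#' @slot forceConstant spring constant (kJ mol^-1 nm^-2)
#' @exportClass ElasticNetwork
setClass("ElasticNetwork",
         representation(pairs = "data.frame", cutoff = "numeric",
                        forceConstant = "numeric"))

setValidity("ElasticNetwork", function(object) {
  msgs <- character()
  p <- object@pairs
  if (nrow(p)) {
    if (any(p$i >= p$j)) msgs <- c(msgs, "pairs must have i < j")
    if (anyDuplicated(p[, c("i", "j")])) msgs <- c(msgs, "duplicate pairs")
    if (any(p$distance > object@cutoff + 1e-12))
      msgs <- c(msgs, "pair distance exceeds cutoff")
  }
  if (length(msgs)) msgs else TRUE
})

#' MembraneSpec: per-leaflet lipid composition
#'
#' @slot lower data.frame: lipid, fraction (mole fractions, sum to 1)
#' @slot upper data.frame: lipid, fraction
#' @slot areaPerLipid named numeric, nm^2 per lipid overrides (e.g. LPS = 1.7)
#' @slot boxDim box dimensions in nm (may be NA when unset)
#' @exportClass MembraneSpec
setClass("MembraneSpec",
         representation(lower = "data.frame", upper = "data.frame",
                        areaPerLipid = "numeric", boxDim = "numeric"))

setValidity("MembraneSpec", function(object) {
  msgs <- character()
  for (side in c("lower", "upper")) {
    lf <- slot(object, side)
    if (nrow(lf)) {
      if (any(lf$fraction < 0))
        msgs <- c(msgs, paste(side, "leaflet has negative fractions"))
      if (abs(sum(lf$fraction) - 1) > 1e-9)
        msgs <- c(msgs, paste(side, "leaflet fractions do not sum to 1"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RunConfig: molecular-dynamics run parameters
#'
#' @slot stage one of assembly, production, umbrella
#' @slot timestep integration step (fs)
#' @slot temperature coupling temperature (K)
#' @slot pressure coupling pressure (bar)
#' @slot tauT thermostat coupling time (ps)
#' @slot tauP barostat coupling time (ps)
#' @slot cutoff nonbonded cutoff (nm)
#' @slot nstlist neighbour-list update interval (steps)
#' @slot salt NaCl concentration (M)
#' @exportClass RunConfig
setClass("RunConfig",
         representation(stage = "character", timestep = "numeric",
                        temperature = "numeric", pressure = "numeric",
                        tauT = "numeric", tauP = "numeric",
                        cutoff = "numeric", nstlist = "numeric",
                        salt = "numeric"))

setValidity("RunConfig", function(object) {
  vals <- c(object@timestep, object@temperature, object@pressure,
            object@tauT, object@tauP, object@cutoff, object@nstlist,
            object@salt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all run parameters must be positive and finite" else TRUE
})

#' UmbrellaSetup: plan of an umbrella-sampling series
#'
#' @slot forceConstant pull/bias force constant (kJ mol^-1 nm^-2)
#' @slot spacing window spacing along the reaction coordinate (nm)
#' @slot centers window centers (nm), an arithmetic sequence
#' @slot frames source frame index selected for each window
#' @slot temperature sampling temperature (K)
#' @slot countInRange TRUE when the window count lies in the conventional
#'   50-80 band
#' @exportClass UmbrellaSetup
setClass("UmbrellaSetup",
         representation(forceConstant = "numeric", spacing = "numeric",
                        centers = "numeric", frames = "integer",
                        temperature = "numeric", countInRange = "logical"))

#' UmbrellaWindow: biased samples of the reaction coordinate
#'
#' @slot center bias center (nm)
#' @slot forceConstant harmonic bias constant (kJ mol^-1 nm^-2); 0 = unbiased
#' @slot samples reaction-coordinate time series (nm)
#' @slot temperature sampling temperature (K)
#' @exportClass UmbrellaWindow
setClass("UmbrellaWindow",
         representation(center = "numeric", forceConstant = "numeric",
                        samples = "numeric", temperature = "numeric"))

setValidity("UmbrellaWindow", function(object) {
  msgs <- character()
  if (length(object@samples) < 1L) msgs <- c(msgs, "window has no samples")
  if (object@forceConstant < 0) msgs <- c(msgs, "force constant must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' PMFProfile: potential-of-mean-force estimate over reaction-coordinate bins
#'
#' The profile is anchored so its minimum is exactly zero; extraction free
#' energies are read as plateau minus minimum.
#'
#' @slot xi bin centers (nm)
#' @slot G free energy per bin (kJ/mol), min = 0; NA in unsampled bins
#' @slot err per-bin bootstrap standard errors (kJ/mol), NA when not computed
#' @slot prob unbiased bin probabilities (sum to 1 over sampled bins)
#' @slot offsets per-window free-energy offsets F_i (kJ/mol)
#' @slot iterations WHAM iterations used
#' @slot temperature temperature (K) used for kT
#' @exportClass PMFProfile
setClass("PMFProfile",
         representation(xi = "numeric", G = "numeric", err = "numeric",
                        prob = "numeric", offsets = "numeric",
                        iterations = "integer", temperature = "numeric"))

setValidity("PMFProfile", function(object) {
  msgs <- character()
  g <- object@G[is.finite(object@G)]
  if (length(g) && abs(min(g)) > 1e-9)
    msgs <- c(msgs, "profile must be anchored at zero minimum")
  if (any(object@err[is.finite(object@err)] < 0))
    msgs <- c(msgs, "bootstrap errors must be >= 0")
  if (length(object@G) != length(object@xi))
    msgs <- c(msgs, "G and xi lengths differ")
  if (length(msgs)) msgs else TRUE
})

#' ContactProfile: per-residue lipid contact counts by bead class
#'
#' @slot counts integer matrix, residues x lipid bead classes
#'   (GL0, NH3, PO4, GL1:2, Tail); accumulated over frames
#' @slot resids residue numbers (rows of counts)
#' @slot resnames residue names (three-letter), parallel to resids
#' @slot nFrames number of frames accumulated
#' @slot cutoff contact cutoff (Angstrom)
#' @exportClass ContactProfile
setClass("ContactProfile",
         representation(counts = "matrix", resids = "integer",
                        resnames = "character", nFrames = "integer",
                        cutoff = "numeric"))

setValidity("ContactProfile", function(object) {
  msgs <- character()
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (nrow(object@counts) != length(object@resids))
    msgs <- c(msgs, "counts rows must match resids")
  if (object@cutoff <= 0) msgs <- c(msgs, "cutoff must be positive")
  if (length(msgs)) msgs else TRUE
})

#' DeformationSurface: leaflet phosphate height maps on an xy grid
#'
#' Heights are mean absolute phosphate distances from the instantaneous
#' membrane center, per leaflet, in Angstrom. Bins never visited by a
#' phosphate are NA (flagged, not zero-filled).
#'
#' @slot upper matrix of mean |z| for the upper leaflet (Angstrom)
#' @slot lower matrix for the lower leaflet
#' @slot flagged logical matrix marking bins with persistently ambiguous
#'   leaflet assignment (|z| < 2 Angstrom from center)
#' @slot x,y bin centers (Angstrom)
#' @slot bin bin size (Angstrom)
#' @slot nFrames frames accumulated
#' @exportClass DeformationSurface
setClass("DeformationSurface",
         representation(upper = "matrix", lower = "matrix",
                        flagged = "matrix", x = "numeric", y = "numeric",
                        bin = "numeric", nFrames = "integer"))

#' TransferCycle: energetics of the three Lol transfer steps
#'
#' Sign convention: a positive step value is energy the cell must supply for
#' that hop (membrane extraction uphill; transfer into a higher-affinity
#' acceptor downhill).
#'
#' @slot energies named extraction free energies (kJ/mol):
#'   IM, LolA, LolB, OM
#' @slot steps named step energies: IM_to_LolA, LolA_to_LolB, LolB_to_OM
#' @slot net net cost of one full transfer (kJ/mol); equals the sum of steps
#' @slot errors per-environment standard errors (kJ/mol; NA when unknown)
#' @slot stepErrors step errors propagated in quadrature
#' @slot moiety "triacyl" or "diacyl"
#' @exportClass TransferCycle
setClass("TransferCycle",
         representation(energies = "numeric", steps = "numeric",
                        net = "numeric", errors = "numeric",
                        stepErrors = "numeric", moiety = "character"))

setValidity("TransferCycle", function(object) {
  msgs <- character()
  if (!identical(names(object@energies), c("IM", "LolA", "LolB", "OM")))
    msgs <- c(msgs, "energies must be named IM, LolA, LolB, OM")
  if (abs(object@net - sum(object@steps)) > 1e-9)
    msgs <- c(msgs, "net must equal the sum of the steps")
  if (length(msgs)) msgs else TRUE
})

#' CGTrajectory: frames of coarse-grained coordinates with bead metadata
#'
#' @slot coords list of n_atoms x 3 coordinate matrices (Angstrom), one per
#'   frame
#' @slot box nFrames x 3 matrix of box dimensions (Angstrom); NA disables
#'   periodic wrapping
#' @slot atoms data.frame: name, resid, resname, segment ("protein"/"lipid"),
#'   class (lipid bead class or NA)
#' @exportClass CGTrajectory
setClass("CGTrajectory",
         representation(coords = "list", box = "matrix", atoms = "data.frame"))

setValidity("CGTrajectory", function(object) {
  msgs <- character()
  n <- nrow(object@atoms)
  if (!all(vapply(object@coords, function(m)
    is.matrix(m) && nrow(m) == n && ncol(m) == 3, logical(1))))
    msgs <- c(msgs, "every frame must be an n_atoms x 3 matrix")
  if (nrow(object@box) != length(object@coords))
    msgs <- c(msgs, "box rows must match frame count")
  if (length(msgs)) msgs else TRUE
})
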