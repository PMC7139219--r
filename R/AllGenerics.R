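## Generics, accessors and show methods.

#' @name LipoCG-accessors
#' @title Accessors for LipoCG S4 classes
#' @description Small accessor functions used instead of direct slot access.
#' @param object an object of the documented class
#' @param x an object of the documented class
NULL

#' @rdname LipoCG-accessors
#' @export
setGeneric("atomRecords", function(object) standardGeneric("atomRecords"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("maturationState",
           function(object) standardGeneric("maturationState"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("anchorType", function(object) standardGeneric("anchorType"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("cysIndex", function(object) standardGeneric("cysIndex"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("beads", function(object) standardGeneric("beads"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("constraints", function(object) standardGeneric("constraints"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("moleculeName", function(object) standardGeneric("moleculeName"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("networkPairs", function(object) standardGeneric("networkPairs"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("contactCounts", function(object) standardGeneric("contactCounts"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("reactionCoord", function(object) standardGeneric("reactionCoord"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("bootstrapError", function(object) standardGeneric("bootstrapError"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("windowOffsets", function(object) standardGeneric("windowOffsets"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("cycleSteps", function(object) standardGeneric("cycleSteps"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("netCost", function(object) standardGeneric("netCost"))
#' @rdname LipoCG-accessors
#' @export
setGeneric("extractionEnergies",
           function(object) standardGeneric("extractionEnergies"))

#' @rdname LipoCG-accessors
#' @export
setMethod("atomRecords", "LipoproteinModel", function(object) object@atoms)
#' @rdname LipoCG-accessors
#' @export
setMethod("maturationState", "LipoproteinModel",
          function(object) object@state)
#' @rdname LipoCG-accessors
#' @export
setMethod("anchorType", "LipoproteinModel", function(object) object@anchor)
#' @rdname LipoCG-accessors
#' @export
setMethod("cysIndex", "LipoproteinModel", function(object) object@cysIndex)

#' @rdname LipoCG-accessors
#' @export
setMethod("beads", "CGTopology", function(object) object@beads)
#' @rdname LipoCG-accessors
#' @export
setMethod("bonds", "CGTopology", function(object) object@bonds)
#' @rdname LipoCG-accessors
#' @export
setMethod("constraints", "CGTopology", function(object) object@constraints)
#' @rdname LipoCG-accessors
#' @export
setMethod("angles", "CGTopology", function(object) object@angles)
#' @rdname LipoCG-accessors
#' @export
setMethod("moleculeName", "CGTopology", function(object) object@molecule)

#' @rdname LipoCG-accessors
#' @export
setMethod("networkPairs", "ElasticNetwork", function(object) object@pairs)

#' @rdname LipoCG-accessors
#' @export
setMethod("contactCounts", "ContactProfile", function(object) object@counts)
#' @rdname LipoCG-accessors
#' @export
setMethod("nFrames", "ContactProfile", function(object) object@nFrames)
#' @rdname LipoCG-accessors
#' @export
setMethod("nFrames", "CGTrajectory",
          function(object) length(object@coords))
#' @rdname LipoCG-accessors
#' @export
setMethod("nFrames", "DeformationSurface", function(object) object@nFrames)

#' @rdname LipoCG-accessors
#' @export
setMethod("freeEnergy", "PMFProfile", function(object) object@G)
#' @rdname LipoCG-accessors
#' @export
setMethod("reactionCoord", "PMFProfile", function(object) object@xi)
#' @rdname LipoCG-accessors
#' @export
setMethod("bootstrapError", "PMFProfile", function(object) object@err)
#' @rdname LipoCG-accessors
#' @export
setMethod("windowOffsets", "PMFProfile", function(object) object@offsets)

#' @rdname LipoCG-accessors
#' @export
setMethod("cycleSteps", "TransferCycle", function(object) object@steps)
#' @rdname LipoCG-accessors
#' @export
setMethod("netCost", "TransferCycle", function(object) object@net)
#' @rdname LipoCG-accessors
#' @export
setMethod("extractionEnergies", "TransferCycle",
          function(object) object@energies)

setMethod("show", "LipoproteinModel", function(object) {
  a <- object@atoms
  cat("LipoproteinModel:", object@state, "state,", object@anchor, "anchor\n")
  cat("  ", length(unique(paste(a$chain, a$resno))), "residues,",
      nrow(a), "beads; anchored Cys at residue",
      ifelse(is.na(object@cysIndex), "-", object@cysIndex), "\n")
  if (length(object@tetherResnos))
    cat("  modelled tether residues:", min(object@tetherResnos), "-",
        max(object@tetherResnos), "\n")
})

setMethod("show", "CGTopology", function(object) {
  cat("CGTopology:", object@molecule, "\n")
  cat("  ", nrow(object@beads), "beads |", nrow(object@bonds), "bonds |",
      nrow(object@constraints), "constraints |", nrow(object@angles),
      "angles\n")
  cat("   net charge:", sum(object@beads$charge), "e\n")
})

setMethod("show", "ElasticNetwork", function(object) {
  cat("ElasticNetwork:", nrow(object@pairs), "pairs within",
      object@cutoff, "nm; k =", object@forceConstant, "kJ mol-1 nm-2\n")
})

setMethod("show", "ContactProfile", function(object) {
  cat("ContactProfile:", nrow(object@counts), "residues x",
      ncol(object@counts), "bead classes;", object@nFrames,
      "frames; cutoff", object@cutoff, "A\n")
})

setMethod("show", "PMFProfile", function(object) {
  g <- object@G[is.finite(object@G)]
  cat("PMFProfile:", length(object@xi), "bins over [",
      round(min(object@xi), 3), ",", round(max(object@xi), 3), "] nm;",
      object@iterations, "WHAM iterations\n")
  if (length(g))
    cat("  range of G: 0 -", round(max(g), 2), "kJ/mol; minimum at xi =",
        round(object@xi[which.min(object@G)], 3), "nm\n")
})

setMethod("show", "TransferCycle", function(object) {
  cat("TransferCycle (", object@moiety, " moiety)\n", sep = "")
  cat(sprintf("  IM -> LolA : %+.1f kJ/mol\n", object@steps["IM_to_LolA"]))
  cat(sprintf("  LolA -> LolB : %+.1f kJ/mol\n", object@steps["LolA_to_LolB"]))
  cat(sprintf("  LolB -> OM : %+.1f kJ/mol\n", object@steps["LolB_to_OM"]))
  cat(sprintf("  net cost : %+.1f kJ/mol\n", object@net))
})

setMethod("show", "MembraneSpec", function(object) {
  cat("MembraneSpec\n")
  for (side in c("upper", "lower")) {
    lf <- slot(object, side)
    if (nrow(lf))
      cat("  ", side, ":", paste(sprintf("%s %.0f%%", lf$lipid,
                                         100 * lf$fraction),
                                 collapse = ", "), "\n")
  }
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig (", object@stage, "): ", object@timestep, " fs, ",
      object@temperature, " K, ", object@pressure, " bar, cutoff ",
      object@cutoff, " nm, ", object@salt, " M NaCl\n", sep = "")
})

setMethod("show", "UmbrellaSetup", function(object) {
  cat("UmbrellaSetup:", length(object@centers), "windows, spacing",
      object@spacing, "nm, k =", object@forceConstant,
      "kJ mol-1 nm-2,", object@temperature, "K\n")
  if (!object@countInRange)
    cat("  note: window count outside the conventional 50-80 band\n")
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat("UmbrellaWindow: center", object@center, "nm, k",
      object@forceConstant, "kJ mol-1 nm-2,", length(object@samples),
      "samples,", object@temperature, "K\n")
})

setMethod("show", "DeformationSurface", function(object) {
  cat("DeformationSurface:", length(object@x), "x", length(object@y),
      "bins of", object@bin, "A;", object@nFrames, "frames\n")
  up <- object@upper[is.finite(object@upper)]
  lo <- object@lower[is.finite(object@lower)]
  if (length(up) && length(lo))
    cat("  max center-to-phosphate:", round(max(up, lo), 1), "A\n")
})

setMethod("show", "CGTrajectory", function(object) {
  cat("CGTrajectory:", length(object@coords), "frames,",
      nrow(object@atoms), "beads (",
      sum(object@atoms$segment == "protein"), "protein /",
      sum(object@atoms$segment == "lipid"), "lipid )\n")
})
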