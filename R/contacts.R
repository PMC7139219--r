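## Residue-lipid contact fingerprints, replicate reproducibility and
## binding-mode classification.

#' Residue-lipid contact profile of a trajectory
#'
#' For every frame, residue and lipid bead class, counts the lipid beads of
#' that class lying within the cutoff of any particle of the residue
#' (minimum-image distances under the orthorhombic box). Counts are
#' accumulated over frames into a residues x classes matrix. The default
#' 6 Angstrom cutoff is the conventional coarse-grained contact criterion.
#'
#' @param traj a \linkS4class{CGTrajectory} whose atoms carry segment
#'   ("protein"/"lipid") and lipid bead class annotations
#' @param cutoff contact cutoff in Angstrom
#' @param classes lipid bead classes to count (columns of the result)
#' @return a \linkS4class{ContactProfile}
#' @export
contactProfile <- function(traj, cutoff = 6,
                           classes = .LIPID_BEAD_CLASSES) {
  stopifnot(is(traj, "CGTrajectory"))
  .stopifnotScalarPositive(cutoff, "cutoff")
  a <- traj@atoms
  prot <- which(a$segment == "protein")
  lip <- which(a$segment == "lipid" & a$class %in% classes)
  if (!length(prot)) stop("empty protein selection", call. = FALSE)
  if (!length(lip)) stop("empty lipid selection", call. = FALSE)
  resids <- sort(unique(a$resid[prot]))
  resnames <- a$resname[prot][match(resids, a$resid[prot])]
  counts <- matrix(0L, length(resids), length(classes),
                   dimnames = list(resids, classes))
  protRes <- match(a$resid[prot], resids)
  lipClass <- match(a$class[lip], classes)
  for (f in seq_along(traj@coords)) {
    box <- traj@box[f, ]
    if (any(is.finite(box) & box < cutoff))
      stop("box smaller than the contact cutoff", call. = FALSE)
    xyz <- traj@coords[[f]]
    d <- .pbcDistance(xyz[prot, , drop = FALSE], xyz[lip, , drop = FALSE],
                      box)
    inContact <- d <= cutoff
    ## per residue: how many beads of each class are within the cutoff of
    ## any particle of the residue
    for (r in seq_along(resids)) {
      hit <- colSums(inContact[protRes == r, , drop = FALSE]) > 0L
      if (any(hit))
        counts[r, ] <- counts[r, ] + tabulate(lipClass[hit],
                                              nbins = length(classes))
    }
  }
  new("ContactProfile", counts = counts, resids = as.integer(resids),
      resnames = resnames, nFrames = length(traj@coords), cutoff = cutoff)
}

#' Pairwise Pearson correlation of replicate contact profiles
#'
#' Entry (a, b) is the Pearson correlation of the per-residue contact
#' vectors of replicates a and b: total counts per residue by default, or
#' the flattened class-resolved matrix with \code{classResolved = TRUE}.
#' A correlation of 1 marks faithful reproduction of a binding mode, -1 a
#' fully anti-correlated footprint. Zero-variance profiles give NA entries
#' (missing, not 0).
#'
#' @param profiles list of \linkS4class{ContactProfile} over the same
#'   residue range
#' @param classResolved correlate class-resolved counts instead of
#'   per-residue totals
#' @return symmetric correlation matrix with unit diagonal
#' @export
replicateCorrelation <- function(profiles, classResolved = FALSE) {
  stopifnot(length(profiles) >= 2L)
  res <- lapply(profiles, function(p) p@resids)
  if (!all(vapply(res[-1], identical, logical(1), res[[1]])))
    stop("profiles cover different residue ranges", call. = FALSE)
  vecs <- lapply(profiles, function(p) {
    m <- contactCounts(p)
    if (classResolved) as.numeric(m) else as.numeric(rowSums(m))
  })
  n <- length(vecs)
  labels <- if (!is.null(names(profiles))) names(profiles)
            else as.character(seq_len(n))
  out <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(out) <- 1
  for (ai in seq_len(n - 1L)) for (bi in (ai + 1L):n) {
    va <- vecs[[ai]]; vb <- vecs[[bi]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next  # undefined -> NA
    out[ai, bi] <- out[bi, ai] <- stats::cor(va, vb)
  }
  out
}

#' Classify replicate binding modes from a correlation matrix
#'
#' Single-linkage grouping: replicates joined whenever their pairwise
#' correlation reaches the threshold, groups labelled by descending size
#' (mode 1 = the primary, most populated binding orientation), ties broken
#' by lowest replicate index. NA correlations never join replicates.
#'
#' @param corMatrix symmetric replicate correlation matrix
#' @param threshold correlation at or above which two replicates share a
#'   mode (default 0.5)
#' @return data.frame with columns replicate and mode
#' @export
classifyBindingModes <- function(corMatrix, threshold = 0.5) {
  n <- nrow(corMatrix)
  stopifnot(n == ncol(corMatrix))
  adj <- !is.na(corMatrix) & corMatrix >= threshold
  diag(adj) <- TRUE
  ## connected components by label propagation
  comp <- seq_len(n)
  repeat {
    newComp <- comp
    for (v in seq_len(n))
      newComp[v] <- min(comp[adj[v, ]])
    if (identical(newComp, comp)) break
    comp <- newComp
  }
  sizes <- table(comp)
  first <- tapply(seq_len(n), comp, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  modeOf <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- if (!is.null(rownames(corMatrix))) rownames(corMatrix)
            else as.character(seq_len(n))
  data.frame(replicate = labels,
             mode = as.integer(modeOf[as.character(comp)]),
             stringsAsFactors = FALSE)
}

#' Mean contact counts per amino-acid type and lipid bead class
#'
#' Aggregates one or more contact profiles over all residues of each
#' amino-acid type, normalised by the number of occurrences of the type, to
#' give the residue-lipid interaction fingerprint across proteins.
#'
#' @param profiles list of \linkS4class{ContactProfile} (possibly from
#'   different proteins)
#' @return matrix of mean counts, amino-acid types x bead classes
#' @export
residueClassEnrichment <- function(profiles) {
  if (is(profiles, "ContactProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  classes <- colnames(contactCounts(profiles[[1]]))
  allRes <- do.call(rbind, lapply(profiles, function(p)
    data.frame(resname = p@resnames, contactCounts(p),
               check.names = FALSE)))
  types <- sort(unique(allRes$resname))
  out <- matrix(0, length(types), length(classes),
                dimnames = list(types, classes))
  for (ty in types) {
    rows <- allRes[allRes$resname == ty, classes, drop = FALSE]
    out[ty, ] <- colMeans(as.matrix(rows))
  }
  out
}

#' Write a contact profile or correlation matrix as TSV
#'
#' @param x a \linkS4class{ContactProfile} or matrix
#' @param path output file
#' @export
writeContactTSV <- function(x, path) {
  df <- if (is(x, "ContactProfile"))
    data.frame(resid = x@resids, resname = x@resnames, contactCounts(x),
               check.names = FALSE)
  else as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = !is(
    x, "ContactProfile"))
  invisible(path)
}
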