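## Membrane deformation mapping from phosphate positions.

#' Map membrane deformation from phosphate positions
#'
#' Bins phosphate beads on an xy grid and accumulates, per leaflet, the mean
#' absolute distance of the phosphates from the instantaneous membrane
#' center (the median phosphate z of the frame; the median, unlike the mean,
#' is not dragged by a strong localized deformation of one leaflet).
#' Leaflets are split by the sign of z relative to that center. Bins no phosphate ever visits are NA;
#' bins where phosphates sit persistently within 2 Angstrom of the center
#' (ambiguous leaflet assignment) are flagged.
#'
#' @param traj a \linkS4class{CGTrajectory} containing PO4-class beads in
#'   both leaflets
#' @param bin grid bin size in Angstrom (default 2)
#' @param ambiguousZ half-width of the ambiguous zone about the center
#' @return a \linkS4class{DeformationSurface}
#' @export
deformationSurface <- function(traj, bin = 2, ambiguousZ = 2) {
  stopifnot(is(traj, "CGTrajectory"))
  .stopifnotScalarPositive(bin, "bin")
  a <- traj@atoms
  po4 <- which(a$class %in% "PO4")
  if (!length(po4)) stop("no phosphate (PO4) beads in trajectory",
                         call. = FALSE)
  box <- traj@box[1L, ]
  if (any(!is.finite(box[1:2])))
    stop("deformation mapping needs finite box x/y dimensions",
         call. = FALSE)
  xb <- seq(0, box[1], by = bin)
  yb <- seq(0, box[2], by = bin)
  if (xb[length(xb)] < box[1]) xb <- c(xb, box[1])
  if (yb[length(yb)] < box[2]) yb <- c(yb, box[2])
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  sums <- list(upper = matrix(0, nx, ny), lower = matrix(0, nx, ny))
  hits <- list(upper = matrix(0L, nx, ny), lower = matrix(0L, nx, ny))
  amb <- matrix(0L, nx, ny)
  zsplit <- logical(length(po4))
  for (f in seq_along(traj@coords)) {
    xyz <- traj@coords[[f]][po4, , drop = FALSE]
    ## wrap into the box
    for (k in 1:2) xyz[, k] <- xyz[, k] %% box[k]
    center <- stats::median(xyz[, 3])
    dz <- xyz[, 3] - center
    ix <- pmin(pmax(findInterval(xyz[, 1], xb, rightmost.closed = TRUE),
                    1L), nx)
    iy <- pmin(pmax(findInterval(xyz[, 2], yb, rightmost.closed = TRUE),
                    1L), ny)
    up <- dz >= 0
    for (side in c("upper", "lower")) {
      sel <- if (side == "upper") up else !up
      if (!any(sel)) next
      sums[[side]] <- sums[[side]] +
        unclass(.binSum(abs(dz[sel]), ix[sel], iy[sel], nx, ny))
      hits[[side]] <- hits[[side]] +
        unclass(.binSum(rep(1L, sum(sel)), ix[sel], iy[sel], nx, ny))
    }
    ambSel <- abs(dz) < ambiguousZ
    if (any(ambSel))
      amb <- amb + unclass(.binSum(rep(1L, sum(ambSel)), ix[ambSel],
                                           iy[ambSel], nx, ny))
    zsplit <- zsplit | ambSel
  }
  mean_ <- function(side) {
    m <- sums[[side]] / hits[[side]]
    m[hits[[side]] == 0L] <- NA_real_
    m
  }
  new("DeformationSurface",
      upper = mean_("upper"), lower = mean_("lower"),
      flagged = amb > length(traj@coords) / 2,
      x = (xb[-1] + xb[-length(xb)]) / 2,
      y = (yb[-1] + yb[-length(yb)]) / 2,
      bin = bin, nFrames = length(traj@coords))
}

## Sum values into an nx x ny matrix by (ix, iy) bin indices.
.binSum <- function(values, ix, iy, nx, ny) {
  idx <- (iy - 1L) * nx + ix
  m <- matrix(0, nx, ny)
  s <- tapply(values, idx, sum)
  m[as.integer(names(s))] <- s
  m
}

#' Summarise a deformation surface
#'
#' Reports the maximum center-to-phosphate distance over both leaflets (the
#' deformation extremum) and the bulk membrane thickness, taken as the sum
#' of the per-leaflet medians over bins beyond a stated radius from the
#' protein (all bins when no protein position is given).
#'
#' @param surface a \linkS4class{DeformationSurface}
#' @param proteinXY optional xy position of the protein (Angstrom)
#' @param bulkRadius radius (Angstrom) beyond which bins count as bulk
#' @return list with maxDistance, maxLeaflet, bulkThickness (Angstrom)
#' @export
deformationSummary <- function(surface, proteinXY = NULL, bulkRadius = 30) {
  stopifnot(is(surface, "DeformationSurface"))
  grid <- expand.grid(x = surface@x, y = surface@y)
  bulkSel <- if (is.null(proteinXY)) rep(TRUE, nrow(grid)) else
    sqrt((grid$x - proteinXY[1])^2 + (grid$y - proteinXY[2])^2) > bulkRadius
  vals <- c(upper = suppressWarnings(max(surface@upper, na.rm = TRUE)),
            lower = suppressWarnings(max(surface@lower, na.rm = TRUE)))
  bulk <- vapply(c("upper", "lower"), function(side) {
    m <- as.numeric(slot(surface, side))
    stats::median(m[bulkSel & is.finite(m)])
  }, numeric(1))
  list(maxDistance = max(vals),
       maxLeaflet = names(vals)[which.max(vals)],
       bulkThickness = sum(bulk))
}

#' Write a deformation surface as a TSV grid
#'
#' @param surface a \linkS4class{DeformationSurface}
#' @param path output file (long format: x, y, upper, lower, flagged)
#' @export
writeDeformationTSV <- function(surface, path) {
  grid <- expand.grid(x = surface@x, y = surface@y)
  grid$upper <- as.numeric(surface@upper)
  grid$lower <- as.numeric(surface@lower)
  grid$flagged <- as.logical(surface@flagged)
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
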