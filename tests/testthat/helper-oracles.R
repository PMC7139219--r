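# Independent oracles used across tests. These deliberately re-derive
# results by brute force (explicit loops, closed forms) rather than calling
# the package's own code paths.

# Brute-force lipobox scan: test every 4-residue window against the
# character classes.
oracleLipobox <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  hits <- integer(0)
  if (length(chars) >= 4L) for (s in 1:(length(chars) - 3L)) {
    w <- chars[s:(s + 3L)]
    if (w[1] %in% c("L", "V", "I") &&
        w[2] %in% c("A", "S", "T", "V", "I") &&
        w[3] %in% c("G", "A", "S") &&
        w[4] == "C") hits <- c(hits, s + 3L)
  }
  hits
}

# Brute-force all-pairs elastic network (no spatial tricks).
oracleENM <- function(xyzNm, resno, cutoff) {
  n <- nrow(xyzNm)
  out <- NULL
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    d <- sqrt(sum((xyzNm[a, ] - xyzNm[b, ])^2))
    if (d <= cutoff)
      out <- rbind(out, data.frame(i = resno[a], j = resno[b], distance = d))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(),
                               distance = numeric()) else out
}

# Minimum-image distance between two points in an orthorhombic box.
oracleMinImage <- function(p, q, box) {
  d <- p - q
  for (k in 1:3) if (is.finite(box[k]) && box[k] > 0)
    d[k] <- d[k] - box[k] * round(d[k] / box[k])
  sqrt(sum(d^2))
}

# Brute-force contact counting: for every frame, residue and class, count
# lipid beads of the class with any residue particle within the cutoff.
oracleContacts <- function(traj, cutoff = 6,
                           classes = c("GL0", "NH3", "PO4", "GL1:2",
                                       "Tail")) {
  a <- traj@atoms
  prot <- which(a$segment == "protein")
  resids <- sort(unique(a$resid[prot]))
  counts <- matrix(0L, length(resids), length(classes),
                   dimnames = list(resids, classes))
  for (f in seq_along(traj@coords)) {
    xyz <- traj@coords[[f]]
    box <- traj@box[f, ]
    for (ri in seq_along(resids)) {
      part <- prot[a$resid[prot] == resids[ri]]
      for (ci in seq_along(classes)) {
        lip <- which(a$segment == "lipid" & !is.na(a$class) &
                     a$class == classes[ci])
        for (lb in lip) {
          touch <- FALSE
          for (pp in part) {
            if (oracleMinImage(xyz[pp, ], xyz[lb, ], box) <= cutoff) {
              touch <- TRUE
              break
            }
          }
          if (touch) counts[ri, ci] <- counts[ri, ci] + 1L
        }
      }
    }
  }
  counts
}

# Direct Boltzmann inversion of a single histogram (shared bin layout with
# the WHAM estimator: left-closed bins over the sample range).
oracleBoltzmannInvert <- function(samples, nBins, kT) {
  rng <- range(samples)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  edges[length(edges)] <- edges[length(edges)] + 1e-12
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  h <- tabulate(idx, nbins = nBins)
  G <- -kT * (log(h) - log(sum(h)))
  G[h == 0L] <- NA_real_
  G - min(G, na.rm = TRUE)
}

# Single-linkage grouping via exhaustive transitive closure.
oracleSingleLinkage <- function(corMatrix, threshold) {
  n <- nrow(corMatrix)
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        link <- any(corMatrix[groups[[a]], groups[[b]]] >= threshold,
                    na.rm = TRUE)
        if (link) {
          groups[[a]] <- sort(c(groups[[a]], groups[[b]]))
          groups[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sizes <- vapply(groups, length, integer(1))
  firsts <- vapply(groups, min, integer(1))
  ord <- order(-sizes, firsts)
  mode <- integer(n)
  for (g in seq_along(ord)) mode[groups[[ord[g]]]] <- g
  mode
}

# One protein bead and one PO4 bead `sep` Angstrom apart.
oneBeadTraj <- function(sep, box = c(60, 60, 60)) {
  atoms <- data.frame(name = c("BB", "PO4"), resid = c(1L, 2L),
                      resname = c("ALA", "POPE"),
                      segment = c("protein", "lipid"),
                      class = c(NA, "PO4"), stringsAsFactors = FALSE)
  newCGTrajectory(list(rbind(c(10, 10, 10), c(10 + sep, 10, 10))), box,
                  atoms)
}

# A rigid random pose (rotation + translation) applied to an atom table.
randomPose <- function(atoms, seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  shift <- runif(3, -30, 30)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# All sorted pairwise distances of the backbone beads of an atom table.
pairwiseDistances <- function(atoms) {
  bb <- atoms[atoms$elety %in% c("BB", "CA"), ]
  as.numeric(dist(as.matrix(bb[, c("x", "y", "z")])))
}
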