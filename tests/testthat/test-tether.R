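makeStub <- function(xyz, resnames = NULL) {
  n <- nrow(xyz)
  data.frame(chain = "A", resno = seq_len(n),
             resname = if (is.null(resnames)) rep("ALA", n) else resnames,
             elety = "BB", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

test_that("orientStructure puts the first two residues on the z-axis with
           the N terminus below the core", {
  toy <- makeToyStructure(seed = 7)
  posed <- randomPose(toy$atoms, seed = 11)
  out <- orientStructure(posed)
  bb <- out[out$elety == "BB", ]
  expect_lt(max(abs(bb[1, c("x", "y")])), 1e-6)
  expect_lt(max(abs(bb[2, c("x", "y")])), 1e-6)
  expect_lt(bb$z[1], mean(bb$z))
  # rigid body: all pairwise distances preserved to 1e-6 Angstrom
  expect_lt(max(abs(pairwiseDistances(posed) - pairwiseDistances(out))),
            1e-6)
})

test_that("orientStructure is idempotent and preserves chirality", {
  toy <- makeToyStructure(seed = 3)
  once <- orientStructure(randomPose(toy$atoms, seed = 5))
  twice <- orientStructure(once)
  expect_equal(as.matrix(twice[, c("x", "y", "z")]),
               as.matrix(once[, c("x", "y", "z")]), tolerance = 1e-9)
  # chirality: signed volume of the first four backbone beads unchanged
  vol <- function(a) {
    m <- as.matrix(a[a$elety == "BB", c("x", "y", "z")])[1:4, ]
    det(cbind(m[2, ] - m[1, ], m[3, ] - m[1, ], m[4, ] - m[1, ]))
  }
  posed <- randomPose(toy$atoms, seed = 9)
  expect_equal(vol(orientStructure(posed)), vol(posed), tolerance = 1e-6)
})

test_that("orientStructure rejects degenerate inputs", {
  one <- makeStub(matrix(c(0, 0, 0), 1))
  expect_error(orientStructure(one), "at least 2 residues")
  coincident <- makeStub(rbind(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)))
  expect_error(orientStructure(coincident), "degenerate")
})

test_that("two-residue stub ends on the z-axis, residue 1 lower", {
  stub <- makeStub(rbind(c(3, -2, 7), c(4, 5, 9)))
  out <- orientStructure(stub)
  expect_lt(max(abs(out[, c("x", "y")])), 1e-6)
  expect_lt(out$z[1], out$z[2])
})

test_that("buildHelix uses canonical 1.5 A rise / 100 degree twist", {
  h10 <- buildHelix(10)
  expect_equal(h10$z[10] - h10$z[1], 13.5)  # 9 x 1.5 A
  h2 <- buildHelix(2)
  expect_equal(h2$z[2] - h2$z[1], 1.5)
  az <- atan2(h2$y, h2$x) * 180 / pi
  expect_equal((az[2] - az[1]) %% 360, 100)
  h1 <- buildHelix("M")
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$z, 0)
  expect_equal(h1$resname, "MET")
  expect_error(buildHelix(0), "at least one residue")
})

test_that("buildLinker applies the 3.5 A per missing residue rule", {
  toy <- makeToyStructure(seed = 1)
  core <- orientStructure(toy$atoms)
  p0 <- as.numeric(core[core$elety == "BB", c("x", "y", "z")][1, ])
  for (n in c(10L, 20L)) {
    lk <- buildLinker(core, n, cysResno = 1L)
    expect_equal(sqrt(sum((lk$cysPosition - p0)^2)), n * 3.5)
    expect_equal(nrow(lk$tether), n + 1L)  # cysteine + linker residues
    expect_equal(lk$tether$resname[1], "CYS")
  }
  # degenerate case: no missing residues, one peptide-unit spacing
  lk0 <- buildLinker(core, 0L, cysResno = 1L)
  expect_equal(sqrt(sum((lk0$cysPosition - p0)^2)), 3.5)
  expect_equal(nrow(lk0$tether), 1L)
})

test_that("linker paths are self-avoiding, clash-free and seeded", {
  toy <- makeToyStructure(seed = 2)
  core <- orientStructure(toy$atoms)
  lk <- buildLinker(core, 12L, cysResno = 1L, seed = 4L)
  pts <- as.matrix(lk$tether[, c("x", "y", "z")])
  coreBB <- as.matrix(core[core$elety == "BB", c("x", "y", "z")])
  d <- as.matrix(dist(rbind(pts, coreBB)))
  diag(d) <- Inf
  nT <- nrow(pts)
  for (a in seq_len(nT - 1L)) d[a, a + 1L] <- d[a + 1L, a] <- Inf
  # consecutive tether-core junction is bonded, not a clash
  d[nT, nT + 1L] <- d[nT + 1L, nT] <- Inf
  expect_gte(min(d[seq_len(nT), ]), 3.0 - 1e-6)
  # determinism under seed
  lk2 <- buildLinker(core, 12L, cysResno = 1L, seed = 4L)
  expect_identical(lk$tether, lk2$tether)
  lk3 <- buildLinker(core, 12L, cysResno = 1L, seed = 5L)
  expect_false(identical(lk$tether, lk3$tether))
})

test_that("assembleState composes helix, linker and core per state", {
  toy <- makeToyStructure(nResidues = 40L, missingNTerminal = 8L,
                          cysPosition = 12L, seed = 6)
  core <- orientStructure(toy$atoms)
  seqs <- toy$sequence

  tri <- assembleState(core, toy$match, "TRI", seqs, orient = FALSE)
  expect_s4_class(tri, "LipoproteinModel")
  expect_identical(anchorType(tri), "triacyl")
  a <- atomRecords(tri)
  expect_equal(min(a$resno), 12L)                 # first residue = cysteine
  expect_identical(a$resname[which.min(a$resno)], "CYS")
  # cysteine sits nLinker * 3.5 A below the core start
  cysZ <- a$z[a$resno == 12L & a$elety == "BB"]
  coreZ <- core$z[core$elety == "BB"][1]
  expect_equal(coreZ - cysZ, 8 * 3.5)

  di <- assembleState(core, toy$match, "DI", seqs, orient = FALSE)
  expect_identical(anchorType(di), "diacyl")

  sp <- assembleState(core, toy$match, "SP", seqs, orient = FALSE)
  expect_identical(anchorType(sp), "none")
  asp <- atomRecords(sp)
  expect_equal(min(asp$resno), 1L)                # SP N terminus
  # the helix spans residue 1 to the cysteine, below the cysteine anchor
  helixZ <- asp$z[asp$resno == 1L & asp$elety == "BB"]
  expect_lt(helixZ, cysZ)

  un <- assembleState(core, toy$match, "UNTETHERED", seqs, orient = FALSE)
  expect_identical(anchorType(un), "none")
  expect_equal(atomRecords(un), core)

  # round trip: model residues = tether residues + core residues, disjoint
  expect_setequal(unique(atomRecords(tri)$resno),
                  c(tri@tetherResnos, unique(core$resno)))
  expect_length(intersect(tri@tetherResnos, core$resno), 0L)
})

test_that("assembleState flags over-long linkers and numbering overlaps", {
  toy <- makeToyStructure(nResidues = 60L, missingNTerminal = 40L,
                          cysPosition = 4L, seed = 8)
  core <- orientStructure(toy$atoms)
  expect_warning(assembleState(core, toy$match, "TRI", toy$sequence,
                               orient = FALSE),
                 "35-residue")
  # cysteine inside the resolved region -> overlap error
  badMatch <- data.frame(cys_position = 50L)
  expect_error(assembleState(core, badMatch, "TRI", toy$sequence,
                             orient = FALSE), "overlap")
})

test_that("models survive PDB and GRO round trips", {
  toy <- makeToyStructure(seed = 10)
  core <- orientStructure(toy$atoms)
  tri <- assembleState(core, toy$match, "TRI", toy$sequence, orient = FALSE)
  pdb <- tempfile(fileext = ".pdb")
  writeStructurePDB(tri, pdb)
  back <- readStructurePDB(pdb)
  a <- atomRecords(tri)
  expect_equal(nrow(back), nrow(a))
  expect_equal(back$resno, a$resno)
  # PDB coordinates carry 3 decimals
  expect_equal(back$x, a$x, tolerance = 1e-3)
  gro <- tempfile(fileext = ".gro")
  writeStructureGRO(tri, gro, box = c(100, 100, 150))
  lines <- readLines(gro)
  expect_equal(as.integer(trimws(lines[2])), nrow(a))
  # nm conversion: first bead x field = Angstrom / 10
  x1 <- as.numeric(substr(lines[3], 21, 28))
  expect_equal(x1, a$x[1] / 10, tolerance = 1e-3)
})
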