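test_that("the 6 Angstrom contact boundary is honoured", {
  inP <- contactProfile(oneBeadTraj(5.9))
  expect_equal(unname(contactCounts(inP)[1, "PO4"]), 1L)
  expect_equal(sum(contactCounts(inP)), 1L)
  outP <- contactProfile(oneBeadTraj(6.1))
  expect_equal(sum(contactCounts(outP)), 0L)
})

test_that("contacts use minimum-image distances across the box", {
  # 58 apart in a 60 box = 2 Angstrom through the boundary
  wrapped <- contactProfile(oneBeadTraj(58))
  expect_equal(unname(contactCounts(wrapped)[1, "PO4"]), 1L)
})

test_that("contactProfile equals the brute-force periodic oracle", {
  gt <- data.frame(resid = c(2L, 2L, 5L, 7L),
                   class = c("PO4", "Tail", "GL0", "NH3"),
                   count = c(3L, 1L, 2L, 4L))
  fx <- makeMembraneTrajectory(gt, nResidues = 8L, nFrames = 3L, seed = 21)
  prof <- contactProfile(fx$trajectory)
  expect_equal(contactCounts(prof), oracleContacts(fx$trajectory))
  expect_equal(nFrames(prof), 3L)
})

test_that("fixture ground truth is recovered exactly", {
  gt <- data.frame(resid = 5L, class = "PO4", count = 3L)
  fx <- makeMembraneTrajectory(gt, nResidues = 6L, nFrames = 2L, seed = 2)
  prof <- contactProfile(fx$trajectory)
  expect_equal(contactCounts(prof), fx$expectedCounts)
  # all-zero request gives a zero profile
  fx0 <- makeMembraneTrajectory(gt[0, ], nResidues = 4L, nFrames = 2L,
                                seed = 3)
  expect_equal(sum(contactCounts(contactProfile(fx0$trajectory))), 0L)
  expect_error(makeMembraneTrajectory(
    data.frame(resid = 99L, class = "PO4", count = 1L), nResidues = 4L),
    "outside the protein")
})

test_that("contactProfile validates selections and box size", {
  atoms <- data.frame(name = "BB", resid = 1L, resname = "ALA",
                      segment = "protein", class = NA_character_)
  noLipid <- newCGTrajectory(list(matrix(0, 1, 3)), c(50, 50, 50), atoms)
  expect_error(contactProfile(noLipid), "empty lipid")
  tiny <- oneBeadTraj(2, box = c(4, 60, 60))
  expect_error(contactProfile(tiny), "box smaller")
})

test_that("replicate correlation hits the documented endpoints", {
  gt <- data.frame(resid = 1:4, class = "PO4", count = c(5L, 1L, 3L, 0L))
  fx <- makeMembraneTrajectory(gt, nResidues = 4L, nFrames = 1L, seed = 4)
  p1 <- contactProfile(fx$trajectory)
  # identical profiles correlate at exactly 1
  m <- replicateCorrelation(list(p1, p1))
  expect_equal(unname(m[1, 2]), 1.0)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c("1" = 1, "2" = 1))
  # jittered replicate from the same ground truth still correlates at 1
  fx2 <- makeMembraneTrajectory(gt, nResidues = 4L, nFrames = 1L, seed = 44)
  p2 <- contactProfile(fx2$trajectory)
  expect_equal(unname(replicateCorrelation(list(p1, p2))[1, 2]), 1.0)
  # anti-correlated footprint: reflect the counts about their midrange
  negCounts <- contactCounts(p1)
  tot <- rowSums(negCounts)
  negCounts[, "PO4"] <- max(tot) + min(tot) - negCounts[, "PO4"]
  neg <- new("ContactProfile", counts = negCounts, resids = p1@resids,
             resnames = p1@resnames, nFrames = p1@nFrames,
             cutoff = p1@cutoff)
  expect_equal(unname(replicateCorrelation(list(p1, neg))[1, 2]), -1.0)
})

test_that("zero-variance profiles give missing correlations, not zero", {
  gt <- data.frame(resid = 1:3, class = "PO4", count = c(2L, 2L, 2L))
  fx <- makeMembraneTrajectory(gt, nResidues = 3L, nFrames = 1L, seed = 5)
  flat <- contactProfile(fx$trajectory)
  gt2 <- data.frame(resid = 1:3, class = "PO4", count = c(1L, 2L, 3L))
  vary <- contactProfile(makeMembraneTrajectory(gt2, nResidues = 3L,
                                                nFrames = 1L,
                                                seed = 6)$trajectory)
  m <- replicateCorrelation(list(flat, vary))
  expect_true(is.na(m[1, 2]))
  expect_equal(diag(m), c("1" = 1, "2" = 1))
})

test_that("binding-mode classification matches single-linkage oracle", {
  # block structure: replicates 1-4 mutually high, replicate 5 apart
  m <- matrix(-0.5, 5, 5)
  m[1:4, 1:4] <- 0.9
  diag(m) <- 1
  modes <- classifyBindingModes(m, threshold = 0.5)
  expect_equal(modes$mode, c(1L, 1L, 1L, 1L, 2L))
  expect_equal(modes$mode, oracleSingleLinkage(m, 0.5))
  # all mutually similar: a single mode of size 5
  all1 <- matrix(0.9, 5, 5); diag(all1) <- 1
  expect_equal(classifyBindingModes(all1)$mode, rep(1L, 5))
  # threshold 1 on noisy data: singletons
  set.seed(8)
  noisy <- matrix(runif(25, -0.9, 0.99), 5, 5)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 1
  expect_equal(sort(classifyBindingModes(noisy, threshold = 1)$mode), 1:5)
  # random symmetric matrices agree with the oracle
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:8, 1)
    mm <- matrix(runif(n * n, -1, 1), n, n)
    mm <- (mm + t(mm)) / 2; diag(mm) <- 1
    expect_equal(classifyBindingModes(mm, 0.3)$mode,
                 oracleSingleLinkage(mm, 0.3), info = s)
  }
})

test_that("correlation matrices are permutation-equivariant", {
  gts <- lapply(1:3, function(k)
    data.frame(resid = 1:5, class = "Tail",
               count = as.integer(c(k, 5 - k, 2, k + 1, 1))))
  profs <- lapply(seq_along(gts), function(k)
    contactProfile(makeMembraneTrajectory(gts[[k]], nResidues = 5L,
                                          nFrames = 1L,
                                          seed = k)$trajectory))
  m <- replicateCorrelation(profs)
  perm <- c(3, 1, 2)
  mp <- replicateCorrelation(profs[perm])
  expect_equal(unname(mp), unname(m[perm, perm]))
})

test_that("residue-class enrichment aggregates over proteins", {
  gt <- data.frame(resid = 2L, class = "Tail", count = 10L)
  fx <- makeMembraneTrajectory(gt, nResidues = 3L,
                               resnames = c("GLY", "PHE", "GLY"),
                               nFrames = 1L, seed = 7)
  p <- contactProfile(fx$trajectory)
  e <- residueClassEnrichment(list(p))
  expect_equal(unname(e["PHE", "Tail"]), 10)
  expect_equal(sum(e) - e["PHE", "Tail"], 0)  # everything else zero
  # two proteins: aggregate equals concatenate-then-group, order-invariant
  gt2 <- data.frame(resid = 1L, class = "Tail", count = 4L)
  p2 <- contactProfile(makeMembraneTrajectory(
    gt2, nResidues = 2L, resnames = c("PHE", "GLY"), nFrames = 1L,
    seed = 9)$trajectory)
  e12 <- residueClassEnrichment(list(p, p2))
  expect_equal(unname(e12["PHE", "Tail"]), (10 + 4) / 2)
  expect_equal(residueClassEnrichment(list(p2, p)), e12)
})
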