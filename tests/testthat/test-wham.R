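kB <- 0.0083144621

test_that("a single unbiased window reduces to Boltzmann inversion", {
  set.seed(31)
  samples <- rnorm(20000, 0.5, 0.12)
  w <- umbrellaWindow(0, 0, samples, temperature = 310)
  prof <- whamEstimate(list(w), bins = 60)
  oracle <- oracleBoltzmannInvert(samples, 60, kB * 310)
  expect_identical(freeEnergy(prof), oracle)   # bit-for-bit
  expect_equal(prof@iterations, 1L)
})

test_that("an unbiased flat sampler yields a flat profile", {
  set.seed(32)
  w <- umbrellaWindow(0, 0, runif(50000), temperature = 310)
  prof <- whamEstimate(list(w), bins = 20)
  g <- freeEnergy(prof)
  # anchored range of pure counting noise: per-bin SE is kT/sqrt(2500)
  # = 0.05 kJ/mol, so the min-to-max spread stays well under 7 SE
  expect_lt(max(g, na.rm = TRUE), 0.35)
})

test_that("WHAM recovers a harmonic potential from exact biased samples", {
  fx <- makeUmbrellaSamples("harmonic", kappa = 10,
                            centers = seq(-1.2, 1.2, 0.1),
                            nPerWindow = 20000, seed = 33)
  prof <- whamEstimate(fx$windows)
  sel <- reactionCoord(prof) >= -1.2 & reactionCoord(prof) <= 1.2 &
    is.finite(freeEnergy(prof))
  xi <- reactionCoord(prof)[sel]
  gTrue <- fx$analyticG(xi)
  expect_lt(max(abs(freeEnergy(prof)[sel] - gTrue)), 0.5)
  # unbiased probabilities are normalised
  expect_equal(sum(prof@prob, na.rm = TRUE), 1)
})

test_that("bias gauge invariance: shifting all centers shifts G rigidly", {
  fx <- makeUmbrellaSamples("harmonic", kappa = 20,
                            centers = seq(-0.8, 0.8, 0.1),
                            nPerWindow = 5000, seed = 34)
  prof <- whamEstimate(fx$windows)
  shifted <- lapply(fx$windows, function(w)
    umbrellaWindow(w@center + 2.5, w@forceConstant, w@samples + 2.5,
                   w@temperature))
  prof2 <- whamEstimate(shifted)
  expect_equal(reactionCoord(prof2), reactionCoord(prof) + 2.5,
               tolerance = 1e-9)
  expect_equal(freeEnergy(prof2), freeEnergy(prof), tolerance = 1e-6)
})

test_that("duplicating a window barely perturbs the estimate", {
  fx <- makeUmbrellaSamples("harmonic", kappa = 15,
                            centers = seq(-0.6, 0.6, 0.1),
                            nPerWindow = 20000, seed = 35)
  prof <- whamEstimate(fx$windows, bins = 80)
  dup <- c(fx$windows, fx$windows[7])
  prof2 <- whamEstimate(dup, bins = 80)
  # exact invariance holds only when empirical histograms equal their
  # biased expectations; with 2e4 exact samples the residual is bounded by
  # the per-window sampling noise (~0.1 kJ/mol here)
  ok <- is.finite(freeEnergy(prof)) & is.finite(freeEnergy(prof2))
  expect_lt(max(abs(freeEnergy(prof)[ok] - freeEnergy(prof2)[ok])), 0.3)
})

test_that("disconnected windows and runaway iteration are reported", {
  set.seed(36)
  wA <- umbrellaWindow(0, 1000, rnorm(500, 0, 0.05))
  wB <- umbrellaWindow(5, 1000, rnorm(500, 5, 0.05))
  expect_error(whamEstimate(list(wA, wB)), "non-overlapping")
  fx <- makeUmbrellaSamples("harmonic", kappa = 10,
                            centers = seq(-0.5, 0.5, 0.1),
                            nPerWindow = 2000, seed = 37)
  expect_error(whamEstimate(fx$windows, maxIter = 2), "did not converge")
  mixed <- fx$windows
  mixed[[1]]@temperature <- 400
  expect_error(whamEstimate(mixed), "one temperature")
})

test_that("histogram overlap hits its closed-form endpoints", {
  set.seed(38)
  s <- rnorm(2000, 1, 0.1)
  wA <- umbrellaWindow(1, 100, s)
  wB <- umbrellaWindow(1.001, 100, s)  # identical histograms
  expect_equal(histogramOverlap(list(wA, wB))$overlap, 1.0)
  wC <- umbrellaWindow(9, 100, rnorm(2000, 9, 0.1))
  expect_equal(histogramOverlap(list(wA, wC), bins = 50)$overlap, 0.0)
  # half-shifted top-hats: overlap exactly 0.5
  wD <- umbrellaWindow(0.5, 0, c(rep(0.25, 60), rep(0.75, 60)))
  wE <- umbrellaWindow(0.75, 0, c(rep(0.75, 60), rep(1.25, 60)))
  expect_equal(histogramOverlap(list(wD, wE), bins = 10)$overlap, 0.5)
  # pairs are ordered by center
  ov <- histogramOverlap(list(wC, wA, wB))
  expect_equal(ov$windowA, c(2L, 3L))
  expect_equal(ov$windowB, c(3L, 1L))
})

test_that("Bayesian bootstrap errors are seeded, non-negative and sane", {
  fx <- makeUmbrellaSamples("harmonic", kappa = 20,
                            centers = seq(-0.5, 0.5, 0.1),
                            nPerWindow = 4000, seed = 39)
  e1 <- bootstrapErrors(fx$windows, nBoot = 30, seed = 7)
  e2 <- bootstrapErrors(fx$windows, nBoot = 30, seed = 7)
  expect_identical(bootstrapError(e1), bootstrapError(e2))
  e3 <- bootstrapErrors(fx$windows, nBoot = 30, seed = 8)
  expect_false(identical(bootstrapError(e1), bootstrapError(e3)))
  err <- bootstrapError(e1)
  expect_true(all(err[is.finite(err)] >= 0))
  expect_equal(attr(e1, "failureRate"), 0)
  # errors shrink with sample size (statistical consistency)
  fxBig <- makeUmbrellaSamples("harmonic", kappa = 20,
                               centers = seq(-0.5, 0.5, 0.1),
                               nPerWindow = 40000, seed = 40)
  eBig <- bootstrapErrors(fxBig$windows, nBoot = 30, seed = 7)
  expect_lt(median(bootstrapError(eBig), na.rm = TRUE),
            median(err, na.rm = TRUE))
})

test_that("convergence diagnostics separate stationary from drifting data", {
  fx <- makeUmbrellaSamples("harmonic", kappa = 15,
                            centers = seq(-0.6, 0.6, 0.1),
                            nPerWindow = 8000, seed = 41)
  conv <- convergenceCheck(fx$windows, nFractions = 2)
  expect_length(conv$profiles, 2L)
  expect_lt(conv$maxDeviation, 1.0)
  one <- convergenceCheck(fx$windows, nFractions = 1)
  expect_equal(one$maxDeviation, 0)
  # generator-injected drift: second half sampled from a different potential
  fx2 <- makeUmbrellaSamples("harmonic", kappa = 60,
                             centers = seq(-0.6, 0.6, 0.1),
                             nPerWindow = 8000, seed = 42)
  drifting <- Map(function(a, b)
    umbrellaWindow(a@center, a@forceConstant,
                   c(a@samples[1:4000], b@samples[1:4000]), a@temperature),
    fx$windows, fx2$windows)
  convDrift <- convergenceCheck(drifting, nFractions = 2)
  expect_gt(convDrift$maxDeviation, conv$maxDeviation * 2)
  expect_error(convergenceCheck(fx$windows, nFractions = 1e6),
               "at least nFractions")
})

test_that("extraction free energy reads plateau minus minimum", {
  xi <- seq(0, 3, by = 0.02)
  g <- 115 * (1 - exp(-3 * xi))^2
  g <- g - min(g)
  prof <- new("PMFProfile", xi = xi, G = g, err = rep(NA_real_, length(xi)),
              prob = rep(1 / length(xi), length(xi)), offsets = 0,
              iterations = 1L, temperature = 310)
  dG <- extractionFreeEnergy(prof, c(2.5, 3))
  expect_equal(as.numeric(dG), 115, tolerance = 0.01)
  expect_lt(attr(dG, "flatness"), 0.2)
  # flat profile: zero extraction cost
  flat <- new("PMFProfile", xi = xi, G = rep(0, length(xi)),
              err = rep(NA_real_, length(xi)),
              prob = rep(1 / length(xi), length(xi)), offsets = 0,
              iterations = 1L, temperature = 310)
  expect_equal(as.numeric(extractionFreeEnergy(flat, c(2, 3))), 0)
  # double well: measured from the global, not local, minimum
  g2 <- 40 * (xi^2 - 1)^2
  g2[xi > 2] <- g2[xi <= 2][sum(xi <= 2)]
  g2 <- g2 - min(g2)
  prof2 <- new("PMFProfile", xi = xi, G = g2,
               err = rep(NA_real_, length(xi)),
               prob = rep(1 / length(xi), length(xi)), offsets = 0,
               iterations = 1L, temperature = 310)
  dG2 <- suppressWarnings(extractionFreeEnergy(prof2, c(2.5, 3)))
  expect_equal(as.numeric(dG2), g2[length(g2)])
  # sloped plateau attaches a warning; outside support errors
  expect_warning(extractionFreeEnergy(prof, c(0.2, 3)), "not flat")
  expect_error(extractionFreeEnergy(prof, c(5, 6)), "outside")
})

test_that("window files and manifests round-trip", {
  fx <- makeUmbrellaSamples("harmonic", kappa = 10,
                            centers = seq(0, 0.3, 0.1),
                            nPerWindow = 50, seed = 43)
  dir <- file.path(tempdir(), "windows-rt")
  manifest <- writeUmbrellaWindows(fx$windows, dir)
  back <- readUmbrellaWindows(manifest)
  expect_length(back, length(fx$windows))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]@center, fx$windows[[k]]@center)
    expect_equal(back[[k]]@samples, fx$windows[[k]]@samples,
                 tolerance = 1e-9)
  }
})
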