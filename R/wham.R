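## Weighted histogram analysis of umbrella-sampling windows: PMF profiles,
## Bayesian-bootstrap errors, overlap and convergence diagnostics, and
## extraction free energies.

#' Construct an UmbrellaWindow
#'
#' @param center harmonic bias center (nm)
#' @param forceConstant bias force constant (kJ mol^-1 nm^-2); 0 = unbiased
#' @param samples reaction-coordinate samples (nm)
#' @param temperature temperature (K)
#' @return an \linkS4class{UmbrellaWindow}
#' @export
umbrellaWindow <- function(center, forceConstant, samples,
                           temperature = 310) {
  new("UmbrellaWindow", center = center, forceConstant = forceConstant,
      samples = as.numeric(samples), temperature = temperature)
}

## Shared histogram bin edges over the sampled range.
.whamBins <- function(windows, bins) {
  rng <- range(unlist(lapply(windows, function(w) range(w@samples))))
  if (identical(bins, "auto")) {
    bins <- max(10L, ceiling(diff(rng) / 0.02))  # one bin per 0.02 nm
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  ## open the last edge a hair so max samples land in the last bin
  edges[length(edges)] <- edges[length(edges)] + 1e-12
  edges
}

.histCounts <- function(samples, edges) {
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= length(edges) - 1L]
  tabulate(idx, nbins = length(edges) - 1L)
}

## Core WHAM iteration on precomputed histograms.
## countsMat: nWindows x nBins; N: effective window sample counts (may be
## fractional under bootstrap weights); biasMat: nWindows x nBins bias
## energies w_i(xi_b) in kJ/mol.
.whamSolve <- function(countsMat, N, biasMat, kT, tol, maxIter) {
  nWin <- nrow(countsMat); nBins <- ncol(countsMat)
  totalCounts <- colSums(countsMat)
  sampled <- totalCounts > 0
  logNum <- ifelse(sampled, log(totalCounts), -Inf)
  F <- numeric(nWin)
  logB <- -biasMat / kT                      # nWin x nBins, fixed
  logN <- log(N)
  iter <- 0L
  logBs <- logB[, sampled, drop = FALSE]
  repeat {
    iter <- iter + 1L
    ## log denominator per bin: logsumexp_i [ log N_i + (F_i - w_ib)/kT ]
    A <- logB + (logN + F / kT)              # column-recycled over bins
    m <- as.numeric(do.call(pmax, asplit(A, 1L)))
    logDen <- m + log(colSums(exp(sweep(A, 2L, m, "-"))))
    logPraw <- logNum - logDen
    ## normalise P over sampled bins
    logP <- logPraw - .logsumexp(logPraw[sampled])
    ## window offsets: F_i = -kT log sum_b P_b exp(-w_ib/kT)
    B2 <- sweep(logBs, 2L, logP[sampled], "+")
    mr <- as.numeric(do.call(pmax, asplit(B2, 2L)))
    Fnew <- -kT * (mr + log(rowSums(exp(B2 - mr))))
    Fnew <- Fnew - Fnew[1L]                  # gauge: anchor first window
    delta <- max(abs(Fnew - F))
    F <- Fnew
    if (delta < tol) break
    if (iter >= maxIter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                   maxIter, delta), call. = FALSE)
  }
  P <- exp(logP)
  P[!sampled] <- NA_real_
  ## logPraw differs from logP by a constant; it is returned so the free
  ## energy can be formed without the normalisation constant touching the
  ## anchored profile
  list(P = P, logP = logPraw, F = F, iterations = iter)
}

#' Estimate a potential of mean force by WHAM
#'
#' Solves the weighted-histogram self-consistency equations
#' \deqn{P(\xi) = \frac{\sum_i n_i(\xi)}{\sum_i N_i \exp[(F_i - w_i(\xi))/kT]},
#'   \quad F_i = -kT \ln \sum_\xi P(\xi) e^{-w_i(\xi)/kT}}
#' with harmonic biases \eqn{w_i(\xi) = k_i (\xi - \xi_i)^2 / 2}, iterating
#' until the window offsets change by less than \code{tol}. The free energy
#' \eqn{G(\xi) = -kT \ln P(\xi)} is anchored at zero at its minimum.
#'
#' @param windows list of \linkS4class{UmbrellaWindow} at one temperature
#' @param bins number of histogram bins, or "auto" (one per 0.02 nm)
#' @param tol convergence tolerance on the offsets F_i (kJ/mol)
#' @param maxIter iteration cap; exceeded = error with the last residual
#' @param minOverlap adjacent-window histogram overlap below which the
#'   estimate is refused (disconnected support)
#' @return a \linkS4class{PMFProfile}
#' @export
whamEstimate <- function(windows, bins = "auto", tol = 1e-6,
                         maxIter = 1e5, minOverlap = 1e-6) {
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, is, logical(1), "UmbrellaWindow")))
  temps <- vapply(windows, function(w) w@temperature, numeric(1))
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature", call. = FALSE)
  kT <- .kT(temps[1])
  edges <- .whamBins(windows, bins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  countsMat <- t(vapply(windows, function(w) .histCounts(w@samples, edges),
                        integer(length(centers))))
  if (length(windows) > 1L) {
    ov <- histogramOverlap(windows, bins = length(centers))
    if (any(ov$overlap < minOverlap))
      stop("non-overlapping window histograms (overlap ",
           paste(signif(ov$overlap[ov$overlap < minOverlap], 2),
                 collapse = ", "),
           "); inspect histogramOverlap() before estimating", call. = FALSE)
  }
  biasMat <- t(vapply(windows, function(w)
    0.5 * w@forceConstant * (centers - w@center)^2, numeric(length(centers))))
  N <- vapply(windows, function(w) length(w@samples), numeric(1))
  sol <- .whamSolve(countsMat, N, biasMat, kT, tol, maxIter)
  G <- -kT * sol$logP
  G[is.na(sol$P)] <- NA_real_
  G <- G - min(G, na.rm = TRUE)
  new("PMFProfile", xi = centers, G = G,
      err = rep(NA_real_, length(centers)), prob = sol$P, offsets = sol$F,
      iterations = sol$iterations, temperature = temps[1])
}

#' Bayesian-bootstrap standard errors for a WHAM profile
#'
#' Each replicate reweights whole windows (trajectories) by unit-mean
#' Dirichlet weights and re-solves WHAM; per-bin errors are the standard
#' deviation of the re-anchored profiles across replicates. Deterministic
#' given the seed. Replicates in which the estimator fails are dropped and
#' counted.
#'
#' @param windows list of \linkS4class{UmbrellaWindow}
#' @param nBoot number of bootstrap replicates (>= 2)
#' @param seed RNG seed
#' @param bins,tol,maxIter estimator settings, as in
#'   \code{\link{whamEstimate}}
#' @return a \linkS4class{PMFProfile} whose \code{err} slot carries the
#'   per-bin standard errors; attribute "failureRate" reports the dropped
#'   fraction
#' @export
bootstrapErrors <- function(windows, nBoot = 200, seed = 1L, bins = "auto",
                            tol = 1e-6, maxIter = 1e5) {
  stopifnot(nBoot >= 2L)
  base <- whamEstimate(windows, bins = bins, tol = tol, maxIter = maxIter)
  kT <- .kT(base@temperature)
  edges <- .whamBins(windows, bins)
  centers <- base@xi
  countsMat <- t(vapply(windows, function(w) .histCounts(w@samples, edges),
                        integer(length(centers))))
  biasMat <- t(vapply(windows, function(w)
    0.5 * w@forceConstant * (centers - w@center)^2,
    numeric(length(centers))))
  N0 <- vapply(windows, function(w) length(w@samples), numeric(1))
  nWin <- length(windows)
  ## unit-mean Dirichlet(1,...,1) weights over windows, one row per replicate
  W <- .withSeed(seed, matrix(-log(stats::runif(nBoot * nWin)), nBoot, nWin))
  W <- W / rowMeans(W)
  Gboot <- matrix(NA_real_, nBoot, length(centers))
  failed <- 0L
  for (b in seq_len(nBoot)) {
    g <- W[b, ]
    res <- tryCatch(
      .whamSolve(countsMat * g, N0 * g, biasMat, kT, tol, maxIter),
      error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    G <- -kT * res$logP
    G[is.na(res$P)] <- NA_real_
    Gboot[b, ] <- G - min(G, na.rm = TRUE)
  }
  err <- apply(Gboot, 2L, stats::sd, na.rm = TRUE)
  out <- new("PMFProfile", xi = centers, G = base@G, err = err,
             prob = base@prob, offsets = base@offsets,
             iterations = base@iterations, temperature = base@temperature)
  attr(out, "failureRate") <- failed / nBoot
  out
}

#' Histogram overlap of adjacent umbrella windows
#'
#' Overlap of two windows is the summed bin-wise minimum of their normalised
#' histograms (1 = identical, 0 = disjoint support). Windows are paired by
#' ascending center.
#'
#' @param windows list of \linkS4class{UmbrellaWindow} (>= 2)
#' @param bins shared histogram bin count or "auto"
#' @return data.frame: windowA, windowB (ascending-center indices), overlap
#' @export
histogramOverlap <- function(windows, bins = "auto") {
  stopifnot(length(windows) >= 2L)
  edges <- .whamBins(windows, bins)
  ord <- order(vapply(windows, function(w) w@center, numeric(1)))
  H <- lapply(windows[ord], function(w) {
    h <- .histCounts(w@samples, edges)
    h / sum(h)
  })
  n <- length(H)
  data.frame(
    windowA = ord[seq_len(n - 1L)], windowB = ord[2L:n],
    overlap = vapply(seq_len(n - 1L), function(a)
      sum(pmin(H[[a]], H[[a + 1L]])), numeric(1)))
}

#' Convergence check over consecutive time fractions
#'
#' Splits every window's samples into consecutive fractions, estimates a
#' profile per fraction, re-anchors each at its minimum, and reports the
#' maximum pairwise per-bin deviation. Bins empty in some fraction are
#' flagged and excluded from the deviation.
#'
#' @param windows list of \linkS4class{UmbrellaWindow}
#' @param nFractions number of consecutive fractions (>= 1)
#' @param bins,tol,maxIter estimator settings
#' @return list with profiles (list of \linkS4class{PMFProfile}),
#'   maxDeviation (kJ/mol), and flaggedBins (bins empty in some fraction)
#' @export
convergenceCheck <- function(windows, nFractions, bins = "auto",
                             tol = 1e-6, maxIter = 1e5) {
  stopifnot(nFractions >= 1L)
  if (any(vapply(windows, function(w) length(w@samples), integer(1)) <
          nFractions))
    stop("every window needs at least nFractions samples", call. = FALSE)
  edges <- .whamBins(windows, bins)
  nb <- length(edges) - 1L
  profiles <- lapply(seq_len(nFractions), function(f) {
    sub <- lapply(windows, function(w) {
      n <- length(w@samples)
      lo <- floor((f - 1) * n / nFractions) + 1L
      hi <- floor(f * n / nFractions)
      umbrellaWindow(w@center, w@forceConstant, w@samples[lo:hi],
                     w@temperature)
    })
    whamEstimate(sub, bins = nb, tol = tol, maxIter = maxIter)
  })
  ## deviations on a common grid: all fractions were binned over their own
  ## sampled range, so interpolate onto the first fraction's grid; only the
  ## planned window range is compared (tail bins beyond the outermost
  ## centers hold a handful of transient samples and carry no signal)
  ref <- profiles[[1]]
  Gmat <- vapply(profiles, function(p)
    stats::approx(p@xi, p@G, xout = ref@xi, rule = 1)$y,
    numeric(length(ref@xi)))
  flagged <- which(rowSums(is.na(Gmat)) > 0)
  centers <- vapply(windows, function(w) w@center, numeric(1))
  inPlan <- ref@xi >= min(centers) & ref@xi <= max(centers)
  maxDev <- 0
  if (nFractions > 1L) {
    ok <- rowSums(is.na(Gmat)) == 0 & inPlan
    for (a in seq_len(nFractions - 1L)) for (b in (a + 1L):nFractions)
      maxDev <- max(maxDev, max(abs(Gmat[ok, a] - Gmat[ok, b])))
  }
  list(profiles = profiles, maxDeviation = maxDev, flaggedBins = flagged)
}

#' Extraction free energy from a PMF profile
#'
#' The extraction free energy is the mean profile value over the plateau
#' region (bulk water, far from membrane or cavity) minus the profile
#' minimum; since profiles are anchored at zero this is the mean plateau
#' value. A plateau whose flatness (max - min over the region) exceeds
#' \code{flatTol} attaches a warning.
#'
#' @param profile a \linkS4class{PMFProfile}
#' @param plateauRegion reaction-coordinate range c(min, max) of the plateau
#' @param flatTol plateau flatness above which a warning is attached
#'   (kJ/mol)
#' @return extraction free energy (kJ/mol) with attribute "flatness"
#' @export
extractionFreeEnergy <- function(profile, plateauRegion, flatTol = 5) {
  stopifnot(is(profile, "PMFProfile"), length(plateauRegion) == 2L)
  sel <- profile@xi >= plateauRegion[1] & profile@xi <= plateauRegion[2] &
    is.finite(profile@G)
  if (!any(sel))
    stop("plateau region outside the profile support", call. = FALSE)
  g <- profile@G[sel]
  flat <- max(g) - min(g)
  if (flat > flatTol)
    warning(sprintf("plateau not flat: spread %.2f kJ/mol over the region",
                    flat), call. = FALSE)
  out <- mean(g)
  attr(out, "flatness") <- flat
  out
}

#' Read umbrella windows from a manifest and per-window sample files
#'
#' The manifest is a TSV with columns file, center, force_constant and
#' optionally temperature; each window file holds (time, xi) columns of
#' reaction-coordinate samples, the conventional pull-output layout.
#'
#' @param manifest manifest TSV path; window files resolve relative to it
#' @param temperature default temperature when the manifest lacks one
#' @return list of \linkS4class{UmbrellaWindow}
#' @export
readUmbrellaWindows <- function(manifest, temperature = 310) {
  df <- utils::read.table(manifest, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(r) {
    s <- utils::read.table(file.path(dir, df$file[r]), header = FALSE)
    umbrellaWindow(df$center[r], df$force_constant[r], s[[2]],
                   if ("temperature" %in% names(df)) df$temperature[r]
                   else temperature)
  })
}

#' Write umbrella windows and their manifest
#'
#' @param windows list of \linkS4class{UmbrellaWindow}
#' @param dir output directory (created if needed)
#' @return the manifest path
#' @export
writeUmbrellaWindows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.xvg", seq_along(windows))
  for (w in seq_along(windows)) {
    s <- windows[[w]]@samples
    utils::write.table(
      data.frame(time = seq_along(s), xi = s),
      file.path(dir, files[w]), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  manifest <- file.path(dir, "windows.tsv")
  utils::write.table(
    data.frame(file = files,
               center = vapply(windows, function(w) w@center, numeric(1)),
               force_constant = vapply(windows, function(w) w@forceConstant,
                                       numeric(1)),
               temperature = vapply(windows, function(w) w@temperature,
                                    numeric(1))),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Write a PMF profile as TSV (xi, G, err)
#'
#' @param profile a \linkS4class{PMFProfile}
#' @param path output file
#' @export
writePMFTSV <- function(profile, path) {
  utils::write.table(
    data.frame(xi_nm = profile@xi, G_kJmol = profile@G,
               err_kJmol = profile@err),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
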