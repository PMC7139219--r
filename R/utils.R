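## Shared constants and small numerical helpers.

#' Boltzmann constant in kJ mol^-1 K^-1
#' @keywords internal
.kB <- 0.0083144621

#' Thermal energy kT in kJ/mol at a given temperature
#' @param temperature temperature in Kelvin
#' @keywords internal
.kT <- function(temperature) .kB * temperature

## log(sum(exp(x))) without overflow; -Inf-safe.
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Largest-remainder apportionment of integer counts
#'
#' Distributes `total` units over categories in proportion to `fractions`,
#' rounding so the category counts sum exactly to `total`.
#'
#' @param fractions non-negative weights (normalised internally)
#' @param total integer total to apportion
#' @return integer vector of counts summing to `total`
#' @keywords internal
.largestRemainder <- function(fractions, total) {
  stopifnot(all(fractions >= 0), sum(fractions) > 0, total >= 0)
  p <- fractions / sum(fractions)
  raw <- p * total
  counts <- floor(raw)
  short <- total - sum(counts)
  if (short > 0) {
    rem <- raw - counts
    ord <- order(rem, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

## Pairwise minimum-image distances under an orthorhombic box.
## a: n x 3, b: m x 3, box: length-3 (same units); returns n x m matrix.
.pbcDistance <- function(a, b, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box) && is.finite(box[k]) && box[k] > 0) {
      dk <- dk - box[k] * round(dk / box[k])
    }
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

## Rotation matrix taking unit vector `from` onto unit vector `to`
## (Rodrigues). Degenerate antiparallel case handled via an orthogonal axis.
.rotationBetween <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  v <- c(f[2] * t[3] - f[3] * t[2],
         f[3] * t[1] - f[1] * t[3],
         f[1] * t[2] - f[2] * t[1])
  c_ <- sum(f * t)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## antiparallel: rotate pi about any axis orthogonal to f
    ax <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * f) * f
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2],
                v[3], 0, -v[1],
                -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

## Evaluate `code` under a fixed seed without disturbing the caller's RNG
## stream. The expression is evaluated in the caller's environment.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

.stopifnotScalarPositive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
  invisible(TRUE)
}
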