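# Density-normalized real spherical harmonics d_lm, l <= 4, and their
# behaviour under orthogonal coordinate changes.
#
# Convention: d_lm(theta, phi) = N_lm * P_l^|m|(cos theta) * T_m(phi) with
#   T_m = cos(m phi) for m > 0, sin(|m| phi) for m < 0, 1 for m = 0,
# associated Legendre functions WITHOUT the Condon-Shortley phase, and N_lm
# fixed by the density normalization of the Hansen-Coppens formalism:
#   integral |d_lm| dOmega = 2 for l > 0,   d_00 = 1/(4 pi).

# Exact density-normalization constants (closed forms in comments; the
# non-elementary ones are given to full double precision):
#   l=0:        1/(4 pi)
#   l=1, all m: 1/pi
#   (2,0): 3 sqrt(3)/(4 pi)   (2,1): 1/4          (2,2): 1/8
#   (3,0): 20/(13 pi)         (3,1): 0.2135553930559056 (root of an
#          arcsin-bearing closed form)             (3,2): 1/15
#   (3,3): 4/(45 pi)
#   (4,0): 0.5553401950750116 (4,1): 448 sqrt(7)/5347 - 343/10694
#   (4,2): 119 sqrt(7)/3252 - 343/6504  (4,3): 1/84  (4,4): 1/224
.shNormTable <- local({
  n <- matrix(NA_real_, nrow = 5, ncol = 5)  # [l+1, m+1]
  n[1, 1] <- 1 / (4 * pi)
  n[2, 1:2] <- 1 / pi
  n[3, 1:3] <- c(3 * sqrt(3) / (4 * pi), 1 / 4, 1 / 8)
  n[4, 1:4] <- c(20 / (13 * pi), 0.213555393055906, 1 / 15, 4 / (45 * pi))
  n[5, 1:5] <- c(0.555340195075012, 0.189601007547585, 0.044078845638587,
                 1 / 84, 1 / 224)
  n
})

# associated Legendre P_l^m(u) (no Condon-Shortley), s = sqrt(1 - u^2)
.assocLegendre <- function(l, m, u, s) {
  switch(paste(l, m),
    "0 0" = rep(1, length(u)),
    "1 0" = u,
    "1 1" = s,
    "2 0" = (3 * u^2 - 1) / 2,
    "2 1" = 3 * u * s,
    "2 2" = 3 * s^2,
    "3 0" = (5 * u^3 - 3 * u) / 2,
    "3 1" = 1.5 * (5 * u^2 - 1) * s,
    "3 2" = 15 * u * s^2,
    "3 3" = 15 * s^3,
    "4 0" = (35 * u^4 - 30 * u^2 + 3) / 8,
    "4 1" = 2.5 * (7 * u^3 - 3 * u) * s,
    "4 2" = 7.5 * (7 * u^2 - 1) * s^2,
    "4 3" = 105 * u * s^3,
    "4 4" = 105 * s^4,
    stop("unsupported (l, m)"))
}

#' Density-normalized real spherical harmonic
#'
#' Evaluates the real spherical harmonic \eqn{d_{lm}} in the density
#' normalization of the multipole formalism: \eqn{\int |d_{lm}|\,d\Omega = 2}
#' for \eqn{l > 0} and \eqn{d_{00} = 1/(4\pi)}.
#'
#' @param l Degree, integer 0..4.
#' @param m Order, integer \code{-l..l}; negative orders are the
#'   \eqn{\sin(|m|\phi)} partners.
#' @param direction Numeric length-3 unit vector, or an n-by-3 matrix of unit
#'   row vectors. Must be normalized to within 1e-8.
#' @return Numeric vector of values, one per direction.
#' @examples
#' realSH(1, 0, c(0, 0, 1))   #  1/pi
#' realSH(1, 0, c(0, 0, -1))  # -1/pi
#' @export
realSH <- function(l, m, direction) {
  if (length(l) != 1L || length(m) != 1L || l != round(l) || m != round(m))
    stop("l and m must be single integers")
  if (l < 0 || l > 4) stop("degree l must be in 0..4")
  if (abs(m) > l) stop("|m| must not exceed l")
  v <- if (is.matrix(direction)) direction else matrix(direction, nrow = 1)
  if (ncol(v) != 3) stop("direction must have 3 components")
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("direction must be a unit vector")
  u <- pmin(pmax(v[, 3], -1), 1)
  s <- sqrt(pmax(0, 1 - u^2))
  phi <- atan2(v[, 2], v[, 1])
  am <- abs(m)
  trig <- if (m > 0) cos(am * phi) else if (m < 0) sin(am * phi) else 1
  .shNormTable[l + 1, am + 1] * .assocLegendre(l, am, u, s) * trig
}

## ---- Plm vector bookkeeping -------------------------------------------

#' Canonical (l, m) index table for multipole populations
#'
#' @param lmax Maximum degree (default 4).
#' @return Data frame with columns \code{l}, \code{m}, \code{name} in the
#'   canonical order (l ascending, m from \code{-l} to \code{l}); names are
#'   \code{"P10"}, \code{"P3-2"}, ...
#' @export
plmIndices <- function(lmax = 4) {
  l <- unlist(lapply(0:lmax, function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(0:lmax, function(li) seq(-li, li)))
  data.frame(l = l, m = m, name = paste0("P", l, m), stringsAsFactors = FALSE)
}

#' Zero-filled named Plm vector in canonical order
#' @param lmax Maximum degree (default 4).
#' @return Named numeric vector of zeros, names \code{P00}, \code{P1-1}, ...
#' @export
plmZero <- function(lmax = 4) {
  idx <- plmIndices(lmax)
  stats::setNames(numeric(nrow(idx)), idx$name)
}

# parse "P<l><m>" names -> data.frame(l, m); stops on malformed or l > 4
.plmParseNames <- function(nm) {
  ok <- grepl("^P[0-9]-?[0-9]$", nm)
  if (!all(ok)) stop("malformed Plm name(s): ", paste(nm[!ok], collapse = ", "))
  l <- as.integer(substr(nm, 2, 2))
  m <- as.integer(sub("^P[0-9]", "", nm))
  if (any(l > 4)) stop("Plm degree l > 4 is not supported (l = ",
                       paste(unique(l[l > 4]), collapse = ","), ")")
  if (any(abs(m) > l)) stop("Plm order |m| > l in: ",
                            paste(nm[abs(m) > l], collapse = ", "))
  data.frame(l = l, m = m)
}

# expand a sparse named Plm vector to the dense canonical layout
.plmDense <- function(plm, lmax = 4) {
  out <- plmZero(lmax)
  if (length(plm) == 0) return(out)
  if (is.null(names(plm))) stop("Plm vector must be named (e.g. \"P10\")")
  .plmParseNames(names(plm))
  keep <- intersect(names(plm), names(out))
  out[keep] <- plm[keep]
  out
}

## ---- representation of O(3) on the d_lm basis -------------------------

# Fixed, well-conditioned spherical point set (Fibonacci lattice, n = 64).
.shSamplePoints <- local({
  n <- 64
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(r * cos(ga * i), r * sin(ga * i), z)
})

.shBasisAt <- function(l, pts) {
  vapply(seq(-l, l), function(m) realSH(l, m, pts), numeric(nrow(pts)))
}

# Matrix M_l acting on the coefficient block (P_{l,-l}..P_{l,l}) for an
# orthogonal coordinate change Q (local_new = Q %*% local_old; det +/-1):
# new coefficients P' = M_l %*% P reproduce the same physical density.
# Built by expanding d_lm(Q^T v) on the d_lm(v) basis over the fixed point
# set (the d_lm of one l span the degree-l harmonics, so the expansion is
# exact; least squares only averages rounding error).
.shBlockMatrix <- function(Q, l) {
  if (l == 0) return(matrix(1, 1, 1))
  A <- .shBasisAt(l, .shSamplePoints)
  B <- .shBasisAt(l, .shSamplePoints %*% Q)
  qr.solve(A, B)  # this IS t(T) with d_m(Q^T v) = sum_m' T[m,m'] d_m'(v)
}

#' Rotate multipole populations between local coordinate systems
#'
#' Applies the exact transformation of density-normalized multipole
#' populations under a proper rotation of the local coordinate system: the
#' returned populations describe the identical physical deformation density
#' expressed in the rotated frame. The action is block-diagonal in the
#' degree l; the monopole is invariant. Note that because the density
#' normalization constants differ between orders m of the same degree, the
#' plain Euclidean norm of a Plm block is not conserved for l >= 2; the
#' conserved quadratic form carries the normalization weights (see the
#' methods vignette).
#'
#' @param plm Named numeric vector of populations (names \code{"P10"},
#'   \code{"P3-2"}, ...); missing indices are treated as zero.
#' @param rotation 3-by-3 proper rotation matrix mapping old local
#'   coordinates to new local coordinates.
#' @param dense If \code{TRUE} (default) return the full canonical l<=4
#'   vector, otherwise only the names present in the input.
#' @return Named numeric vector of rotated populations.
#' @export
rotatePlm <- function(plm, rotation, dense = TRUE) {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3, 3))) stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  if (det(R) < 0)
    stop("improper operation (det = -1): rotatePlm handles proper rotations ",
         "only; mirrors are treated analytically in the site-symmetry module")
  p <- .plmDense(plm)
  idx <- plmIndices(4)
  out <- p
  for (l in 1:4) {
    sel <- idx$l == l
    if (any(p[sel] != 0)) out[sel] <- as.vector(.shBlockMatrix(R, l) %*% p[sel])
  }
  if (dense) out else out[names(plm)]
}

# weights k_lm = N_lm / (orthonormal normalization); ||diag(k) P_l|| is the
# rotation-invariant norm of a degree-l block
.shOrthoWeights <- function() {
  idx <- plmIndices(4)
  w <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    l <- idx$l[i]; m <- abs(idx$m[i])
    # wavefunction (orthonormal) constant for the same functional form
    nl <- sqrt((2 * l + 1) / (4 * pi) *
               ifelse(m == 0, 1, 2 * factorial(l - m) / factorial(l + m)))
    w[i] <- .shNormTable[l + 1, m + 1] / nl
  }
  stats::setNames(w, idx$name)
}
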