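# Pseudoatom electron density: spherical core + kappa-scaled spherical
# valence + deformation valence built from Slater radial functions and
# density-normalized real spherical harmonics:
#
#   rho(r) = rho_core(r) + Pval kappa^3 rho_val(kappa r)
#            + sum_l kappa'^3 R_l(kappa' r) sum_m Plm d_lm(r/|r|)
#
# Radial parts are single-zeta Slater forms chosen by this package (any
# internally consistent choice serves: clustering consumes parameters, the
# density exists chiefly as the rotation oracle).
#   rho_val(r)  = zeta^(n+3) / (4 pi (n+2)!) * r^n exp(-zeta r),
#                 normalized so the term integrates to Pval electrons;
#   R_l(r)      = zeta_l^(n_l+3) / (n_l+2)! * r^(n_l) exp(-zeta_l r),
#                 normalized so integral R_l r^2 dr = 1.
# Units: electrons and Angstrom (zeta in 1/Angstrom).

# per-element defaults: core electron count, core/valence Slater parameters
# and deformation powers n_l (row-typical values; exponents are package
# choices of realistic magnitude, not fitted constants)
.radialDefaults <- list(
  H  = list(nCore = 0,  zCore = NA,   nVal = 0, zVal = 4.5,
            nl = c(0, 1, 2, 3, 4), zl = 4.5),
  C  = list(nCore = 2,  zCore = 21.4, nVal = 2, zVal = 6.2,
            nl = c(2, 2, 2, 3, 4), zl = 6.2),
  N  = list(nCore = 2,  zCore = 25.2, nVal = 2, zVal = 7.2,
            nl = c(2, 2, 2, 3, 4), zl = 7.2),
  O  = list(nCore = 2,  zCore = 29.0, nVal = 2, zVal = 8.3,
            nl = c(2, 2, 2, 3, 4), zl = 8.3),
  S  = list(nCore = 10, zCore = 41.0, nVal = 4, zVal = 6.3,
            nl = c(4, 4, 4, 5, 6), zl = 6.3),
  P  = list(nCore = 10, zCore = 38.0, nVal = 4, zVal = 5.7,
            nl = c(4, 4, 4, 5, 6), zl = 5.7),
  F  = list(nCore = 2,  zCore = 32.7, nVal = 2, zVal = 9.4,
            nl = c(2, 2, 2, 3, 4), zl = 9.4),
  Cl = list(nCore = 10, zCore = 44.5, nVal = 4, zVal = 6.9,
            nl = c(4, 4, 4, 5, 6), zl = 6.9),
  Br = list(nCore = 28, zCore = 70.0, nVal = 6, zVal = 7.3,
            nl = c(6, 6, 6, 7, 8), zl = 7.3))

#' Slater radial model for one element
#'
#' @param element Element symbol with a built-in parameter set (H, C, N, O,
#'   S, P, F, Cl, Br).
#' @return A list of class \code{"RadialModel"} with the core electron
#'   count, core and valence Slater parameters, and per-l deformation powers
#'   \code{nl} (with \code{nl[l+1] >= l}) and exponent \code{zl}.
#' @export
radialModel <- function(element) {
  rm <- .radialDefaults[[element]]
  if (is.null(rm))
    stop("no radial model configured for element '", element, "'")
  rm$element <- element
  stopifnot(all(rm$nl >= 0:4), is.na(rm$zCore) || rm$zCore > 0, rm$zVal > 0)
  class(rm) <- "RadialModel"
  rm
}

# normalized Slater density r^n exp(-z r) * z^(n+3)/(4 pi (n+2)!):
# integrates to one electron over all space
.slaterDensity <- function(r, n, z) {
  z^(n + 3) / (4 * pi * factorial(n + 2)) * r^n * exp(-z * r)
}

# normalized radial function: integral R(r) r^2 dr = 1
.slaterRadial <- function(r, n, z) {
  z^(n + 3) / factorial(n + 2) * r^n * exp(-z * r)
}

#' Evaluate the pseudoatom electron density
#'
#' @param params A \code{\linkS4class{MultipoleParams}}.
#' @param radial A \code{RadialModel} (see \code{\link{radialModel}}).
#' @param points Length-3 vector or n-by-3 matrix of positions relative to
#'   the nucleus, in Angstrom. Radii are capped below at 1e-4 Angstrom to
#'   avoid the nuclear singularity.
#' @return Numeric vector of densities in e per cubic Angstrom.
#' @export
pseudoatomDensity <- function(params, radial, points) {
  stopifnot(methods::is(params, "MultipoleParams"),
            inherits(radial, "RadialModel"))
  pts <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  r <- pmax(sqrt(rowSums(pts^2)), 1e-4)
  u <- pts / r
  # points at (or capped near) the nucleus get an arbitrary fixed direction
  bad <- abs(rowSums(u^2) - 1) > 1e-8
  if (any(bad)) u[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
  rho <- numeric(nrow(pts))
  if (radial$nCore > 0)
    rho <- rho + radial$nCore * .slaterDensity(r, 0, radial$zCore)
  k <- params@kappa
  rho <- rho + params@pval * k^3 * .slaterDensity(k * r, radial$nVal,
                                                  radial$zVal)
  plm <- .plmDense(params@plm)
  if (any(plm != 0)) {
    kp <- params@kappaPrime
    idx <- plmIndices(4)
    # the deformation radial functions (r^n_l, n_l >= l) vanish at the
    # nucleus, so the true radius is used there, not the capped one
    rTrue <- sqrt(rowSums(pts^2))
    for (l in 0:4) {
      sel <- which(idx$l == l & plm != 0)
      if (!length(sel)) next
      Rl <- kp^3 * .slaterRadial(kp * rTrue, radial$nl[l + 1], radial$zl)
      ang <- numeric(nrow(pts))
      for (i in sel)
        ang <- ang + plm[i] * realSH(l, idx$m[i], u)
      rho <- rho + Rl * ang
    }
  }
  rho
}

#' Evaluate a pseudoatom density on a regular grid
#'
#' @param params A \code{MultipoleParams}.
#' @param radial A \code{RadialModel}.
#' @param origin Grid origin (corner), length 3, Angstrom.
#' @param spacing Grid spacing, positive scalar, Angstrom.
#' @param n Number of points per axis (scalar or length 3).
#' @return A list of class \code{"DensityGrid"} with \code{origin},
#'   \code{spacing}, \code{dim}, the coordinate matrix \code{points} and
#'   the density \code{values} (vector in point order, x fastest).
#' @export
densityOnGrid <- function(params, radial, origin = c(-3, -3, -3),
                          spacing = 0.2, n = 31) {
  stopifnot(spacing > 0)
  n <- rep(as.integer(n), length.out = 3)
  ax <- lapply(1:3, function(i) origin[i] + spacing * (seq_len(n[i]) - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- pseudoatomDensity(params, radial, pts)
  structure(list(origin = origin, spacing = spacing, dim = n,
                 points = pts, values = vals), class = "DensityGrid")
}

#' @export
print.DensityGrid <- function(x, ...) {
  cat(sprintf("DensityGrid %dx%dx%d, spacing %.3f A, max %.4g e/A^3\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, max(x$values)))
  invisible(x)
}

#' Export a density grid as a CSV of (x, y, z, rho)
#' @param grid A \code{DensityGrid}.
#' @param file Output path.
#' @return Invisibly, the data frame written.
#' @export
gridToCSV <- function(grid, file) {
  df <- data.frame(grid$points, rho = grid$values)
  names(df) <- c("x", "y", "z", "rho")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
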