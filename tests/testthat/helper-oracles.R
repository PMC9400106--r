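# Independent oracles used across the suite.

# uniform random proper rotation from a quaternion
randomRotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w)),
        c(2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w)),
        c(2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)))
}

# High-precision quadrature of integral |d_lm| dOmega by separation of
# variables: the phi factor is 2*pi (m = 0) or 4 (|m| > 0, integral of
# |cos m phi| over a period); the theta factor integrates |P_l^m(u)| over
# [-1, 1] piecewise between sign changes with Gauss-Legendre panels.
shAbsIntegralOracle <- function(l, m) {
  am <- abs(m)
  # integrate |P_l^m(cos th)| sin th over theta: a trig polynomial, smooth
  # between its roots, so panelwise Gauss-Legendre converges spectrally
  f <- function(th) taamkit:::.assocLegendre(l, am, cos(th), sin(th)) *
    sin(th)
  grid <- seq(0, pi, length.out = 4001)
  fv <- f(grid)
  sgn <- sign(fv)
  brk <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(brk, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root, numeric(1))
  exact <- grid[sgn == 0 & grid > 0 & grid < pi]   # grid points on a root
  pts <- sort(unique(c(0, roots, exact, pi)))
  gl <- function(a, b, n = 40) {            # Gauss-Legendre on [a, b]
    i <- 1:(n - 1); bb <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n); J[cbind(i, i + 1)] <- bb; J <- J + t(J)
    E <- eigen(J, symmetric = TRUE)
    x <- E$values; w <- 2 * E$vectors[1, ]^2
    sum(w * abs(f((a + b) / 2 + (b - a) / 2 * x))) * (b - a) / 2
  }
  theta <- sum(vapply(seq_len(length(pts) - 1), function(i)
    gl(pts[i], pts[i + 1]), numeric(1)))
  phi <- if (am == 0) 2 * pi else 4
  nrm <- taamkit:::.shNormTable[l + 1, am + 1]
  nrm * theta * phi
}

# hand-coded Cartesian forms of the density-normalized harmonics, l <= 2
# (independent of the package's theta/phi evaluation path)
cartSHOracle <- function(l, m, v) {
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  switch(paste(l, m),
    "0 0" = rep(1 / (4 * pi), nrow(v)),
    "1 -1" = y / pi, "1 0" = z / pi, "1 1" = x / pi,
    "2 -2" = (3 / 4) * x * y,
    "2 -1" = (1 / 4) * 3 * y * z,
    "2 0" = (3 * sqrt(3) / (4 * pi)) * (3 * z^2 - 1) / 2,
    "2 1" = (1 / 4) * 3 * x * z,
    "2 2" = (1 / 8) * 3 * (x^2 - y^2),
    stop("no oracle"))
}

# brute-force DBSCAN reference: full distance matrix, core mask, igraph
# components over the core-core eps graph, border points attached to the
# cluster of their smallest-index core neighbor
dbscanReference <- function(m, eps, minPts) {
  n <- nrow(m)
  D <- as.matrix(stats::dist(m))
  inEps <- D <= eps
  core <- rowSums(inEps) >= minPts
  lab <- rep(-1L, n)
  if (any(core)) {
    A <- inEps[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    lab[core] <- comp
    for (i in which(!core)) {
      cn <- which(inEps[i, ] & core)
      if (length(cn)) lab[i] <- lab[min(cn)]
    }
    # renumber by first occurrence
    pos <- lab > 0
    first <- vapply(split(seq_len(n)[pos], lab[pos]), min, integer(1))
    remap <- stats::setNames(order(order(first)) - 1L, names(first))
    lab[pos] <- remap[as.character(lab[pos])]
  }
  lab
}

# two label vectors describe the same partition (noise must match exactly)
samePartition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  ta <- table(a[ok], b[ok])
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# small deterministic member set for frame tests
makeMembers <- function(group, plm, n = 4, jitterDeg = 0, seed = 1,
                        frameName = enumerateFrames(group)[[1]]@name) {
  spec <- plantedClusterSpec(
    element = "C", group = group, hybridization = "sp3",
    pointGroup = "1", frameName = frameName,
    plm = plm, nTypes = 1, nMembers = n,
    noise = list(plm = 0, kappa = 0, kappap = 0, pval = 0),
    jitterDeg = jitterDeg)
  sim <- generateBank(list(spec), seed = seed)
  sim$members[[1]]
}

fixturePath <- function(f) system.file("extdata", f, package = "taamkit")
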