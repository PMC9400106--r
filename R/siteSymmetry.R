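# Site symmetry: allowed (l, m) index sets per point group, derived by
# group-averaging the action of the group elements on the d_lm basis (no
# lookup table), and detection of the highest symmetry compatible with a
# Plm vector.
#
# Orientation conventions (fixed to match the frames that reveal each
# group):
#   m      mirror plane = local XZ plane
#   mm2    2-fold along Z, mirrors XZ and YZ
#   3m     3-fold along Z, one mirror = XZ plane
#   -6m2   3-fold along Z, horizontal mirror = XY, one vertical mirror = XZ
#   -43m   oriented as realized by a ZabXc frame: Z bisects neighbors a,b
#          (a 2-fold axis), X towards neighbor c; mirrors are the XZ and YZ
#          planes
#   cylindrical  continuous rotation about Z (handled analytically: m = 0)

.rotZ <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

.rotAxis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.pointGroupGenerators <- function(name) {
  sigXZ <- diag(c(1, -1, 1)); sigYZ <- diag(c(-1, 1, 1))
  sigXY <- diag(c(1, 1, -1))
  switch(name,
    "1" = list(),
    "m" = list(sigXZ),
    "mm2" = list(.rotZ(180), sigXZ),
    "3m" = list(.rotZ(120), sigXZ),
    "-6m2" = list(.rotZ(120), sigXY, sigXZ),
    "-43m" = {
      # tetrahedron in the ZabXc orientation: a, b in the YZ plane
      s <- sqrt(2 / 3); c1 <- 1 / sqrt(3)
      a <- c(0, s, c1)
      list(sigXZ, sigYZ, .rotAxis(a, 120))
    },
    stop("unknown point group name: ", name))
}

#' Point groups available for site-symmetry analysis
#' @return Character vector of group names ordered by decreasing group
#'   order (the tie-break precedence used by \code{\link{detectSymmetry}}).
#' @export
pointGroupNames <- function() c("cylindrical", "-43m", "-6m2", "3m", "mm2",
                                "m", "1")

#' Order (number of elements) of a point group
#' @param name Group name; \code{"cylindrical"} reports \code{Inf}.
#' @return Numeric group order.
#' @export
pointGroupOrder <- function(name) {
  if (name == "cylindrical") return(Inf)
  length(.pointGroupElements(name))
}

# closure of the generator set; elements keyed by rounded entries
.pointGroupElements <- function(name) {
  gens <- .pointGroupGenerators(name)
  els <- list(diag(3))
  keys <- paste(round(diag(3), 8), collapse = ",")
  queue <- els
  while (length(queue)) {
    nxt <- list()
    for (e in queue) for (g in gens) {
      h <- g %*% e
      k <- paste(round(h, 8), collapse = ",")
      if (!k %in% keys) {
        keys <- c(keys, k)
        els[[length(els) + 1L]] <- h
        nxt[[length(nxt) + 1L]] <- h
      }
    }
    queue <- nxt
    if (length(els) > 200) stop("generators do not generate a small group")
  }
  els
}

# representation of one orthogonal element on the full dense Plm layout
.plmRepMatrix <- function(Q, lmax = 4) {
  idx <- plmIndices(lmax)
  M <- matrix(0, nrow(idx), nrow(idx))
  for (l in 0:lmax) {
    sel <- which(idx$l == l)
    M[sel, sel] <- .shBlockMatrix(Q, l)
  }
  M
}

# group-average projector on the dense Plm layout
.groupProjector <- function(name, lmax = 4) {
  els <- .pointGroupElements(name)
  Reduce(`+`, lapply(els, .plmRepMatrix, lmax = lmax)) / length(els)
}

#' Symmetry-allowed multipole indices of a point group
#'
#' An index (l, m) is allowed iff the group-averaged (symmetry-projected)
#' \eqn{d_{lm}} does not vanish; the projector is computed by averaging the
#' action of all group elements on the harmonic basis. The cylindrical
#' limit is handled analytically (only m = 0 survives).
#'
#' @param group Group name (see \code{\link{pointGroupNames}}).
#' @param lmax Maximum degree, 0..4 (default 4).
#' @return Data frame with columns l, m, name of the allowed indices.
#' @export
allowedIndices <- function(group, lmax = 4) {
  stopifnot(lmax >= 0, lmax <= 4)
  idx <- plmIndices(lmax)
  if (group == "cylindrical") return(idx[idx$m == 0, ])
  P <- .groupProjector(group, lmax)
  keep <- abs(diag(P)) > 1e-8
  idx[keep, ]
}

#' Detect the highest point symmetry compatible with a Plm vector
#'
#' Returns the candidate group of largest order whose disallowed indices
#' all have populations of magnitude at most \code{tol}; ties are broken by
#' the fixed precedence of \code{\link{pointGroupNames}}.
#'
#' @param plm Named numeric vector of populations.
#' @param candidates Character vector of candidate group names (default all
#'   seven).
#' @param tol Tolerance in electrons (default 0.005, just above the 0.002 e
#'   storage floor).
#' @return The detected group name.
#' @export
detectSymmetry <- function(plm, candidates = pointGroupNames(),
                           tol = 0.005) {
  if (!length(candidates)) stop("empty candidate list")
  stopifnot(tol > 0)
  p <- .plmDense(plm)
  cand <- candidates[order(match(candidates, pointGroupNames()))]
  for (g in cand) {
    ok <- allowedIndices(g, 4)$name
    if (all(abs(p[setdiff(names(p), ok)]) <= tol)) return(g)
  }
  # group "1" allows everything, so we only get here if it is not a
  # candidate
  cand[length(cand)]
}

#' Symmetrize a Plm vector by group averaging
#'
#' Averages the action of all group elements on the populations; disallowed
#' indices are zeroed exactly (to machine precision) and allowed ones keep
#' their symmetric component.
#' @param plm Named numeric vector.
#' @param group Group name.
#' @return Dense named vector of symmetrized populations.
#' @export
symmetrizePlm <- function(plm, group) {
  p <- .plmDense(plm)
  if (group == "cylindrical") {
    idx <- plmIndices(4)
    p[idx$m != 0] <- 0
    return(p)
  }
  stats::setNames(as.vector(.groupProjector(group, 4) %*% p), names(p))
}

#' Export allowed-index tables for a set of groups
#' @param groups Group names (default all).
#' @param lmax Maximum degree.
#' @return Data frame with columns group, l, m, allowed.
#' @export
allowedIndexTable <- function(groups = pointGroupNames(), lmax = 4) {
  idx <- plmIndices(lmax)
  do.call(rbind, lapply(groups, function(g) {
    ok <- allowedIndices(g, lmax)$name
    data.frame(group = g, l = idx$l, m = idx$m,
               allowed = idx$name %in% ok, stringsAsFactors = FALSE)
  }))
}
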