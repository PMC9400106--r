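# Seeded synthetic atom-type bank with planted clusters: every planted
# cluster fixes an element, a frame group, a hybridization, a point
# symmetry, a reference local coordinate system, mean parameters and noise
# levels. Member atoms get idealized neighbor geometries with angular
# jitter and noisy parameters; ground truth records the plant per entry.

# idealized first-neighbor unit directions per group (Angstrom-scaled by
# bond length at generation time)
.idealDirections <- function(group) {
  s <- sqrt(2 / 3); c1 <- 1 / sqrt(3)
  switch(group,
    "1x" = rbind(a = c(0, 0, 1)),
    "1p" = rbind(a = c(0, 0, 1)),
    "2x" = rbind(a = c(0, 0, 1), b = c(0, 0, -1)),
    # bent, tetrahedral angle, in the YZ plane (so the ZabYa frame realizes
    # the canonical mm2 orientation: molecular plane = YZ)
    "2p" = {
      th <- acos(-1 / 3) / 2
      rbind(a = c(0, sin(th), cos(th)), b = c(0, -sin(th), cos(th)))
    },
    # trigonal planar
    "3p" = rbind(a = c(1, 0, 0), b = c(-0.5, sqrt(3) / 2, 0),
                 c = c(-0.5, -sqrt(3) / 2, 0)),
    # pyramidal: three bonds below the +z lone-pair direction
    "3n" = {
      th <- acos(-1 / 3)
      t(vapply(0:2, function(k)
        c(sin(th) * cos(2 * pi * k / 3), sin(th) * sin(2 * pi * k / 3),
          cos(th)), numeric(3))) -> d
      rownames(d) <- c("a", "b", "c"); d
    },
    # tetrahedral in the canonical ZabXc orientation (a, b in the YZ plane)
    "4n" = rbind(a = c(0, s, c1), b = c(0, -s, c1), c = c(s, 0, -c1),
                 d = c(-s, 0, -c1)),
    "6n" = rbind(a = c(0, 0, 1), b = c(0, 0, -1), c = c(1, 0, 0),
                 d = c(-1, 0, 0), e = c(0, 1, 0), f = c(0, -1, 0)),
    stop("no idealized geometry for group ", group))
}

#' Specification of one planted cluster
#'
#' @param element Central element symbol.
#' @param group Frame group label.
#' @param hybridization \code{"sp1"}, \code{"sp2"} or \code{"sp3"}.
#' @param pointGroup Planted site symmetry (must admit the Plm pattern).
#' @param frameName Reference frame the pattern is expressed in (one of the
#'   group's enumerated frames).
#' @param kappa,pval,kappap Mean spherical parameters.
#' @param plm Named numeric vector: the planted Plm pattern.
#' @param nTypes Number of atom types in the cluster.
#' @param nMembers Member atoms averaged per type (default 8).
#' @param noise List with per-class Gaussian noise sd: \code{plm} (default
#'   0.02 e), \code{kappa}, \code{kappap} (default 0.01), \code{pval}
#'   (default 0.03 e).
#' @param jitterDeg Angular jitter of member bond directions, degrees sd
#'   (default 2).
#' @param bondLength Bond length in Angstrom (default 1.5).
#' @return Validated planted-cluster spec (list, class
#'   \code{"PlantedClusterSpec"}). The pattern must only populate indices
#'   allowed by the planted point group.
#' @export
plantedClusterSpec <- function(element, group, hybridization, pointGroup,
                               frameName, kappa = 1, pval = NULL,
                               kappap = 1, plm, nTypes = 6, nMembers = 8,
                               noise = list(), jitterDeg = 2,
                               bondLength = 1.5) {
  if (is.null(pval)) pval <- unname(.valenceElectrons[element])
  noise <- utils::modifyList(list(plm = 0.02, kappa = 0.01, kappap = 0.01,
                                  pval = 0.03), noise)
  if (any(unlist(noise) < 0)) stop("noise sd must be >= 0")
  ok <- allowedIndices(pointGroup, 4)$name
  bad <- setdiff(names(plm)[plm != 0], ok)
  if (length(bad))
    stop("pattern violates the planted point group ", pointGroup, ": ",
         paste(bad, collapse = ", "))
  frames <- enumerateFrames(group)
  fnames <- vapply(frames, function(f) f@name, character(1))
  if (!frameName %in% fnames)
    stop("frameName must be one of the group's frames: ",
         paste(fnames, collapse = ", "))
  stopifnot(hybridization %in% c("sp1", "sp2", "sp3"), nTypes >= 1,
            nMembers >= 2)
  structure(list(element = element, group = group,
                 hybridization = hybridization, pointGroup = pointGroup,
                 frameName = frameName, kappa = kappa, pval = pval,
                 kappap = kappap, plm = plm, nTypes = nTypes,
                 nMembers = nMembers, noise = noise, jitterDeg = jitterDeg,
                 bondLength = bondLength), class = "PlantedClusterSpec")
}

# rotate each row of a direction matrix by a small random angle
.jitterDirections <- function(dirs, sdDeg) {
  if (sdDeg <= 0) return(dirs)
  t(apply(dirs, 1, function(d) {
    p <- stats::rnorm(3, 0, sdDeg * pi / 180)
    p <- p - sum(p * d) * d          # tangential perturbation
    .unit(d + p)
  }))
}

# first-neighbor element sets per plant (cosmetic variety for topology)
.neighborChoices <- list(
  H = list("O", "N", "C"), C = list(c("C", "H"), c("N", "O"), c("C", "O")),
  N = list(c("C", "H"), c("C", "C")), O = list(c("C", "H"), c("C", "C")),
  S = list(c("C", "C"), c("C", "H")))

#' Generate a synthetic atom-type bank with planted clusters
#'
#' Reproducible for a fixed seed: member atoms receive jittered idealized
#' geometries and Plm patterns plus Gaussian noise expressed in the
#' reference frame realized from their own geometry; type-level parameters
#' are the member means with unweighted sample standard deviations.
#'
#' @param specs List of \code{\link{plantedClusterSpec}} objects.
#' @param seed Integer seed.
#' @return List with \code{bank} (an \code{AtomTypeBank}), \code{members}
#'   (per entry: list of member geometries and source-frame Plm vectors,
#'   plus the reference \code{LocalFrame}), and \code{truth} (data frame:
#'   entry, clusterId, element, group, pointGroup, frame).
#' @export
generateBank <- function(specs, seed = 1) {
  if (!length(specs)) stop("specs must be non-empty")
  if (inherits(specs, "PlantedClusterSpec")) specs <- list(specs)
  set.seed(seed)
  entries <- list(); members <- list(); truthRows <- list()
  counter <- 0L
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    frames <- enumerateFrames(sp$group)
    ref <- frames[[match(sp$frameName,
                         vapply(frames, function(f) f@name, character(1)))]]
    ideal <- .idealDirections(sp$group) * sp$bondLength
    nbChoices <- .neighborChoices[[sp$element]]
    for (ti in seq_len(sp$nTypes)) {
      counter <- counter + 1L
      name <- sprintf("%s%s%02d%s", sp$element,
                      substr(sp$group, 1, 1), counter, letters[ci])
      memberList <- lapply(seq_len(sp$nMembers), function(mi) {
        nb <- .jitterDirections(ideal / sp$bondLength, sp$jitterDeg) *
          sp$bondLength
        rownames(nb) <- rownames(ideal)
        plm <- .plmDense(sp$plm)
        active <- plmIndices(4)$l >= 1
        plm[active] <- plm[active] +
          stats::rnorm(sum(active), 0, sp$noise$plm)
        second <- if (sp$group %in% c("1x", "1p")) {
          # a second neighbor bonded to 'a': collinear continuation for 1x,
          # bent (120 deg at the first neighbor) for 1p
          if (sp$group == "1x") nb["a", ] * 2 else
            nb["a", ] + sp$bondLength * .unit(c(0.87, 0, -0.5))
        }
        list(central = c(0, 0, 0), neighbors = nb, secondNeighbor = second,
             plm = plm)
      })
      M <- do.call(rbind, lapply(memberList, `[[`, "plm"))
      mu <- colMeans(M)
      sdv <- apply(M, 2, stats::sd)
      params <- MultipoleParams(
        kappa = sp$kappa + stats::rnorm(1, 0, sp$noise$kappa),
        kappaPrime = sp$kappap + stats::rnorm(1, 0, sp$noise$kappap),
        pval = sp$pval + stats::rnorm(1, 0, sp$noise$pval),
        plm = mu, sd = sdv)
      firstEls <- nbChoices[[1 + (ti %% length(nbChoices))]]
      firstEls <- rep(firstEls,
                      length.out = .groupNeighborCount[[sp$group]])
      nbdf <- data.frame(shell = 1L, element = firstEls,
                         planar = sp$group %in% c("1p", "2p", "3p"),
                         rings = "", parent = NA_integer_,
                         stringsAsFactors = FALSE)
      # a couple of wildcard second neighbors on the first first-neighbor
      # (variety for the topology trees; H gets none)
      if (sp$element != "H" && ti %% 2 == 0)
        nbdf <- rbind(nbdf, data.frame(shell = 2L, element = "X",
                                       planar = FALSE, rings = "",
                                       parent = 1L, stringsAsFactors = FALSE))
      topo <- methods::new("AtomTypeTopology", element = sp$element,
                           neighbors = nbdf, groupLabel = sp$group,
                           secondShell = if (any(nbdf$shell == 2))
                             "records" else "unspecified")
      entry <- AtomTypeEntry(name, topo, sp$frameName, params)
      entries[[length(entries) + 1L]] <- entry
      members[[name]] <- list(members = memberList, referenceFrame = ref)
      truthRows[[length(truthRows) + 1L]] <-
        data.frame(entry = name, clusterId = ci, element = sp$element,
                   group = sp$group, pointGroup = sp$pointGroup,
                   frame = sp$frameName, stringsAsFactors = FALSE)
    }
  }
  list(bank = AtomTypeBank(entries), members = members,
       truth = do.call(rbind, truthRows))
}

#' Default planted-cluster specification
#'
#' Ten planted clusters spanning H, C, N, O and S over the 1x, 2x, 2p, 3p,
#' 3n and 4n groups, mirroring the qualitative structure of a real
#' pseudoatom bank: polar and nonpolar hydrogens (cylindrical), sp1 carbon
#' (cylindrical), sp2 carbon (positive P33 in its planar frame), sp3
#' carbon (negative P32 in its bisecting tetrahedral frame), sp3 nitrogen
#' (3m octupole pattern), sp2-plane nitrogen, lone-pair-dominated oxygens
#' and an sp3 sulfur with the largest populations.
#'
#' @param noisePlm Plm noise sd in electrons: 0.02 (default preset, below
#'   the 0.05 e inconsistency threshold) or e.g. 0.08 (\code{"hard"}
#'   preset, designed to trip it).
#' @param typeScale Multiplier on the per-cluster type counts (values below
#'   1 shrink the bank for quick runs; at least one type per cluster).
#' @return List of \code{\link{plantedClusterSpec}} objects.
#' @export
defaultSyntheticSpec <- function(noisePlm = 0.02, typeScale = 1) {
  nz <- list(plm = noisePlm)
  nt <- function(n) max(1L, as.integer(round(n * typeScale)))
  list(
    # polar H: larger dipole, depleted valence
    plantedClusterSpec("H", "1x", "sp1", "cylindrical", "1x_1-ZaXany",
      kappa = 1.12, pval = 0.85, kappap = 1.2,
      plm = c(P10 = 0.15, P20 = 0.08), nTypes = nt(8), noise = nz),
    # nonpolar H
    plantedClusterSpec("H", "1x", "sp1", "cylindrical", "1x_1-ZaXany",
      kappa = 1.17, pval = 1.05, kappap = 1.2,
      plm = c(P10 = 0.10, P20 = 0.03), nTypes = nt(8), noise = nz),
    # sp1 C, symmetric (even-l pattern only, so both 2x frames agree)
    plantedClusterSpec("C", "2x", "sp1", "cylindrical", "2x_1-ZaXany",
      kappa = 0.99, pval = 4.05, kappap = 0.92,
      plm = c(P20 = 0.30), nTypes = nt(5), noise = nz),
    # sp2 C, trigonal planar: dominant +P33 in the XabYa reference
    plantedClusterSpec("C", "3p", "sp2", "-6m2", "3p_21-XabYa",
      kappa = 0.995, pval = 4.0, kappap = 0.90,
      plm = c(P33 = 0.32, P20 = -0.08), nTypes = nt(8), noise = nz),
    # sp3 C, tetrahedral: dominant -P32 in the ZabXc reference
    plantedClusterSpec("C", "4n", "sp3", "-43m", "4n_41-ZabXc",
      kappa = 1.005, pval = 4.2, kappap = 0.88,
      plm = c(P32 = -0.30), nTypes = nt(10), noise = nz),
    # sp3 N, pyramidal, 3m in the ZabcXa reference
    plantedClusterSpec("N", "3n", "sp3", "3m", "3n_61-ZabcXa",
      kappa = 0.99, pval = 5.1, kappap = 0.85,
      plm = c(P10 = 0.05, P20 = 0.10, P30 = -0.12, P33 = -0.25),
      nTypes = nt(7), noise = nz),
    # planar-frame N (amide-like), mm2 in the ZabYa reference
    plantedClusterSpec("N", "2p", "sp3", "mm2", "2p_71-ZabYa",
      kappa = 0.985, pval = 5.05, kappap = 0.86,
      plm = c(P10 = -0.15, P20 = 0.18, P22 = 0.12), nTypes = nt(6),
      noise = nz),
    # carbonyl-like O with in-plane lone pairs: mirror symmetry in ZaXx
    plantedClusterSpec("O", "1p", "sp2", "m", "1p_1-ZaXx",
      kappa = 0.97, pval = 6.2, kappap = 0.95,
      plm = c(P10 = 0.10, P11 = 0.05, P20 = -0.12, P22 = 0.10),
      nTypes = nt(8), noise = nz),
    # water/ether-like O, mm2 in ZabYa
    plantedClusterSpec("O", "2p", "sp3", "mm2", "2p_71-ZabYa",
      kappa = 0.975, pval = 6.15, kappap = 0.93,
      plm = c(P10 = -0.12, P20 = 0.10, P22 = -0.08), nTypes = nt(6),
      noise = nz),
    # sulfide-like S: largest populations in the bank
    plantedClusterSpec("S", "2p", "sp3", "mm2", "2p_71-ZabYa",
      kappa = 0.99, pval = 6.1, kappap = 0.80,
      plm = c(P10 = -0.25, P20 = 0.28, P22 = -0.15), nTypes = nt(5),
      noise = nz))
}
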