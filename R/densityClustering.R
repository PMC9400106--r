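# Electron-density clustering: the 18-dimensional feature space (kappa,
# Pval, kappa', and the 15 dipole-to-octupole populations), the subtraction
# and L2-normalization transforms, knee-method epsilon estimation, DBSCAN,
# and the multi-level subdivision protocol with an sd-based stopping rule.

.valenceElectrons <- c(H = 1, C = 4, N = 5, O = 6, S = 6, P = 5, F = 7,
                       Cl = 7, Br = 7)

#' Fixed feature column order
#' @return Character vector of the 18 feature names: kappa, Pval, kappap,
#'   then P1-1 .. P33 (hexadecapoles are never clustering features).
#' @export
featureColumns <- function() {
  idx <- plmIndices(3)
  c("kappa", "Pval", "kappap", idx$name[idx$l >= 1])
}

#' Feature matrix over rotated atom-type entries
#'
#' @slot features Numeric matrix, 18 columns in \code{\link{featureColumns}}
#'   order, one row per (atom type, frame) entry.
#' @slot info Data frame parallel to the rows: \code{entry}, \code{frame},
#'   \code{element}, \code{group}, \code{inconsistent}.
#' @slot transform One of original / subtract / normalize /
#'   subtract-normalize.
#' @slot scaleFactor Uniform factor applied after the transform (cosmetic
#'   rescaling of the whole data set; default 1).
#' @export
setClass("FeatureSet",
  representation(features = "matrix", info = "data.frame",
                 transform = "character", scaleFactor = "numeric"))

setValidity("FeatureSet", function(object) {
  if (!identical(colnames(object@features), featureColumns()))
    return("features must have exactly the 18 canonical columns")
  if (nrow(object@features) != nrow(object@info))
    return("info must have one row per feature row")
  if (!all(is.finite(object@features))) return("features must be finite")
  if (!all(c("entry", "frame", "element", "group") %in% names(object@info)))
    return("info needs entry, frame, element, group columns")
  TRUE
})

setMethod("show", "FeatureSet", function(object)
  cat(sprintf("FeatureSet: %d rows x 18 features (%s%s)\n",
              nrow(object@features), object@transform,
              if (object@scaleFactor != 1)
                sprintf(", x%g", object@scaleFactor) else "")))

#' Build a FeatureSet from a rotated-entries table
#'
#' @param rotated Data frame as produced by \code{\link{rotateBank}}: one
#'   row per (type, frame) with columns entry, frame, element, group,
#'   kappa, Pval, kappap, the Plm means, and optionally inconsistent.
#' @return A \code{\linkS4class{FeatureSet}} with transform
#'   \code{"original"}.
#' @export
featureMatrix <- function(rotated) {
  cols <- featureColumns()
  miss <- setdiff(cols, names(rotated))
  if (length(miss)) stop("missing feature columns: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(rotated[cols])
  rownames(m) <- NULL
  info <- data.frame(entry = rotated$entry, frame = rotated$frame,
                     element = rotated$element, group = rotated$group,
                     inconsistent = if ("inconsistent" %in% names(rotated))
                       rotated$inconsistent else FALSE,
                     stringsAsFactors = FALSE)
  methods::new("FeatureSet", features = m, info = info,
               transform = "original", scaleFactor = 1)
}

#' Subtraction / L2-normalization feature transforms
#'
#' \code{"subtract"} recenters the spherical parameters at zero: kappa and
#' kappa' have 1 subtracted and Pval has the element's formal valence
#' electron count subtracted (4 for C, 5 for N, 6 for O, ...); the Plm
#' columns are untouched. \code{"normalize"} divides every column by its L2
#' norm over all n rows. \code{"subtract-normalize"} composes the two in
#' that order. An optional uniform scale factor is applied last.
#'
#' @param fs A \code{FeatureSet} with transform \code{"original"}.
#' @param mode One of original, subtract, normalize, subtract-normalize.
#' @param scaleFactor Uniform multiplier applied after the transform.
#' @return The transformed \code{FeatureSet}. Zero-norm columns are left at
#'   zero with a warning.
#' @export
transformFeatures <- function(fs, mode = c("original", "subtract",
                                           "normalize",
                                           "subtract-normalize"),
                              scaleFactor = 1) {
  mode <- match.arg(mode)
  stopifnot(methods::is(fs, "FeatureSet"))
  if (fs@transform != "original")
    stop("transformFeatures expects an untransformed FeatureSet")
  m <- fs@features
  if (mode %in% c("subtract", "subtract-normalize")) {
    zv <- .valenceElectrons[fs@info$element]
    if (anyNA(zv)) stop("unknown valence electron count for element(s): ",
                        paste(unique(fs@info$element[is.na(zv)]),
                              collapse = ", "))
    m[, "kappa"] <- m[, "kappa"] - 1
    m[, "kappap"] <- m[, "kappap"] - 1
    m[, "Pval"] <- m[, "Pval"] - zv
  }
  if (mode %in% c("normalize", "subtract-normalize")) {
    nrm <- sqrt(colSums(m^2))
    zero <- nrm == 0
    if (any(zero)) warning("zero-norm column(s) left at zero: ",
                           paste(colnames(m)[zero], collapse = ", "))
    m[, !zero] <- sweep(m[, !zero, drop = FALSE], 2, nrm[!zero], "/")
  }
  m <- m * scaleFactor
  methods::new("FeatureSet", features = m, info = fs@info, transform = mode,
               scaleFactor = scaleFactor)
}

#' Knee-method epsilon estimate
#'
#' Sorts the per-point k-nearest-neighbor distances ascending and returns
#' the distance at the point of maximum perpendicular distance to the chord
#' joining the curve's endpoints. Exact duplicate rows are removed first
#' (duplicates make all small distances zero and hide the knee).
#'
#' @param m Numeric matrix (rows are points) or a \code{FeatureSet}.
#' @param k Neighbor count; the DBSCAN MinPts is the standard choice.
#' @return The epsilon estimate (scalar). Errors if fewer than k + 1
#'   distinct points remain, or if all k-distances are zero.
#' @export
estimateEps <- function(m, k = 2) {
  if (methods::is(m, "FeatureSet")) m <- m@features
  m <- unique(as.matrix(m))
  n <- nrow(m)
  if (n < k + 1)
    stop(sprintf(
      "degenerate input: %d distinct point(s), need at least %d", n, k + 1))
  D <- as.matrix(stats::dist(m))
  kdist <- apply(D, 1, function(d) sort(d)[k + 1])  # k-th NN, self excluded
  if (all(kdist == 0)) stop("degenerate input: all k-distances are zero")
  s <- sort(kdist)
  # perpendicular distance to the chord from (1, s[1]) to (n, s[n])
  x <- seq_len(n)
  dx <- n - 1; dy <- s[n] - s[1]
  perp <- abs(dy * (x - 1) - dx * (s - s[1])) / sqrt(dx^2 + dy^2)
  unname(s[which.max(perp)])
}

# shared neighbor/core machinery; d <= eps, the point itself counts towards
# MinPts (so MinPts = 1 makes every point a core point)
.dbscanCore <- function(m, eps, minPts) {
  D <- as.matrix(stats::dist(m))
  nbr <- lapply(seq_len(nrow(D)), function(i) which(D[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= minPts
  list(nbr = nbr, core = core)
}

#' DBSCAN clustering
#'
#' Standard core/border/noise semantics under Euclidean distance: a core
#' point has at least \code{minPts} points (itself included) within
#' \code{eps}; clusters are grown over eps-reachable core points; a
#' non-core point within eps of a core point joins the cluster of its
#' smallest-index core neighbor (a deterministic, order-independent border
#' rule); remaining points are noise (-1). Cluster labels are integers from
#' 0, numbered by order of first member row.
#'
#' @param m Numeric matrix or \code{FeatureSet}.
#' @param eps Radius, positive.
#' @param minPts Minimum neighborhood size (default 2).
#' @return Integer label vector (one per row; -1 = noise).
#' @export
dbscan <- function(m, eps, minPts = 2) {
  if (methods::is(m, "FeatureSet")) m <- m@features
  stopifnot(eps > 0, minPts >= 1)
  n <- nrow(m)
  if (n == 0) return(integer(0))
  cm <- .dbscanCore(m, eps, minPts)
  lab <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!cm$core[i] || !is.na(lab[i])) next
    cl <- cl + 1L
    queue <- i; lab[i] <- cl
    while (length(queue)) {        # BFS over eps-reachable core points
      j <- queue[1]; queue <- queue[-1]
      for (k in cm$nbr[[j]]) {
        if (cm$core[k] && is.na(lab[k])) {
          lab[k] <- cl
          queue <- c(queue, k)
        }
      }
    }
  }
  for (i in which(!cm$core)) {      # border points
    cores <- cm$nbr[[i]][cm$core[cm$nbr[[i]]]]
    lab[i] <- if (length(cores)) lab[min(cores)] else -1L
  }
  # renumber by order of first member
  pos <- lab >= 0
  if (any(pos)) {
    first <- vapply(split(seq_len(n)[pos], lab[pos]), min, integer(1))
    remap <- stats::setNames(order(order(first)) - 1L, names(first))
    lab[pos] <- remap[as.character(lab[pos])]
  }
  lab
}

#' Multi-level DBSCAN with sd-based stopping
#'
#' Level 1 clusters all rows; a cluster is re-clustered at the next level
#' iff any of its 15 Plm columns has a sample standard deviation above
#' \code{sdThreshold} on the original parameter scale (kappa, Pval and
#' kappa' never trigger subdivision: they are untouched by frame changes).
#' Outliers are never subdivided; recursion is capped at \code{maxLevels}.
#' Epsilon per sub-run comes from \code{epsSchedule} when a matching path
#' is present, otherwise from \code{\link{estimateEps}}. Labels accumulate
#' into underscore-joined paths (outlier -1 terminates a path).
#'
#' @param fs \code{FeatureSet} to cluster (any transform).
#' @param minPts DBSCAN MinPts (default 2).
#' @param maxLevels Maximum number of levels (default 4).
#' @param sdThreshold Subdivision threshold in electrons (default 0.05).
#' @param epsSchedule Named numeric vector mapping cluster paths (\code{""}
#'   for the first level) to manual epsilon values.
#' @param eps Optional manual first-level epsilon (shorthand for
#'   \code{epsSchedule[""]}).
#' @param original Optional untransformed \code{FeatureSet} supplying the
#'   original-scale Plm values for the stopping rule; defaults to \code{fs}
#'   (required when \code{fs} is transformed).
#' @return List with \code{paths} (character vector of label paths, one per
#'   row), \code{log} (data frame of every sub-run: path, n, eps, source)
#'   and \code{leaves} (integer leaf ids parallel to paths).
#' @export
multilevelCluster <- function(fs, minPts = 2, maxLevels = 4,
                              sdThreshold = 0.05, epsSchedule = NULL,
                              eps = NULL, original = NULL) {
  stopifnot(methods::is(fs, "FeatureSet"))
  if (is.null(original)) original <- fs
  if (original@transform != "original")
    stop("the stopping rule needs original-scale parameters; supply ",
         "'original'")
  if (!is.null(eps)) {
    epsSchedule <- c(epsSchedule, stats::setNames(eps, ""))
  }
  m <- fs@features
  plmCols <- featureColumns()[-(1:3)]
  orig <- original@features[, plmCols, drop = FALSE]
  n <- nrow(m)
  paths <- rep("", n)
  logRows <- list()
  recurse <- function(rows, path, level) {
    # lookup by match, not [name]: the root path is the empty string
    schedIdx <- if (!is.null(epsSchedule)) match(path, names(epsSchedule))
      else NA_integer_
    epsHere <- if (!is.na(schedIdx)) {
      src <- "schedule"; unname(epsSchedule[[schedIdx]])
    } else {
      src <- "knee"
      tryCatch(estimateEps(m[rows, , drop = FALSE], k = minPts),
               error = function(e) {
                 if (level == 1)
                   stop("first-level epsilon estimation failed (",
                        conditionMessage(e),
                        "); provide a manual eps", call. = FALSE)
                 warning("cluster ", path, " left undivided: ",
                         conditionMessage(e), call. = FALSE)
                 NA_real_
               })
    }
    if (is.na(epsHere)) return()
    lab <- dbscan(m[rows, , drop = FALSE], epsHere, minPts)
    logRows[[length(logRows) + 1L]] <<-
      data.frame(path = path, n = length(rows), eps = epsHere, source = src,
                 stringsAsFactors = FALSE)
    for (cl in sort(unique(lab))) {
      sub <- rows[lab == cl]
      subPath <- if (path == "") as.character(cl) else
        paste(path, cl, sep = "_")
      paths[sub] <<- subPath
      if (cl == -1L) next
      if (level >= maxLevels) next
      if (length(sub) < 2) next
      sds <- apply(orig[sub, , drop = FALSE], 2, stats::sd)
      if (any(sds > sdThreshold + 1e-12)) {
        if (nrow(unique(m[sub, , drop = FALSE])) < minPts + 1 &&
            !(subPath %in% names(epsSchedule))) {
          warning("cluster ", subPath,
                  " needs subdivision but is degenerate; left as-is",
                  call. = FALSE)
          next
        }
        recurse(sub, subPath, level + 1)
      }
    }
  }
  recurse(seq_len(n), "", 1)
  leafIds <- match(paths, unique(paths[order(paths)]))
  list(paths = paths, log = do.call(rbind, logRows), leaves = leafIds)
}

#' Per-cluster summary report
#'
#' @param fs \code{FeatureSet} (original scale recommended for
#'   interpretability).
#' @param paths Character label paths from \code{\link{multilevelCluster}}.
#' @param symmetryTol Tolerance for \code{\link{detectSymmetry}} on the
#'   cluster mean (default 0.02 e; cluster means of noisy synthetic data
#'   sit above the refinement-level default).
#' @return Data frame, one row per cluster: path, n, detected point group
#'   of the mean Plm, dominant multipoles (within 50% of the top absolute
#'   mean, signed), inconsistent fraction, then mean and sd of all 18
#'   features (columns \code{mean.*}, \code{sd.*}).
#' @export
clusterReport <- function(fs, paths, symmetryTol = 0.02) {
  stopifnot(methods::is(fs, "FeatureSet"), length(paths) == nrow(fs@features))
  plmCols <- featureColumns()[-(1:3)]
  rows <- lapply(split(seq_along(paths), paths), function(i) {
    sub <- fs@features[i, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- if (length(i) > 1) apply(sub, 2, stats::sd) else mu * 0
    plmMu <- mu[plmCols]
    top <- max(abs(plmMu))
    dom <- if (top > 0) {
      sel <- which(abs(plmMu) >= 0.5 * top)
      paste(sprintf("%s%s", ifelse(plmMu[sel] >= 0, "+", "-"),
                    plmCols[sel]), collapse = ",")
    } else ""
    data.frame(path = paths[i[1]], n = length(i),
               pointGroup = detectSymmetry(plmMu, tol = symmetryTol),
               dominant = dom,
               inconsistentFraction = mean(fs@info$inconsistent[i]),
               t(stats::setNames(mu, paste0("mean.", names(mu)))),
               t(stats::setNames(sdv, paste0("sd.", names(sdv)))),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
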