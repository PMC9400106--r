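# Local coordinate systems: enumeration per group, realization as rotation
# matrices from neighbor geometry, and recomputation of atom-type statistics
# in every frame.
#
# Frame names follow "[group]_[rotation number]-[system]", e.g.
# "4n_62-ZabdXa". Rotation numbers are banded by system family:
#   1-12  ZaXb (incl. the degenerate ZaXany and ZaXx variants)
#   21-32 XabYa     41-52 ZabXc     61-64 ZabcXa     71-72 ZabYa
# Within a band slots are filled in a fixed lexicographic order over the
# neighbor labels a,b,c,d (the published figure fixes only the bands; any
# fixed bijection inside a band is equivalent).

#' A named local-coordinate-system construction rule
#'
#' @slot name Full frame name, e.g. \code{"4n_41-ZabXc"}.
#' @slot group Group label the frame belongs to.
#' @slot rotation Rotation number within the group's numbering bands.
#' @slot system Realized system string, e.g. \code{"ZabdXa"}.
#' @slot axis1,axis2 Axis specs: lists with \code{label} (\code{"X"},
#'   \code{"Y"} or \code{"Z"}) and \code{targets} (neighbor letters, or
#'   \code{"any"} for a deterministic orthogonal, or \code{"x"} for the
#'   nearest non-collinear second-or-further neighbor).
#' @export
setClass("LocalFrame",
  representation(name = "character", group = "character",
                 rotation = "integer", system = "character",
                 axis1 = "list", axis2 = "list"))

setValidity("LocalFrame", function(object) {
  if (object@axis1$label == object@axis2$label)
    return("primary and secondary axis labels must differ")
  if (!grepl("^[1-6][xpn]_[0-9]+-", object@name))
    return("frame name must look like <group>_<rotation>-<system>")
  TRUE
})

setMethod("show", "LocalFrame", function(object)
  cat("LocalFrame", object@name, "\n"))

.mkFrame <- function(group, rotation, system, axis1, axis2) {
  methods::new("LocalFrame",
               name = sprintf("%s_%d-%s", group, rotation, system),
               group = group, rotation = as.integer(rotation),
               system = system, axis1 = axis1, axis2 = axis2)
}

.axis <- function(label, targets) list(label = label, targets = targets)

# ordered pairs / unordered pairs / triples of the first k letters
.letters <- function(k) letters[seq_len(k)]

#' Enumerate the local coordinate systems of a group
#'
#' Frame counts per group: 1x and 1p have 1; 2x has 2; 2p has 6 (ZaXb,
#' XabYa and ZabYa, two each); 3p has 12 (6 ordered-pair ZaXb + 6 XabYa);
#' 3n has 16 (6 ZaXb + 6 XabYa + 3 ZabXc + 1 ZabcXa); 4n has 40 (12 ZaXb +
#' 12 XabYa + 12 ZabXc + 4 ZabcXa); 6n has 1.
#'
#' @param group Group label (\code{"1x"}, ..., \code{"6n"}).
#' @param nFirstNeighbors Optional declared first-neighbor count; must be
#'   consistent with the group.
#' @return List of \code{\linkS4class{LocalFrame}} objects.
#' @export
enumerateFrames <- function(group, nFirstNeighbors = NULL) {
  if (!group %in% .groupLabels) stop("unknown group label: ", group)
  nReq <- .groupNeighborCount[[group]]
  if (!is.null(nFirstNeighbors) && nFirstNeighbors != nReq)
    stop(sprintf("group %s implies %d first neighbors, got %d", group, nReq,
                 nFirstNeighbors))
  fr <- list()
  add <- function(f) fr[[length(fr) + 1L]] <<- f
  if (group == "1x") {
    add(.mkFrame("1x", 1, "ZaXany", .axis("Z", "a"), .axis("X", "any")))
  } else if (group == "1p") {
    add(.mkFrame("1p", 1, "ZaXx", .axis("Z", "a"), .axis("X", "x")))
  } else if (group == "2x") {
    add(.mkFrame("2x", 1, "ZaXany", .axis("Z", "a"), .axis("X", "any")))
    add(.mkFrame("2x", 2, "ZbXany", .axis("Z", "b"), .axis("X", "any")))
  } else if (group == "6n") {
    add(.mkFrame("6n", 1, "ZaXb", .axis("Z", "a"), .axis("X", "b")))
  } else {
    ltr <- .letters(nReq)
    rot <- 1L
    for (z in ltr) for (x in setdiff(ltr, z)) {     # band 1..: ZaXb
      add(.mkFrame(group, rot, paste0("Z", z, "X", x),
                   .axis("Z", z), .axis("X", x)))
      rot <- rot + 1L
    }
    pairs <- utils::combn(ltr, 2, simplify = FALSE)
    rot <- 21L                                       # band 21..: XabYa
    for (p in pairs) for (y in p) {
      add(.mkFrame(group, rot, paste0("X", p[1], p[2], "Y", y),
                   .axis("X", p), .axis("Y", y)))
      rot <- rot + 1L
    }
    if (group == "2p") {                             # band 71-72: ZabYa
      rot <- 71L
      for (y in c("a", "b")) {
        add(.mkFrame(group, rot, paste0("ZabY", y),
                     .axis("Z", c("a", "b")), .axis("Y", y)))
        rot <- rot + 1L
      }
    }
    if (group %in% c("3n", "4n")) {
      rot <- 41L                                     # band 41..: ZabXc
      for (p in pairs) for (x in setdiff(ltr, p)) {
        add(.mkFrame(group, rot, paste0("Z", p[1], p[2], "X", x),
                     .axis("Z", p), .axis("X", x)))
        rot <- rot + 1L
      }
      rot <- 61L                                     # band 61..: ZabcXa
      # quartet order abc, abd, bcd, acd with X on the first triple member
      # (ZabcXa, ZabdXa, ZbcdXb, ZacdXa)
      triples <- if (nReq == 4)
        list(c("a", "b", "c"), c("a", "b", "d"), c("b", "c", "d"),
             c("a", "c", "d"))
      else list(c("a", "b", "c"))
      for (tp in triples) {
        add(.mkFrame(group, rot, paste0("Z", paste(tp, collapse = ""), "X",
                                        tp[1]),
                     .axis("Z", tp), .axis("X", tp[1])))
        rot <- rot + 1L
      }
    }
  }
  fr
}

#' Frame census over a set of per-group atom-type counts
#'
#' Multiplies each group's enumerated frame count by the number of atom
#' types in the group, reproducing the rotated-entry bookkeeping of a bank.
#' @param typeCounts Named integer vector, names are group labels.
#' @return Data frame with columns group, nFrames, nTypes, total, plus a
#'   \code{"grandTotal"} attribute.
#' @export
frameCensus <- function(typeCounts) {
  groups <- names(typeCounts)
  nf <- vapply(groups, function(g) length(enumerateFrames(g)), integer(1))
  out <- data.frame(group = groups, nFrames = nf,
                    nTypes = as.integer(typeCounts),
                    total = nf * as.integer(typeCounts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "grandTotal") <- sum(out$total)
  out
}

#' System family of a frame
#'
#' Maps a frame (or frame name) to its system family: \code{ZaXb},
#' \code{XabYa}, \code{ZabXc}, \code{ZabcXa}, \code{ZabYa}, \code{ZaXany}
#' or \code{ZaXx}.
#' @param frame A \code{LocalFrame} or a frame name string.
#' @return Family string.
#' @export
frameFamily <- function(frame) {
  nm <- if (methods::is(frame, "LocalFrame")) frame@system else
    sub("^.*-", "", frame)
  vapply(nm, function(s) {
    if (grepl("Xany$", s)) return("ZaXany")
    if (grepl("Xx$", s)) return("ZaXx")
    if (grepl("^X", s)) return("XabYa")
    if (grepl("^Z[a-f]{3}X", s)) return("ZabcXa")
    if (grepl("^Z[a-f]{2}Y", s)) return("ZabYa")
    if (grepl("^Z[a-f]{2}X", s)) return("ZabXc")
    "ZaXb"
  }, character(1), USE.NAMES = FALSE)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (zero-length) direction")
  v / n
}

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# direction for an axis spec given unit bond vectors (named rows) and the
# optional second-neighbor direction
.axisDirection <- function(spec, dirs, xDir, primary = NULL) {
  tg <- spec$targets
  if (identical(tg, "any")) {
    stopifnot(!is.null(primary))
    # deterministic: the coordinate axis least parallel to the primary axis
    ax <- diag(3)[which.min(abs(primary)), ]
    return(ax)
  }
  if (identical(tg, "x")) {
    if (is.null(xDir)) stop("frame needs a second-or-further neighbor (x)")
    return(xDir)
  }
  miss <- setdiff(tg, rownames(dirs))
  if (length(miss))
    stop("missing labeled neighbor(s): ", paste(miss, collapse = ", "))
  .unit(colMeans(dirs[tg, , drop = FALSE]))
}

#' Realize a local frame as a rotation matrix from neighbor geometry
#'
#' The primary axis lies exactly along its spec direction; the secondary
#' axis is Gram-Schmidt orthogonalized against it; the third axis follows
#' the right-hand rule. The returned matrix maps global displacement
#' vectors to local coordinates (rows are the local X, Y, Z axes).
#'
#' @param frame A \code{\linkS4class{LocalFrame}}.
#' @param central Length-3 position of the central atom.
#' @param neighbors Matrix of first-neighbor positions with rownames
#'   \code{"a"}, \code{"b"}, ... (descending atomic number, ties by input
#'   order, is the labeling convention used by the generator).
#' @param secondNeighbor Optional position of the second-or-further neighbor
#'   used by \code{ZaXx} frames.
#' @param angularTol Minimum angle (degrees) between the axis specs before
#'   the frame is declared degenerate (default 1).
#' @return 3-by-3 orthonormal rotation matrix (det +1) with attribute
#'   \code{"frame"} carrying the frame name.
#' @export
realizeFrame <- function(frame, central, neighbors, secondNeighbor = NULL,
                         angularTol = 1) {
  nb <- rbind(neighbors)
  if (is.null(rownames(nb)))
    rownames(nb) <- letters[seq_len(nrow(nb))]
  dirs <- t(apply(nb, 1, function(p) .unit(p - central)))
  rownames(dirs) <- rownames(nb)
  xDir <- if (!is.null(secondNeighbor)) .unit(secondNeighbor - central)
  e1 <- .axisDirection(frame@axis1, dirs, xDir)
  raw2 <- .axisDirection(frame@axis2, dirs, xDir, primary = e1)
  # Gram-Schmidt; reject near-collinear axis specs
  proj <- raw2 - sum(raw2 * e1) * e1
  if (sqrt(sum(proj^2)) < sin(angularTol * pi / 180))
    stop(sprintf("degenerate frame %s: axis specs are collinear",
                 frame@name))
  e2 <- .unit(proj)
  axes <- list()
  axes[[frame@axis1$label]] <- e1
  axes[[frame@axis2$label]] <- e2
  lab3 <- setdiff(c("X", "Y", "Z"), c(frame@axis1$label, frame@axis2$label))
  axes[[lab3]] <- switch(lab3,
    X = .cross(axes$Y, axes$Z),
    Y = .cross(axes$Z, axes$X),
    Z = .cross(axes$X, axes$Y))
  R <- rbind(X = axes$X, Y = axes$Y, Z = axes$Z)
  stopifnot(abs(det(R) - 1) < 1e-9)
  attr(R, "frame") <- frame@name
  R
}

#' Recompute an atom type's parameters in a set of target frames
#'
#' Each member atom carries its own geometry and its Plm populations
#' expressed in the source frame realized from that geometry. For every
#' target frame the member populations are rotated into the target frame
#' and averaged; the unweighted sample standard deviation over members
#' yields the per-frame inconsistency flag (some Plm sd > threshold).
#' No symmetry filtering is applied.
#'
#' @param members List of member atoms; each a list with \code{central}
#'   (length-3), \code{neighbors} (labeled matrix), optional
#'   \code{secondNeighbor}, and \code{plm} (named vector, source frame).
#' @param sourceFrame The \code{LocalFrame} the member populations are
#'   expressed in.
#' @param targetFrames List of \code{LocalFrame}s.
#' @param sdThreshold Inconsistency threshold in electrons (default 0.05).
#' @return Named list (by target frame name) of lists with \code{mean},
#'   \code{sd} (dense named vectors), \code{n} members used and
#'   \code{inconsistent}. Members whose geometry cannot realize a frame are
#'   skipped with a warning.
#' @export
recomputeTypeInFrames <- function(members, sourceFrame, targetFrames,
                                  sdThreshold = 0.05) {
  stopifnot(length(members) >= 2)
  out <- list()
  for (tf in targetFrames) {
    rows <- list()
    for (i in seq_along(members)) {
      mb <- members[[i]]
      rec <- tryCatch({
        Rs <- realizeFrame(sourceFrame, mb$central, mb$neighbors,
                           mb$secondNeighbor)
        Rt <- realizeFrame(tf, mb$central, mb$neighbors, mb$secondNeighbor)
        rotatePlm(mb$plm, Rt %*% t(Rs))
      }, error = function(e) {
        warning(sprintf("member %d skipped for frame %s: %s", i, tf@name,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
    }
    if (!length(rows)) {
      out[[tf@name]] <- NULL
      next
    }
    M <- do.call(rbind, rows)
    mu <- colMeans(M)
    sdv <- if (nrow(M) > 1) apply(M, 2, stats::sd) else mu * 0
    out[[tf@name]] <- list(mean = mu, sd = sdv, n = nrow(M),
                           inconsistent = any(sdv > sdThreshold + 1e-12))
  }
  out
}

#' Export a list of frames as a table
#' @param frames List of \code{LocalFrame}s.
#' @return Data frame with name, group, rotation number, system and axis
#'   specs.
#' @export
framesToTable <- function(frames) {
  data.frame(
    name = vapply(frames, function(f) f@name, character(1)),
    group = vapply(frames, function(f) f@group, character(1)),
    rotation = vapply(frames, function(f) f@rotation, integer(1)),
    system = vapply(frames, function(f) f@system, character(1)),
    axis1 = vapply(frames, function(f)
      paste0(f@axis1$label, "<-", paste(f@axis1$targets, collapse = "")),
      character(1)),
    axis2 = vapply(frames, function(f)
      paste0(f@axis2$label, "<-", paste(f@axis2$targets, collapse = "")),
      character(1)),
    stringsAsFactors = FALSE)
}
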