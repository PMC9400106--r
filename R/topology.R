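# Topology classification: layered element -> first-neighbor-count ->
# first-neighbor-types -> second-neighbor-count -> second-neighbor-types
# trees with atom-type names at the terminal level.
#
# Three tree kinds: "extended" uses all five levels; "general" stops before
# the second-neighbor levels; "concise" additionally drops the
# first-neighbor element level (and leaf names). Planarity and ring
# membership are carried as leaf annotations, never as dividing levels.

# multiset of elements as a deterministic string: alphabetical, wildcard
# "X" sorted last
.elementMultiset <- function(els) {
  if (!length(els)) return("")
  ord <- order(els == "X", els)
  paste(els[ord], collapse = ",")
}

# the five level values of one entry
.topoSignature <- function(entry) {
  tp <- entry@topology
  nb <- tp@neighbors
  first <- nb[nb$shell == 1, , drop = FALSE]
  second <- nb[nb$shell == 2, , drop = FALSE]
  if (nrow(second)) {
    n2 <- as.character(nrow(second))
    e2 <- .elementMultiset(second$element)
  } else if (tp@secondShell == "none") {
    n2 <- "none"; e2 <- "none"
  } else {
    n2 <- "unspecified"; e2 <- "unspecified"
  }
  c(element = tp@element, n1 = as.character(nrow(first)),
    firstElements = .elementMultiset(first$element), n2 = n2,
    secondElements = e2)
}

#' Hierarchical topology tree over a bank
#'
#' @slot kind \code{"extended"}, \code{"general"} or \code{"concise"}.
#' @slot paths Data frame: one row per entry with the level values used by
#'   the tree kind plus \code{name}, \code{planar} and \code{rings}
#'   annotations.
#' @slot leafLabels Optional per-entry annotations added by
#'   \code{\link{overlayDensityClusters}} (data frame or NULL-length list).
#' @export
setClass("TopologyTree",
  representation(kind = "character", paths = "data.frame",
                 leafLabels = "list"))

setValidity("TopologyTree", function(object) {
  if (!object@kind %in% c("extended", "general", "concise"))
    return("kind must be extended/general/concise")
  if (anyDuplicated(object@paths$name))
    return("every bank entry must appear in exactly one leaf")
  TRUE
})

setMethod("show", "TopologyTree", function(object) {
  lv <- attr(object@paths, "levels")
  cat(sprintf("TopologyTree (%s): %d entries, %d terminal clusters\n",
              object@kind, nrow(object@paths),
              length(unique(do.call(paste, object@paths[lv])))))
})

.treeLevels <- function(kind) switch(kind,
  extended = c("element", "n1", "firstElements", "n2", "secondElements"),
  general = c("element", "n1", "firstElements"),
  concise = c("element", "n1"))

#' Build a topology tree
#'
#' @param bank An \code{\linkS4class{AtomTypeBank}} or list of entries.
#' @param kind Tree kind: \code{"extended"} (default), \code{"general"} or
#'   \code{"concise"}.
#' @return A \code{\linkS4class{TopologyTree}}. Construction is
#'   deterministic and invariant under entry permutation (children sort
#'   alphabetically, then numerically).
#' @export
buildTopologyTree <- function(bank, kind = c("extended", "general",
                                             "concise")) {
  kind <- match.arg(kind)
  entries <- if (methods::is(bank, "AtomTypeBank")) bank@entries else bank
  sig <- t(vapply(entries, .topoSignature, character(5)))
  df <- as.data.frame(sig, stringsAsFactors = FALSE)
  df$name <- vapply(entries, function(e) e@name, character(1))
  df$planar <- vapply(entries, function(e)
    e@topology@groupLabel %in% c("1p", "2p", "3p"), logical(1))
  df$rings <- vapply(entries, function(e) {
    r <- e@topology@neighbors$rings
    .elementMultiset(unique(unlist(strsplit(r[nzchar(r)], ","))))
  }, character(1))
  lv <- .treeLevels(kind)
  ord <- do.call(order, c(df[lv], list(df$name)))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "levels") <- lv
  methods::new("TopologyTree", kind = kind, paths = df, leafLabels = list())
}

#' Terminal clusters of an extended topology tree
#'
#' Atom types with identical first- and second-neighbor numbers and types
#' form one terminal cluster; the clusters partition the bank.
#' @param tree An extended \code{TopologyTree}.
#' @return Named list of character vectors of atom-type names; names are
#'   the joined level values.
#' @export
terminalClusters <- function(tree) {
  stopifnot(methods::is(tree, "TopologyTree"))
  if (tree@kind != "extended")
    stop("terminal clusters are defined on the extended tree")
  lv <- attr(tree@paths, "levels")
  key <- do.call(paste, c(tree@paths[lv], sep = "|"))
  split(tree@paths$name, key)
}

#' Overlay density-cluster labels on a topology tree
#'
#' Attaches per-entry categories derived from multi-level density-cluster
#' label paths over all frames of each entry: \code{"main"} (always in its
#' frame's largest cluster), \code{"distinct"} (in the largest cluster for
#' some frames only), \code{"unique"} (always in singleton clusters),
#' \code{"outlier"} (labeled -1 everywhere) and \code{"complex"} (any other
#' combination).
#'
#' @param tree A general or concise \code{TopologyTree}.
#' @param labels Data frame with columns \code{entry}, \code{frame},
#'   \code{path} (underscore label paths, see
#'   \code{\link{multilevelCluster}}).
#' @return The tree with \code{leafLabels} populated (data frame entry,
#'   category, mainFraction).
#' @export
overlayDensityClusters <- function(tree, labels) {
  stopifnot(methods::is(tree, "TopologyTree"))
  if (tree@kind == "extended")
    stop("overlay is drawn on general or concise trees")
  need <- c("entry", "frame", "path")
  if (!all(need %in% names(labels)))
    stop("labels needs columns entry, frame, path")
  miss <- setdiff(tree@paths$name, labels$entry)
  if (length(miss))
    stop("missing density labels for: ", paste(miss, collapse = ", "))
  # largest cluster per frame
  labels$fam <- frameFamily(labels$frame)
  byFrame <- split(seq_len(nrow(labels)), labels$frame)
  sizes <- table(paste(labels$frame, labels$path, sep = "@"))
  labels$clusterSize <- as.integer(sizes[paste(labels$frame, labels$path,
                                               sep = "@")])
  mainOf <- vapply(byFrame, function(i) {
    i <- i[labels$path[i] != "-1"]
    if (!length(i)) return("")
    labels$path[i][which.max(labels$clusterSize[i])]
  }, character(1))
  labels$inMain <- labels$path == mainOf[labels$frame] & labels$path != "-1"
  cat0 <- vapply(split(seq_len(nrow(labels)), labels$entry), function(i) {
    inMain <- labels$inMain[i]; path <- labels$path[i]
    size <- labels$clusterSize[i]
    if (all(inMain)) return("main")
    if (any(inMain)) return("distinct")
    if (all(path == "-1")) return("outlier")
    if (all(size == 1)) return("unique")
    "complex"
  }, character(1))
  frac <- vapply(split(labels$inMain, labels$entry), mean, numeric(1))
  ann <- data.frame(entry = names(cat0), category = unname(cat0),
                    mainFraction = unname(frac[names(cat0)]),
                    stringsAsFactors = FALSE)
  tree@leafLabels <- list(annotations = ann)
  tree
}

# documented background palette for DOT export (ring colors are arbitrary
# but fixed)
.categoryPalette <- c(main = "white", distinct = "lightsalmon",
                      unique = "red", outlier = "gray80",
                      complex = "white")

#' Export a topology tree in DOT (Graphviz) format
#'
#' Planar-group leaves use bold font; density-cluster categories (if
#' overlaid) color the leaf background (red = unique, lighter hue =
#' distinct, white = main/complex).
#' @param tree A \code{TopologyTree}.
#' @param file Optional output path.
#' @return The DOT source as a character string (invisibly when written).
#' @export
treeToDot <- function(tree, file = NULL) {
  lv <- attr(tree@paths, "levels")
  df <- tree@paths
  ann <- if (length(tree@leafLabels)) tree@leafLabels$annotations
  nodes <- character(0); edges <- character(0)
  seen <- character(0)
  nid <- function(path) paste0("n", match(path, seen))
  addNode <- function(path, label, extra = "") {
    if (!path %in% seen) {
      seen <<- c(seen, path)
      nodes <<- c(nodes, sprintf("%s [label=\"%s\"%s];", nid(path), label,
                                 extra))
    }
    nid(path)
  }
  root <- addNode("<root>", "bank")
  for (i in seq_len(nrow(df))) {
    parent <- root; acc <- "<root>"
    for (l in lv) {
      acc <- paste(acc, df[[l]][i], sep = "/")
      id <- addNode(acc, df[[l]][i])
      e <- paste(parent, "->", id)
      if (!e %in% edges) edges <- c(edges, e)
      parent <- id
    }
    if (tree@kind != "concise") {
      style <- if (df$planar[i]) ", fontname=\"bold\"" else ""
      if (!is.null(ann)) {
        cat0 <- ann$category[match(df$name[i], ann$entry)]
        style <- paste0(style, sprintf(
          ", style=filled, fillcolor=\"%s\"", .categoryPalette[[cat0]]))
      }
      leaf <- addNode(paste(acc, df$name[i], sep = "/"), df$name[i], style)
      edges <- c(edges, paste(parent, "->", leaf))
    }
  }
  dot <- paste(c("digraph topology {", "  rankdir=TB;",
                 paste0("  ", nodes), paste0("  ", edges), "}"),
               collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' Export a topology tree as nested JSON
#' @param tree A \code{TopologyTree}.
#' @param file Optional output path.
#' @return JSON string (invisibly when written).
#' @export
treeToJSON <- function(tree, file = NULL) {
  lv <- attr(tree@paths, "levels")
  df <- tree@paths
  build <- function(rows, depth) {
    if (depth > length(lv))
      return(lapply(rows, function(i) list(name = df$name[i],
                                           planar = df$planar[i],
                                           rings = df$rings[i])))
    vals <- vapply(rows, function(i) df[[lv[depth]]][i], character(1))
    lapply(split(rows, vals), build, depth = depth + 1)
  }
  js <- jsonlite::toJSON(build(seq_len(nrow(df)), 1), auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
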