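# Central S4 classes. Populations are in electrons, coordinates in Angstrom,
# kappa / kappa' dimensionless.

.knownElements <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "X")
.groupLabels <- c("1x", "1p", "2x", "2p", "3p", "3n", "4n", "6n")
.groupNeighborCount <- c("1x" = 1L, "1p" = 1L, "2x" = 2L, "2p" = 2L,
                         "3p" = 3L, "3n" = 3L, "4n" = 4L, "6n" = 6L)

#' Multipole parameter set of a pseudoatom
#'
#' Holds the Hansen-Coppens parameters of one atom type: the spherical
#' valence population \code{pval}, the contraction-expansion scalings
#' \code{kappa} (spherical valence) and \code{kappaPrime} (deformation
#' valence), and the deformation populations \code{plm} with their sample
#' standard deviations \code{sd} (named vectors, names \code{"P10"},
#' \code{"P3-2"}, ..., l <= 4).
#'
#' @slot kappa Dimensionless positive scaling of the spherical valence.
#' @slot kappaPrime Dimensionless positive scaling of the deformation radial
#'   functions.
#' @slot pval Valence population in electrons, positive.
#' @slot plm Named numeric vector of deformation populations (electrons).
#' @slot sd Named numeric vector of sample standard deviations; covers every
#'   stored \code{plm} key.
#' @export
setClass("MultipoleParams",
  representation(kappa = "numeric", kappaPrime = "numeric", pval = "numeric",
                 plm = "numeric", sd = "numeric"),
  prototype(kappa = 1, kappaPrime = 1, pval = 1,
            plm = stats::setNames(numeric(0), character(0)),
            sd = stats::setNames(numeric(0), character(0))))

setValidity("MultipoleParams", function(object) {
  msg <- character(0)
  if (length(object@kappa) != 1 || !is.finite(object@kappa) ||
      object@kappa <= 0) msg <- c(msg, "kappa must be a single positive value")
  if (length(object@kappaPrime) != 1 || !is.finite(object@kappaPrime) ||
      object@kappaPrime <= 0)
    msg <- c(msg, "kappaPrime must be a single positive value")
  if (length(object@pval) != 1 || !is.finite(object@pval) || object@pval <= 0)
    msg <- c(msg, "pval must be a single positive value")
  if (length(object@plm)) {
    res <- tryCatch(.plmParseNames(names(object@plm)), error = function(e)
      conditionMessage(e))
    if (is.character(res)) msg <- c(msg, res)
    if (!all(names(object@plm) %in% names(object@sd)))
      msg <- c(msg, "every stored Plm key needs an sd entry")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MultipoleParams object
#' @param kappa,kappaPrime,pval Scalars (see class docs).
#' @param plm Named numeric vector of deformation populations.
#' @param sd Named numeric vector of sample standard deviations; defaults to
#'   zeros over the \code{plm} keys.
#' @return A \code{MultipoleParams} object.
#' @export
MultipoleParams <- function(kappa = 1, kappaPrime = 1, pval = 1,
                            plm = stats::setNames(numeric(0), character(0)),
                            sd = NULL) {
  if (is.null(sd)) sd <- stats::setNames(numeric(length(plm)), names(plm))
  methods::new("MultipoleParams", kappa = kappa, kappaPrime = kappaPrime,
               pval = pval, plm = plm, sd = sd)
}

#' Chemical topology of an atom type
#'
#' @slot element Element symbol of the central atom.
#' @slot neighbors Data frame of neighbor records, columns \code{shell}
#'   (1 = covalently bonded, 2 = bonded to a first neighbor), \code{element}
#'   (symbol or wildcard \code{"X"}), \code{planar} (logical flag: the atom
#'   and its first neighbors form a planar group), \code{rings} (comma string
#'   out of 3,4 and planar 5,6,7 ring sizes, may be empty), \code{parent}
#'   (index of the first-shell record a second-shell record attaches to;
#'   \code{NA} for shell 1).
#' @slot groupLabel One of 1x, 1p, 2x, 2p, 3p, 3n, 4n, 6n.
#' @slot secondShell \code{"records"} if second-shell records are present,
#'   \code{"none"} if the type cannot have second neighbors, or
#'   \code{"unspecified"}.
#' @export
setClass("AtomTypeTopology",
  representation(element = "character", neighbors = "data.frame",
                 groupLabel = "character", secondShell = "character"))

setValidity("AtomTypeTopology", function(object) {
  msg <- character(0)
  nb <- object@neighbors
  need <- c("shell", "element", "planar", "rings", "parent")
  if (!all(need %in% names(nb)))
    return(paste("neighbors needs columns", paste(need, collapse = ", ")))
  if (!object@element %in% setdiff(.knownElements, "X"))
    msg <- c(msg, paste("unknown central element:", object@element))
  if (!all(nb$element %in% .knownElements))
    msg <- c(msg, paste("unknown neighbor element(s):",
                        paste(setdiff(nb$element, .knownElements),
                              collapse = ", ")))
  n1 <- sum(nb$shell == 1)
  if (n1 < 1) msg <- c(msg, "at least one first-shell neighbor is required")
  if (!object@groupLabel %in% .groupLabels)
    msg <- c(msg, paste("unknown group label:", object@groupLabel))
  else if (.groupNeighborCount[[object@groupLabel]] != n1)
    msg <- c(msg, sprintf(
      "group %s implies %d first neighbors but %d are declared",
      object@groupLabel, .groupNeighborCount[[object@groupLabel]], n1))
  i2 <- which(nb$shell == 2)
  if (length(i2)) {
    first <- which(nb$shell == 1)
    bad <- !(nb$parent[i2] %in% first)
    if (any(bad))
      msg <- c(msg, "every second-shell record must attach to a declared first-shell record")
    if (object@secondShell != "records")
      msg <- c(msg, "secondShell must be \"records\" when shell-2 records exist")
  }
  if (!object@secondShell %in% c("records", "none", "unspecified"))
    msg <- c(msg, "secondShell must be records/none/unspecified")
  if (length(msg)) msg else TRUE
})

#' Construct an AtomTypeTopology
#' @param element Central element symbol.
#' @param neighbors Neighbor data frame (see class docs); convenience: a
#'   character vector of first-neighbor elements is also accepted.
#' @param groupLabel Group label (1x..6n).
#' @param secondShell "records", "none" or "unspecified"; inferred when
#'   omitted.
#' @return An \code{AtomTypeTopology} object.
#' @export
AtomTypeTopology <- function(element, neighbors, groupLabel,
                             secondShell = NULL) {
  if (is.character(neighbors))
    neighbors <- data.frame(shell = 1L, element = neighbors, planar = FALSE,
                            rings = "", parent = NA_integer_,
                            stringsAsFactors = FALSE)
  if (is.null(secondShell))
    secondShell <- if (any(neighbors$shell == 2)) "records" else "unspecified"
  methods::new("AtomTypeTopology", element = element, neighbors = neighbors,
               groupLabel = groupLabel, secondShell = secondShell)
}

#' One atom-type record of a data bank
#'
#' @slot name Bank identifier (e.g. \code{"C313b"}).
#' @slot topology An \code{\linkS4class{AtomTypeTopology}}.
#' @slot frameName Name of the deposited local coordinate system, e.g.
#'   \code{"4n_41-ZabXc"}.
#' @slot params A \code{\linkS4class{MultipoleParams}}.
#' @slot inconsistent Flag: \code{TRUE} iff some Plm sample standard
#'   deviation exceeds 0.05 e.
#' @export
setClass("AtomTypeEntry",
  representation(name = "character", topology = "AtomTypeTopology",
                 frameName = "character", params = "MultipoleParams",
                 inconsistent = "logical"))

setValidity("AtomTypeEntry", function(object) {
  msg <- character(0)
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  expect <- any(object@params@sd > 0.05 + 1e-12)
  if (!identical(object@inconsistent, expect))
    msg <- c(msg, sprintf(
      "inconsistent flag is %s but some-Plm-sd>0.05 is %s",
      object@inconsistent, expect))
  if (length(msg)) msg else TRUE
})

#' Construct an AtomTypeEntry
#' @param name Bank identifier.
#' @param topology \code{AtomTypeTopology}.
#' @param frameName Deposited local-coordinate-system name.
#' @param params \code{MultipoleParams}.
#' @return An \code{AtomTypeEntry}; the inconsistency flag is derived from
#'   the parameter standard deviations (threshold 0.05 e).
#' @export
AtomTypeEntry <- function(name, topology, frameName, params) {
  methods::new("AtomTypeEntry", name = name, topology = topology,
               frameName = frameName, params = params,
               inconsistent = any(params@sd > 0.05 + 1e-12))
}

#' A collection of atom-type entries
#'
#' Thin ordered container over \code{\linkS4class{AtomTypeEntry}} objects
#' with list-like access by position or entry name.
#' @slot entries List of \code{AtomTypeEntry} objects.
#' @export
setClass("AtomTypeBank", representation(entries = "list"))

setValidity("AtomTypeBank", function(object) {
  ok <- vapply(object@entries, methods::is, logical(1), "AtomTypeEntry")
  if (!all(ok)) return("all entries must be AtomTypeEntry objects")
  nm <- vapply(object@entries, function(e) e@name, character(1))
  if (anyDuplicated(nm)) return("duplicated entry names")
  TRUE
})

#' Construct an AtomTypeBank
#' @param entries List of \code{AtomTypeEntry} objects.
#' @return An \code{AtomTypeBank}.
#' @export
AtomTypeBank <- function(entries = list()) {
  methods::new("AtomTypeBank", entries = entries)
}

#' @describeIn AtomTypeBank Number of entries.
#' @param x An \code{AtomTypeBank}.
#' @export
setMethod("length", "AtomTypeBank", function(x) length(x@entries))

#' @describeIn AtomTypeBank Entry names.
#' @export
setMethod("names", "AtomTypeBank", function(x)
  vapply(x@entries, function(e) e@name, character(1)))

#' @describeIn AtomTypeBank Extract one entry by position or name.
#' @param i Index or entry name.
#' @export
setMethod("[[", "AtomTypeBank", function(x, i) {
  if (is.character(i)) i <- match(i, names(x))
  x@entries[[i]]
})

setMethod("show", "AtomTypeBank", function(object) {
  el <- table(vapply(object@entries, function(e) e@topology@element,
                     character(1)))
  cat("AtomTypeBank with", length(object), "entries\n")
  if (length(el))
    cat("  elements:", paste(names(el), el, sep = ":", collapse = " "), "\n")
})

setMethod("show", "MultipoleParams", function(object) {
  cat(sprintf("MultipoleParams: kappa=%.4f kappa'=%.4f Pval=%.4f, %d Plm\n",
              object@kappa, object@kappaPrime, object@pval,
              length(object@plm)))
})

setMethod("show", "AtomTypeEntry", function(object) {
  cat(sprintf("AtomTypeEntry %s (%s, group %s, frame %s)%s\n", object@name,
              object@topology@element, object@topology@groupLabel,
              object@frameName,
              if (object@inconsistent) " [inconsistent]" else ""))
})

## accessors ----------------------------------------------------------------

#' @rdname accessors
#' @param object A package object.
#' @export
setGeneric("entryName", function(object) standardGeneric("entryName"))
#' Accessors for atom-type objects
#' @name accessors
#' @param object A package object.
#' @return The corresponding slot value.
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("multipoleParams", function(object)
  standardGeneric("multipoleParams"))
#' @rdname accessors
#' @export
setGeneric("isInconsistent", function(object)
  standardGeneric("isInconsistent"))

#' @rdname accessors
setMethod("entryName", "AtomTypeEntry", function(object) object@name)
#' @rdname accessors
setMethod("groupLabel", "AtomTypeEntry", function(object)
  object@topology@groupLabel)
#' @rdname accessors
setMethod("groupLabel", "AtomTypeTopology", function(object)
  object@groupLabel)
#' @rdname accessors
setMethod("multipoleParams", "AtomTypeEntry", function(object) object@params)
#' @rdname accessors
setMethod("isInconsistent", "AtomTypeEntry", function(object)
  object@inconsistent)
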