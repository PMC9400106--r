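# Plain-text bank dialect: reader, writer, storage filter, group assignment.
#
# Grammar (one block per entry, key-value lines, '#' comments ignored):
#   TYPE <name>
#   ELEMENT <symbol>
#   GROUP <1x|1p|2x|2p|3p|3n|4n|6n>
#   FRAME <local-coordinate-system name>
#   SECOND none                        (optional: type cannot have 2nd shell)
#   NB <shell> <element|X> planar=<0|1> rings=<csv|-> parent=<idx|->
#   KAPPA  <value> <sd>
#   KAPPAP <value> <sd>
#   PVAL   <value> <sd>
#   PLM <l> <m> <value> <sd>
#   END
# Numbers are written with six decimals; a document produced by writeBank()
# is canonical and round-trips bit-exactly.

.fmtNum <- function(x) sprintf("%.6f", x)

#' Write an atom-type bank in the package text dialect
#'
#' @param bank An \code{\linkS4class{AtomTypeBank}} (or list of entries).
#' @param file Optional path; when omitted the document is returned as a
#'   single string.
#' @return The document, invisibly when written to a file.
#' @export
writeBank <- function(bank, file = NULL) {
  entries <- if (methods::is(bank, "AtomTypeBank")) bank@entries else bank
  blocks <- vapply(entries, .writeEntry, character(1))
  doc <- paste0(paste(blocks, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}

.writeEntry <- function(e) {
  tp <- e@topology; pp <- e@params
  out <- c(paste("TYPE", e@name),
           paste("ELEMENT", tp@element),
           paste("GROUP", tp@groupLabel),
           paste("FRAME", e@frameName))
  if (tp@secondShell == "none") out <- c(out, "SECOND none")
  nb <- tp@neighbors
  for (i in seq_len(nrow(nb))) {
    rings <- if (nzchar(nb$rings[i])) nb$rings[i] else "-"
    parent <- if (is.na(nb$parent[i])) "-" else as.character(nb$parent[i])
    out <- c(out, sprintf("NB %d %s planar=%d rings=%s parent=%s",
                          nb$shell[i], nb$element[i], as.integer(nb$planar[i]),
                          rings, parent))
  }
  out <- c(out,
           paste("KAPPA", .fmtNum(pp@kappa), .fmtNum(0)),
           paste("KAPPAP", .fmtNum(pp@kappaPrime), .fmtNum(0)),
           paste("PVAL", .fmtNum(pp@pval), .fmtNum(0)))
  if (length(pp@plm)) {
    lm <- .plmParseNames(names(pp@plm))
    ord <- order(lm$l, lm$m)
    for (i in ord)
      out <- c(out, sprintf("PLM %d %d %s %s", lm$l[i], lm$m[i],
                            .fmtNum(pp@plm[i]), .fmtNum(pp@sd[i])))
  }
  paste(c(out, "END"), collapse = "\n")
}

#' Parse an atom-type bank document
#'
#' @param text Bank document as a single string, character vector of lines,
#'   or a file path (existing file).
#' @return An \code{\linkS4class{AtomTypeBank}}; entries are validated
#'   against the type invariants. Malformed blocks raise an error naming the
#'   entry and line.
#' @export
parseBank <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  keep <- which(nzchar(trimws(lines)))
  entries <- list()
  cur <- NULL; curStart <- NA_integer_
  for (i in keep) {
    ln <- trimws(lines[i])
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "TYPE") {
      if (!is.null(cur)) stop(sprintf(
        "line %d: TYPE before END of entry '%s' (line %d)", i, cur$name,
        curStart))
      if (length(tok) != 2) stop(sprintf("line %d: TYPE needs a name", i))
      cur <- list(name = tok[2], nb = list(), plm = numeric(0),
                  sd = numeric(0), second = "unspecified")
      curStart <- i
      next
    }
    if (is.null(cur)) stop(sprintf("line %d: content outside an entry block", i))
    err <- function(msg) stop(sprintf("entry '%s', line %d: %s", cur$name, i,
                                      msg), call. = FALSE)
    switch(tok[1],
      ELEMENT = { if (length(tok) != 2) err("ELEMENT needs a symbol")
                  cur$element <- tok[2] },
      GROUP = { if (length(tok) != 2) err("GROUP needs a label")
                cur$group <- tok[2] },
      FRAME = { if (length(tok) != 2) err("FRAME needs a name")
                cur$frame <- tok[2] },
      SECOND = { if (length(tok) != 2 || tok[2] != "none")
                   err("SECOND only admits 'none'")
                 cur$second <- "none" },
      NB = {
        if (length(tok) != 6) err("NB needs: shell element planar rings parent")
        kv <- function(j, key) {
          if (!startsWith(tok[j], paste0(key, "=")))
            err(sprintf("NB field %d must be %s=...", j, key))
          sub(paste0("^", key, "="), "", tok[j])
        }
        shell <- suppressWarnings(as.integer(tok[2]))
        if (is.na(shell) || !shell %in% c(1L, 2L)) err("NB shell must be 1 or 2")
        pl <- kv(4, "planar"); ri <- kv(5, "rings"); pa <- kv(6, "parent")
        if (!pl %in% c("0", "1")) err("planar must be 0 or 1")
        cur$nb[[length(cur$nb) + 1L]] <- data.frame(
          shell = shell, element = tok[3], planar = pl == "1",
          rings = if (ri == "-") "" else ri,
          parent = if (pa == "-") NA_integer_ else as.integer(pa),
          stringsAsFactors = FALSE)
      },
      KAPPA = { if (length(tok) != 3) err("KAPPA needs value and sd")
                cur$kappa <- as.numeric(tok[2]) },
      KAPPAP = { if (length(tok) != 3) err("KAPPAP needs value and sd")
                 cur$kappap <- as.numeric(tok[2]) },
      PVAL = { if (length(tok) != 3) err("PVAL needs value and sd")
               cur$pval <- as.numeric(tok[2]) },
      PLM = {
        if (length(tok) != 5) err("PLM needs l m value sd")
        l <- suppressWarnings(as.integer(tok[2]))
        m <- suppressWarnings(as.integer(tok[3]))
        if (is.na(l) || l < 0 || l > 4) err("PLM degree l must be in 0..4")
        if (is.na(m) || abs(m) > l) err("PLM order |m| must not exceed l")
        nm <- paste0("P", l, m)
        cur$plm[nm] <- as.numeric(tok[4])
        cur$sd[nm] <- as.numeric(tok[5])
      },
      END = {
        for (f in c("element", "group", "frame", "kappa", "kappap", "pval"))
          if (is.null(cur[[f]])) err(paste("missing field", toupper(f)))
        nb <- do.call(rbind, cur$nb)
        if (is.null(nb)) err("at least one NB record is required")
        second <- if (any(nb$shell == 2)) "records" else cur$second
        topo <- tryCatch(
          methods::new("AtomTypeTopology", element = cur$element,
                       neighbors = nb, groupLabel = cur$group,
                       secondShell = second),
          error = function(e) err(conditionMessage(e)))
        params <- tryCatch(
          MultipoleParams(cur$kappa, cur$kappap, cur$pval, cur$plm, cur$sd),
          error = function(e) err(conditionMessage(e)))
        entries[[length(entries) + 1L]] <-
          AtomTypeEntry(cur$name, topo, cur$frame, params)
        cur <- NULL
      },
      err(paste("unknown directive", tok[1])))
  }
  if (!is.null(cur))
    stop(sprintf("entry '%s' (line %d) is missing END", cur$name, curStart))
  AtomTypeBank(entries)
}

#' Storage filter for deformation populations
#'
#' Applies the bank storage rule: a population is kept iff its magnitude
#' exceeds 0.002 e, exceeds its own sample standard deviation, and its
#' (l, m) index is in the symmetry-allowed set.
#'
#' @param plm Named numeric vector of populations.
#' @param sd Named numeric vector covering all \code{plm} keys.
#' @param allowed Character vector of allowed names (\code{"P10"}, ...) or a
#'   two-column matrix/data frame of (l, m) pairs. Defaults to all indices.
#' @param floor Magnitude floor in electrons (default 0.002).
#' @return The filtered named vector (subset of the input; idempotent).
#' @export
filterStoredPlm <- function(plm, sd, allowed = NULL, floor = 0.002) {
  if (length(plm) == 0) return(plm)
  if (!all(names(plm) %in% names(sd)))
    stop("sd must cover all plm keys")
  if (is.null(allowed)) {
    allowedNames <- names(plm)
  } else if (is.character(allowed)) {
    allowedNames <- allowed
  } else {
    allowed <- as.data.frame(allowed)
    allowedNames <- paste0("P", allowed[[1]], allowed[[2]])
  }
  keep <- abs(plm) > floor & abs(plm) > sd[names(plm)] &
    names(plm) %in% allowedNames
  plm[keep]
}

#' Classify the neighbor arrangement into a frame group
#'
#' Assigns the group label from the number of first neighbors and their
#' arrangement: 1 neighbor is \code{"1x"} when the first and second neighbor
#' are collinear with the center (or no second neighbor exists), else
#' \code{"1p"}; 2 neighbors are \code{"2x"} when collinear else \code{"2p"};
#' 3 neighbors are \code{"3p"} when coplanar with the center else
#' \code{"3n"}; 4 and 6 neighbors map to \code{"4n"} / \code{"6n"}.
#'
#' @param firstNeighbors n-by-3 matrix of first-neighbor coordinates.
#' @param central Length-3 coordinate of the central atom.
#' @param secondNeighbors Optional matrix of second-neighbor coordinates
#'   (used for the 1-neighbor collinearity test).
#' @param angularTol Collinearity tolerance: within this many degrees of 180
#'   (default 5).
#' @param planarTol Planarity tolerance: maximum out-of-plane distance in
#'   Angstrom of any atom from the best-fit plane (default 0.1).
#' @return A group label string.
#' @export
assignGroup <- function(firstNeighbors, central, secondNeighbors = NULL,
                        angularTol = 5, planarTol = 0.1) {
  fn <- rbind(firstNeighbors)
  n <- nrow(fn)
  colinear <- function(p, q, o) {
    u <- p - o; v <- q - o
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi <= angularTol
  }
  if (n == 1) {
    if (is.null(secondNeighbors) || nrow(rbind(secondNeighbors)) == 0)
      return("1x")
    sn <- rbind(secondNeighbors)
    all2 <- apply(sn, 1, function(s) colinear(s, central, fn[1, ]))
    return(if (all(all2)) "1x" else "1p")
  }
  if (n == 2) return(if (colinear(fn[1, ], fn[2, ], central)) "2x" else "2p")
  if (n == 3) {
    pts <- rbind(central, fn)
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    maxDev <- max(abs(sweep(pts, 2, ctr) %*% sv$v[, 3]))
    return(if (maxDev <= planarTol) "3p" else "3n")
  }
  if (n == 4) return("4n")
  if (n == 6) return("6n")
  stop("unsupported number of first neighbors: ", n)
}

#' Export a bank as a flat CSV table
#'
#' One row per type with name, element, group, frame, kappa, Pval, kappa'
#' and the 24 deformation populations \code{P1-1}..\code{P44}.
#' @param bank An \code{AtomTypeBank}.
#' @param file Optional output path.
#' @return The data frame, invisibly when written.
#' @export
bankToTable <- function(bank, file = NULL) {
  idx <- plmIndices(4); cols <- idx$name[idx$l >= 1]
  rows <- lapply(bank@entries, function(e) {
    p <- .plmDense(e@params@plm)
    cbind(data.frame(name = e@name, element = e@topology@element,
                     group = e@topology@groupLabel, frame = e@frameName,
                     kappa = e@params@kappa, Pval = e@params@pval,
                     kappap = e@params@kappaPrime,
                     inconsistent = e@inconsistent,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p[cols]), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
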