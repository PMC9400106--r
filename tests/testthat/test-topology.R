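# topology trees: construction, terminal clusters, density overlay

# hand-built 12-entry fixture with known terminal structure
makeTopoFixture <- function() {
  mk <- function(name, el, first, second = NULL, group = NULL,
                 secondNone = FALSE) {
    if (is.null(group))
      group <- c("1x", "2p", "3p", "4n")[length(first)]
    nb <- data.frame(shell = 1L, element = first, planar = FALSE,
                     rings = "", parent = NA_integer_,
                     stringsAsFactors = FALSE)
    if (!is.null(second))
      nb <- rbind(nb, data.frame(shell = 2L, element = second,
                                 planar = FALSE, rings = "", parent = 1L,
                                 stringsAsFactors = FALSE))
    topo <- methods::new("AtomTypeTopology", element = el, neighbors = nb,
                         groupLabel = group,
                         secondShell = if (!is.null(second)) "records"
                         else if (secondNone) "none" else "unspecified")
    AtomTypeEntry(name, topo, paste0(group, "_1-ZaXb"),
                  MultipoleParams(pval = 4))
  }
  list(
    mk("C01", "C", c("C", "H", "H", "H"), c("C", "C")),   # cluster A
    mk("C02", "C", c("C", "H", "H", "H"), c("C", "C")),   # cluster A
    mk("C03", "C", c("C", "H", "H", "H"), c("C", "O")),   # cluster B
    mk("C04", "C", c("C", "C", "H", "H"), c("C", "C")),   # cluster C
    mk("C05", "C", c("C", "C", "H")),                     # cluster D
    mk("C06", "C", c("C", "C", "H")),                     # cluster D
    mk("N01", "N", c("C", "C", "C"), c("X", "X"), "3n"),  # cluster E
    mk("N02", "N", c("C", "C", "C"), c("X", "X"), "3n"),  # cluster E
    mk("N03", "N", c("C", "C", "C"), c("X", "H"), "3n"),  # cluster F
    mk("O01", "O", c("H", "H"), secondNone = TRUE),       # cluster G
    mk("O02", "O", c("C", "H")),                          # cluster H
    mk("H01", "H", "O"))                                  # cluster I
}

test_that("the 12-entry fixture yields the hand-enumerated 9 clusters", {
  entries <- makeTopoFixture()
  tree <- buildTopologyTree(entries, "extended")
  cl <- terminalClusters(tree)
  expect_length(cl, 9)
  sizes <- sort(vapply(cl, length, integer(1)))
  expect_equal(unname(sizes), c(1, 1, 1, 1, 1, 1, 2, 2, 2))
  expect_true(any(vapply(cl, function(x) setequal(x, c("C01", "C02")),
                         logical(1))))
  expect_true(any(vapply(cl, function(x) setequal(x, c("N01", "N02")),
                         logical(1))))
  # partition: every entry in exactly one cluster
  expect_setequal(unlist(cl), vapply(entries, entryName, character(1)))
})

test_that("second-neighbor detail splits extended but not general trees", {
  entries <- makeTopoFixture()[1:3]    # same through level 3
  ext <- buildTopologyTree(entries, "extended")
  gen <- buildTopologyTree(entries, "general")
  expect_length(terminalClusters(ext), 2)   # C,C vs C,O second shells
  lv <- attr(gen@paths, "levels")
  expect_equal(length(unique(do.call(paste, gen@paths[lv]))), 1)
})

test_that("types that cannot have second neighbors read 'none'", {
  entries <- makeTopoFixture()
  tree <- buildTopologyTree(entries, "extended")
  row <- tree@paths[tree@paths$name == "O01", ]
  expect_equal(row$n2, "none")
  expect_equal(row$secondElements, "none")
})

test_that("tree building is deterministic and order-invariant", {
  entries <- makeTopoFixture()
  t1 <- buildTopologyTree(entries, "extended")
  set.seed(3)
  t2 <- buildTopologyTree(sample(entries), "extended")
  expect_identical(t1@paths, t2@paths)
})

test_that("general-tree leaves refine to extended-tree leaves", {
  entries <- makeTopoFixture()
  ext <- terminalClusters(buildTopologyTree(entries, "extended"))
  gen <- buildTopologyTree(entries, "general")
  lv <- attr(gen@paths, "levels")
  genKey <- do.call(paste, c(gen@paths[lv], sep = "|"))
  genCl <- split(gen@paths$name, genKey)
  # every extended cluster sits inside exactly one general cluster
  for (e in ext) {
    host <- vapply(genCl, function(g) all(e %in% g), logical(1))
    expect_equal(sum(host), 1)
  }
  expect_equal(sum(lengths(ext)), length(entries))
})

test_that("density overlay categorizes unique/distinct/main leaves", {
  entries <- makeTopoFixture()[c(1, 2, 3)]
  gen <- buildTopologyTree(entries, "general")
  labels <- data.frame(
    entry = rep(c("C01", "C02", "C03"), each = 2),
    frame = rep(c("4n_1-ZaXb", "4n_21-XabYa"), 3),
    path = c("0", "0",      # C01 always in the big cluster
             "0", "1",      # C02 leaves it in one frame -> distinct
             "2", "3"),     # C03 alone everywhere -> unique
    stringsAsFactors = FALSE)
  out <- overlayDensityClusters(gen, labels)
  ann <- out@leafLabels$annotations
  expect_equal(ann$category[ann$entry == "C01"], "main")
  expect_equal(ann$category[ann$entry == "C02"], "distinct")
  expect_equal(ann$category[ann$entry == "C03"], "unique")
  # outlier label -1 in one frame with main elsewhere stays distinct
  labels$path[labels$entry == "C02"] <- c("0", "-1")
  ann2 <- overlayDensityClusters(gen, labels)@leafLabels$annotations
  expect_equal(ann2$category[ann2$entry == "C02"], "distinct")
  expect_error(overlayDensityClusters(gen, labels[1:4, ]), "missing")
  # DOT export carries the category colors
  dot <- treeToDot(out)
  expect_match(dot, "fillcolor=\"red\"")
  js <- treeToJSON(out)
  expect_true(jsonlite::validate(js))
})
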