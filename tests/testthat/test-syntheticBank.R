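# synthetic bank generator: determinism, validity, planted structure

test_that("generation is reproducible and entries validate", {
  spec <- defaultSyntheticSpec(typeScale = 0.3)
  s1 <- generateBank(spec, seed = 42)
  s2 <- generateBank(spec, seed = 42)
  expect_identical(writeBank(s1$bank), writeBank(s2$bank))
  expect_identical(s1$members, s2$members)
  s3 <- generateBank(spec, seed = 43)
  expect_false(identical(writeBank(s1$bank), writeBank(s3$bank)))
  # every entry passes validation and round-trips through the text format
  doc <- writeBank(s1$bank)
  expect_identical(writeBank(parseBank(doc)), doc)
  expect_true(all(vapply(s1$bank@entries, methods::validObject,
                         logical(1))))
  # ground truth is a bijection with the entries
  expect_setequal(s1$truth$entry, names(s1$bank))
})

test_that("zero noise and zero jitter give identical members with sd 0", {
  spec <- plantedClusterSpec("N", "3n", "sp3", "3m", "3n_61-ZabcXa",
                             plm = c(P30 = -0.1, P33 = -0.25), nTypes = 1,
                             nMembers = 3,
                             noise = list(plm = 0, kappa = 0, kappap = 0,
                                          pval = 0), jitterDeg = 0)
  sim <- generateBank(list(spec), seed = 1)
  e <- sim$bank[[1]]
  expect_equal(max(e@params@sd), 0)
  expect_false(isInconsistent(e))
  res <- recomputeTypeInFrames(sim$members[[1]]$members,
                               sim$members[[1]]$referenceFrame,
                               enumerateFrames("3n"))
  for (r in res) expect_lt(max(r$sd), 1e-12)
})

test_that("patterns violating the planted point group are rejected", {
  expect_error(
    plantedClusterSpec("C", "4n", "sp3", "-43m", "4n_41-ZabXc",
                       plm = c(P32 = -0.3, P10 = 0.1)),
    "violates the planted point group")
  expect_error(
    plantedClusterSpec("C", "4n", "sp3", "-43m", "4n_1-nope",
                       plm = c(P32 = -0.3)), "must be one of")
})

test_that("planted symmetry is recovered on noise-free means", {
  cases <- list(
    list("H", "1x", "cylindrical", "1x_1-ZaXany", c(P10 = 0.15, P20 = 0.08)),
    list("O", "1p", "m", "1p_1-ZaXx", c(P10 = 0.1, P11 = 0.05, P22 = 0.1)),
    list("O", "2p", "mm2", "2p_71-ZabYa", c(P10 = -0.12, P22 = -0.08)),
    list("N", "3n", "3m", "3n_61-ZabcXa", c(P30 = -0.12, P33 = -0.25)),
    list("C", "3p", "-6m2", "3p_21-XabYa", c(P33 = 0.32, P20 = -0.08)),
    list("C", "4n", "-43m", "4n_41-ZabXc", c(P32 = -0.3)),
    list("C", "2x", "1", "2x_1-ZaXany", c(P20 = 0.3)))
  for (cs in cases) {
    spec <- plantedClusterSpec(cs[[1]], cs[[2]], "sp3",
                               cs[[3]], cs[[4]], plm = cs[[5]],
                               nTypes = 1, nMembers = 2,
                               noise = list(plm = 0, kappa = 0,
                                            kappap = 0, pval = 0),
                               jitterDeg = 0)
    sim <- generateBank(list(spec), seed = 5)
    det <- detectSymmetry(sim$bank[[1]]@params@plm, tol = 1e-8)
    if (cs[[3]] == "1") {
      # cylindrical pattern planted under the trivial group is still
      # detected at its true (higher) symmetry
      expect_equal(det, "cylindrical")
    } else {
      expect_equal(det, cs[[3]], label = paste("plant", cs[[3]]))
    }
  }
})

test_that("per-element Pval means sit near the formal valence counts", {
  sim <- generateBank(defaultSyntheticSpec(typeScale = 0.3), seed = 7)
  tab <- bankToTable(sim$bank)
  val <- c(H = 1, C = 4, N = 5, O = 6, S = 6)
  for (el in unique(tab$element)) {
    expect_lt(abs(mean(tab$Pval[tab$element == el]) - val[[el]]), 0.5)
  }
  # kappa and kappa' near 1
  expect_lt(max(abs(tab$kappa - 1)), 0.35)
  expect_lt(max(abs(tab$kappap - 1)), 0.35)
})

test_that("the default spec spans the required elements and groups", {
  spec <- defaultSyntheticSpec()
  expect_gte(length(spec), 8)
  els <- vapply(spec, `[[`, character(1), "element")
  grps <- vapply(spec, `[[`, character(1), "group")
  expect_true(all(c("H", "C", "N", "O", "S") %in% els))
  expect_true(all(c("1x", "2p", "3p", "3n", "4n") %in% grps))
})

test_that("increasing noise monotonically degrades planted recovery", {
  skip_if_not_installed("mclust")
  # levels in the blur-dominated regime at and beyond the inconsistency
  # threshold, where separation loss governs recovery; well below it,
  # near-duplicate rotation rows compress the k-distance curve and the
  # knee over-splits instead (see the methods vignette)
  ari <- vapply(c(0.08, 0.15, 0.30), function(nz) {
    spec <- defaultSyntheticSpec(noisePlm = nz, typeScale = 0.4)
    sim <- generateBank(spec, seed = 13)
    rot <- rotateBank(sim)
    res <- suppressWarnings(clusterBank(rot))
    truth <- paste(sim$truth$clusterId[match(rot$entry, sim$truth$entry)],
                   rot$family, sep = "@")
    mclust::adjustedRandIndex(res$assignments$path, truth)
  }, numeric(1))
  expect_true(all(diff(ari) < 0))
  expect_gt(ari[1], 0.8)
})
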