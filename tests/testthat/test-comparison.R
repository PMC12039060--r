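# build the second resonance form of the acetate complex by swapping the
# roles of the two carboxylate oxygens
.acetateResonancePair <- function() {
  a <- xyzToSmiles(makeFixture("acetato_cobalt3")$xyz, 2L)$smiles
  m <- parseSmiles(a)
  oc <- which(m@elements == "O" & m@charges == -1L)
  ot <- which(m@elements == "O" & m@charges == 0L)
  cC <- which(m@bonds[oc, ] > 0L & m@elements == "C")
  m@bonds[oc, cC] <- m@bonds[cC, oc] <- 2L
  m@bonds[ot, cC] <- m@bonds[cC, ot] <- 1L
  m@charges[oc] <- 0L
  m@charges[ot] <- -1L
  c(a, canonicalSmiles(m))
}

test_that("identical strings are equal at all three levels", {
  s <- okResults()[[1]]$result$smiles
  out <- compareSmiles(s, s)
  expect_true(all(out$equal))
})

test_that("resonance forms differ directly but match at the resonance levels", {
  pair <- .acetateResonancePair()
  expect_false(identical(pair[1], pair[2]))
  out <- compareSmiles(pair[1], pair[2])
  expect_equal(out$equal, c(FALSE, TRUE, TRUE))
})

test_that("an extra metal-ligand bond separates only the disconnect level", {
  a <- xyzToSmiles(makeFixture("acetato_cobalt3")$xyz, 2L)$smiles
  m <- parseSmiles(a)
  mi <- which(isDBlock(m@elements))
  # chelate the carbonyl O too (kappa-2 acetate), same ligand charges
  ot <- which(m@elements == "O" & m@charges == 0L)
  m@bonds[ot, mi] <- m@bonds[mi, ot] <- 1L
  m@dative[ot, mi] <- m@dative[mi, ot] <- TRUE
  b <- canonicalSmiles(m)
  out <- compareSmiles(a, b)
  expect_equal(out$equal, c(FALSE, FALSE, TRUE))
})

test_that("different ligand charges or sets differ at every level", {
  a <- xyzToSmiles(makeFixture("acetato_cobalt3")$xyz, 2L)$smiles
  b <- xyzToSmiles(makeFixture("mesylate_cobalt3")$xyz, 2L)$smiles
  expect_false(any(compareSmiles(a, b)$equal))
})

test_that("comparison is symmetric and monotone across the whole suite", {
  smis <- vapply(okResults(), function(fx) fx$result$smiles, "")
  pairs <- utils::combn(length(smis), 2)
  extra <- .acetateResonancePair()
  allPairs <- cbind(pairs, matrix(c(length(smis) + 1L, length(smis) + 2L)))
  smisAll <- c(smis, extra)
  for (k in seq_len(ncol(allPairs))) {
    i <- allPairs[1, k]; j <- allPairs[2, k]
    ab <- compareSmiles(smisAll[i], smisAll[j])
    ba <- compareSmiles(smisAll[j], smisAll[i])
    expect_identical(ab$equal, ba$equal)
    # monotone: direct => resonance_tmc => disconnect_resonance
    expect_true(!ab$equal[1] || ab$equal[2])
    expect_true(!ab$equal[2] || ab$equal[3])
  }
})

test_that("unparsable sides are named in the error", {
  good <- okResults()[[1]]$result$smiles
  expect_error(compareSmiles("C1CC", good), "left")
  expect_error(compareSmiles(good, "C1CC"), "right")
})

test_that("the oxidation-state profile counts and flags correctly", {
  smis <- vapply(okResults(), function(fx) fx$result$smiles, "")
  prof <- oxidationStateProfile(smis)
  expect_equal(sum(prof$count), length(smis))
  # the perchlorate artifact shows up as an unusual entry
  expect_true(any(prof$unusual & prof$oxidationState > 10))
  # three identical +3 fixtures count together
  expect_gte(prof$count[prof$oxidationState == 3], 3)
  empty <- oxidationStateProfile(character())
  expect_equal(nrow(empty), 0)
})

test_that("coordination environments follow the caption grammar", {
  env1 <- coordinationEnvironments(
    xyzToSmiles(makeFixture("tetrachloro_platinum2")$xyz, -2L)$smiles)
  expect_equal(env1$environment, "Cl")
  expect_equal(env1$count, 4L)
  env2 <- coordinationEnvironments(
    xyzToSmiles(makeFixture("pyridine_ruthenium2")$xyz, 2L)$smiles)
  expect_setequal(env2$environment, c("N", "N(c,c)"))
  env3 <- coordinationEnvironments(
    xyzToSmiles(makeFixture("hexacarbonyl_chromium0")$xyz, 0L)$smiles)
  expect_equal(env3$environment, "C(O)")
  env4 <- coordinationEnvironments(
    xyzToSmiles(makeFixture("cp_manganese1")$xyz, 0L)$smiles)
  expect_setequal(env4$environment, c("C(c,c)", "C(O)"))
})

test_that("environment strings are invariant under atom reordering", {
  fx <- makeFixture("bipyridine_nickel2")
  s <- parseXYZ(fx$xyz)
  base <- coordinationEnvironments(xyzToSmiles(fx$xyz, 0L)$smiles)
  set.seed(3)
  p <- sample(atomCount(s))
  s2 <- new("XYZStructure", elements = s@elements[p],
            coords = s@coords[p, , drop = FALSE])
  perm <- coordinationEnvironments(xyzToSmiles(formatXYZ(s2), 0L)$smiles)
  expect_identical(base, perm)
})
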