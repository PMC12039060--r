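test_that("xyz parsing handles the standard layout and rejects malformed input", {
  s <- parseXYZ("1\n\nFe 0 0 0")
  expect_equal(atomCount(s), 1L)
  expect_equal(s@elements, "Fe")

  w <- parseXYZ("3\nwater\nO 0 0 0\nH 0.96 0 0\nH -0.24 0.93 0")
  expect_equal(w@elements, c("O", "H", "H"))

  expect_error(parseXYZ("5\n\nC 0 0 0\nC 1 0 0\nC 2 0 0"), "3 atom lines")
  expect_error(parseXYZ("abc\n\nC 0 0 0"), "header")
  expect_error(parseXYZ("1\n\nXx 0 0 0"), "unknown element")
  expect_error(parseXYZ("1\n\nC a b c"), "non-numeric")
})

test_that("distance criterion bonds atoms within radii sum plus tolerance", {
  two <- function(d) parseXYZ(sprintf("2\n\nC 0 0 0\nC %.2f 0 0", d))
  # r_C + r_C + 0.45 = 1.97
  expect_equal(adjacency(buildAdjacency(two(1.50)))[1, 2], 1L)
  expect_equal(adjacency(buildAdjacency(two(2.10)))[1, 2], 0L)
  # boundary: just inside / outside
  expect_equal(adjacency(buildAdjacency(two(1.96)))[1, 2], 1L)
  expect_equal(adjacency(buildAdjacency(two(1.98)))[1, 2], 0L)
  # single atom: 1x1 zero matrix
  single <- buildAdjacency(parseXYZ("1\n\nFe 0 0 0"))
  expect_equal(adjacency(single), matrix(0L, 1, 1))
})

test_that("adjacency is symmetric, binary, zero-diagonal and permutation-consistent", {
  fx <- makeFixture("acac_cobalt3")
  s <- parseXYZ(fx$xyz)
  ac <- adjacency(buildAdjacency(s))
  expect_true(all(ac %in% 0:1))
  expect_identical(ac, t(ac))
  expect_true(all(diag(ac) == 0L))
  set.seed(7)
  p <- sample(atomCount(s))
  s2 <- new("XYZStructure", elements = s@elements[p],
            coords = s@coords[p, , drop = FALSE])
  ac2 <- adjacency(buildAdjacency(s2))
  expect_identical(ac2, ac[p, p])
})

test_that("valence trimming cuts the longest relative bond of a violator", {
  # carbon with 5 neighbors: 4 at typical lengths, one stretched to a
  # relative length far above the others
  xyz <- paste("6", "crowded carbon",
               "C 0 0 0",
               "H 1.09 0 0", "H -1.09 0 0", "H 0 1.09 0", "H 0 -1.09 0",
               "F 0 0 1.70",   # rel = 1.70/1.33 = 1.28 vs H rel = 0.78
               sep = "\n")
  s <- parseXYZ(xyz)
  am0 <- buildAdjacency(s)
  expect_equal(sum(adjacency(am0)[1, ]), 5)
  am <- enforceValenceLimits(am0, s)
  expect_equal(sum(adjacency(am)[1, ]), 4)
  expect_equal(adjacency(am)[1, 6], 0L)     # the F bond went
  expect_equal(cutLog(am)$reason, "valence")
  # oracle: the cut bond is the max of d/(r_i+r_j) over the atom's bonds
  rel <- vapply(2:6, function(j)
    sqrt(sum((s@coords[1, ] - s@coords[j, ])^2)) /
      (0.76 + elementTables()$covalentRadius[[s@elements[j]]]), 0)
  expect_equal(which.max(rel) + 1L, 6L)
})

test_that("molecules without violations pass through untouched", {
  fx <- makeFixture("hexaammine_cobalt3")
  s <- parseXYZ(fx$xyz)
  am0 <- buildAdjacency(s)
  am <- enforceValenceLimits(am0, s)
  expect_identical(adjacency(am), adjacency(am0))
  expect_equal(nrow(cutLog(am)), 0L)
})

test_that("a bridging hydride loses its longer relative B-H bond", {
  # H between two B atoms, slightly closer to the first
  xyz <- "3\nbridge\nB 0 0 0\nH 1.30 0 0\nB 2.65 0 0"
  s <- parseXYZ(xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  deg <- rowSums(adjacency(am))
  expect_equal(deg[[2]], 1)          # H down to one neighbor
  expect_equal(adjacency(am)[2, 1], 1L)  # kept the shorter bond
  expect_equal(adjacency(am)[2, 3], 0L)
})

test_that("after trimming no non-metal atom exceeds its maximum valence", {
  tables <- elementTables()
  for (fx in fixtureSuite()) {
    s <- parseXYZ(fx$xyz)
    am <- enforceValenceLimits(buildAdjacency(s), s)
    deg <- rowSums(adjacency(am))
    for (i in seq_along(s@elements)) {
      if (isDBlock(s@elements[i])) next
      lim <- tables$maxValence[[s@elements[i]]]
      expect_lte(deg[[i]], lim)
    }
  }
})

test_that("spurious haptic bonds are cut while genuine eta-5 patches survive", {
  # the methylamine fixture: N at 2.0 A, its C dragged in at 2.9 A
  fx <- makeFixture("fake_haptic_zirconium4")
  s <- parseXYZ(fx$xyz)
  am0 <- enforceValenceLimits(buildAdjacency(s), s)
  metal <- which(isDBlock(s@elements))
  cIdx <- which(s@elements == "C")
  expect_equal(adjacency(am0)[cIdx, metal], 1L)  # perceived fake bond
  am <- pruneFakeHaptic(am0, s, metal)
  expect_equal(adjacency(am)[cIdx, metal], 0L)
  expect_true("fake_haptic" %in% cutLog(am)$reason)
  # the N (shortest bond of the patch) is never cut
  nIdx <- which(s@elements == "N")
  expect_equal(adjacency(am)[nIdx, metal], 1L)

  # idealized eta-5 cyclopentadienyl: all five distances equal, untouched
  fcp <- makeFixture("cp_manganese1")
  s2 <- parseXYZ(fcp$xyz)
  am2 <- enforceValenceLimits(buildAdjacency(s2), s2)
  m2 <- which(isDBlock(s2@elements))
  before <- sum(adjacency(am2)[, m2])
  am2p <- pruneFakeHaptic(am2, s2, m2)
  expect_equal(sum(adjacency(am2p)[, m2]), before)

  # monodentate, non-adjacent coordinating atoms: no patch, no change
  fmono <- makeFixture("hexaammine_cobalt3")
  s3 <- parseXYZ(fmono$xyz)
  am3 <- enforceValenceLimits(buildAdjacency(s3), s3)
  am3p <- pruneFakeHaptic(am3, s3, which(isDBlock(s3@elements)))
  expect_identical(adjacency(am3p), adjacency(am3))
})

test_that("ligand splitting partitions atoms and flags counter-ions", {
  fx <- makeFixture("tetrachloro_platinum2")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  expect_length(sp$fragments, 4)
  for (f in sp$fragments) {
    expect_equal(f@elements, "Cl")
    expect_length(f@coordinatingAtoms, 1)
    expect_false(f@isCounterIon)
  }
  # partition property across the suite: fragments + metal == all atoms
  for (fr in suiteResults()) {
    s2 <- parseXYZ(fr$xyz)
    am2 <- enforceValenceLimits(buildAdjacency(s2), s2)
    sp2 <- splitLigands(am2, s2)
    idx <- sort(c(sp2$metalIndex,
                  unlist(lapply(sp2$fragments, function(f) f@atomIndices))))
    expect_equal(idx, seq_len(atomCount(s2)))
  }
  # a bipyridine keeps both coordinating nitrogens in one fragment
  fb <- makeFixture("bipyridine_nickel2")
  sb <- parseXYZ(fb$xyz)
  amb <- enforceValenceLimits(buildAdjacency(sb), sb)
  spb <- splitLigands(amb, sb)
  big <- spb$fragments[[which.max(lengths(lapply(spb$fragments,
                                                 slot, "elements")))]]
  expect_length(big@coordinatingAtoms, 2)
  expect_equal(sort(big@elements[big@coordinatingAtoms]), c("N", "N"))

  # no metal at all -> not mononuclear error
  org <- parseXYZ("2\n\nC 0 0 0\nO 1.2 0 0")
  expect_error(splitLigands(buildAdjacency(org), org), "not mononuclear")
})
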