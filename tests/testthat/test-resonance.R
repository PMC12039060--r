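test_that("resonance enumeration covers equivalent charge placements", {
  # acetate coordinating through one O: the -1 can sit on either oxygen
  fx <- makeFixture("acetato_cobalt3")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  f <- sp$fragments[[which(vapply(sp$fragments, function(x)
    sum(x@elements == "O") == 2, TRUE))]]
  first <- enumerateBondOrders(f, -1L)
  cands <- enumerateResonance(first)
  expect_gte(length(cands), 2)
  oxPlacements <- vapply(cands, function(c)
    which(c$mol@charges[f@elements == "O"] == -1L)[1], 0L)
  expect_equal(sort(unique(oxPlacements)), c(1L, 2L))
  # all candidates share adjacency and total charge
  for (c in cands) {
    expect_equal((c$mol@bonds > 0L) * 1L, f@ac)
    expect_equal(sum(c$mol@charges), -1L)
    expect_null(tmcSMILES:::.sanitizeCheck(c$mol))
  }

  # a rigid fragment with no movable electrons gives exactly one candidate
  fCl <- new("LigandFragment", atomIndices = 1L, elements = "Cl",
             coords = matrix(0, 1, 3), ac = matrix(0L, 1, 1),
             coordinatingAtoms = 1L, isCounterIon = FALSE)
  mCl <- enumerateBondOrders(fCl, -1L)
  expect_length(enumerateResonance(mCl), 1)
})

test_that("scoring prefers larger aromatic systems, then uncharged forms", {
  a <- list(nAromatic = 6L, penalized = 3L, nCharged = 3L, smiles = "a")
  b <- list(nAromatic = 0L, penalized = 0L, nCharged = 0L, smiles = "b")
  expect_equal(tmcSMILES:::.pickBest(list(a, b))$smiles, "a")
  # equal aromaticity: a negative charge on a coordinating atom is free
  c1 <- list(nAromatic = 0L, penalized = 0L, nCharged = 1L, smiles = "c1")
  c2 <- list(nAromatic = 0L, penalized = 1L, nCharged = 1L, smiles = "c2")
  expect_equal(tmcSMILES:::.pickBest(list(c2, c1))$smiles, "c1")
  # identical keys: canonical-string order decides, deterministically
  d1 <- list(nAromatic = 0L, penalized = 0L, nCharged = 0L, smiles = "x",
             mol = NULL)
  d2 <- list(nAromatic = 0L, penalized = 0L, nCharged = 0L, smiles = "y",
             mol = NULL)
  expect_equal(tmcSMILES:::.pickBest(list(d2, d1))$smiles, "x")
})

test_that("the selected acetate and mesylate forms charge the coordinating O", {
  for (nm in c("acetato_cobalt3", "mesylate_cobalt3")) {
    fx <- makeFixture(nm)
    s <- parseXYZ(fx$xyz)
    am <- enforceValenceLimits(buildAdjacency(s), s)
    sp <- splitLigands(am, s)
    f <- sp$fragments[[which(vapply(sp$fragments, function(x)
      sum(x@elements == "O") >= 2, TRUE))]]
    g <- adjustCharge(huckelChargeGuess(f))
    sel <- selectLigandRepresentation(f, g)
    expect_equal(sel$charge, -1L)
    coord <- sel$mol@coordinatingAtoms
    expect_equal(sel$mol@charges[coord], -1L,
                 info = paste(nm, "coordinating atom must carry the charge"))
  }
})

test_that("the carbene form beats the zwitterion for the NHC ligand", {
  fx <- makeFixture("nhc_silver1")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  f <- sp$fragments[[which(vapply(sp$fragments, function(x)
    length(x@elements) > 1, TRUE))]]
  g <- adjustCharge(huckelChargeGuess(f))
  expect_equal(g@charge, 0L)
  sel <- selectLigandRepresentation(f, g)
  # the chosen form is the neutral carbene, not the (+N, -C) zwitterion
  expect_true(all(sel$mol@charges == 0L))
  expect_length(sel$mol@carbeneAtoms, 1)
  expect_equal(f@elements[sel$mol@carbeneAtoms], "C")
  # the carbene carbon is the coordinating atom
  expect_equal(sel$mol@carbeneAtoms, sel$mol@coordinatingAtoms)
  # the zwitterion exists among the carbene-disallowed candidates
  noCarb <- enumerateBondOrders(f, 0L, allowCarbene = FALSE)
  expect_false(all(noCarb@charges == 0L))
})

test_that("a fragment solvable only without carbenes still solves", {
  # plain pyridine: both passes give the identical aromatic structure
  fx <- makeFixture("pyridine_ruthenium2")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  f <- sp$fragments[[which(vapply(sp$fragments, function(x)
    length(x@elements) > 4, TRUE))]]
  withC <- selectLigandRepresentation(f, charge = 0L)
  noC <- selectLigandRepresentation(f, charge = 0L,
                                    config = tmcConfig(allowCarbenes = FALSE))
  expect_equal(canonicalSmiles(withC$mol), canonicalSmiles(noC$mol))
})

test_that("selection is deterministic across atom orderings", {
  fx <- makeFixture("acetato_cobalt3")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  f <- sp$fragments[[which(vapply(sp$fragments, function(x)
    sum(x@elements == "O") == 2, TRUE))]]
  base <- selectLigandRepresentation(f, charge = -1L)
  set.seed(11)
  for (rep in 1:3) {
    p <- sample(length(f@elements))
    f2 <- new("LigandFragment", atomIndices = seq_along(p),
              elements = f@elements[p],
              coords = f@coords[p, , drop = FALSE],
              ac = f@ac[p, p],
              coordinatingAtoms = match(f@coordinatingAtoms, p),
              isCounterIon = FALSE)
    sel2 <- selectLigandRepresentation(f2, charge = -1L)
    expect_equal(canonicalSmiles(sel2$mol), canonicalSmiles(base$mol))
  }
})
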