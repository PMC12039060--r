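test_that("covalent metal bonds convert to dative with valence-based transfer", {
  # chlorides need the metal bond for their valence: transfer fires
  r <- fixCSDSmiles("[Pt](Cl)(Cl)(Cl)Cl")
  expect_false(is.na(r@outputSmiles))
  m <- parseSmiles(r@outputSmiles)
  mi <- which(isDBlock(m@elements))
  expect_true(all(m@dative[m@bonds[, mi] > 0L, mi]))  # no covalent M bonds
  expect_equal(m@charges[mi], 4L)
  expect_true(all(m@charges[m@elements == "Cl"] == -1L))
  expect_equal(r@chargeDeltaMetal, 4L)

  # an amine nitrogen 3-coordinate including the metal: bond order 1 case,
  # +1 metal / -1 N
  r2 <- fixCSDSmiles("CN(C)[Sc]")
  m2 <- parseSmiles(r2@outputSmiles)
  expect_equal(m2@charges[which(isDBlock(m2@elements))], 1L)
  expect_equal(m2@charges[which(m2@elements == "N")], -1L)

  # a neutral pyridine donor keeps its charge: plain dative conversion
  r3 <- fixCSDSmiles("c1ccn(cc1)[Fe]")
  m3 <- parseSmiles(r3@outputSmiles)
  expect_equal(sum(m3@charges), 0L)
  expect_equal(m3@charges[which(isDBlock(m3@elements))], 0L)
  expect_true(any(grepl("dative_conversion\\(", r3@appliedRules)))
})

test_that("already-valid dative SMILES pass through with no applied rules", {
  s <- "[Cl-]->[Pt+2](<-[Cl-])(<-[Cl-])<-[Cl-]"
  r <- fixCSDSmiles(s)
  expect_identical(r@outputSmiles, s)
  expect_length(r@appliedRules, 0)
  expect_equal(r@chargeDeltaMetal, 0L)
})

test_that("hypervalent N and B away from the metal get balanced charges", {
  r <- fixCSDSmiles("C[N](C)(C)CC[Pt]Cl")
  m <- parseSmiles(r@outputSmiles)
  nIdx <- which(m@elements == "N")
  expect_equal(m@charges[nIdx], 1L)
  expect_true(any(grepl("hypervalent_N", r@appliedRules)))
  # net formal charge unchanged
  expect_equal(sum(m@charges), sum(parseSmiles("C[N](C)(C)CC[Pt]Cl")@charges))

  r2 <- fixCSDSmiles("C[B](C)(C)CC[Pt]Cl")
  m2 <- parseSmiles(r2@outputSmiles)
  expect_equal(m2@charges[which(m2@elements == "B")], -1L)
  expect_true(any(grepl("hypervalent_B", r2@appliedRules)))
})

test_that("special cases: pyrrolide, carbene CO and metal-nitrogen triples", {
  # covalent aromatic pyrrole N on the metal becomes an anionic pyrrolide
  r <- fixCSDSmiles("[Ru]n1cccc1")
  m <- parseSmiles(r@outputSmiles)
  expect_equal(m@charges[which(m@elements == "N")], -1L)
  expect_equal(sum(m@charges), 0L)

  # carbene-drawn carbonyl becomes the triple-bond form
  r2 <- fixCSDSmiles("[Cr]=C=O")
  expect_match(r2@outputSmiles, "[C-]", fixed = TRUE)
  expect_match(r2@outputSmiles, "#[O+]", fixed = TRUE)

  # metal-nitrogen triple bond: nitride bookkeeping
  r3 <- fixCSDSmiles("[Mo]#N")
  m3 <- parseSmiles(r3@outputSmiles)
  expect_equal(m3@charges[which(m3@elements == "N")], -3L)
  expect_equal(m3@charges[which(isDBlock(m3@elements))], 3L)
})

test_that("the fixer is idempotent and preserves net formal charge", {
  cases <- c("[Pt](Cl)(Cl)(Cl)Cl", "[Ru]n1cccc1", "c1ccn(cc1)[Fe]",
             "[Ag]C1N(C)C=CN1C", "[Cr]=C=O", "[Mo]#N",
             "C[N](C)(C)CC[Pt]Cl")
  for (s in cases) {
    r1 <- fixCSDSmiles(s)
    expect_false(is.na(r1@outputSmiles), info = s)
    r2 <- fixCSDSmiles(r1@outputSmiles)
    expect_identical(r2@outputSmiles, r1@outputSmiles, info = s)
    expect_length(r2@appliedRules, 0)
    expect_equal(sum(parseSmiles(r1@outputSmiles)@charges),
                 sum(parseSmiles(s)@charges), info = s)
  }
})

test_that("inputs that are not mononuclear TMC SMILES are rejected with reasons", {
  r <- fixCSDSmiles("CCO")
  expect_true(is.na(r@outputSmiles))
  expect_match(r@failure, "d-block")
  r2 <- fixCSDSmiles("[Fe][Fe]")
  expect_match(r2@failure, "found 2")
  r3 <- fixCSDSmiles("C1CC")
  expect_match(r3@failure, "parse")
})

test_that("formula verification flags hydrogen deficits", {
  ok <- checkFormula("[Cl-]->[Pt+2](<-[Cl-])(<-[Cl-])<-[Cl-]", "Cl4Pt")
  expect_true(ok$pass)
  okH <- checkFormula("[Co+3](<-N)(<-N)(<-N)(<-N)(<-N)<-N", "CoH18N6")
  expect_true(okH$pass)
  # a deliberately H-deficient structure against the true formula
  bad <- checkFormula("[Co+3](<-N)(<-N)(<-N)(<-N)(<-N)<-[NH]", "CoH18N6")
  expect_false(bad$pass)
  expect_equal(unname(bad$diff[["H"]]), -2L)
  expect_error(checkFormula("CCO", "C6H?"), "unparsable")
})

test_that("formula check integrates with the fixer report", {
  r <- fixCSDSmiles("[Pt](Cl)(Cl)(Cl)Cl", referenceFormula = "Cl4Pt")
  expect_equal(r@formulaCheck, "pass")
  r2 <- fixCSDSmiles("[Pt](Cl)(Cl)(Cl)Cl", referenceFormula = "Cl4H2Pt")
  expect_equal(r2@formulaCheck, "fail")
  r3 <- fixCSDSmiles("[Pt](Cl)(Cl)(Cl)Cl")
  expect_equal(r3@formulaCheck, "skipped")
})
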