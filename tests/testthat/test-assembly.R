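test_that("oxidation state arithmetic and the unusual-value warning", {
  expect_equal(metalOxidationState(0, c(-1, -1, 0, 0)), 2L)
  expect_equal(metalOxidationState(3, rep(0, 6)), 3L)
  expect_equal(metalOxidationState(-2, rep(-1, 4)), 2L)
  expect_warning(metalOxidationState(2, rep(-2, 5)), "unusual")
  expect_warning(metalOxidationState(-2, rep(0, 4)), "unusual")
})

test_that("assembly wires one dative bond per coordinating atom", {
  fx <- makeFixture("tetrachloro_platinum2")
  res <- xyzToSmiles(fx$xyz, fx$charge)
  m <- res$mol
  db <- dativeBonds(m)
  expect_equal(nrow(db), 4)
  expect_true(all(m@elements[db[, "acceptor"]] == "Pt"))
  expect_true(all(m@elements[db[, "donor"]] == "Cl"))
  expect_equal(m@charges[m@metalIndex], 2L)
  expect_equal(sum(m@charges), -2L)
  # no covalent metal bonds exist
  mi <- m@metalIndex
  expect_true(all(m@dative[m@bonds[, mi] > 0L, mi]))

  # bare ion with a single ligand keeps the arithmetic trivially
  bare <- xyzToSmiles("2\n\nCu 0 0 0\nCl 2.1 0 0", 1L)
  expect_equal(bare$oxidationState, 2L)
})

test_that("the whole suite conserves charge and the oxidation-state identity", {
  for (fx in okResults()) {
    m <- fx$result$mol
    expect_equal(sum(m@charges), fx$charge, info = fx$name)
    expect_equal(m@oxidationState,
                 fx$charge - sum(m@ligandCharges) - sum(m@counterIonCharges),
                 info = fx$name)
    # and still after re-applying both fixes (idempotence + bookkeeping)
    m2 <- fixNitro(fixSulfonateLike(m))
    expect_equal(sum(m2@charges), fx$charge, info = fx$name)
    expect_identical(canonicalSmiles(m2), canonicalSmiles(m), info = fx$name)
  }
})

# a hand-built complex with the sulfonate defect: the charge sits on a
# terminal O while a neutral O coordinates
.defectiveSulfonate <- function() {
  smi <- "CS(=O->[Co+3](<-N)(<-N)(<-N)(<-N)<-N)(=O)[O-]"
  m <- parseSmiles(smi)
  mi <- which(isDBlock(m@elements))
  new("TMCMol", elements = m@elements, bonds = m@bonds, dative = m@dative,
      charges = m@charges, coords = m@coords, metalIndex = mi,
      oxidationState = 3L, overallCharge = 2L,
      ligandCharges = c(-1L, rep(0L, 5)), counterIonCharges = integer())
}

test_that("the sulfonate fix moves the charge onto the coordinating oxygen", {
  m <- .defectiveSulfonate()
  mi <- m@metalIndex
  coordO <- which(m@dative[, mi] & m@elements == "O")
  expect_equal(m@charges[coordO], 0L)          # defect present
  fixed <- fixSulfonateLike(m)
  expect_equal(fixed@charges[coordO], -1L)
  expect_equal(sum(fixed@charges), 2L)
  # idempotent
  again <- fixSulfonateLike(fixed)
  expect_identical(canonicalSmiles(again), canonicalSmiles(fixed))
  # charge already on the coordinating O: untouched
  ok <- xyzToSmiles(makeFixture("mesylate_cobalt3")$xyz, 2L)$mol
  expect_identical(canonicalSmiles(fixSulfonateLike(ok)),
                   canonicalSmiles(ok))
  # free, non-coordinated sulfonate counter-ion: untouched
  free <- parseSmiles("CS(=O)(=O)[O-].[Co+3](<-N)(<-N)(<-N)(<-N)(<-N)<-N")
  tm <- new("TMCMol", elements = free@elements, bonds = free@bonds,
            dative = free@dative, charges = free@charges,
            coords = free@coords,
            metalIndex = which(isDBlock(free@elements)),
            oxidationState = 3L, overallCharge = 2L,
            ligandCharges = rep(0L, 6), counterIonCharges = -1L)
  expect_identical(canonicalSmiles(fixSulfonateLike(tm)),
                   canonicalSmiles(tm))
})

test_that("the nitro fix rewrites to the neutral form and rebalances", {
  # charged nitro on a coordinated pyridine (fixed-charge path, ligand 0)
  fx <- makeFixture("nitropyridine_ruthenium2")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  tab <- data.frame(charge = rep(0L, length(sp$fragments)))
  tab$atoms <- lapply(sp$fragments, function(f) f@atomIndices)
  res <- assembleFromFixedCharges(fx$xyz, 2L, tab)
  expect_true(res$ok)
  expect_match(res$smiles, "N(=O)=O", fixed = TRUE)
  expect_equal(res$oxidationState, 2L)
  m <- res$mol
  expect_equal(sum(m@charges), 2L)
  expect_true(all(m@charges[m@elements == "N"] <= 0L))
  # idempotent; a nitro-free complex is untouched
  expect_identical(canonicalSmiles(fixNitro(m)), canonicalSmiles(m))
  plain <- xyzToSmiles(makeFixture("hexaammine_cobalt3")$xyz, 3L)$mol
  expect_identical(canonicalSmiles(fixNitro(plain)), canonicalSmiles(plain))
})

test_that("two charged nitro groups are both rewritten with consistent bookkeeping", {
  smi <- paste0("[Ru+2](<-N)(<-N)(<-N)(<-[N+](=O)[O-])<-[N+](=O)[O-]")
  m <- parseSmiles(smi)
  tm <- new("TMCMol", elements = m@elements, bonds = m@bonds,
            dative = m@dative, charges = m@charges, coords = m@coords,
            metalIndex = which(isDBlock(m@elements)),
            oxidationState = 2L, overallCharge = 2L,
            ligandCharges = rep(0L, 5), counterIonCharges = integer())
  fixed <- fixNitro(tm)
  expect_equal(sum(fixed@charges), 2L)
  expect_equal(sum(fixed@charges[fixed@elements == "N"] == 1L), 0)
  expect_equal(sum(fixed@charges[fixed@elements == "O"] == -1L), 0)
})

test_that("SMILES emission is canonical and failures surface with stages", {
  fx <- okResults()[[1]]
  smi <- fx$result$smiles
  expect_identical(canonicalSmiles(parseSmiles(smi)), smi)
  # failure report carries the stage
  bad <- xyzToSmiles("2\n\nC 0 0 0\nO 1.2 0 0", 0L)
  expect_false(bad$ok)
  expect_equal(bad$stage, "not_mononuclear")
  borane <- xyzToSmiles(makeFixture("borane_chromium")$xyz, 0L)
  expect_false(borane$ok)
  expect_equal(borane$stage, "ligand_lewis")
})

test_that("the fixed-charge path matches the occupancy path and checks its table", {
  fx <- makeFixture("tetrachloro_platinum2")
  s <- parseXYZ(fx$xyz)
  am <- enforceValenceLimits(buildAdjacency(s), s)
  sp <- splitLigands(am, s)
  tab <- data.frame(charge = rep(-1L, 4))
  tab$atoms <- lapply(sp$fragments, function(f) f@atomIndices)
  res <- assembleFromFixedCharges(fx$xyz, -2L, tab)
  expect_identical(res$smiles, xyzToSmiles(fx$xyz, -2L)$smiles)
  # deliberately impossible fixed charge
  tabBad <- tab; tabBad$charge <- rep(-3L, 4)
  expect_equal(assembleFromFixedCharges(fx$xyz, -2L, tabBad)$stage,
               "ligand_lewis")
  # missing fragment
  tabShort <- tab[1:3, ]
  expect_equal(assembleFromFixedCharges(fx$xyz, -2L, tabShort)$stage,
               "fixed_charge_table")
})
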