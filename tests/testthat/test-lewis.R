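.mkFragment <- function(elements, ac, coordinating = integer()) {
  n <- length(elements)
  new("LigandFragment", atomIndices = seq_len(n), elements = elements,
      coords = matrix(0, n, 3), ac = ac,
      coordinatingAtoms = as.integer(coordinating),
      isCounterIon = length(coordinating) == 0L)
}

.chain <- function(n) {
  ac <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) ac[i, i + 1] <- ac[i + 1, i] <- 1L
  ac
}

test_that("single-atom and simple fragments solve to the expected structures", {
  # chloride: no bonds, formal charge -1
  f <- .mkFragment("Cl", matrix(0L, 1, 1), 1L)
  m <- enumerateBondOrders(f, -1L)
  expect_s4_class(m, "LigandMol")
  expect_equal(m@charges, -1L)

  # ethene: the C=C double bond emerges, all charges zero
  ac <- matrix(0L, 6, 6)
  ac[1, 2] <- ac[2, 1] <- 1L
  ac[1, 3] <- ac[3, 1] <- 1L; ac[1, 4] <- ac[4, 1] <- 1L
  ac[2, 5] <- ac[5, 2] <- 1L; ac[2, 6] <- ac[6, 2] <- 1L
  f2 <- .mkFragment(c("C", "C", "H", "H", "H", "H"), ac)
  m2 <- enumerateBondOrders(f2, 0L)
  expect_equal(m2@bonds[1, 2], 2L)
  expect_true(all(m2@charges == 0L))

  # CO at charge 0: the triple-bond charge-separated form is the only one
  f3 <- .mkFragment(c("C", "O"), .chain(2), 1L)
  m3 <- enumerateBondOrders(f3, 0L)
  expect_equal(m3@bonds[1, 2], 3L)
  expect_equal(m3@charges, c(-1L, 1L))

  # methane at charge +5: impossible
  ac4 <- matrix(0L, 5, 5)
  for (j in 2:5) { ac4[1, j] <- ac4[j, 1] <- 1L }
  f4 <- .mkFragment(c("C", "H", "H", "H", "H"), ac4)
  expect_null(enumerateBondOrders(f4, 5L))
})

test_that("returned structures conserve the requested charge", {
  for (fr in suiteFragments()) {
    f <- fr$fragment
    g <- adjustCharge(huckelChargeGuess(f))
    sel <- selectLigandRepresentation(f, g)
    if (is.null(sel)) next
    expect_equal(sum(sel$mol@charges), sel$charge)
    expect_s4_class(sel$mol, "LigandMol")
    # every atom realizes its bond-order sum
    expect_true(all(sel$mol@bonds >= 0 & sel$mol@bonds <= 3))
  }
})

test_that("the two-electron fallback retries once in the right direction", {
  # q = 0 fails for CH4 missing an H... use CH3 fragment: radical at 0,
  # solvable at -1 (carbanion) via the q-2 retry
  ac <- .chain(2)
  ac <- matrix(0L, 4, 4)
  for (j in 2:4) { ac[1, j] <- ac[j, 1] <- 1L }
  f <- .mkFragment(c("C", "H", "H", "H"), ac, 1L)
  expect_null(enumerateBondOrders(f, 0L))    # no neutral CH3 state
  g <- new("ChargeGuess", orbitalEnergies = numeric(),
           nValenceElectrons = 7L, charge = 0L, flagged = TRUE)
  # direction: q >= 0 -> retry at q - 2... CH3 needs -1 (odd), so use parity
  # -1: q = 1 retries at -1 and succeeds
  g1 <- new("ChargeGuess", orbitalEnergies = numeric(),
            nValenceElectrons = 7L, charge = 1L, flagged = TRUE)
  m <- chargeFallback(f, g1)
  expect_s4_class(m, "LigandMol")
  expect_equal(sum(m@charges), -1L)
  # direction: q = -1 retries at +1
  g2 <- new("ChargeGuess", orbitalEnergies = numeric(),
            nValenceElectrons = 7L, charge = -1L, flagged = TRUE)
  m2 <- chargeFallback(f, g2)
  expect_equal(sum(m2@charges), 1L)
  # both attempts failing yields the failure sentinel through the selector
  fBad <- .mkFragment(c("C", "H", "H", "H", "H"),
                      rbind(cbind(0L, t(rep(1L, 4))),
                            cbind(rep(1L, 4), matrix(0L, 4, 4))), 1L)
  gBad <- new("ChargeGuess", orbitalEnergies = numeric(),
              nValenceElectrons = 8L, charge = 6L, flagged = TRUE)
  expect_null(selectLigandRepresentation(fBad, gBad))
})

test_that("enumeration agrees with exhaustive brute force on small fragments", {
  cfg <- tmcConfig(allowCarbenes = FALSE)
  nChecked <- 0L
  for (fr in suiteFragments()) {
    f <- fr$fragment
    nHeavy <- sum(f@elements != "H")
    if (nHeavy > 6L) next
    for (q in -4:2) {
      oracle <- bruteForceLewisSolvable(f@elements, f@ac, q)
      impl <- !is.null(enumerateBondOrders(f, q, allowCarbene = FALSE,
                                           config = cfg))
      expect_equal(impl, oracle,
                   info = sprintf("%s fragment (%s) at q=%d", fr$fixture,
                                  paste(f@elements, collapse = ""), q))
      nChecked <- nChecked + 1L
    }
  }
  expect_gte(nChecked, 40L)
})
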