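#' @import methods
NULL

#' XYZStructure: one molecule as element symbols plus Cartesian coordinates
#'
#' Minimal container for a parsed xyz block. Coordinates are in Angstrom.
#'
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric matrix with one row per atom and columns x, y, z.
#' @slot comment the xyz comment line (second line of the block).
#'
#' @exportClass XYZStructure
setClass("XYZStructure",
  representation(elements = "character", coords = "matrix",
                 comment = "character"),
  prototype(comment = ""))

setValidity("XYZStructure", function(object) {
  msgs <- character()
  if (nrow(object@coords) != length(object@elements))
    msgs <- c(msgs, "number of coordinate rows must equal number of elements")
  if (ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must have 3 columns")
  unknown <- setdiff(object@elements, names(.covalentRadii))
  if (length(unknown))
    msgs <- c(msgs, paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' AdjacencyMatrix: perceived 0/1 connectivity with a log of removed bonds
#'
#' @slot ac symmetric integer matrix with zero diagonal; 1 marks a perceived
#'   bond between atoms i and j.
#' @slot cutLog data.frame with columns i, j, reason, relLength recording
#'   every bond removed by valence enforcement or haptic pruning.
#'
#' @exportClass AdjacencyMatrix
setClass("AdjacencyMatrix",
  representation(ac = "matrix", cutLog = "data.frame"),
  prototype(cutLog = data.frame(i = integer(), j = integer(),
                                reason = character(),
                                relLength = numeric())))

setValidity("AdjacencyMatrix", function(object) {
  ac <- object@ac
  msgs <- character()
  if (nrow(ac) != ncol(ac)) msgs <- c(msgs, "ac must be square")
  else {
    if (!all(ac %in% c(0L, 1L))) msgs <- c(msgs, "ac entries must be 0/1")
    if (!isTRUE(all.equal(ac, t(ac)))) msgs <- c(msgs, "ac must be symmetric")
    if (any(diag(ac) != 0L)) msgs <- c(msgs, "ac diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' LigandFragment: one connected ligand cut out of a complex
#'
#' Atom bookkeeping for a single connected component of the adjacency matrix
#' after deleting the metal. \code{coordinatingAtoms} are fragment-local
#' indices of atoms bonded to the metal; a fragment with none is a
#' counter-ion.
#'
#' @slot atomIndices integer indices into the parent structure.
#' @slot elements,coords restricted views of the parent structure.
#' @slot ac integer connectivity restricted to the fragment.
#' @slot coordinatingAtoms integer fragment-local indices bonded to the metal.
#' @slot isCounterIon logical scalar.
#'
#' @exportClass LigandFragment
setClass("LigandFragment",
  representation(atomIndices = "integer", elements = "character",
                 coords = "matrix", ac = "matrix",
                 coordinatingAtoms = "integer", isCounterIon = "logical"),
  prototype(isCounterIon = FALSE))

#' ChargeGuess: extended Hueckel occupancy result for one ligand
#'
#' Holds the ordered molecular-orbital energies (eV), the fragment's valence
#' electron count, the resulting integer charge and the history of
#' two-electron frontier adjustments.
#'
#' @slot orbitalEnergies ascending numeric MO energies in eV.
#' @slot nValenceElectrons integer sum of per-atom valence electron counts.
#' @slot charge integer ligand charge after adjustments.
#' @slot adjustments character log, one entry per two-electron step.
#' @slot engine identifier of the orbital-energy engine used.
#' @slot flagged logical; TRUE when the orbital computation failed and the
#'   charge came from electron-count parity only.
#'
#' @exportClass ChargeGuess
setClass("ChargeGuess",
  representation(orbitalEnergies = "numeric", nValenceElectrons = "integer",
                 charge = "integer", adjustments = "character",
                 engine = "character", flagged = "logical"),
  prototype(adjustments = character(), engine = "tmcSMILES-EHT",
            flagged = FALSE))

setValidity("ChargeGuess", function(object) {
  if (length(object@charge) != 1L) return("charge must be a single integer")
  if (is.unsorted(object@orbitalEnergies))
    return("orbitalEnergies must be ascending")
  if ((object@charge - object@nValenceElectrons) %% 2L != 0L &&
      length(object@orbitalEnergies))
    return("charge and electron count must have equal parity")
  TRUE
})

#' MolGraph: a molecular graph with bond orders, formal charges and
#' optional dative bonds
#'
#' The package's working representation of a molecule: integer bond orders
#' over an explicit-hydrogen atom list, per-atom formal charges, and a
#' logical matrix marking which bonds are dative (ligand-to-metal donor
#' bonds). Ligand Lewis structures are MolGraphs without dative bonds.
#'
#' @slot elements character element symbols.
#' @slot bonds symmetric integer matrix of bond orders (0 = no bond).
#' @slot dative symmetric logical matrix; TRUE marks a dative bond. The
#'   donor is the non-metal atom.
#' @slot charges integer formal charges.
#' @slot coords numeric matrix (may have zero rows when no geometry exists).
#'
#' @exportClass MolGraph
setClass("MolGraph",
  representation(elements = "character", bonds = "matrix",
                 dative = "matrix", charges = "integer", coords = "matrix"))

setValidity("MolGraph", function(object) {
  n <- length(object@elements)
  msgs <- character()
  if (!all(dim(object@bonds) == c(n, n))) msgs <- c(msgs, "bonds dim mismatch")
  if (!all(dim(object@dative) == c(n, n))) msgs <- c(msgs, "dative dim mismatch")
  if (length(object@charges) != n) msgs <- c(msgs, "charges length mismatch")
  if (n && !isTRUE(all.equal(object@bonds, t(object@bonds))))
    msgs <- c(msgs, "bonds must be symmetric")
  if (n && any(diag(object@bonds) != 0)) msgs <- c(msgs, "bond diagonal must be 0")
  if (length(msgs)) msgs else TRUE
})

#' LigandMol: a solved ligand Lewis structure
#'
#' A \linkS4class{MolGraph} over one ligand fragment's atoms, carrying the
#' fragment-local coordinating-atom indices and the indices of any neutral
#' divalent (carbene) carbons admitted by the enumeration.
#'
#' @slot coordinatingAtoms fragment-local indices bonded to the metal.
#' @slot carbeneAtoms fragment-local indices of neutral divalent carbons.
#' @slot charge integer total ligand charge (= sum of formal charges).
#'
#' @exportClass LigandMol
setClass("LigandMol", contains = "MolGraph",
  representation(coordinatingAtoms = "integer", carbeneAtoms = "integer",
                 charge = "integer"),
  prototype(carbeneAtoms = integer()))

setValidity("LigandMol", function(object) {
  if (sum(object@charges) != object@charge)
    return("formal charges must sum to the ligand charge")
  TRUE
})

#' TMCMol: an assembled transition metal complex
#'
#' A MolGraph for the whole complex plus the metal bookkeeping: metal index,
#' oxidation state, overall charge and the per-ligand charges that produced
#' it. The class invariant is the oxidation-state identity
#' M_ox = Q - sum(q_i) and global charge conservation
#' sum(formal charges) = Q.
#'
#' @slot metalIndex integer index of the single d-block atom.
#' @slot oxidationState integer metal oxidation state (= metal formal charge).
#' @slot overallCharge integer overall complex charge Q.
#' @slot ligandCharges integer per-ligand charges q_i (coordinated ligands).
#' @slot counterIonCharges integer charges of non-coordinated fragments.
#' @slot notes character vector of warnings accumulated during assembly.
#'
#' @exportClass TMCMol
setClass("TMCMol", contains = "MolGraph",
  representation(metalIndex = "integer", oxidationState = "integer",
                 overallCharge = "integer", ligandCharges = "integer",
                 counterIonCharges = "integer", notes = "character"),
  prototype(notes = character(), counterIonCharges = integer()))

setValidity("TMCMol", function(object) {
  msgs <- character()
  if (length(object@metalIndex) != 1L)
    msgs <- c(msgs, "exactly one metal index required")
  if (sum(object@charges) != object@overallCharge)
    msgs <- c(msgs, "sum of formal charges must equal overall charge")
  ox <- object@overallCharge - sum(object@ligandCharges) -
    sum(object@counterIonCharges)
  if (length(object@oxidationState) == 1L && ox != object@oxidationState)
    msgs <- c(msgs, "oxidation state must equal Q - sum(ligand charges)")
  if (length(msgs)) msgs else TRUE
})

#' FixReport: outcome of the CSD SMILES repair procedure
#'
#' @slot inputSmiles the raw input string.
#' @slot outputSmiles repaired canonical SMILES, or NA on failure.
#' @slot appliedRules ordered character log of rewrite rules that fired.
#' @slot formulaCheck "pass", "fail" or "skipped".
#' @slot chargeDeltaMetal net charge moved onto the metal by the rules.
#' @slot failure reason string when outputSmiles is NA.
#'
#' @exportClass FixReport
setClass("FixReport",
  representation(inputSmiles = "character", outputSmiles = "character",
                 appliedRules = "character", formulaCheck = "character",
                 chargeDeltaMetal = "integer", failure = "character"),
  prototype(appliedRules = character(), formulaCheck = "skipped",
            chargeDeltaMetal = 0L, failure = NA_character_))
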