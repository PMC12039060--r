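#' Metal oxidation state from charge bookkeeping
#'
#' M_ox = Q - sum(q_i): the overall charge minus the sum of the fragment
#' charges. Values below 0 or above 10 are chemically unusual (the highest
#' oxidation state observed in a stable complex is 10) and are flagged with
#' a warning, never rejected.
#'
#' @param Q integer overall complex charge.
#' @param ligandCharges integer vector of fragment charges.
#' @return integer oxidation state.
#' @examples
#' metalOxidationState(0, c(-1, -1, 0, 0))
#' @export
metalOxidationState <- function(Q, ligandCharges) {
  ox <- as.integer(Q - sum(ligandCharges))
  if (ox < 0L || ox > 10L)
    warning("unusual metal oxidation state: ", ox, call. = FALSE)
  ox
}

#' Assemble a complex from its solved ligands
#'
#' Rebuilds the complex graph from the metal and the solved ligand Lewis
#' structures using the initially perceived adjacency: every
#' (coordinating atom, metal) pair present in the adjacency becomes one
#' dative bond with the ligand atom as donor. The metal formal charge is
#' set to the oxidation state so the formal charges sum to Q. Counter-ion
#' fragments are carried as disconnected components; their charges take
#' part in the bookkeeping.
#'
#' @param s the parent \linkS4class{XYZStructure}.
#' @param am the complex \linkS4class{AdjacencyMatrix}.
#' @param metalIndex index of the metal atom.
#' @param fragments list of \linkS4class{LigandFragment}s (from
#'   \code{\link{splitLigands}}).
#' @param ligandMols list of solved \linkS4class{LigandMol}s, parallel to
#'   \code{fragments}.
#' @param Q integer overall charge.
#' @return a \linkS4class{TMCMol}.
#' @export
assembleComplex <- function(s, am, metalIndex, fragments, ligandMols, Q) {
  n <- atomCount(s)
  bonds <- matrix(0L, n, n)
  dative <- matrix(FALSE, n, n)
  charges <- integer(n)
  notes <- character()
  ligQ <- integer(0)
  cionQ <- integer(0)
  for (k in seq_along(fragments)) {
    f <- fragments[[k]]
    mol <- ligandMols[[k]]
    idx <- f@atomIndices
    bonds[idx, idx] <- mol@bonds
    charges[idx] <- mol@charges
    if (f@isCounterIon) {
      cionQ <- c(cionQ, mol@charge)
    } else {
      ligQ <- c(ligQ, mol@charge)
      for (c0 in f@coordinatingAtoms) {
        a <- idx[c0]
        if (am@ac[a, metalIndex] != 1L)
          stop("internal consistency error: coordinating atom ", a,
               " missing from the adjacency matrix")
        bonds[a, metalIndex] <- bonds[metalIndex, a] <- 1L
        dative[a, metalIndex] <- dative[metalIndex, a] <- TRUE
      }
    }
  }
  ox <- withCallingHandlers(
    metalOxidationState(Q, c(ligQ, cionQ)),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  charges[metalIndex] <- ox
  new("TMCMol", elements = s@elements, bonds = bonds, dative = dative,
      charges = charges, coords = s@coords, metalIndex = metalIndex,
      oxidationState = ox, overallCharge = as.integer(Q),
      ligandCharges = ligQ, counterIonCharges = cionQ, notes = notes)
}

# fragments of a complex graph: connected components after removing the
# metal; returns a list of integer index vectors
.complexFragments <- function(m) {
  n <- length(m@elements)
  keep <- setdiff(seq_len(n), m@metalIndex)
  if (!length(keep)) return(list())
  sub <- (m@bonds[keep, keep, drop = FALSE] > 0L) * 1L
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  memb <- igraph::components(g)$membership
  lapply(split(seq_along(keep), memb), function(loc) keep[loc])
}

# recompute per-fragment charges and the metal charge after a graph rewrite
# so that sum(charges) == Q and the oxidation-state identity keeps holding
.rebalanceMetal <- function(m) {
  frs <- .complexFragments(m)
  ligQ <- integer(0); cionQ <- integer(0)
  for (idx in frs) {
    qf <- sum(m@charges[idx])
    if (any(m@dative[idx, m@metalIndex])) ligQ <- c(ligQ, qf)
    else cionQ <- c(cionQ, qf)
  }
  ox <- as.integer(m@overallCharge - sum(ligQ) - sum(cionQ))
  m@charges[m@metalIndex] <- ox
  m@oxidationState <- ox
  m@ligandCharges <- ligQ
  m@counterIonCharges <- cionQ
  if (ox < 0L || ox > 10L)
    m@notes <- unique(c(m@notes, paste0("unusual metal oxidation state: ", ox)))
  m
}

#' Move misplaced charges onto coordinating oxygens (sulfonate-type fix)
#'
#' For oxyanion groups whose terminal oxygens are equivalent in the isolated
#' ligand but not in the complex (sulfonate, carboxylate, ...): when a
#' metal-coordinating terminal oxygen is neutral (double-bonded to the
#' central atom) while a non-coordinating sibling carries the -1 charge
#' (single bond), the charge and the bond orders are swapped so that the
#' coordinating atom carries the charge. Idempotent.
#'
#' @param m a \linkS4class{TMCMol}.
#' @return the fixed \linkS4class{TMCMol}.
#' @export
fixSulfonateLike <- function(m) {
  mi <- m@metalIndex
  coordAtoms <- which(m@dative[, mi])
  for (a in coordAtoms) {
    if (m@elements[a] != "O" || m@charges[a] != 0L) next
    # a must be terminal: exactly one non-metal neighbor (the central atom)
    nb <- setdiff(which(m@bonds[a, ] > 0L), mi)
    if (length(nb) != 1L || m@bonds[a, nb] != 2L) next
    center <- nb
    sibs <- setdiff(which(m@bonds[center, ] > 0L), c(a, mi))
    for (b in sibs) {
      if (m@elements[b] != "O" || m@charges[b] != -1L) next
      if (m@dative[b, mi]) next
      bnb <- setdiff(which(m@bonds[b, ] > 0L), mi)
      if (length(bnb) != 1L || m@bonds[b, center] != 1L) next
      # swap: coordinating O takes the charge and the single bond
      m@bonds[a, center] <- m@bonds[center, a] <- 1L
      m@bonds[b, center] <- m@bonds[center, b] <- 2L
      m@charges[a] <- -1L
      m@charges[b] <- 0L
      m@notes <- c(m@notes, sprintf(
        "sulfonate-like fix: moved -1 from atom %d to coordinating atom %d",
        b, a))
      .tmcLog("fix_sulfonate_like", from = b, to = a)
      break
    }
  }
  validObject(m)
  m
}

#' Rewrite charged nitro groups to the neutral form
#'
#' Every nitro group matched in the charge-separated form (N+ with a singly
#' bonded O-) is rewritten to the neutral two-double-bond form N(=O)=O. If
#' the rewrite changes a ligand's charge, the metal oxidation state is
#' recomputed so the formal charges still sum to Q. Idempotent.
#'
#' @param m a \linkS4class{TMCMol}.
#' @return the fixed \linkS4class{TMCMol}.
#' @export
fixNitro <- function(m) {
  mi <- m@metalIndex
  changed <- FALSE
  for (a in which(m@elements == "N" & m@charges == 1L)) {
    nb <- setdiff(which(m@bonds[a, ] > 0L), mi)
    os <- nb[m@elements[nb] == "O"]
    # terminal oxygens only (bonded to N alone, metal aside)
    terminal <- os[vapply(os, function(o)
      length(setdiff(which(m@bonds[o, ] > 0L), mi)) == 1L, TRUE)]
    dbl <- terminal[vapply(terminal, function(o)
      m@bonds[a, o] == 2L && m@charges[o] == 0L, TRUE)]
    sgl <- terminal[vapply(terminal, function(o)
      m@bonds[a, o] == 1L && m@charges[o] == -1L, TRUE)]
    if (length(dbl) >= 1L && length(sgl) >= 1L) {
      o <- sgl[1]
      m@bonds[a, o] <- m@bonds[o, a] <- 2L
      m@charges[a] <- 0L
      m@charges[o] <- 0L
      changed <- TRUE
      m@notes <- c(m@notes, sprintf(
        "nitro fix: neutral N(=O)=O form at atom %d", a))
      .tmcLog("fix_nitro", nitrogen = a)
    }
  }
  if (changed) m <- .rebalanceMetal(m)
  validObject(m)
  m
}

# Sanitization: every non-metal atom must sit in an admissible
# (valence, charge) state. The admissible set is the enumeration's state
# table plus two post-fix states: the neutral pentavalent nitro nitrogen
# and the neutral divalent carbene carbon. Dative bonds do not count toward
# the donor's valence. Returns NULL when fine, else a reason string.
.sanitizeCheck <- function(m) {
  n <- length(m@elements)
  metal <- isDBlock(m@elements)
  for (a in seq_len(n)) {
    if (metal[a]) next
    el <- m@elements[a]
    v <- 0L
    for (j in which(m@bonds[a, ] > 0L))
      if (!m@dative[a, j]) v <- v + m@bonds[a, j]
    q <- m@charges[a]
    states <- .lewisStates[[el]]
    if (is.null(states)) next  # exotic main-group element: not constrained
    ok <- any(vapply(states, function(st) st[1] == v && st[2] == q, TRUE))
    if (!ok && el == "C" && v == 2L && q == 0L) ok <- TRUE   # carbene
    if (!ok && el == "N" && v == 5L && q == 0L) ok <- TRUE   # neutral nitro
    if (!ok)
      return(sprintf("atom %d (%s): valence %d with charge %+d not allowed",
                     a, el, v, q))
  }
  NULL
}

#' Canonical SMILES of an assembled complex
#'
#' Runs the sanitization check and emits the canonical dative-bond SMILES.
#' A sanitization failure returns NULL (the complex is reported as failed,
#' consistent with the conversion bookkeeping).
#'
#' @param m a \linkS4class{TMCMol} (or any \linkS4class{MolGraph}).
#' @return a SMILES string, or NULL when the structure does not sanitize.
#' @export
toSmiles <- function(m) {
  reason <- .sanitizeCheck(m)
  if (!is.null(reason)) {
    .tmcLog("sanitize_failure", reason = reason)
    return(NULL)
  }
  canonicalSmiles(m)
}

# shared driver: fragments -> ligand mols (Hueckel or fixed charges) ->
# assembly -> fixes -> sanitize -> SMILES
.convertStructure <- function(s, Q, config, fixedCharges = NULL) {
  fail <- function(stage, message, ligand = NA_integer_)
    list(ok = FALSE, stage = stage, ligand = ligand, message = message)

  am <- buildAdjacency(s, config)
  am <- enforceValenceLimits(am, s, config)
  split0 <- tryCatch(splitLigands(am, s), error = function(e) e)
  if (inherits(split0, "error"))
    return(fail("not_mononuclear", conditionMessage(split0)))
  am <- pruneFakeHaptic(am, s, split0$metalIndex, config)
  split <- splitLigands(am, s)
  mi <- split$metalIndex
  frags <- split$fragments

  ligandMols <- vector("list", length(frags))
  for (k in seq_along(frags)) {
    f <- frags[[k]]
    if (is.null(fixedCharges)) {
      g <- tryCatch(adjustCharge(huckelChargeGuess(f, config), config),
                    error = function(e) e)
      if (inherits(g, "error"))
        return(fail("ligand_charges", conditionMessage(g), k))
      sel <- selectLigandRepresentation(f, g, config = config)
    } else {
      qFixed <- .lookupFixedCharge(fixedCharges, f)
      if (inherits(qFixed, "error"))
        return(fail("fixed_charge_table", conditionMessage(qFixed), k))
      sel <- selectLigandRepresentation(f, charge = qFixed, config = config)
    }
    if (is.null(sel))
      return(fail("ligand_lewis",
                  "no Lewis structure at the guessed charge nor after the two-electron fallback",
                  k))
    ligandMols[[k]] <- sel$mol
  }

  tm <- assembleComplex(s, am, mi, frags, ligandMols, Q)
  tm <- fixSulfonateLike(tm)
  tm <- fixNitro(tm)
  smi <- toSmiles(tm)
  if (is.null(smi))
    return(fail("sanitize", "assembled complex failed sanitization"))
  list(ok = TRUE, smiles = smi, mol = tm, cutLog = am@cutLog,
       oxidationState = tm@oxidationState,
       ligandCharges = tm@ligandCharges,
       counterIonCharges = tm@counterIonCharges,
       notes = tm@notes)
}

#' Convert an xyz structure to a dative-bond SMILES
#'
#' The full pipeline: distance-based bond perception, valence trimming,
#' spurious-haptic pruning, ligand splitting, extended Hueckel charge
#' assignment with frontier adjustments, Lewis/resonance solving per ligand
#' (with the two-electron fallback), reassembly with dative bonds, the
#' sulfonate and nitro fixes, sanitization and canonical SMILES emission.
#'
#' @param xyz path to an xyz file or xyz text.
#' @param Q integer overall charge of the complex.
#' @param config pipeline configuration.
#' @return on success, a list with \code{ok = TRUE}, the \code{smiles}
#'   string, the assembled \code{mol} (\linkS4class{TMCMol}),
#'   \code{oxidationState}, \code{ligandCharges} and any \code{notes};
#'   on failure, \code{ok = FALSE} with the failing \code{stage},
#'   offending \code{ligand} index (when applicable) and \code{message}.
#' @examples
#' xyz <- "2\nbare ion + chloride\nCu 0 0 0\nCl 2.1 0 0"
#' res <- xyzToSmiles(xyz, Q = 1)
#' res$smiles
#' @export
xyzToSmiles <- function(xyz, Q, config = tmcConfig()) {
  s <- tryCatch(parseXYZ(xyz), error = function(e) e)
  if (inherits(s, "error"))
    return(list(ok = FALSE, stage = "parse", ligand = NA_integer_,
                message = conditionMessage(s)))
  .convertStructure(s, Q, config)
}

.lookupFixedCharge <- function(fixedCharges, f) {
  key <- paste(sort(f@atomIndices), collapse = ",")
  hit <- which(vapply(fixedCharges$atoms, function(a)
    paste(sort(as.integer(a)), collapse = ",") == key, TRUE))
  if (length(hit) != 1L)
    return(simpleError(paste0(
      "fixed-charge table does not cover fragment with atoms {",
      paste(f@atomIndices, collapse = ","), "}")))
  as.integer(fixedCharges$charge[[hit]])
}

#' Assemble a complex from fixed per-ligand charges
#'
#' The fixed-charge path: identical to \code{\link{xyzToSmiles}} except that
#' ligand charges come from a table (as with charges derived from natural
#' bond orbital analysis) instead of the extended Hueckel guess, and the
#' two-electron fallback is skipped: when no Lewis structure exists at the
#' fixed charge, the complex fails.
#'
#' @param xyz path to an xyz file or xyz text.
#' @param Q integer overall charge.
#' @param ligandTable a data.frame (or list) with columns \code{atoms} (a
#'   list of integer atom-index vectors identifying each fragment in the
#'   complex, 1-based into the xyz) and \code{charge}.
#' @param config pipeline configuration.
#' @return as \code{\link{xyzToSmiles}}.
#' @export
assembleFromFixedCharges <- function(xyz, Q, ligandTable,
                                     config = tmcConfig()) {
  s <- tryCatch(parseXYZ(xyz), error = function(e) e)
  if (inherits(s, "error"))
    return(list(ok = FALSE, stage = "parse", ligand = NA_integer_,
                message = conditionMessage(s)))
  .convertStructure(s, Q, config, fixedCharges = ligandTable)
}
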