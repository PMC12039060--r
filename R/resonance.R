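# Resonance forms: alternative bond-order / formal-charge placements on the
# same connectivity at the same total charge. The set is produced by the
# same valence-state search as the initial Lewis structure, collected
# exhaustively up to a cap and deduplicated by canonical form.

#' Enumerate resonance forms of a solved ligand
#'
#' Returns every Lewis structure of the ligand's fragment at the ligand's
#' charge (same adjacency, same total charge), deduplicated canonically and
#' annotated with the two scoring quantities: the aromatic atom count and
#' the penalized formal-charge count (negative charges on metal-coordinating
#' atoms are not penalized). The input structure itself is always in the
#' list. The list is capped at \code{config$resonanceCap} candidates (in
#' canonical search order) and the cap is logged when hit.
#'
#' @param m a \linkS4class{LigandMol}.
#' @param allowCarbene admit the neutral divalent carbon state (use the
#'   setting that produced \code{m}).
#' @param config pipeline configuration.
#' @return a list of annotated candidates: each has elements \code{mol},
#'   \code{nAromatic}, \code{penalized}, \code{smiles}.
#' @export
enumerateResonance <- function(m, allowCarbene = TRUE, config = tmcConfig()) {
  f <- new("LigandFragment", atomIndices = seq_along(m@elements),
           elements = m@elements, coords = m@coords,
           ac = (m@bonds > 0L) * 1L,
           coordinatingAtoms = m@coordinatingAtoms,
           isCounterIon = length(m@coordinatingAtoms) == 0L)
  sols <- .enumLewis(m@elements, f@ac, m@charge, allowCarbene,
                     cap = config$resonanceCap + 1L, config = config)
  if (length(sols) > config$resonanceCap) {
    .tmcLog("resonance_cap_hit", cap = config$resonanceCap, config = config)
    sols <- sols[seq_len(config$resonanceCap)]
  }
  mols <- lapply(sols, function(s) .ligandMolFromSolution(f, s))
  # make sure the input form is present (it is found by the same search, but
  # the cap could in principle have cut it off)
  keys <- vapply(mols, canonicalSmiles, "")
  mKey <- canonicalSmiles(m)
  if (!mKey %in% keys) {
    mols <- c(list(m), mols)
    keys <- c(mKey, keys)
  }
  keep <- !duplicated(keys)
  mols <- mols[keep]; keys <- keys[keep]
  lapply(seq_along(mols), function(i)
    .annotateCandidate(mols[[i]], keys[i]))
}

.annotateCandidate <- function(mol, smiles = canonicalSmiles(mol),
                               rings = NULL) {
  coord <- mol@coordinatingAtoms
  charges <- mol@charges
  penalized <- sum(charges != 0L) -
    sum(charges < 0L & seq_along(charges) %in% coord)
  nAromatic <- if (is.null(rings)) countAromaticAtoms(mol) else
    sum(.aromaticFromRings(mol@elements, mol@charges, mol@bonds, rings,
                           mol@carbeneAtoms))
  list(mol = mol,
       nAromatic = as.integer(nAromatic),
       penalized = as.integer(penalized),
       nCharged = sum(charges != 0L),
       smiles = smiles)
}

#' Ordering key for a resonance candidate
#'
#' Lexicographic: larger aromatic systems win; then fewer penalized formal
#' charges (negative charges on coordinating atoms are free); then the
#' non-zwitterionic (fewest charged atoms overall) form, which implements
#' the carbene-over-charged preference; final deterministic tie-break by
#' canonical SMILES string order.
#'
#' @param candidate an annotated candidate from
#'   \code{\link{enumerateResonance}}.
#' @return a list with components usable with \code{order()}:
#'   \code{negAromatic}, \code{penalized}, \code{nCharged}, \code{smiles}.
#' @export
scoreResonance <- function(candidate) {
  list(negAromatic = -candidate$nAromatic,
       penalized = candidate$penalized,
       nCharged = candidate$nCharged,
       smiles = candidate$smiles)
}

.pickBest <- function(candidates) {
  negArom <- vapply(candidates, function(c) -c$nAromatic, 0L)
  pen <- vapply(candidates, `[[`, 0L, "penalized")
  nch <- vapply(candidates, `[[`, 0L, "nCharged")
  best <- which(negArom == min(negArom))
  best <- best[pen[best] == min(pen[best])]
  best <- best[nch[best] == min(nch[best])]
  if (length(best) > 1L) {
    # deterministic final tie-break by canonical form (computed lazily,
    # only for the tied candidates)
    smi <- vapply(best, function(i) {
      if (is.null(candidates[[i]]$smiles))
        canonicalSmiles(candidates[[i]]$mol) else candidates[[i]]$smiles
    }, "")
    best <- best[order(smi, method = "radix")]
  }
  candidates[[best[1]]]
}

#' Select the best ligand representation
#'
#' Runs the full search -- Lewis enumeration at the adjusted charge (with
#' the two-electron fallback), resonance enumeration, scoring -- twice, once
#' admitting carbenes and once not, pools all candidates and returns the
#' global best. When a carbene form and a zwitterionic form tie on aromatic
#' size and penalized charges, the carbene (non-zwitterionic) form wins.
#'
#' @param f a \linkS4class{LigandFragment}.
#' @param g an adjusted \linkS4class{ChargeGuess} (or any object with a
#'   charge to use; for the fixed-charge path pass the charge directly via
#'   \code{charge}).
#' @param charge optional fixed integer charge overriding \code{g}; when
#'   given, the two-electron fallback is skipped (the fixed-charge assembly
#'   path).
#' @param config pipeline configuration.
#' @return a list: \code{mol} (the chosen \linkS4class{LigandMol}),
#'   \code{charge}, \code{usedFallback}; or NULL when no Lewis structure
#'   exists at the guessed charge nor after the fallback.
#' @export
selectLigandRepresentation <- function(f, g = NULL, charge = NULL,
                                       config = tmcConfig()) {
  fixed <- !is.null(charge)
  q <- if (fixed) as.integer(charge) else g@charge
  passes <- if (config$allowCarbenes) c(TRUE, FALSE) else FALSE
  usedFallback <- FALSE

  rings <- .smallestRings((f@ac > 0L) * 1L)
  solveAt <- function(qq) {
    found <- list()
    rawSeen <- character(0)
    for (carb in passes) {
      sols <- .enumLewis(f@elements, f@ac, qq, carb,
                         cap = config$resonanceCap + 1L, config = config)
      if (!length(sols)) next
      if (length(sols) > config$resonanceCap) {
        .tmcLog("resonance_cap_hit", cap = config$resonanceCap,
                config = config)
        sols <- sols[seq_len(config$resonanceCap)]
      }
      for (sl in sols) {
        # candidates share the fragment's atom order, so the raw bond/charge
        # pattern is an exact duplicate key
        raw <- paste(c(sl$bonds[upper.tri(sl$bonds)], sl$charges),
                     collapse = ",")
        if (raw %in% rawSeen) next
        rawSeen <- c(rawSeen, raw)
        found[[length(found) + 1L]] <- .annotateCandidate(
          .ligandMolFromSolution(f, sl), smiles = NULL, rings = rings)
      }
    }
    found
  }

  cands <- solveAt(q)
  if (!length(cands) && !fixed) {
    usedFallback <- TRUE
    q <- if (q >= 0L) q - 2L else q + 2L
    .tmcLog("charge_fallback", to = q, config = config)
    cands <- solveAt(q)
  }
  if (!length(cands)) return(NULL)
  best <- .pickBest(cands)
  list(mol = best$mol, charge = q, usedFallback = usedFallback,
       nCandidates = length(cands))
}
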