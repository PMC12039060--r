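# Lewis structure search: assign integer bond orders over a fixed
# connectivity so that every atom realizes an allowed (valence, formal
# charge) state and the formal charges sum to the requested ligand charge.
#
# The search enumerates per-atom valence states in the documented canonical
# order (atoms by index, states in the order of the element's state table,
# carbene state last) and realizes each state combination as bond orders by
# backtracking over edges in lexicographic order. It can return the first
# solution or every solution up to a cap (the resonance set).

# Admissible (bond-order sum, charge) states for one atom of a fragment.
# A carbene state (2 single bonds, charge 0) is appended for carbons with
# exactly two sigma neighbors when carbenes are allowed.
.atomStates <- function(el, degree, allowCarbene) {
  states <- .lewisStates[[el]]
  if (is.null(states)) return(NULL)
  out <- lapply(states, function(s) list(v = s[1], q = s[2], carbene = FALSE))
  if (allowCarbene && el == "C" && degree == 2L)
    out <- c(out, list(list(v = 2L, q = 0L, carbene = TRUE)))
  out
}

# All assignments of "extra" bond order (0..2 per edge, bond order 1+extra)
# such that the per-atom sums of extras equal `need`. Backtracking over
# edges; returns a list of extra vectors (or at most `cap`).
.edgeRealizations <- function(edges, n, need, cap = Inf, firstOnly = FALSE) {
  nE <- nrow(edges)
  sols <- list()
  if (nE == 0L) {
    if (all(need == 0L)) sols <- list(integer(0))
    return(sols)
  }
  # remaining extra capacity per atom as edges get decided
  edgesAt <- lapply(seq_len(n), function(i)
    which(edges[, 1] == i | edges[, 2] == i))
  remCap <- vapply(seq_len(n), function(i) 2L * length(edgesAt[[i]]), 0L)
  extra <- integer(nE)
  acc <- integer(n)
  recurse <- function(k) {
    if (length(sols) >= cap) return(TRUE)
    if (k > nE) {
      if (all(acc == need)) {
        sols[[length(sols) + 1L]] <<- extra
        if (firstOnly || length(sols) >= cap) return(TRUE)
      }
      return(FALSE)
    }
    i <- edges[k, 1]; j <- edges[k, 2]
    remCap[i] <<- remCap[i] - 2L
    remCap[j] <<- remCap[j] - 2L
    for (e in 0:2) {
      ai <- acc[i] + e; aj <- acc[j] + e
      if (ai > need[i] || aj > need[j]) break
      if (ai + remCap[i] < need[i] || aj + remCap[j] < need[j]) next
      extra[k] <<- e
      acc[i] <<- ai; acc[j] <<- aj
      done <- recurse(k + 1L)
      acc[i] <<- acc[i] - e; acc[j] <<- acc[j] - e
      if (done) {
        remCap[i] <<- remCap[i] + 2L
        remCap[j] <<- remCap[j] + 2L
        return(TRUE)
      }
    }
    extra[k] <<- 0L
    remCap[i] <<- remCap[i] + 2L
    remCap[j] <<- remCap[j] + 2L
    FALSE
  }
  recurse(1L)
  sols
}

# Core search over valence-state combinations. Returns a list of solutions,
# each list(bonds = integer matrix, charges = integer vector,
# carbeneAtoms = integer vector).
.enumLewis <- function(elements, ac, charge, allowCarbene,
                       cap = 1L, config = tmcConfig()) {
  n <- length(elements)
  deg <- if (n > 1L) rowSums(ac) else 0L
  stateList <- lapply(seq_len(n), function(i)
    .atomStates(elements[i], as.integer(deg[i]), allowCarbene))
  if (any(vapply(stateList, is.null, TRUE))) return(list())
  edges <- which(upper.tri(ac) & ac == 1L, arr.ind = TRUE)
  if (length(edges)) {
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    storage.mode(edges) <- "integer"
  } else edges <- matrix(integer(), 0, 2)

  qMin <- vapply(stateList, function(ss) min(vapply(ss, `[[`, 0L, "q")), 0L)
  qMax <- vapply(stateList, function(ss) max(vapply(ss, `[[`, 0L, "q")), 0L)
  sufMin <- rev(cumsum(rev(c(qMin, 0L))))  # sufMin[i] = min sum from atom i on
  sufMax <- rev(cumsum(rev(c(qMax, 0L))))

  sols <- list()
  pick <- vector("list", n)
  realCache <- new.env(parent = emptyenv())
  realCap <- max(config$resonanceCap, 16L)
  chooseState <- function(i, qAcc) {
    if (length(sols) >= cap) return()
    if (i > n) {
      if (qAcc != charge) return()
      v <- vapply(pick, `[[`, 0L, "v")
      need <- as.integer(v - deg)
      if (any(need < 0L) || sum(need) %% 2L != 0L) return()
      key <- paste(need, collapse = ",")
      real <- realCache[[key]]
      if (is.null(real)) {
        real <- .edgeRealizations(edges, n, need, cap = realCap)
        realCache[[key]] <- real
      }
      for (extra in real) {
        if (length(sols) >= cap) return()
        bonds <- matrix(0L, n, n)
        if (nrow(edges)) {
          bo <- 1L + extra
          bonds[edges] <- bo
          bonds[edges[, c(2, 1), drop = FALSE]] <- bo
        }
        # carbene state demands two single bonds, not one double
        carb <- which(vapply(pick, `[[`, FALSE, "carbene"))
        okCarb <- all(vapply(carb, function(a)
          all(bonds[a, bonds[a, ] > 0L] == 1L), TRUE))
        if (!okCarb) next
        sols[[length(sols) + 1L]] <<- list(
          bonds = bonds,
          charges = vapply(pick, `[[`, 0L, "q"),
          carbeneAtoms = as.integer(carb))
        if (length(sols) >= cap) return()
      }
      return()
    }
    for (s in stateList[[i]]) {
      if (s$v < deg[i]) next                    # cannot realize fewer bonds
      if (s$v > deg[i] * 3L) next               # nor more than triple each
      q2 <- qAcc + s$q
      if (q2 + sufMin[i + 1L] > charge) next
      if (q2 + sufMax[i + 1L] < charge) next
      pick[[i]] <<- s
      chooseState(i + 1L, q2)
      if (length(sols) >= cap) return()
    }
  }
  chooseState(1L, 0L)
  sols
}

.ligandMolFromSolution <- function(f, sol) {
  new("LigandMol", elements = f@elements, bonds = sol$bonds,
      dative = matrix(FALSE, length(f@elements), length(f@elements)),
      charges = as.integer(sol$charges), coords = f@coords,
      coordinatingAtoms = f@coordinatingAtoms,
      carbeneAtoms = sol$carbeneAtoms,
      charge = as.integer(sum(sol$charges)))
}

#' Find a Lewis structure for a ligand fragment at a given charge
#'
#' Loops over combinations of allowed per-atom valence states (in canonical
#' order) and realizes bond orders on the fragment's fixed connectivity
#' until a structure matching the requested total charge is found. When
#' \code{allowCarbene} is TRUE, a neutral divalent carbon with two single
#' bonds is an admissible state for carbons with exactly two neighbors.
#'
#' @param f a \linkS4class{LigandFragment}.
#' @param charge requested integer ligand charge.
#' @param allowCarbene admit the neutral divalent carbon state.
#' @param config pipeline configuration.
#' @return a \linkS4class{LigandMol}, or NULL when no combination exists
#'   (the failure sentinel that triggers the charge fallback).
#' @export
enumerateBondOrders <- function(f, charge, allowCarbene = TRUE,
                                config = tmcConfig()) {
  sols <- .enumLewis(f@elements, f@ac, as.integer(charge), allowCarbene,
                     cap = 1L, config = config)
  if (!length(sols)) return(NULL)
  .ligandMolFromSolution(f, sols[[1]])
}

#' Retry a failed Lewis search with a two-electron charge shift
#'
#' When no Lewis structure exists at the guessed charge q, exactly one retry
#' is made: at q - 2 when q >= 0 (two electrons added), else at q + 2 (two
#' electrons removed). On a second failure the ligand -- and hence the
#' complex -- yields no SMILES.
#'
#' @param f a \linkS4class{LigandFragment}.
#' @param g the \linkS4class{ChargeGuess} whose charge failed.
#' @param allowCarbene admit the carbene state.
#' @param config pipeline configuration.
#' @return a \linkS4class{LigandMol} or NULL.
#' @export
chargeFallback <- function(f, g, allowCarbene = TRUE, config = tmcConfig()) {
  q <- g@charge
  q2 <- if (q >= 0L) q - 2L else q + 2L
  .tmcLog("charge_fallback", from = q, to = q2, config = config)
  enumerateBondOrders(f, q2, allowCarbene, config)
}
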