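#' Initial ligand charge from extended Hueckel occupancy
#'
#' Computes the fragment's molecular-orbital ladder and counts the orbitals
#' below the cutoff energy (default +10 eV) as doubly occupied:
#' q = sum(V_i) - 2 * #(E < E_C). The orbital ladder is retained for the
#' frontier-based adjustment step. If the orbital computation fails, the
#' guess falls back to electron-count parity (0 for an even electron count,
#' -1 for odd) and is flagged.
#'
#' @param f a \linkS4class{LigandFragment}.
#' @param config pipeline configuration (\code{cutoffEnergy}).
#' @return a \linkS4class{ChargeGuess}.
#' @export
huckelChargeGuess <- function(f, config = tmcConfig()) {
  if (length(f@elements) == 0L) stop("empty fragment")
  V <- as.integer(sum(.valenceElectrons[f@elements]))
  energies <- tryCatch(ehtOrbitalEnergies(f@elements, f@coords),
                       error = function(e) e)
  if (inherits(energies, "error")) {
    q <- if (V %% 2L == 0L) 0L else -1L
    .tmcLog("huckel_failure", message = conditionMessage(energies),
            fallbackCharge = q, config = config)
    return(new("ChargeGuess", orbitalEnergies = numeric(),
               nValenceElectrons = V, charge = q,
               adjustments = "parity_fallback", flagged = TRUE))
  }
  nFilled <- sum(energies < config$cutoffEnergy)
  q <- V - 2L * nFilled
  .tmcLog("huckel_guess", nValenceElectrons = V, nFilled = nFilled,
          charge = q, engine = "tmcSMILES-EHT", config = config)
  new("ChargeGuess", orbitalEnergies = energies, nValenceElectrons = V,
      charge = as.integer(q))
}

# frontier orbitals at a given filling level of a fixed ladder
.frontier <- function(energies, nFilled) {
  homo <- if (nFilled >= 1L && nFilled <= length(energies))
    energies[nFilled] else NA_real_
  lumo <- if (nFilled + 1L <= length(energies))
    energies[nFilled + 1L] else NA_real_
  list(homo = homo, lumo = lumo)
}

#' Iterative frontier-orbital charge adjustment
#'
#' Applies the two-electron correction rules to an occupancy-based charge
#' guess: while the charge is positive and the LUMO lies below -9 eV, two
#' electrons are added; while the charge is -2 or lower and the HOMO lies
#' above -10.2 eV, two electrons are removed. The frontier orbitals are
#' re-read from the fixed orbital ladder at the new filling after every
#' step; nothing is recomputed. The function is idempotent. If the two rules
#' would fire alternately, only the first direction is applied and the guard
#' is logged.
#'
#' @param g a \linkS4class{ChargeGuess} from \code{\link{huckelChargeGuess}}.
#' @param config pipeline configuration (\code{lumoLow}, \code{homoHigh},
#'   \code{maxAdjust}).
#' @return the adjusted \linkS4class{ChargeGuess}.
#' @export
adjustCharge <- function(g, config = tmcConfig()) {
  if (g@flagged || length(g@orbitalEnergies) == 0L) return(g)
  energies <- g@orbitalEnergies
  q <- g@charge
  adj <- g@adjustments
  nFilled <- (g@nValenceElectrons - q) %/% 2L
  usedDirection <- NULL

  addRuleFires <- function(q, nFilled) {
    fr <- .frontier(energies, nFilled)
    q > 0L && !is.na(fr$lumo) && fr$lumo < config$lumoLow
  }
  removeRuleFires <- function(q, nFilled) {
    fr <- .frontier(energies, nFilled)
    q <= -2L && !is.na(fr$homo) && fr$homo > config$homoHigh
  }

  steps <- 0L
  while (addRuleFires(q, nFilled) && steps < config$maxAdjust) {
    fr <- .frontier(energies, nFilled)
    q <- q - 2L; nFilled <- nFilled + 1L; steps <- steps + 1L
    adj <- c(adj, sprintf("+2e(low LUMO %.2f eV)", fr$lumo))
    usedDirection <- "add"
  }
  if (is.null(usedDirection) || !removeRuleFires(q, nFilled)) {
    steps2 <- 0L
    while (removeRuleFires(q, nFilled) && steps2 < config$maxAdjust) {
      fr <- .frontier(energies, nFilled)
      q <- q + 2L; nFilled <- nFilled - 1L; steps2 <- steps2 + 1L
      adj <- c(adj, sprintf("-2e(high HOMO %.2f eV)", fr$homo))
      usedDirection <- if (is.null(usedDirection)) "remove" else usedDirection
    }
  } else {
    # oscillation guard: the add direction already ran and the remove rule
    # now fires; stop here rather than ping-pong
    adj <- c(adj, "oscillation_guard")
    .tmcLog("charge_adjust_oscillation", charge = q, config = config)
  }
  if (length(adj) > length(g@adjustments))
    .tmcLog("charge_adjusted", from = g@charge, to = q,
            steps = length(adj) - length(g@adjustments), config = config)
  new("ChargeGuess", orbitalEnergies = energies,
      nValenceElectrons = g@nValenceElectrons, charge = as.integer(q),
      adjustments = adj, engine = g@engine, flagged = g@flagged)
}
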