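# show methods and small accessors, Bioconductor style

setMethod("show", "XYZStructure", function(object) {
  cat("XYZStructure with", length(object@elements), "atoms:",
      paste(unique(object@elements), collapse = " "), "\n")
})

setMethod("show", "AdjacencyMatrix", function(object) {
  cat("AdjacencyMatrix:", nrow(object@ac), "atoms,",
      sum(object@ac) / 2, "bonds,", nrow(object@cutLog), "cut\n")
})

setMethod("show", "LigandFragment", function(object) {
  cat("LigandFragment:", length(object@elements), "atoms (",
      paste0(object@elements, collapse = ""), "), ",
      length(object@coordinatingAtoms), " coordinating atom(s)",
      if (object@isCounterIon) " [counter-ion]" else "", "\n", sep = "")
})

setMethod("show", "ChargeGuess", function(object) {
  cat("ChargeGuess: q =", object@charge, "(", object@nValenceElectrons,
      "valence electrons,", length(object@orbitalEnergies), "MOs )\n")
  if (length(object@adjustments))
    cat("  adjustments:", paste(object@adjustments, collapse = "; "), "\n")
})

setMethod("show", "MolGraph", function(object) {
  cat(class(object), "with", length(object@elements), "atoms, net charge",
      sum(object@charges), "\n")
})

setMethod("show", "TMCMol", function(object) {
  cat("TMCMol:", object@elements[object@metalIndex],
      sprintf("(M_ox %+d),", object@oxidationState),
      length(object@ligandCharges), "ligand(s), Q =",
      object@overallCharge, "\n")
  if (length(object@notes)) cat("  notes:",
                                paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "FixReport", function(object) {
  cat("FixReport:", if (is.na(object@outputSmiles)) "FAILED" else "fixed",
      "\n  in: ", object@inputSmiles, "\n")
  if (!is.na(object@outputSmiles)) cat("  out:", object@outputSmiles, "\n")
  if (length(object@appliedRules))
    cat("  rules:", paste(object@appliedRules, collapse = "; "), "\n")
  if (!is.na(object@failure)) cat("  failure:", object@failure, "\n")
})

#' Accessors for molecular graphs and complexes
#'
#' @param m a \linkS4class{MolGraph} or \linkS4class{TMCMol}.
#' @return \code{formalCharges}: integer vector; \code{bondOrders}: integer
#'   matrix; \code{dativeBonds}: two-column matrix (donor, metal);
#'   \code{oxidationState}, \code{overallCharge}: integers;
#'   \code{ligandCharges}: integer vector.
#' @export
formalCharges <- function(m) m@charges

#' @rdname formalCharges
#' @export
bondOrders <- function(m) m@bonds

#' @rdname formalCharges
#' @export
dativeBonds <- function(m) {
  idx <- which(upper.tri(m@dative) & m@dative, arr.ind = TRUE)
  metal <- isDBlock(m@elements)
  out <- t(apply(idx, 1, function(e) {
    if (metal[e[1]]) c(e[2], e[1]) else c(e[1], e[2])
  }))
  if (!nrow(idx)) out <- matrix(integer(), 0, 2)
  colnames(out) <- c("donor", "acceptor")
  out
}

#' @rdname formalCharges
#' @export
oxidationState <- function(m) m@oxidationState

#' @rdname formalCharges
#' @export
overallCharge <- function(m) m@overallCharge

#' @rdname formalCharges
#' @export
ligandCharges <- function(m) m@ligandCharges
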