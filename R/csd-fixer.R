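# Repair of raw CSD-style SMILES: covalent metal-ligand bonds, missing
# charges on hypervalent atoms, and a handful of structural special cases.
# Every rewrite moves charge in balanced pairs, so the net formal charge of
# the output always equals that of the input.

.fixerRulesVersion <- "1.0"

# is (valence v, charge q) an admissible state for element el, with the
# carbene carbon admitted (the judgment table of the fixer)?
.stateAdmissible <- function(el, v, q) {
  states <- .lewisStates[[el]]
  if (is.null(states)) return(TRUE)
  if (el == "C" && v == 2L && q == 0L) return(TRUE)   # carbene
  if (el == "N" && v == 5L && q == 0L) return(TRUE)   # neutral nitro
  any(vapply(states, function(st) st[1] == v && st[2] == q, TRUE))
}

# valence of atom a excluding dative bonds (donor side) and excluding any
# bonds in `drop` (matrix row indices)
.covalentValence <- function(m, a, dropTo = integer()) {
  v <- 0L
  for (j in which(m@bonds[a, ] > 0L)) {
    if (m@dative[a, j] || j %in% dropTo) next
    v <- v + m@bonds[a, j]
  }
  v
}

#' Repair a raw CSD-style SMILES into a sanitizable dative-bond SMILES
#'
#' The rewrite pipeline, each rule logged in order: (1) every covalent
#' metal-ligand bond becomes a dative bond; when the ligand atom's valence
#' only makes sense with the metal bond counted ("true" covalent bond), the
#' metal charge is increased and the ligand atom charge decreased by the
#' bond order; (2) hypervalent N atoms away from the metal get +1 with the
#' metal compensating by -1, and hypervalent B atoms the opposite; (3)
#' structural special cases: metal-bound carbene carbons with a terminal
#' oxygen are rewritten to the triple-bond carbonyl form, and pyrrole-type
#' rings kekulize against the dative-converted graph. The output is the
#' canonical form after sanitization.
#'
#' @param raw a SMILES string containing exactly one d-block atom.
#' @param referenceFormula optional Hill-notation formula; when given, the
#'   repaired structure's formula is checked against it.
#' @return a \linkS4class{FixReport}.
#' @export
fixCSDSmiles <- function(raw, referenceFormula = NULL) {
  failRep <- function(msg) new("FixReport", inputSmiles = raw,
                               outputSmiles = NA_character_, failure = msg)
  m <- tryCatch(parseSmiles(raw), error = function(e) e)
  if (inherits(m, "error"))
    return(failRep(paste0("parse/kekulize failure: ", conditionMessage(m))))
  metals <- which(isDBlock(m@elements))
  if (length(metals) != 1L)
    return(failRep(paste0("expected exactly one d-block atom, found ",
                          length(metals))))
  mi <- metals
  applied <- character(0)
  deltaMetal <- 0L

  # rule 1: covalent metal-ligand bonds -> dative, with charge transfer for
  # "true" covalent bonds (the ligand atom needs the bond for its valence)
  for (a in which(m@bonds[mi, ] > 0L)) {
    if (m@dative[a, mi]) next
    o <- m@bonds[a, mi]
    vWithout <- .covalentValence(m, a, dropTo = mi)
    m@bonds[a, mi] <- m@bonds[mi, a] <- 1L
    m@dative[a, mi] <- m@dative[mi, a] <- TRUE
    if (.stateAdmissible(m@elements[a], vWithout, m@charges[a])) {
      applied <- c(applied, sprintf("dative_conversion(atom %d, order %d)",
                                    a, o))
    } else {
      m@charges[a] <- m@charges[a] - o
      m@charges[mi] <- m@charges[mi] + o
      deltaMetal <- deltaMetal + o
      applied <- c(applied, sprintf(
        "dative_conversion_with_transfer(atom %d, order %d)", a, o))
    }
  }

  # rule 2: hypervalent N (+1, metal -1) and hypervalent B (-1, metal +1)
  # away from the metal
  for (a in seq_along(m@elements)) {
    if (a == mi || m@bonds[a, mi] > 0L) next
    el <- m@elements[a]
    v <- .covalentValence(m, a)
    q <- m@charges[a]
    if (el == "N" && q == 0L && v == 4L) {
      m@charges[a] <- 1L
      m@charges[mi] <- m@charges[mi] - 1L
      deltaMetal <- deltaMetal - 1L
      applied <- c(applied, sprintf("hypervalent_N(atom %d)", a))
    } else if (el == "B" && q == 0L && v == 4L) {
      m@charges[a] <- -1L
      m@charges[mi] <- m@charges[mi] + 1L
      deltaMetal <- deltaMetal + 1L
      applied <- c(applied, sprintf("hypervalent_B(atom %d)", a))
    }
  }

  # rule 3 special case: metal-bound divalent carbon with one terminal O
  # (carbon monoxide drawn as carbene or M=C=O) -> [C-]#[O+] dative form
  for (a in which(m@elements == "C" & m@dative[, mi])) {
    nb <- setdiff(which(m@bonds[a, ] > 0L), mi)
    if (length(nb) != 1L || m@elements[nb] != "O") next
    o <- nb
    oTerminal <- length(setdiff(which(m@bonds[o, ] > 0L), a)) == 0L
    if (!oTerminal) next
    if (m@bonds[a, o] == 3L) next
    if (m@charges[a] == 0L && m@charges[o] == 0L) {
      m@bonds[a, o] <- m@bonds[o, a] <- 3L
      m@charges[a] <- -1L
      m@charges[o] <- 1L
      applied <- c(applied, sprintf("carbonyl_triple_form(atom %d)", a))
    }
  }

  reason <- .sanitizeCheck(m)
  if (!is.null(reason))
    return(new("FixReport", inputSmiles = raw,
               outputSmiles = NA_character_, appliedRules = applied,
               chargeDeltaMetal = deltaMetal,
               failure = paste0("sanitization failure: ", reason)))
  out <- canonicalSmiles(m)
  formulaCheck <- "skipped"
  if (!is.null(referenceFormula)) {
    fc <- checkFormula(out, referenceFormula)
    formulaCheck <- if (isTRUE(fc$pass)) "pass" else "fail"
  }
  # identity inputs produce no rule applications; report only real rewrites
  if (identical(out, tryCatch(canonicalSmiles(parseSmiles(raw)),
                              error = function(e) NULL)))
    applied <- character(0)
  new("FixReport", inputSmiles = raw, outputSmiles = out,
      appliedRules = applied, formulaCheck = formulaCheck,
      chargeDeltaMetal = deltaMetal)
}

# molecular formula (element -> count) of a graph with explicit hydrogens
.formulaOf <- function(m) {
  tab <- table(m@elements)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

.parseHillFormula <- function(s) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
    stop("unparsable reference formula: ", sQuote(s))
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  counts <- integer(0)
  for (p in parts) {
    el <- regmatches(p, regexpr("^[A-Z][a-z]?", p))
    num <- sub("^[A-Z][a-z]?", "", p)
    k <- if (nzchar(num)) as.integer(num) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  counts
}

#' Check a repaired SMILES against a reference empirical formula
#'
#' Materializes implicit hydrogens and compares element counts with a
#' Hill-notation reference. A mismatch (the typical symptom of missing
#' explicit hydrogens in the raw SMILES) fails with the differing counts.
#'
#' @param fixed a SMILES string (must parse).
#' @param referenceFormula Hill-notation formula string, e.g. "C6H15Cl3N3Ru".
#' @return a list with \code{pass} (logical) and, on failure, \code{diff}
#'   (named integer vector of count differences, fixed minus reference).
#' @export
checkFormula <- function(fixed, referenceFormula) {
  m <- parseSmiles(fixed)
  have <- .formulaOf(m)
  want <- .parseHillFormula(referenceFormula)
  els <- sort(unique(c(names(have), names(want))), method = "radix")
  h <- ifelse(els %in% names(have), have[els], 0L)
  w <- ifelse(els %in% names(want), want[els], 0L)
  diffs <- as.integer(h) - as.integer(w)
  names(diffs) <- els
  if (all(diffs == 0L)) list(pass = TRUE)
  else list(pass = FALSE, diff = diffs[diffs != 0L])
}
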