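# SMILES parsing.
#
# Supports the subset of SMILES this package needs: organic-subset and
# bracket atoms (charge, explicit H count, isotopes ignored), single /
# double / triple / aromatic bonds, directional dative tokens `->` and
# `<-`, branches, ring closures (including %nn), dot-separated components
# and lowercase aromatic atoms. Aromatic systems are kekulized on read by a
# backtracking perfect matching; stereo markers are accepted and dropped.

.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

.parseBracket <- function(body) {
  s <- body
  # isotope
  s <- sub("^[0-9]+", "", s)
  mEl <- regmatches(s, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", s))
  if (!length(mEl)) stop("SMILES parse error: bad bracket atom [", body, "]")
  el <- mEl
  s <- substring(s, nchar(el) + 1L)
  aromatic <- el %in% c(.AROMATIC_ORGANIC, "as", "se")
  if (aromatic) {
    el <- paste0(toupper(substring(el, 1, 1)), substring(el, 2))
  }
  # chirality markers dropped
  s <- sub("^@+(TH[12]|AL[12]|SP[1-3]|TB[0-9]+|OH[0-9]+)?", "", s)
  hCount <- 0L
  mH <- regmatches(s, regexpr("^H[0-9]*", s))
  if (length(mH)) {
    hCount <- if (nchar(mH) == 1L) 1L else as.integer(substring(mH, 2))
    s <- substring(s, nchar(mH) + 1L)
  }
  charge <- 0L
  mC <- regmatches(s, regexpr("^(\\+{1,3}|-{1,3})([0-9]+)?", s))
  if (length(mC) && nzchar(mC)) {
    sign <- if (substring(mC, 1, 1) == "+") 1L else -1L
    digits <- sub("^[+-]+", "", mC)
    charge <- if (nzchar(digits)) sign * as.integer(digits)
              else sign * nchar(mC)
    s <- substring(s, nchar(mC) + 1L)
  }
  s <- sub("^:[0-9]+", "", s)  # atom map
  if (nzchar(s))
    stop("SMILES parse error: unparsed bracket content ", sQuote(s),
         " in [", body, "]")
  if (!el %in% names(.covalentRadii))
    stop("SMILES parse error: unknown element ", sQuote(el))
  list(el = el, aromatic = aromatic, hCount = hCount, charge = charge,
       explicitH = TRUE)
}

# tokenize + build the raw graph (no kekulization yet)
.parseSmilesGraph <- function(s) {
  atoms <- list()
  bonds <- list()      # list of c(i, j, orderCode) ; codes: 1,2,3 covalent,
                       # 5 aromatic/unspecified-aromatic, 6 dative i->j
  prev <- NA_integer_
  stack <- integer(0)
  pendingBond <- NULL  # NULL = default
  ringMap <- list()    # digit -> list(atom, bond)
  i <- 1L
  nc <- nchar(s)

  addAtom <- function(at) {
    atoms[[length(atoms) + 1L]] <<- at
    idx <- length(atoms)
    if (!is.na(prev)) {
      bond <- pendingBond
      if (is.null(bond)) bond <- list(code = 0L)  # default
      if (bond$code == 6L) {
        bonds[[length(bonds) + 1L]] <<- c(prev, idx, 6L)
      } else if (bond$code == 7L) {
        bonds[[length(bonds) + 1L]] <<- c(idx, prev, 6L)
      } else {
        bonds[[length(bonds) + 1L]] <<- c(prev, idx, bond$code)
      }
    }
    pendingBond <<- NULL
    prev <<- idx
  }

  closeRing <- function(digit) {
    bond <- pendingBond
    pendingBond <<- NULL
    key <- as.character(digit)
    if (is.null(ringMap[[key]])) {
      ringMap[[key]] <<- list(atom = prev, bond = bond)
    } else {
      open <- ringMap[[key]]
      ringMap[[key]] <<- NULL
      b1 <- open$bond; b2 <- bond
      code <- 0L
      flip <- FALSE
      pickCode <- function(b) if (is.null(b)) NA_integer_ else b$code
      c1 <- pickCode(b1); c2 <- pickCode(b2)
      # dative ring closures: direction tokens are written from each side's
      # own perspective; -> at the opening atom means open->close
      norm <- function(cc, fromOpen) {
        if (is.na(cc)) return(NA_integer_)
        if (cc == 7L) return(if (fromOpen) -6L else 6L)
        if (cc == 6L) return(if (fromOpen) 6L else -6L)
        cc
      }
      c1n <- norm(c1, TRUE); c2n <- norm(c2, FALSE)
      use <- c1n
      if (is.na(use)) use <- c2n
      else if (!is.na(c2n) && c1n != c2n)
        stop("SMILES parse error: conflicting ring-closure bonds for ring ",
             key)
      if (is.na(use)) use <- 0L
      if (use == 6L) {
        bonds[[length(bonds) + 1L]] <<- c(open$atom, prev, 6L)
      } else if (use == -6L) {
        bonds[[length(bonds) + 1L]] <<- c(prev, open$atom, 6L)
      } else {
        bonds[[length(bonds) + 1L]] <<- c(open$atom, prev, use)
      }
    }
  }

  while (i <= nc) {
    ch <- substring(s, i, i)
    two <- substring(s, i, i + 1L)
    if (ch == " ") { i <- i + 1L; next }
    if (two == "->") { pendingBond <- list(code = 6L); i <- i + 2L; next }
    if (two == "<-") { pendingBond <- list(code = 7L); i <- i + 2L; next }
    if (ch == "-") { pendingBond <- list(code = 1L); i <- i + 1L; next }
    if (ch == "=") { pendingBond <- list(code = 2L); i <- i + 1L; next }
    if (ch == "#") { pendingBond <- list(code = 3L); i <- i + 1L; next }
    if (ch == ":") { pendingBond <- list(code = 5L); i <- i + 1L; next }
    if (ch == "/" || ch == "\\") { pendingBond <- list(code = 1L); i <- i + 1L; next }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("SMILES parse error: unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") { prev <- NA_integer_; pendingBond <- NULL; i <- i + 1L; next }
    if (ch == "%") {
      digit <- substring(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", digit))
        stop("SMILES parse error: bad %nn ring closure at position ", i)
      closeRing(as.integer(digit))
      i <- i + 3L; next
    }
    if (grepl("^[0-9]$", ch)) {
      closeRing(as.integer(ch))
      i <- i + 1L; next
    }
    if (ch == "[") {
      end <- regexpr("]", substring(s, i + 1L), fixed = TRUE)
      if (end < 0) stop("SMILES parse error: unterminated bracket atom")
      body <- substring(s, i + 1L, i + end - 1L)
      addAtom(.parseBracket(body))
      i <- i + end + 1L
      next
    }
    if (two %in% c("Cl", "Br")) {
      addAtom(list(el = two, aromatic = FALSE, hCount = NA_integer_,
                   charge = 0L, explicitH = FALSE))
      i <- i + 2L; next
    }
    if (grepl("^[A-Z]$", ch)) {
      if (!ch %in% .ORGANIC_SUBSET)
        stop("SMILES parse error: element ", sQuote(ch),
             " must be bracketed")
      addAtom(list(el = ch, aromatic = FALSE, hCount = NA_integer_,
                   charge = 0L, explicitH = FALSE))
      i <- i + 1L; next
    }
    if (ch %in% .AROMATIC_ORGANIC) {
      addAtom(list(el = toupper(ch), aromatic = TRUE, hCount = NA_integer_,
                   charge = 0L, explicitH = FALSE))
      i <- i + 1L; next
    }
    stop("SMILES parse error: unexpected character ", sQuote(ch),
         " at position ", i)
  }
  if (length(ringMap)) {
    stillOpen <- names(ringMap)[!vapply(ringMap, is.null, TRUE)]
    if (length(stillOpen))
      stop("SMILES parse error: unclosed ring bond(s) ",
           paste(stillOpen, collapse = ", "))
  }
  if (length(stack)) stop("SMILES parse error: unbalanced '('")
  list(atoms = atoms, bonds = bonds)
}

# Kekulize: decide double-bond placement on the aromatic subgraph via
# backtracking matching. Atoms are classified as needing a double bond
# (TRUE), not taking one (FALSE), or optional (metal-bonded aromatic N/P,
# which may be pyridine- or pyrrolide-like).
.kekulize <- function(elements, charges, aromatic, hCount, bondTriples,
                      metal) {
  n <- length(elements)
  aromEdges <- list()
  sigma <- integer(n)        # non-metal sigma partners
  metalBonded <- logical(n)  # any bond (covalent or dative) to a metal
  hasMultiple <- logical(n)  # carries an explicit double/triple bond
  for (b in bondTriples) {
    i <- b[1]; j <- b[2]; code <- b[3]
    isArom <- code == 5L || (code == 0L && aromatic[i] && aromatic[j])
    if (code == 6L || metal[i] || metal[j]) {
      # metal sigma bonds (and all dative bonds) never constrain the ring
      # system: the aromatic type of a metal-bonded N is decided by the
      # matching itself (pyridine-like vs pyrrolide-like)
      if (metal[j]) metalBonded[i] <- TRUE
      if (metal[i]) metalBonded[j] <- TRUE
      next
    }
    if (isArom) {
      aromEdges[[length(aromEdges) + 1L]] <- c(i, j)
      sigma[i] <- sigma[i] + 1L
      sigma[j] <- sigma[j] + 1L
    } else {
      sigma[i] <- sigma[i] + 1L
      sigma[j] <- sigma[j] + 1L
      if (code >= 2L && code <= 3L) {
        hasMultiple[i] <- TRUE
        hasMultiple[j] <- TRUE
      }
    }
  }
  sigmaH <- sigma + ifelse(is.na(hCount), 0L, hCount)

  needs <- rep(NA, n)  # TRUE / FALSE / NA = optional
  for (a in which(aromatic)) {
    el <- elements[a]; q <- charges[a]
    tot <- sigmaH[a]
    needs[a] <- if (hasMultiple[a]) FALSE else switch(el,
      C = if (q != 0L) FALSE else if (tot >= 4L) FALSE else TRUE,
      N = , P = {
        if (q < 0L) FALSE
        else if (q > 0L) (tot <= 3L)
        else if (tot >= 3L) FALSE
        else if (metalBonded[a]) NA       # pyridine- or pyrrolide-like
        else if (is.na(hCount[a]) && tot == 2L) NA  # n: pyridine or pyrrole-NH
        else TRUE
      },
      O = , S = , Se = FALSE,
      B = FALSE,
      FALSE)
  }

  need <- which(aromatic & !is.na(needs) & unlist(needs))
  optional <- which(aromatic & is.na(needs))
  adj <- vector("list", n)
  for (e in aromEdges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  matched <- rep(NA_integer_, n)
  allowed <- function(a) a %in% need || a %in% optional
  target <- need[order(need)]
  assign1 <- function(k) {
    if (k > length(target)) return(TRUE)
    a <- target[k]
    if (!is.na(matched[a])) return(assign1(k + 1L))
    for (b in adj[[a]]) {
      if (!allowed(b) || !is.na(matched[b])) next
      matched[a] <<- b; matched[b] <<- a
      if (assign1(k + 1L)) return(TRUE)
      matched[a] <<- NA_integer_; matched[b] <<- NA_integer_
    }
    FALSE
  }
  if (!assign1(1L))
    stop("kekulization failure: no alternating bond assignment exists")
  list(matched = matched, aromEdges = aromEdges, sigmaH = sigmaH,
       metalBonded = metalBonded)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds a \linkS4class{MolGraph} with explicit hydrogens materialized:
#' implicit hydrogen counts are inferred for organic-subset atoms from
#' their default valences after kekulization, and bracket atoms use their
#' explicit H counts. Aromatic (lowercase) input is kekulized on read;
#' dative bonds are read from the directional \code{->} / \code{<-} tokens
#' and recorded with the non-metal end as donor.
#'
#' @param s a SMILES string.
#' @param kekulize logical; when FALSE aromatic bonds cause an error (used
#'   internally by the fixer which manages kekulization itself).
#' @return a \linkS4class{MolGraph}.
#' @examples
#' m <- parseSmiles("c1ccncc1")
#' sum(m@elements == "H")
#' @export
parseSmiles <- function(s, kekulize = TRUE) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("SMILES parse error: input must be one nonempty string")
  raw <- .parseSmilesGraph(s)
  atoms <- raw$atoms
  n <- length(atoms)
  elements <- vapply(atoms, `[[`, "", "el")
  charges <- vapply(atoms, function(a) as.integer(a$charge), 0L)
  aromatic <- vapply(atoms, `[[`, FALSE, "aromatic")
  hCount <- vapply(atoms, function(a) as.integer(a$hCount), 0L)
  explicitH <- vapply(atoms, `[[`, FALSE, "explicitH")
  metal <- isDBlock(elements)

  kek <- .kekulize(elements, charges, aromatic, hCount, raw$bonds, metal)

  bonds <- matrix(0L, n, n)
  dative <- matrix(FALSE, n, n)
  for (b in raw$bonds) {
    i <- b[1]; j <- b[2]; code <- b[3]
    if (code == 6L) {
      bonds[i, j] <- bonds[j, i] <- 1L
      dative[i, j] <- dative[j, i] <- TRUE
    } else if (code == 5L || (code == 0L && aromatic[i] && aromatic[j])) {
      ord <- if (!is.na(kek$matched[i]) && kek$matched[i] == j) 2L else 1L
      bonds[i, j] <- bonds[j, i] <- ord
    } else {
      ord <- if (code == 0L) 1L else code
      bonds[i, j] <- bonds[j, i] <- ord
    }
  }

  # implicit hydrogens for organic-subset atoms
  for (a in seq_len(n)) {
    if (explicitH[a]) next
    if (metal[a]) { hCount[a] <- 0L; next }
    v <- 0L
    for (j in which(bonds[a, ] > 0L)) if (!dative[a, j]) v <- v + bonds[a, j]
    if (aromatic[a] && elements[a] %in% c("N", "P") && charges[a] == 0L &&
        is.na(kek$matched[a])[1]) {
      # pyrrole-type nitrogen: lone pair in the ring
      hCount[a] <- if (kek$metalBonded[a] || v >= 3L) 0L else max(0L, 3L - v)
    } else {
      imp <- .impliedH(elements[a], v)
      hCount[a] <- if (is.na(imp)) 0L else imp
    }
  }
  hCount[is.na(hCount)] <- 0L

  # materialize hydrogens
  nH <- sum(hCount)
  total <- n + nH
  bonds2 <- matrix(0L, total, total)
  dative2 <- matrix(FALSE, total, total)
  bonds2[seq_len(n), seq_len(n)] <- bonds
  dative2[seq_len(n), seq_len(n)] <- dative
  elements2 <- c(elements, rep("H", nH))
  charges2 <- c(charges, rep(0L, nH))
  k <- n
  for (a in seq_len(n)) {
    if (hCount[a] > 0L) for (x in seq_len(hCount[a])) {
      k <- k + 1L
      bonds2[a, k] <- bonds2[k, a] <- 1L
    }
  }
  new("MolGraph", elements = elements2, bonds = bonds2, dative = dative2,
      charges = charges2, coords = matrix(numeric(), 0, 3))
}
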