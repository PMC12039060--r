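# Canonical SMILES emission.
#
# Atom ordering comes from igraph::canonical_permutation (BLISS) on an
# augmented colored graph: real atoms colored by (element, charge, implicit
# H count), plus one dummy vertex per bond colored by bond type (single /
# double / triple / dative), which encodes edge colors in a vertex-colored
# canonization. The canonical labeling is invariant under atom reordering,
# so the emitted string is a true canonical form. Bonds are written in
# Kekulé form (no lowercase aromatic output); dative bonds use the
# directional `->` / `<-` tokens with the ligand atom as donor.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.defaultValences <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)

# Implicit H count inferred for an unbracketed atom: fill up to the
# element's default valence; atoms already at or above it get none (so
# hypervalent atoms written without brackets gain no hydrogens, mirroring
# the common toolkit behavior the fixer's hypervalence rules rely on).
.impliedH <- function(el, valence) {
  dv <- unname(.defaultValences[el])
  if (is.na(dv)) return(NA_integer_)
  max(0L, dv - as.integer(valence))
}

# Collapse plain hydrogens (one heavy neighbor, single covalent bond, no
# charge) into implicit counts. Returns list(keep, nH, map) where map[i]
# gives the reduced index of kept atom i.
.collapseHydrogens <- function(m) {
  n <- length(m@elements)
  nbCount <- rowSums(m@bonds > 0L)
  collapse <- logical(n)
  nH <- integer(n)
  for (i in seq_len(n)) {
    if (m@elements[i] != "H" || m@charges[i] != 0L) next
    nb <- which(m@bonds[i, ] > 0L)
    if (length(nb) != 1L) next
    j <- nb
    if (m@elements[j] == "H" || isDBlock(m@elements[j])) next
    if (m@bonds[i, j] != 1L || m@dative[i, j]) next
    collapse[i] <- TRUE
    nH[j] <- nH[j] + 1L
  }
  keep <- which(!collapse)
  map <- integer(n); map[keep] <- seq_along(keep)
  list(keep = keep, nH = nH[keep], map = map)
}

# canonical ranks of the reduced atoms (1 = first in canonical order)
.canonicalRanks <- function(elements, charges, nH, bonds, dative) {
  n <- length(elements)
  if (n == 1L) return(1L)
  atomKey <- paste(elements, charges, nH, sep = "|")
  atomColor <- as.integer(factor(atomKey, levels = sort(unique(atomKey), method = "radix")))
  edges <- which(upper.tri(bonds) & bonds > 0L, arr.ind = TRUE)
  nE <- nrow(edges)
  bondCode <- integer(nE)
  for (k in seq_len(nE)) {
    bondCode[k] <- if (dative[edges[k, 1], edges[k, 2]]) 4L
                   else bonds[edges[k, 1], edges[k, 2]]
  }
  nColors <- max(atomColor)
  el <- integer(0)
  for (k in seq_len(nE))
    el <- c(el, edges[k, 1], n + k, n + k, edges[k, 2])
  g <- igraph::make_empty_graph(n = n + nE, directed = FALSE)
  if (length(el)) g <- igraph::add_edges(g, el)
  colors <- c(atomColor, nColors + bondCode)
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  # labeling maps vertex -> canonical label; rank real atoms by label
  as.integer(rank(perm[seq_len(n)]))
}

.chargeToken <- function(q) {
  if (q == 0L) ""
  else if (q == 1L) "+"
  else if (q == -1L) "-"
  else if (q > 1L) paste0("+", q)
  else paste0("-", abs(q))
}

.atomToken <- function(el, charge, nH, valence, metal) {
  if (!metal && charge == 0L && el %in% .ORGANIC_SUBSET) {
    implied <- .impliedH(el, valence)
    if (!is.na(implied) && implied == nH) return(el)
  }
  hPart <- if (nH == 1L) "H" else if (nH > 1L) paste0("H", nH) else ""
  paste0("[", el, hPart, .chargeToken(charge), "]")
}

.bondToken <- function(order, dat, fromDonor) {
  if (dat) return(if (fromDonor) "->" else "<-")
  switch(order, "", "=", "#")
}

#' Canonical SMILES of a molecular graph
#'
#' Emits a canonical Kekulé SMILES with explicit charges and directional
#' dative-bond tokens (`->` pointing from the ligand donor atom to the
#' metal). Hydrogens with a single plain bond to a heavy atom are folded
#' into implicit counts; all other atoms are written bracketed when their
#' implicit-hydrogen or charge state requires it. Parsing the output and
#' re-canonicalizing reproduces the same string.
#'
#' @param m a \linkS4class{MolGraph} (or subclass).
#' @return a single SMILES string.
#' @examples
#' m <- parseSmiles("O=C=O")
#' canonicalSmiles(m)
#' @export
canonicalSmiles <- function(m) {
  col <- .collapseHydrogens(m)
  keep <- col$keep
  elements <- m@elements[keep]
  charges <- m@charges[keep]
  bonds <- m@bonds[keep, keep, drop = FALSE]
  dative <- m@dative[keep, keep, drop = FALSE]
  nH <- col$nH
  n <- length(elements)
  if (n == 0L) return("")
  metal <- isDBlock(elements)
  ranks <- .canonicalRanks(elements, charges, nH, bonds, dative)

  # valence for implicit-H bookkeeping: covalent orders; a donor's dative
  # bond does not count toward its valence
  valence <- integer(n)
  for (i in seq_len(n)) {
    nb <- which(bonds[i, ] > 0L)
    v <- 0L
    for (j in nb) {
      if (dative[i, j]) {
        if (metal[i]) v <- v + 0L   # dative bonds don't add to either side
      } else v <- v + bonds[i, j]
    }
    valence[i] <- v   # heavy-atom covalent orders; the reader infers H
  }

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(bonds > 0L, mode = "undirected")
  )$membership
  compOrder <- unique(comp[order(ranks)])

  # pass 1: spanning DFS (neighbors in canonical-rank order) collecting the
  # tree and the back (ring-closure) edges
  visited <- logical(n)
  parentOf <- rep(NA_integer_, n)
  childrenOf <- vector("list", n)
  prepos <- integer(n)          # preorder position
  counter <- 0L
  backKeys <- character(0)
  backEdges <- list()
  starts <- integer(0)

  dfs1 <- function(a) {
    visited[a] <<- TRUE
    counter <<- counter + 1L
    prepos[a] <<- counter
    nb <- which(bonds[a, ] > 0L)
    for (b in nb[order(ranks[nb])]) {
      if (!visited[b]) {
        parentOf[b] <<- a
        childrenOf[[a]] <<- c(childrenOf[[a]], b)
        dfs1(b)
      } else if (!identical(parentOf[a], b)) {
        key <- paste(min(a, b), max(a, b), sep = ",")
        if (!key %in% backKeys) {
          backKeys <<- c(backKeys, key)
          backEdges[[length(backEdges) + 1L]] <<- c(a, b)
        }
      }
    }
  }
  for (ci in compOrder) {
    atoms <- which(comp == ci)
    start <- atoms[order(ranks[atoms])][1]
    starts <- c(starts, start)
    dfs1(start)
  }

  # ring digits: assigned in order of the first endpoint's output position
  ringAt <- vector("list", n)   # per atom: list of c(digitString, partner)
  if (length(backEdges)) {
    firstPos <- vapply(backEdges, function(e) min(prepos[e]), 0L)
    secondPos <- vapply(backEdges, function(e) max(prepos[e]), 0L)
    ord <- order(firstPos, secondPos)
    for (d in seq_along(ord)) {
      e <- backEdges[[ord[d]]]
      digit <- if (d < 10L) as.character(d) else sprintf("%%%02d", d)
      for (a in e) {
        other <- e[e != a][1]
        ringAt[[a]] <- c(ringAt[[a]], list(c(digit, other)))
      }
    }
  }

  emit <- function(a) {
    token <- .atomToken(elements[a], charges[a], nH[a], valence[a], metal[a])
    ringPart <- ""
    for (rc in ringAt[[a]]) {
      b <- as.integer(rc[2])
      bt <- .bondToken(bonds[a, b], dative[a, b], fromDonor = !metal[a])
      ringPart <- paste0(ringPart, bt, rc[1])
    }
    kids <- childrenOf[[a]]
    subParts <- vapply(kids, function(b)
      paste0(.bondToken(bonds[a, b], dative[a, b], fromDonor = !metal[a]),
             emit(b)), "")
    body <- ""
    if (length(subParts) > 1L)
      body <- paste0(paste0("(", subParts[-length(subParts)], ")",
                            collapse = ""), subParts[length(subParts)])
    else if (length(subParts) == 1L) body <- subParts
    paste0(token, ringPart, body)
  }

  paste(vapply(starts, emit, ""), collapse = ".")
}
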