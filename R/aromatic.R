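# Aromaticity perception: a deliberately simple Hueckel 4n+2 model over the
# smallest rings of the molecular graph. It is used for two things only --
# sizing aromatic systems when scoring resonance forms, and lowercasing
# atoms in coordination-environment strings -- so a robust approximation is
# preferred over a full aromaticity engine. Dative bonds and metals are
# ignored throughout.

# smallest rings: for every non-bridge edge, the shortest cycle through it
# (computed by shortest path between its endpoints with the edge removed);
# deduplicated. Ring size capped at 8.
.smallestRings <- function(bonds) {
  n <- nrow(bonds)
  adj <- bonds > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  rings <- list()
  seen <- character()
  if (nrow(edges) == 0L) return(rings)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, i, j)$vpath[[1]])
    if (length(sp) < 2L || length(sp) > 7L) next
    ring <- sort(as.integer(sp))
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- as.integer(sp)
    }
  }
  rings
}

# Per-atom pi-electron contribution inside a candidate ring, or NA when the
# atom cannot take part in a conjugated ring. `carbene` marks neutral
# divalent carbons whose lone pair is in-plane (contributes 0).
.piContribution <- function(el, charge, bondOrders, degree, inCarbene) {
  hasMultiple <- any(bondOrders > 1L)
  if (hasMultiple) return(1L)
  # a neutral divalent carbon is a carbene whether or not it was flagged:
  # its lone pair lies in the ring plane and contributes no pi electrons
  if (inCarbene || (el == "C" && charge == 0L && degree == 2L)) return(0L)
  V <- .valenceElectrons[[el]]
  if (is.null(V) || is.na(V)) return(NA_integer_)
  nonbonding <- V - charge - sum(bondOrders)
  if (nonbonding >= 2L && degree <= 3L) return(2L)
  # empty p orbital (e.g. tropylium carbon)
  if (charge > 0L && degree <= 3L) return(0L)
  NA_integer_
}

#' Aromatic atoms of a molecular graph
#'
#' Flags every atom belonging to at least one ring that satisfies the
#' package's Hueckel model: all ring atoms pi-capable (a multiple bond, a
#' usable lone pair, an empty p orbital, or a carbene center) and the ring's
#' pi-electron count equal to 4n+2. Metals and dative bonds are ignored.
#'
#' @param m a \linkS4class{MolGraph} (or subclass).
#' @param carbeneAtoms indices of neutral divalent carbons (their in-plane
#'   lone pair contributes no pi electrons).
#' @return logical vector, one flag per atom.
#' @export
aromaticAtoms <- function(m, carbeneAtoms = integer()) {
  n <- length(m@elements)
  flag <- logical(n)
  if (n < 3L) return(flag)
  bonds <- m@bonds
  bonds[m@dative] <- 0L           # dative bonds never carry pi systems here
  metal <- isDBlock(m@elements)
  bonds[metal, ] <- 0L
  bonds[, metal] <- 0L
  if (inherits(m, "LigandMol") && length(m@carbeneAtoms))
    carbeneAtoms <- union(carbeneAtoms, m@carbeneAtoms)
  .aromaticFromRings(m@elements, m@charges, bonds, .smallestRings(bonds),
                     carbeneAtoms)
}

# core flagging given precomputed rings (ring perception depends only on
# connectivity, so candidates sharing a skeleton can share rings)
.aromaticFromRings <- function(elements, charges, bonds, rings,
                               carbeneAtoms = integer()) {
  flag <- logical(length(elements))
  for (ring in rings) {
    contrib <- vapply(ring, function(a) {
      nb <- which(bonds[a, ] > 0L)
      .piContribution(elements[a], charges[a], bonds[a, nb],
                      length(nb), a %in% carbeneAtoms)
    }, NA_integer_)
    if (anyNA(contrib)) next
    pi <- sum(contrib)
    if (pi >= 2L && (pi - 2L) %% 4L == 0L) flag[ring] <- TRUE
  }
  flag
}

#' @describeIn aromaticAtoms count of aromatic atoms.
#' @export
countAromaticAtoms <- function(m, carbeneAtoms = integer())
  sum(aromaticAtoms(m, carbeneAtoms))
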