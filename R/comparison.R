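# Three-level SMILES agreement and descriptor profiles.
#
# Level 1 (direct): canonical-string equality.
# Level 2 (resonance_tmc): the two complexes share a resonance form --
#   equivalent to isomorphism of the bond-order-erased complex graphs with
#   every atom annotated by its fragment's total charge (the resonance set
#   of a fragment at fixed connectivity and charge is exactly the set of
#   Lewis solutions, so two sets intersect iff connectivity and charge
#   match), with dative topology and the metal oxidation state preserved.
# Level 3 (disconnect_resonance): after deleting all metal-ligand bonds,
#   the ligand multisets match (same skeletons, same charges) and the metal
#   and its oxidation state match.

# canonical key of a vertex-colored, edge-coded graph via BLISS
.canonicalGraphKey <- function(colors, edgeMat) {
  n <- length(colors)
  if (n == 0L) return("")
  colorIds <- as.integer(factor(colors,
    levels = sort(unique(colors), method = "radix")))
  edges <- which(upper.tri(edgeMat) & edgeMat > 0L, arr.ind = TRUE)
  nE <- nrow(edges)
  el <- integer(0)
  codes <- integer(nE)
  for (k in seq_len(nE)) {
    el <- c(el, edges[k, 1], n + k, n + k, edges[k, 2])
    codes[k] <- edgeMat[edges[k, 1], edges[k, 2]]
  }
  g <- igraph::make_empty_graph(n = n + nE, directed = FALSE)
  if (length(el)) g <- igraph::add_edges(g, el)
  lab <- igraph::canonical_permutation(
    g, colors = c(colorIds, max(colorIds) + codes))$labeling
  perm <- order(order(lab[seq_len(n)]))   # canonical rank per vertex
  vPart <- paste(colors[order(perm)], collapse = ";")
  if (nE) {
    ep <- cbind(perm[edges[, 1]], perm[edges[, 2]], codes)
    ep[, 1:2] <- t(apply(ep[, 1:2, drop = FALSE], 1, sort))
    ep <- ep[order(ep[, 1], ep[, 2], ep[, 3]), , drop = FALSE]
    ePart <- paste(apply(ep, 1, paste, collapse = "-"), collapse = ";")
  } else ePart <- ""
  paste(vPart, ePart, sep = "||")
}

.requireOneMetal <- function(m, side) {
  mi <- which(isDBlock(m@elements))
  if (length(mi) != 1L)
    stop("SMILES ", side, " is not a mononuclear complex (",
         length(mi), " d-block atoms)")
  mi
}

# per-atom fragment charges + fragment partition of a parsed complex
.fragmentInfo <- function(m) {
  mi <- which(isDBlock(m@elements))[1]
  n <- length(m@elements)
  keep <- setdiff(seq_len(n), mi)
  frs <- list()
  if (length(keep)) {
    sub <- (m@bonds[keep, keep, drop = FALSE] > 0L) * 1L
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    memb <- igraph::components(g)$membership
    frs <- lapply(split(seq_along(keep), memb), function(loc) keep[loc])
  }
  fragQ <- integer(n)
  for (idx in frs) fragQ[idx] <- sum(m@charges[idx])
  fragQ[mi] <- m@charges[mi]
  list(metalIndex = mi, fragments = frs, fragQ = fragQ)
}

.levelKey <- function(m, level) {
  info <- .fragmentInfo(m)
  mi <- info$metalIndex
  n <- length(m@elements)
  if (level == "resonance_tmc") {
    edgeMat <- matrix(0L, n, n)
    edgeMat[m@bonds > 0L] <- 1L
    edgeMat[m@dative] <- 2L
    colors <- paste(m@elements, info$fragQ, sep = "/")
    .canonicalGraphKey(colors, edgeMat)
  } else if (level == "disconnect_resonance") {
    fragKeys <- vapply(info$fragments, function(idx) {
      sub <- m@bonds[idx, idx, drop = FALSE]
      edgeMat <- matrix(0L, length(idx), length(idx))
      edgeMat[sub > 0L] <- 1L
      paste0(.canonicalGraphKey(m@elements[idx], edgeMat),
             "@q=", sum(m@charges[idx]))
    }, "")
    paste(m@elements[mi], m@charges[mi],
          paste(sort(fragKeys, method = "radix"), collapse = "&"), sep = "|")
  } else stop("unknown level ", level)
}

#' Compare two complex SMILES at the three agreement levels
#'
#' \code{direct} compares canonical strings; \code{resonance_tmc} compares
#' the complexes' resonance-form sets (two resonance forms of the same
#' complex are equal at this level); \code{disconnect_resonance} compares
#' the per-ligand resonance sets after deleting all metal-ligand bonds,
#' requiring the same ligand multiset, the same ligand charges and the same
#' metal oxidation state. Equality is monotone across the levels in that
#' order. The comparison is symmetric in its arguments.
#'
#' @param s1,s2 SMILES strings of mononuclear complexes.
#' @param level one of "direct", "resonance_tmc", "disconnect_resonance" or
#'   "all".
#' @return a data.frame with columns \code{level}, \code{equal},
#'   \code{detail}.
#' @examples
#' a <- "[Cu+2](<-[NH3])<-[NH3]"
#' compareSmiles(a, a)$equal
#' @export
compareSmiles <- function(s1, s2, level = "all") {
  levels <- c("direct", "resonance_tmc", "disconnect_resonance")
  want <- if (identical(level, "all")) levels else match.arg(level, levels)
  m1 <- tryCatch(parseSmiles(s1), error = function(e)
    stop("left SMILES failed to parse: ", conditionMessage(e)))
  m2 <- tryCatch(parseSmiles(s2), error = function(e)
    stop("right SMILES failed to parse: ", conditionMessage(e)))
  .requireOneMetal(m1, "left"); .requireOneMetal(m2, "right")

  out <- data.frame(level = character(), equal = logical(),
                    detail = character())
  canon1 <- canonicalSmiles(m1); canon2 <- canonicalSmiles(m2)
  for (lv in want) {
    if (lv == "direct") {
      eq <- canon1 == canon2
      detail <- if (eq) "identical canonical SMILES" else
        "canonical SMILES differ"
    } else {
      k1 <- .levelKey(m1, lv); k2 <- .levelKey(m2, lv)
      eq <- k1 == k2
      detail <- if (eq) {
        if (canon1 == canon2) "identical canonical SMILES"
        else if (lv == "resonance_tmc") "resonance forms of the same complex"
        else "same ligand set, charges and oxidation state"
      } else {
        if (lv == "resonance_tmc")
          "connectivity, ligand charges or oxidation state differ"
        else "ligand multiset, charges or oxidation state differ"
      }
    }
    out <- rbind(out, data.frame(level = lv, equal = eq, detail = detail))
  }
  out
}

#' Oxidation-state profile of a SMILES set
#'
#' Reads the metal formal charge (the oxidation state under the dative
#' convention) from every SMILES and tabulates the counts per integer
#' value. Values below 0 or above 10 are marked unusual.
#'
#' @param smiles character vector of complex SMILES.
#' @return a data.frame with columns \code{oxidationState}, \code{count},
#'   \code{unusual}, sorted by oxidation state.
#' @export
oxidationStateProfile <- function(smiles) {
  if (!length(smiles))
    return(data.frame(oxidationState = integer(), count = integer(),
                      unusual = logical()))
  ox <- vapply(smiles, function(s) {
    m <- parseSmiles(s)
    mi <- .requireOneMetal(m, "input")
    m@charges[mi]
  }, 0L, USE.NAMES = FALSE)
  tab <- table(ox)
  vals <- as.integer(names(tab))
  data.frame(oxidationState = vals, count = as.integer(tab),
             unusual = vals < 0L | vals > 10L)
}

#' Coordination-environment strings of a SMILES set
#'
#' For every metal-coordinating atom, emits \code{X(y,z,...)}: the
#' coordinating element first, then its heavy-atom neighbors (metal
#' excluded) sorted; lowercase marks aromatic atoms. Monatomic ligands give
#' a bare symbol. Returns counts sorted descending.
#'
#' @param smiles character vector of complex SMILES.
#' @return a data.frame with columns \code{environment} and \code{count}.
#' @export
coordinationEnvironments <- function(smiles) {
  envs <- character(0)
  for (s in smiles) {
    m <- parseSmiles(s)
    mi <- .requireOneMetal(m, "input")
    arom <- aromaticAtoms(m)
    sym <- function(a) if (arom[a]) tolower(m@elements[a]) else m@elements[a]
    coordAtoms <- which(m@bonds[, mi] > 0L)
    for (a in coordAtoms) {
      nb <- setdiff(which(m@bonds[a, ] > 0L), mi)
      nb <- nb[m@elements[nb] != "H"]
      # the coordinating atom itself is always uppercase; lowercase marks
      # aromaticity of the neighbor labels
      envs <- c(envs, if (!length(nb)) m@elements[a] else
        paste0(m@elements[a], "(",
               paste(sort(vapply(nb, sym, ""), method = "radix"),
                     collapse = ","), ")"))
    }
  }
  if (!length(envs))
    return(data.frame(environment = character(), count = integer()))
  tab <- table(envs)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  data.frame(environment = names(tab)[ord], count = as.integer(tab)[ord],
             row.names = NULL)
}
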