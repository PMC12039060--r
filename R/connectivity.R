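#' Perceive connectivity from interatomic distances
#'
#' Two atoms are bonded when their distance is shorter than the sum of their
#' covalent radii plus a tolerance (default 0.45 Angstrom). Geometry is never
#' rejected here; impossible valences are handled downstream.
#'
#' @param s an \linkS4class{XYZStructure}.
#' @param config pipeline configuration; \code{config$tolerance} is the
#'   distance tolerance in Angstrom.
#' @return an \linkS4class{AdjacencyMatrix} with an empty cut log.
#' @examples
#' s <- parseXYZ("2\n\nC 0 0 0\nC 1.5 0 0")
#' adjacency(buildAdjacency(s))
#' @export
buildAdjacency <- function(s, config = tmcConfig()) {
  n <- atomCount(s)
  d <- as.matrix(stats::dist(s@coords))
  r <- .covalentRadii[s@elements]
  thr <- outer(r, r, `+`) + config$tolerance
  ac <- matrix(0L, n, n)
  ac[d < thr] <- 1L
  diag(ac) <- 0L
  dimnames(ac) <- NULL
  new("AdjacencyMatrix", ac = ac)
}

# distance and relative-length helpers over a structure
.distMat <- function(s) as.matrix(stats::dist(s@coords))

.relLength <- function(s, i, j, d = NULL) {
  if (is.null(d)) d <- sqrt(sum((s@coords[i, ] - s@coords[j, ])^2))
  d / (.covalentRadii[[s@elements[i]]] + .covalentRadii[[s@elements[j]]])
}

#' Enforce per-element valence limits on a perceived connectivity
#'
#' The distance criterion can over-connect (five bonds to carbon, bridging
#' hydrides). For every non-metal atom whose neighbor count exceeds its
#' element's maximum, the weakest bond -- the longest relative to the sum of
#' covalent radii -- is cut, one bond per violating atom per pass, until the
#' limits hold. Atoms with more violations are processed first; ties break by
#' relative length then atom index. Metals are exempt. Every cut is recorded
#' in the cut log with its relative length.
#'
#' @param am an \linkS4class{AdjacencyMatrix} from \code{\link{buildAdjacency}}.
#' @param s the parent \linkS4class{XYZStructure}.
#' @param config pipeline configuration (\code{maxValence} table).
#' @return the trimmed \linkS4class{AdjacencyMatrix} with an updated cut log.
#' @export
enforceValenceLimits <- function(am, s, config = tmcConfig()) {
  ac <- am@ac
  log <- am@cutLog
  d <- .distMat(s)
  r <- .covalentRadii[s@elements]
  rel <- d / outer(r, r, `+`)
  metal <- isDBlock(s@elements)
  limit <- .maxValenceFor(s@elements, config)
  repeat {
    deg <- rowSums(ac)
    excess <- deg - limit
    excess[metal] <- 0L
    if (all(excess <= 0)) break
    viol <- which(excess > 0)
    # worst violator first; tie-break by its longest relative bond, then index
    worstRel <- vapply(viol, function(i) max(rel[i, ac[i, ] == 1L]), 0)
    ord <- order(-excess[viol], -worstRel, viol)
    for (i in viol[ord]) {
      if (sum(ac[i, ]) <= limit[i]) next  # fixed by an earlier cut this pass
      nb <- which(ac[i, ] == 1L)
      pick <- nb[order(-rel[i, nb], nb)][1]
      ac[i, pick] <- ac[pick, i] <- 0L
      log <- rbind(log, data.frame(i = min(i, pick), j = max(i, pick),
                                   reason = "valence",
                                   relLength = rel[i, pick]))
      .tmcLog("cut_bond", i = i, j = pick, reason = "valence",
              relLength = rel[i, pick], config = config)
    }
  }
  new("AdjacencyMatrix", ac = ac, cutLog = log)
}

#' Prune spuriously perceived haptic bonds
#'
#' Within every patch of metal-coordinating atoms that are also mutually
#' bonded (a perceived haptic unit), a metal bond is cut when its metal
#' distance exceeds \code{ratioCutoff} times the shortest metal distance in
#' the patch. A genuine eta-bonded ring (all metal distances similar)
#' survives; a neighbor of a coordinating atom dragged in by the distance
#' tolerance is released. The shortest bond of a patch is never cut.
#'
#' @param am an \linkS4class{AdjacencyMatrix}.
#' @param s the parent \linkS4class{XYZStructure}.
#' @param metalIndex index of the (single) transition-metal atom.
#' @param config pipeline configuration (\code{hapticRatioCutoff}).
#' @return the pruned \linkS4class{AdjacencyMatrix}.
#' @export
pruneFakeHaptic <- function(am, s, metalIndex, config = tmcConfig()) {
  ac <- am@ac
  log <- am@cutLog
  coord <- which(ac[metalIndex, ] == 1L)
  coord <- coord[!isDBlock(s@elements[coord])]
  if (length(coord) < 2L) return(am)
  sub <- ac[coord, coord, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(g)$membership
  dM <- sqrt(colSums((t(s@coords[coord, , drop = FALSE]) -
                        s@coords[metalIndex, ])^2))
  for (patch in split(seq_along(coord), comp)) {
    if (length(patch) < 2L) next
    dmin <- min(dM[patch])
    for (k in patch) {
      if (dM[k] > config$hapticRatioCutoff * dmin) {
        a <- coord[k]
        ac[a, metalIndex] <- ac[metalIndex, a] <- 0L
        log <- rbind(log, data.frame(i = min(a, metalIndex),
                                     j = max(a, metalIndex),
                                     reason = "fake_haptic",
                                     relLength = dM[k] / dmin))
        .tmcLog("cut_bond", i = a, j = metalIndex, reason = "fake_haptic",
                ratio = dM[k] / dmin, config = config)
      }
    }
  }
  new("AdjacencyMatrix", ac = ac, cutLog = log)
}

#' Split a complex into its metal and ligand fragments
#'
#' Deletes the single d-block atom from the connectivity and returns the
#' connected components as \linkS4class{LigandFragment}s, each carrying the
#' fragment-local indices of its metal-coordinating atoms. Fragments with no
#' metal bond are flagged as counter-ions. Fragments are ordered by their
#' smallest parent atom index.
#'
#' @param am an \linkS4class{AdjacencyMatrix} of the full complex.
#' @param s the parent \linkS4class{XYZStructure}.
#' @return a list with components \code{metalIndex} (integer) and
#'   \code{fragments} (list of \linkS4class{LigandFragment}).
#' @export
splitLigands <- function(am, s) {
  metals <- which(isDBlock(s@elements))
  if (length(metals) != 1L)
    stop("not mononuclear: found ", length(metals), " d-block atoms")
  m <- metals
  n <- atomCount(s)
  keep <- setdiff(seq_len(n), m)
  sub <- am@ac[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  memb <- igraph::components(g)$membership
  frags <- lapply(split(seq_along(keep), memb), function(loc) {
    idx <- keep[loc]
    coordLocal <- which(am@ac[idx, m] == 1L)
    new("LigandFragment",
        atomIndices = as.integer(idx),
        elements = s@elements[idx],
        coords = s@coords[idx, , drop = FALSE],
        ac = am@ac[idx, idx, drop = FALSE],
        coordinatingAtoms = as.integer(coordLocal),
        isCounterIon = length(coordLocal) == 0L)
  })
  ord <- order(vapply(frags, function(f) min(f@atomIndices), 0L))
  list(metalIndex = m, fragments = unname(frags[ord]))
}

#' Accessors for perceived connectivity
#'
#' \code{adjacency} returns the 0/1 matrix; \code{cutLog} the removed-bond
#' log.
#'
#' @param am an \linkS4class{AdjacencyMatrix}.
#' @return matrix or data.frame respectively.
#' @export
adjacency <- function(am) am@ac

#' @rdname adjacency
#' @export
cutLog <- function(am) am@cutLog
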