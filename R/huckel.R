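# Extended Hueckel engine.
#
# Minimal valence basis of Slater-type orbitals (one s shell, one p shell per
# main-group atom), diagonal elements H_ii from the classic valence-state
# ionization potential table, off-diagonal elements from the
# Wolfsberg-Helmholz formula, overlaps computed exactly (to quadrature
# accuracy) in prolate-spheroidal coordinates. Only the ordered orbital
# energy ladder is consumed downstream, to count doubly occupied orbitals.

.BOHR_PER_ANGSTROM <- 1.8897259886

.quadEnv <- new.env(parent = emptyenv())

.quadNodes <- function() {
  if (is.null(.quadEnv$lag)) {
    .quadEnv$lag <- pracma::gaussLaguerre(48)
    .quadEnv$leg <- pracma::gaussLegendre(48, -1, 1)
  }
  list(lag = .quadEnv$lag, leg = .quadEnv$leg)
}

# Radial normalization of an STO: N r^(n-1) exp(-zeta r)
.stoNorm <- function(n, zeta) (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))

# Primitive two-center STO overlaps in the local frame where z points from
# center a to center b. `type` is one of "ss", "sp" (s on a, p_sigma on b),
# "ps", "pp_sigma", "pp_pi". R in bohr; (na, zetaA) describe the orbital on
# a, (nb, zetaB) on b.
.stoOverlap <- function(type, na, zetaA, nb, zetaB, R) {
  if (R < 1e-10) stop("two-center overlap requested at zero distance")
  qn <- .quadNodes()
  p <- R * (zetaA + zetaB) / 2
  q <- R * (zetaA - zetaB) / 2
  xi <- 1 + qn$lag$x / p
  eta <- qn$leg$x
  # outer(xi, eta) grids
  XI <- matrix(xi, length(xi), length(eta))
  ETA <- matrix(eta, length(xi), length(eta), byrow = TRUE)
  ra <- R * (XI + ETA) / 2
  rb <- R * (XI - ETA) / 2
  cosA <- (1 + XI * ETA) / (XI + ETA)
  cosB <- (XI * ETA - 1) / (XI - ETA)
  ang <- switch(type,
    ss = 1,
    sp = sqrt(3) * cosB,
    ps = sqrt(3) * cosA,
    pp_sigma = 3 * cosA * cosB,
    pp_pi = 1.5 * sqrt(pmax(1 - cosA^2, 0)) * sqrt(pmax(1 - cosB^2, 0)),
    stop("unknown overlap type ", type))
  # pp_pi carries the phi integral pi (cos^2), others 2*pi; the 1/(4*pi)
  # angular normalizations are folded into `ang` (factor 3 for p pairs,
  # sqrt(3) for s-p); the pi/2pi ratio is folded into pp_pi's 1.5 above.
  base <- ra^(na - 1) * rb^(nb - 1) * exp(-q * ETA) * (XI^2 - ETA^2)
  Fg <- ang * base
  # eta quadrature then xi (Gauss-Laguerre against exp(-p*(xi-1)))
  etaInt <- Fg %*% qn$leg$w
  xiInt <- sum(qn$lag$w * etaInt) / p * exp(-p)
  pref <- .stoNorm(na, zetaA) * .stoNorm(nb, zetaB) * (R / 2)^3 / 2
  pref * xiInt
}

# Basis bookkeeping: one row per AO with atom, l, m (0 for s; 1..3 for
# p_x, p_y, p_z), n, zeta, hii.
.ehtBasis <- function(elements) {
  rows <- list()
  for (i in seq_along(elements)) {
    par <- .ehtParams[[elements[i]]]
    if (is.null(par))
      stop("no extended Hueckel parameters for element ", elements[i])
    for (k in seq_len(nrow(par$shells))) {
      sh <- par$shells[k, ]
      if (sh$l == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          atom = i, l = 0L, m = 0L, n = sh$n, zeta = sh$zeta, hii = sh$hii)
      } else {
        for (m in 1:3)
          rows[[length(rows) + 1L]] <- data.frame(
            atom = i, l = 1L, m = m, n = sh$n, zeta = sh$zeta, hii = sh$hii)
      }
    }
  }
  do.call(rbind, rows)
}

# Full AO overlap matrix via Slater-Koster rotation of the local-frame
# primitives. coords in Angstrom.
.ehtOverlapMatrix <- function(basis, coords) {
  nb <- nrow(basis)
  S <- diag(1, nb)
  atoms <- unique(basis$atom)
  for (ai in atoms) for (bj in atoms) {
    if (bj <= ai) next
    ia <- which(basis$atom == ai)
    ib <- which(basis$atom == bj)
    v <- (coords[bj, ] - coords[ai, ]) * .BOHR_PER_ANGSTROM
    R <- sqrt(sum(v^2))
    u <- v / R
    # primitive overlaps per shell pair
    for (p1 in ia) for (p2 in ib) {
      b1 <- basis[p1, ]; b2 <- basis[p2, ]
      if (b1$l == 0L && b2$l == 0L) {
        s <- .stoOverlap("ss", b1$n, b1$zeta, b2$n, b2$zeta, R)
      } else if (b1$l == 0L && b2$l == 1L) {
        sp <- .stoOverlap("sp", b1$n, b1$zeta, b2$n, b2$zeta, R)
        s <- u[b2$m] * sp
      } else if (b1$l == 1L && b2$l == 0L) {
        ps <- .stoOverlap("ps", b1$n, b1$zeta, b2$n, b2$zeta, R)
        s <- u[b1$m] * ps
      } else {
        pps <- .stoOverlap("pp_sigma", b1$n, b1$zeta, b2$n, b2$zeta, R)
        ppp <- .stoOverlap("pp_pi", b1$n, b1$zeta, b2$n, b2$zeta, R)
        s <- u[b1$m] * u[b2$m] * (pps - ppp) + (b1$m == b2$m) * ppp
      }
      if (abs(s) < 1e-12) s <- 0
      S[p1, p2] <- S[p2, p1] <- s
    }
  }
  S
}

#' Extended Hueckel molecular orbital energies
#'
#' Computes the full molecular-orbital energy ladder (eV, ascending) of a
#' fragment with a minimal Slater basis, classic VSIP diagonal parameters
#' and the weighted Wolfsberg-Helmholz off-diagonal formula. Implemented for
#' main-group elements (the pipeline only ever runs it on metal-free ligand
#' fragments).
#'
#' @param elements character element symbols.
#' @param coords numeric matrix of Cartesian coordinates in Angstrom.
#' @param K Wolfsberg-Helmholz constant (1.75); the weighted variant
#'   \code{K + Delta^2 + Delta^4 (1 - K)} is applied per pair.
#' @return numeric vector of orbital energies in eV, ascending.
#' @examples
#' ehtOrbitalEnergies("Cl", matrix(0, 1, 3))
#' @export
ehtOrbitalEnergies <- function(elements, coords, K = 1.75) {
  basis <- .ehtBasis(elements)
  if (length(elements) == 1L) return(sort(basis$hii))
  S <- .ehtOverlapMatrix(basis, coords)
  hii <- basis$hii
  Hsum <- outer(hii, hii, `+`) / 2
  Delta <- outer(hii, hii, `-`) / outer(hii, hii, `+`)
  Kw <- K + Delta^2 + Delta^4 * (1 - K)
  H <- Kw * Hsum * S
  diag(H) <- hii
  # canonical orthogonalization
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-8
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Ht <- t(X) %*% H %*% X
  sort(eigen((Ht + t(Ht)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
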