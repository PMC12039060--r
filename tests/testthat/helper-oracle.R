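# Independent brute-force Lewis oracle: enumerates every bond-order matrix
# over the fragment's edges (orders 1..3) with only an element-wise maximum
# valence prune, then checks whether per-atom charges drawn from a literal
# state table can sum to the requested total. Shares nothing with the
# package's valence-state search.
.oracleStates <- list(
  H  = list(c(1, 0), c(0, -1)),
  B  = list(c(3, 0), c(4, -1)),
  C  = list(c(4, 0), c(3, -1), c(3, 1)),
  N  = list(c(3, 0), c(4, 1), c(2, -1), c(0, -3)),
  O  = list(c(2, 0), c(1, -1), c(3, 1), c(0, -2)),
  F  = list(c(1, 0), c(0, -1)),
  Cl = list(c(1, 0), c(0, -1)),
  Br = list(c(1, 0), c(0, -1)),
  I  = list(c(1, 0), c(0, -1)),
  Si = list(c(4, 0)),
  P  = list(c(3, 0), c(5, 0), c(4, 1)),
  S  = list(c(2, 0), c(4, 0), c(6, 0), c(1, -1), c(3, 1), c(0, -2)))

bruteForceLewisSolvable <- function(elements, ac, charge) {
  n <- length(elements)
  maxV <- vapply(elements, function(el)
    max(vapply(.oracleStates[[el]], `[`, 0, 1)), 0)
  edges <- which(upper.tri(ac) & ac == 1L, arr.ind = TRUE)
  nE <- nrow(edges)
  found <- FALSE

  chargeReachable <- function(sums) {
    # per-atom charge options for these bond-order sums
    opts <- lapply(seq_len(n), function(i) {
      qs <- vapply(Filter(function(st) st[1] == sums[i],
                          .oracleStates[[elements[i]]]),
                   `[`, 0, 2)
      unique(qs)
    })
    if (any(!lengths(opts))) return(FALSE)
    reach <- 0
    for (o in opts) reach <- unique(as.vector(outer(reach, o, `+`)))
    charge %in% reach
  }

  orders <- integer(nE)
  sums <- integer(n)
  recurse <- function(k) {
    if (found) return()
    if (k > nE) {
      if (chargeReachable(sums)) found <<- TRUE
      return()
    }
    i <- edges[k, 1]; j <- edges[k, 2]
    for (o in 1:3) {
      if (sums[i] + o > maxV[i] || sums[j] + o > maxV[j]) break
      sums[i] <<- sums[i] + o; sums[j] <<- sums[j] + o
      recurse(k + 1L)
      sums[i] <<- sums[i] - o; sums[j] <<- sums[j] - o
      if (found) return()
    }
  }
  if (nE == 0L) return(chargeReachable(sums))
  recurse(1L)
  found
}
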