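# shared, memoized end-to-end results over the fixture suite so the many
# tests that consume them pay the pipeline cost once
.suiteCache <- new.env(parent = emptyenv())

suiteResults <- function() {
  if (is.null(.suiteCache$res)) {
    .suiteCache$res <- lapply(fixtureSuite(), function(fx) {
      fx$result <- xyzToSmiles(fx$xyz, fx$charge)
      fx
    })
  }
  .suiteCache$res
}

okResults <- function() {
  Filter(function(fx) isTRUE(fx$result$ok), suiteResults())
}

# all post-split ligand fragments of the suite, with the structures they
# came from
suiteFragments <- function() {
  if (is.null(.suiteCache$frags)) {
    out <- list()
    for (fx in fixtureSuite()) {
      s <- parseXYZ(fx$xyz)
      am <- enforceValenceLimits(buildAdjacency(s), s)
      sp <- tryCatch(splitLigands(am, s), error = function(e) NULL)
      if (is.null(sp)) next
      am <- pruneFakeHaptic(am, s, sp$metalIndex)
      sp <- splitLigands(am, s)
      for (f in sp$fragments)
        out[[length(out) + 1L]] <- list(fixture = fx$name, fragment = f)
    }
    .suiteCache$frags <- out
  }
  .suiteCache$frags
}
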