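# Shared fixtures. The fixture library is generated once per test run and
# memoized (molecule parsing is the expensive step).

.fixture_memo <- new.env(parent = emptyenv())

fixture_library_memo <- function(n = 300, seed = 7) {
  key <- paste0("lib_", n, "_", seed)
  hit <- get0(key, envir = .fixture_memo)
  if (!is.null(hit)) return(hit)
  lib <- generate_fixture_library(n, seed = seed)
  assign(key, lib, envir = .fixture_memo)
  lib
}

# random fingerprints with a fixed generator, for property-style tests
random_fingerprint <- function(nbits = 256L, density = 0.1, kind = "ECFP4") {
  nbit_on <- max(1L, stats::rbinom(1L, nbits, density))
  fingerprint(sample.int(nbits, nbit_on) - 1L, kind = kind, nbits = nbits)
}

# brute-force oracles -------------------------------------------------------

# O(n^2 m) non-dominated sorting by repeated removal of the dominated-by-none
bruteforce_fronts <- function(scores) {
  n <- nrow(scores)
  remaining <- seq_len(n)
  fronts <- list()
  dominates_bf <- function(u, v) all(u >= v) && any(u > v)
  while (length(remaining)) {
    fr <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && dominates_bf(scores[j, ], scores[i, ]), TRUE))
    }, TRUE)]
    fronts[[length(fronts) + 1L]] <- fr
    remaining <- setdiff(remaining, fr)
  }
  fronts
}

# plain double-loop mean pairwise Tanimoto distance
bruteforce_crowding <- function(fps) {
  n <- length(fps)
  if (n == 1L) return(1)
  vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(j)
      tanimoto_distance(fps[[i]], fps[[j]]), 0))
  }, 0)
}

mini_population <- function(fitness) {
  # population whose geometric-mean fitness equals the given vector
  mols <- rep(list(structure(list(smiles = "C", valid = TRUE, input = "C",
                                  data = NULL), class = "molecule")),
              length(fitness))
  new_population(mols, matrix(fitness, ncol = 1L))
}
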