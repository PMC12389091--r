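# Built-in drug-like seed library generator.
#
# Removes any data-download requirement: molecules are enumerated from a
# grid of common medicinal-chemistry scaffolds crossed with substituent
# sets and methylene linker lengths, giving a seed set that spans roughly
# TPSA 0-150, logP -1-6, MW 78-500 and 0-8 rotatable bonds.

.FIXTURE_SCAFFOLDS_1 <- c(           # one substitution slot
  benzene = "c1ccc(%s)cc1",
  pyridine = "c1ccnc(%s)c1",
  pyrimidine = "c1cnc(%s)nc1",
  furan = "c1ccc(%s)o1",
  thiophene = "c1ccc(%s)s1",
  pyrrole = "c1cc[nH]c1%s",
  imidazole = "c1cnc(%s)[nH]1",
  naphthalene = "c1ccc2cc(%s)ccc2c1",
  quinoline = "c1ccc2ncc(%s)cc2c1",
  indole = "c1ccc2c(c1)cc(%s)[nH]2",
  piperidine = "C1CCN(%s)CC1",
  morpholine = "O1CCN(%s)CC1",
  pyrrolidine = "C1CCN(%s)C1",
  cyclohexane = "C1CCC(%s)CC1",
  thiazolidinedione = "O=C1NC(=O)SC1%s",
  biphenyl = "c1ccc(-c2ccc(%s)cc2)cc1",
  anisole = "COc1ccc(%s)cc1",
  benzamide = "NC(=O)c1ccc(%s)cc1"
)

.FIXTURE_SCAFFOLDS_2 <- c(           # two substitution slots
  benzene_para = "c1cc(%s)ccc1%s",
  pyridine_25 = "c1cc(%s)cnc1%s",
  piperazine = "C1CN(%s)CCN1%s",
  biphenyl_44 = "c1cc(%s)ccc1-c1ccc(%s)cc1",
  benzylbenzene = "c1cc(%s)ccc1Cc1ccc(%s)cc1",
  phenoxybenzene = "c1cc(%s)ccc1Oc1ccc(%s)cc1"
)

.FIXTURE_GROUPS <- c("C", "O", "OC", "N", "NC", "C(=O)O", "C(=O)OC", "C(=O)N",
                     "F", "Cl", "Br", "C(F)(F)F", "S(=O)(=O)N", "C#N",
                     "[N+](=O)[O-]", "OCC(=O)O")

.FIXTURE_LINKERS <- c("", "C", "CC", "CCC")

.fixture_smiles_grid <- function() {
  subs <- as.vector(outer(.FIXTURE_LINKERS, .FIXTURE_GROUPS, paste0))
  out <- character(0)
  for (sc in .FIXTURE_SCAFFOLDS_1) out <- c(out, sprintf(sc, subs))
  # two-slot scaffolds: pair each substituent with a compact second set to
  # keep the grid size moderate while reaching higher MW/TPSA
  second <- c("C", "O", "F", "C(=O)O", "S(=O)(=O)N", "C(F)(F)F", "OC", "CCO")
  for (sc in .FIXTURE_SCAFFOLDS_2)
    out <- c(out, as.vector(outer(subs, second,
                                  function(a, b) sprintf(sc, a, b))))
  # bare ring systems pad the low-MW end
  out <- c(out, "c1ccccc1", "c1ccncc1", "C1CCNCC1", "C1COCCN1", "c1ccc2ccccc2c1",
           "c1ccoc1", "c1ccsc1", "C1CCCCC1")
  unique(out)
}

#' Generate the built-in drug-like seed library
#'
#' Deterministically enumerates candidate SMILES from a scaffold x
#' substituent x linker grid, shuffles them with the given seed, truncates
#' to `n` and parses them. The caller's RNG state is left untouched.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer shuffle seed.
#' @return List of `n` valid `molecule`s.
#' @export
generate_fixture_library <- function(n, seed = 7L) {
  stopifnot(n >= 1L)
  grid <- .fixture_smiles_grid()
  if (n > length(grid))
    stop(sprintf("n = %d exceeds the enumerable fixture space (max %d)",
                 n, length(grid)), call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ord <- sample.int(length(grid))
  picked <- character(0); i <- 0L
  mols <- list()
  while (length(mols) < n && i < length(ord)) {
    # parse in chunks; drop the (rare) grid entries OpenBabel rejects
    take <- ord[(i + 1L):min(i + n - length(mols) + 16L, length(ord))]
    i <- i + length(take)
    batch <- parse_molecules(grid[take])
    batch <- batch[vapply(batch, is_valid, TRUE)]
    mols <- c(mols, batch)
  }
  if (length(mols) < n)
    stop("fixture space exhausted before reaching n valid molecules", call. = FALSE)
  mols[seq_len(n)]
}
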