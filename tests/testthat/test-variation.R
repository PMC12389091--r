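test_that("decomposition: scaffold, side chains, and edge cases", {
  fr <- decompose(parse_molecule("Cc1ccccc1"))        # toluene
  expect_equal(nrow(fr$core$atoms), 6L)               # benzene scaffold
  expect_length(fr$chains, 1L)
  expect_equal(nrow(fr$chains[[1L]]$graph$atoms), 1L) # methyl
  expect_equal(fr$chains[[1L]]$graph$atoms$elem, "C")
  fr2 <- decompose(parse_molecule("c1ccccc1"))        # bare ring: no chains
  expect_length(fr2$chains, 0L)
  fr3 <- decompose(parse_molecule("CCCCCC"))          # ring-free: all core
  expect_equal(nrow(fr3$core$atoms), 6L)
  expect_length(fr3$chains, 0L)
  # exocyclic carbonyl oxygens stay on the core
  fr4 <- decompose(parse_molecule("O=C1NC(=O)SC1"))
  expect_equal(nrow(fr4$core$atoms), 7L)
  expect_length(fr4$chains, 0L)
  # acyclic linkers between rings stay on the core
  fr5 <- decompose(parse_molecule("c1ccccc1CCc1ccncc1"))
  expect_equal(nrow(fr5$core$atoms), 14L)
  expect_error(decompose(parse_molecule("C1CC")))
})

test_that("decompose -> reassemble round-trips the canonical SMILES", {
  lib <- fixture_library_memo(120, seed = 3)
  for (m in lib) {
    r <- reassemble(decompose(m))
    expect_identical(mol_smiles(r), mol_smiles(m))
  }
})

test_that("crossover stays within the reachable recombinant set", {
  tol <- parse_molecule("Cc1ccccc1")
  etb <- parse_molecule("CCc1ccccc1")
  benzene <- mol_smiles(parse_molecule("c1ccccc1"))
  reachable <- c(benzene, mol_smiles(tol), mol_smiles(etb))
  set.seed(10)
  got <- character(0)
  for (i in 1:40) got <- c(got, mol_smiles(crossover(tol, etb)))
  expect_true(all(got %in% reachable))
  expect_gt(length(unique(got)), 1L)   # actually recombines
  # identical scaffold-only parents reproduce themselves
  b <- parse_molecule("c1ccccc1")
  expect_identical(mol_smiles(crossover(b, b)), benzene)
})

test_that("mutation adds, replaces or deletes side chains and stays valid", {
  methyl_pool <- list(molega:::.frag("C"))
  # add on benzene with a methyl-only pool can only give toluene
  set.seed(2)
  b <- parse_molecule("c1ccccc1")
  expect_identical(mol_smiles(mutate(b, methyl_pool)),
                   mol_smiles(parse_molecule("Cc1ccccc1")))
  # toluene with a methyl-only pool: delete -> benzene, replace -> toluene,
  # add -> xylenes / ethylbenzene; nothing else is reachable
  tol <- parse_molecule("Cc1ccccc1")
  reachable <- vapply(parse_molecules(c(
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1",
    "Cc1ccccc1C", "Cc1cccc(C)c1", "Cc1ccc(C)cc1")), mol_smiles, "")
  set.seed(6)
  got <- vapply(1:40, function(i) mol_smiles(mutate(tol, methyl_pool)), "")
  expect_true(all(got %in% reachable))
  expect_true(reachable[[1L]] %in% got)   # delete was exercised
})

test_that("variation operators are deterministic under a fixed seed", {
  lib <- fixture_library_memo(120, seed = 3)
  a <- lib[[5L]]; b <- lib[[17L]]
  pool <- fragment_pool(lib[1:10])
  set.seed(42); x1 <- mol_smiles(crossover(a, b)); m1 <- mol_smiles(mutate(a, pool))
  set.seed(42); x2 <- mol_smiles(crossover(a, b)); m2 <- mol_smiles(mutate(a, pool))
  expect_identical(x1, x2)
  expect_identical(m1, m2)
})

test_that("make_offspring produces the requested number of valid scored offspring", {
  task <- benchmark_task("pioglitazone")
  lib <- fixture_library_memo(120, seed = 3)
  pop <- score_population(lib[1:20], task, capacity = 20L)
  set.seed(11)
  off <- make_offspring(pop, 20L, task)
  expect_length(off, 20L)
  expect_true(all(vapply(off$molecules, is_valid, TRUE)))
  expect_true(all(off$scores >= 0 & off$scores <= 1))
  # crossover fraction 0: all offspring from mutation
  set.seed(12)
  off2 <- make_offspring(pop, 10L, task, crossover_fraction = 0)
  expect_length(off2, 10L)
  expect_error(make_offspring(pop, 0L, task))
  # seeded determinism of the whole offspring batch
  set.seed(13); s1 <- vapply(make_offspring(pop, 15L, task)$molecules, mol_smiles, "")
  set.seed(13); s2 <- vapply(make_offspring(pop, 15L, task)$molecules, mol_smiles, "")
  expect_identical(s1, s2)
})
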