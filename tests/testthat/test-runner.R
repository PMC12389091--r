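test_that("fixture library: deterministic, valid, and spans the target ranges", {
  a <- generate_fixture_library(100, seed = 7)
  b <- generate_fixture_library(100, seed = 7)
  expect_identical(vapply(a, mol_smiles, ""), vapply(b, mol_smiles, ""))
  expect_true(all(vapply(a, is_valid, TRUE)))
  lib <- fixture_library_memo(300, seed = 7)
  tpsa <- vapply(lib, compute_descriptor, 0, kind = "TPSA")
  logp <- vapply(lib, compute_descriptor, 0, kind = "logP")
  mw <- vapply(lib, compute_descriptor, 0, kind = "molecular_weight")
  rotb <- vapply(lib, compute_descriptor, 0, kind = "n_rotatable_bonds")
  expect_lt(min(tpsa), 10); expect_gt(max(tpsa), 100)
  expect_lt(min(logp), 0.5); expect_gt(max(logp), 3.5)
  expect_lt(min(mw), 110); expect_gt(max(mw), 350)
  expect_equal(min(rotb), 0); expect_gte(max(rotb), 5)
  # some member satisfies the joint TPSA/logP window of the fexofenadine task
  expect_true(any(tpsa >= 80 & tpsa <= 100 & logp >= 2 & logp <= 6))
  # exceeding the enumerable space errors and names the maximum
  expect_error(generate_fixture_library(1e6), "max")
})

test_that("fixture generation leaves the caller's RNG stream untouched", {
  set.seed(123); x1 <- stats::runif(1)
  set.seed(123); invisible(generate_fixture_library(5, seed = 9)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("SMILES library I/O round-trips and skips bad records", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene", "C1CC broken",
               "", "# comment", "CC(=O)O acetic"), path)
  expect_warning(lib <- read_smiles_library(path), "1 invalid")
  expect_length(lib, 3L)
  expect_identical(attr(lib, "n_invalid"), 1L)
  expect_identical(mol_smiles(lib[[1L]]), mol_smiles(parse_molecule("CCO")))
  out <- tempfile(fileext = ".smi")
  write_smiles(lib, out)
  lib2 <- read_smiles_library(out)
  expect_identical(vapply(lib2, mol_smiles, ""), vapply(lib, mol_smiles, ""))
  # empty file -> empty library
  empty <- tempfile(fileext = ".smi"); writeLines(character(0), empty)
  expect_length(read_smiles_library(empty), 0L)
  expect_error(read_smiles_library(tempfile()))
})

test_that("run_optimization: trace shape, generation 0, determinism, errors", {
  lib <- fixture_library_memo(120, seed = 3)
  cfg0 <- run_config(task = "pioglitazone", population_size = 10L,
                     generations = 0L, trials = 1L, seed = 5L)
  r0 <- run_optimization(cfg0, library = lib)
  expect_equal(nrow(r0$trace), 1L)
  expect_equal(r0$trace$generation, 0L)
  cfg <- run_config(task = "pioglitazone", population_size = 12L,
                    generations = 3L, trials = 2L, seed = 5L)
  r1 <- run_optimization(cfg, library = lib)
  r2 <- run_optimization(cfg, library = lib)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$final, r2$final)
  expect_equal(nrow(r1$trace), 2L * (3L + 1L))
  expect_true(all(table(r1$trace$trial) == 4L))
  # capacity is held every generation
  expect_true(all(vapply(r1$final, nrow, 0L) == 12L))
  # library smaller than the population errors
  expect_error(run_optimization(run_config(population_size = 500L, trials = 1L),
                                library = lib), "need")
})

test_that("write_results emits the documented files and schema", {
  lib <- fixture_library_memo(120, seed = 3)
  cfg <- run_config(task = "fexofenadine", population_size = 10L,
                    generations = 2L, trials = 2L, seed = 9L)
  res <- run_optimization(cfg, library = lib)
  outdir <- file.path(tempdir(), "molega_out")
  write_results(res, outdir)
  expect_true(file.exists(file.path(outdir, "config.json")))
  trace <- utils::read.csv(file.path(outdir, "trace.csv"))
  expect_identical(colnames(trace),
                   c("trial", "generation", "hv", "success_rate", "max_gm",
                     "internal_similarity", "n_valid", "n_unique", "p_a",
                     "n_fallback"))
  expect_equal(nrow(trace), 2L * 3L)   # trials * (generations + 1)
  fin <- utils::read.csv(file.path(outdir, "final_population.csv"),
                         check.names = FALSE)
  expect_true(all(c("trial", "smiles", "fitness", "rank", "crowding",
                    "success") %in% colnames(fin)))
  # the emitted .smi re-reads to the same canonical SMILES
  smi <- read_smiles_library(file.path(outdir, "final_population_trial1.smi"))
  expect_identical(vapply(smi, mol_smiles, ""), res$final[[1L]]$smiles)
  cfg_echo <- jsonlite::read_json(file.path(outdir, "config.json"))
  expect_identical(cfg_echo$task, "fexofenadine")
  expect_identical(cfg_echo$mode, "mogata")
})
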