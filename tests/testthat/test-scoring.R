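test_that("descriptor values match hand-countable cases", {
  expect_equal(compute_descriptor(parse_molecule("FC(F)(F)F"), "n_fluorine"), 4)
  expect_equal(compute_descriptor(parse_molecule("c1ccccc1"), "n_aromatic_rings"), 1)
  expect_equal(compute_descriptor(parse_molecule("CC"), "n_rotatable_bonds"), 0)
  expect_equal(compute_descriptor(parse_molecule("CCc1ccccc1"), "n_rotatable_bonds"), 1)
  expect_equal(compute_descriptor(parse_molecule("c1ccc2ccccc2c1"), "n_aromatic_rings"), 2)
  # saturated thiazolidinedione ring is not aromatic
  expect_equal(compute_descriptor(parse_molecule("O=C1NC(=O)SC1"), "n_aromatic_rings"), 0)
  expect_equal(compute_descriptor(parse_molecule("c1ccccc1"), "TPSA"), 0)
  expect_gt(compute_descriptor(parse_molecule("NS(=O)(=O)c1ccccc1"), "TPSA"), 60)
  # QED and CNS desirabilities stay in [0, 1]
  for (smi in c("c1ccccc1", "CCO", "Cc1ccc(CC2SC(=O)NC2=O)cc1")) {
    q <- compute_descriptor(parse_molecule(smi), "QED")
    cns <- compute_descriptor(parse_molecule(smi), "CNS")
    expect_gte(q, 0); expect_lte(q, 1)
    expect_gte(cns, 0); expect_lte(cns, 1)
  }
  expect_error(compute_descriptor(parse_molecule("C1CC"), "TPSA"))
})

test_that("modifier closed forms", {
  expect_equal(apply_modifier(modifier("Gaussian", 356, 10), 356), 1.0)
  expect_equal(apply_modifier(modifier("Gaussian", 0, 0.1), 0.1), exp(-0.5))
  tl <- modifier("ThresholdedLinear", 0.8)
  expect_equal(apply_modifier(tl, 0.4), 0.5)
  expect_equal(apply_modifier(tl, 0.9), 1.0)
  expect_equal(apply_modifier(modifier("MaxGaussian", 90, 10), 95), 1.0)
  expect_equal(apply_modifier(modifier("MaxGaussian", 90, 10), 80), exp(-0.5))
  expect_equal(apply_modifier(modifier("MinGaussian", 4, 2), 3), 1.0)
  expect_equal(apply_modifier(modifier("MinGaussian", 4, 2), 6), exp(-0.5))
  expect_error(modifier("ThresholdedLinear", 0))
  expect_error(modifier("Gaussian", 1, 0))
})

test_that("modifier monotonicity and range invariants", {
  xs <- seq(-5, 15, by = 0.25)
  maxg <- apply_modifier(modifier("MaxGaussian", 5, 2), xs)
  ming <- apply_modifier(modifier("MinGaussian", 5, 2), xs)
  tl <- apply_modifier(modifier("ThresholdedLinear", 5), xs)
  expect_true(all(diff(maxg) >= -1e-12))
  expect_true(all(diff(ming) <= 1e-12))
  expect_true(all(diff(tl) >= -1e-12))
  expect_true(all(tl[xs >= 5] == 1))
  for (v in list(maxg, ming, tl)) {
    expect_true(all(v >= 0 & v <= 1))
  }
  # Gaussian-family success window {x: |x-mu| <= sigma} <=> score >= exp(-1/2)
  g <- apply_modifier(modifier("Gaussian", 5, 2), xs)
  expect_identical(g >= exp(-0.5) - 1e-12, abs(xs - 5) <= 2 + 1e-9)
})

test_that("geometric mean", {
  expect_equal(geometric_mean(c(1, 1, 1)), 1.0)
  expect_equal(geometric_mean(c(0.25, 1.0)), 0.5)
  expect_equal(geometric_mean(c(0.9, 0, 0.4)), 0.0)
  expect_error(geometric_mean(numeric(0)))
})

test_that("score_molecule produces modified scores in [0,1], zeros when invalid", {
  task <- benchmark_task("fexofenadine")
  target <- parse_molecule(benchmark_targets()[["fexofenadine"]])
  s <- score_molecule(target, task, raw = TRUE)
  expect_length(s, 3L)
  expect_true(all(s >= 0 & s <= 1))
  # self-similarity 1 >= threshold 0.8 -> ThresholdedLinear score 1
  expect_equal(unname(s[1L]), 1.0)
  expect_equal(attr(s, "raw")[1L], 1.0)
  expect_equal(score_molecule(parse_molecule("C1CC"), task), rep(0, 3L))
  # pure function of the canonical SMILES
  expect_identical(score_molecule(parse_molecule("CCO"), task),
                   score_molecule(parse_molecule("OCC"), task))
})

test_that("success windows derive from modifiers and respect boundaries", {
  # a synthetic 2-objective task with known windows
  t2 <- mol_task("windows", list(
    mol_objective("tpsa", descriptor_scorer("TPSA"), modifier("MaxGaussian", 90, 10)),
    mol_objective("nf", descriptor_scorer("n_fluorine"), modifier("Gaussian", 1, 1))))
  w <- t2$objectives[[1L]]$success
  expect_equal(c(w$lo, w$hi), c(80, 100))
  expect_false(w$lo_open); expect_false(w$hi_open)
  # thresholded similarity success is raw < mu (novelty rule)
  fx <- benchmark_task("fexofenadine")
  ws <- fx$objectives[[1L]]$success
  expect_equal(ws$hi, 0.8); expect_true(ws$hi_open)
  expect_true(molega:::.in_window(0.799, ws))
  expect_false(molega:::.in_window(0.8, ws))
  # closed interval boundaries for the Gaussian family
  wt <- fx$objectives[[2L]]$success
  expect_true(molega:::.in_window(100, wt))
  expect_true(molega:::.in_window(80, wt))
  expect_false(molega:::.in_window(100.01, wt))
  # flipped thresholded rule is available
  fx2 <- benchmark_task("fexofenadine", thresholded_success = "above")
  expect_equal(fx2$objectives[[1L]]$success$lo, 0.8)
  # invalid molecules never succeed
  expect_false(as.logical(check_success(parse_molecule("C1CC"), t2)))
})

test_that("check_success evaluates raw-value windows per objective", {
  t2 <- mol_task("fluor", list(
    mol_objective("nf", descriptor_scorer("n_fluorine"), modifier("Gaussian", 1, 1)),
    mol_objective("tpsa", descriptor_scorer("TPSA"), modifier("Gaussian", 0, 60))))
  ok <- check_success(parse_molecule("Fc1ccccc1"), t2)     # nF = 1 in [0, 2]
  expect_true(as.logical(ok))
  bad <- check_success(parse_molecule("FC(F)(F)c1ccc(F)cc1"), t2)  # nF = 4
  expect_false(as.logical(bad))
  per <- attr(bad, "per_objective")
  expect_false(per[["nf"]]); expect_true(per[["tpsa"]])
})

test_that("plugin scorers and task serialization round-trip", {
  tp <- mol_task("plugin", list(
    mol_objective("const", plugin_scorer(function(mol) 0.75), NULL),
    mol_objective("tpsa", descriptor_scorer("TPSA"), modifier("MaxGaussian", 90, 10))))
  s <- score_molecule(parse_molecule("CCO"), tp)
  expect_equal(unname(s[1L]), 0.75)
  expect_error(write_task(tp, tempfile()))  # plugins are not serializable
  t1 <- benchmark_task("ranolazine")
  path <- tempfile(fileext = ".json")
  write_task(t1, path)
  t1b <- read_task(path)
  expect_equal(length(t1b$objectives), length(t1$objectives))
  m <- parse_molecule("COc1ccccc1OCC(O)CN")
  expect_equal(score_molecule(m, t1b), score_molecule(m, t1))
  expect_equal(as.logical(check_success(m, t1b)), as.logical(check_success(m, t1)))
})
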