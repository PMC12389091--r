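# Orchestration: run configuration, the optimization loop, and file I/O.

#' Run configuration
#'
#' Defaults follow the benchmark protocol: 20 trials per task, population
#' size 100, 150 generations, acceptance-probability decay beta = 0.45,
#' ECFP4 crowding fingerprints.
#'
#' @param task Task name (see [benchmark_task()]) or a `mol_task`.
#' @param population_size Population capacity N.
#' @param generations Number of generations per trial.
#' @param trials Number of independent trials.
#' @param beta Acceptance-probability decay parameter.
#' @param mode Population-update mode: `"mogata"`, `"mogat"` or `"nsga2"`.
#' @param fp_kind Fingerprint kind for crowding and internal similarity.
#' @param nbits Fingerprint folded length.
#' @param seed Base RNG seed; trial t uses `seed + t - 1`.
#' @param crossover_fraction Fraction of offspring produced by crossover.
#' @param p_bare Bare-attachment probability in crossover.
#' @param max_attempts Sanitization retries per offspring.
#' @param library `"fixtures"` (built-in generated seed library) or a path to
#'   a `.smi` file.
#' @param fixture_n Size of the generated seed library when
#'   `library = "fixtures"`.
#' @return A `run_config` list.
#' @export
run_config <- function(task = "pioglitazone",
                       population_size = 100L,
                       generations = 150L,
                       trials = 20L,
                       beta = 0.45,
                       mode = c("mogata", "mogat", "nsga2"),
                       fp_kind = "ECFP4",
                       nbits = 2048L,
                       seed = 42L,
                       crossover_fraction = 0.5,
                       p_bare = 0.2,
                       max_attempts = 10L,
                       library = "fixtures",
                       fixture_n = 600L) {
  mode <- match.arg(mode)
  fp_kind <- match.arg(fp_kind, .FP_KINDS)
  stopifnot(population_size >= 2L, generations >= 0L, trials >= 1L, beta > 0)
  structure(list(task = task, population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 trials = as.integer(trials), beta = beta, mode = mode,
                 fp_kind = fp_kind, nbits = as.integer(nbits),
                 seed = as.integer(seed),
                 crossover_fraction = crossover_fraction, p_bare = p_bare,
                 max_attempts = as.integer(max_attempts),
                 library = library, fixture_n = as.integer(fixture_n)),
            class = "run_config")
}

.resolve_task <- function(task) {
  if (inherits(task, "mol_task")) return(task)
  benchmark_task(task)
}

.resolve_library <- function(cfg) {
  if (identical(cfg$library, "fixtures"))
    generate_fixture_library(cfg$fixture_n, seed = cfg$seed)
  else read_smiles_library(cfg$library)
}

#' Run the multi-objective molecular optimization
#'
#' For each trial: seeds the RNG with `seed + trial - 1`, samples an initial
#' population from the seed library (deduplicated by canonical SMILES),
#' scores it, and then iterates offspring generation
#' ([make_offspring()]) and the elitist population update
#' ([update_population()]), recording per-generation metrics.
#'
#' @param cfg A [run_config()].
#' @param task Optional `mol_task` overriding `cfg$task`.
#' @param library Optional list of `molecule`s overriding `cfg$library`.
#' @param verbose Print a progress line per generation.
#' @return A `molega_result`: `list(config, task_name, trace, final)` where
#'   `trace` is a data.frame of per-generation metrics (all trials;
#'   generation 0 is the initial population) and `final` a list of per-trial
#'   data.frames (SMILES, scores, fitness, rank, crowding, success).
#' @export
run_optimization <- function(cfg, task = NULL, library = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  task <- if (is.null(task)) .resolve_task(cfg$task) else task
  lib <- if (is.null(library)) .resolve_library(cfg) else library
  lib <- lib[vapply(lib, is_valid, TRUE)]
  smi <- vapply(lib, mol_smiles, "")
  lib <- lib[!duplicated(smi)]
  N <- cfg$population_size
  if (length(lib) < N)
    stop(sprintf("seed library has %d unique valid molecules; need >= %d",
                 length(lib), N), call. = FALSE)
  traces <- list(); finals <- list()
  for (t in seq_len(cfg$trials)) {
    set.seed(cfg$seed + t - 1L)
    pop <- score_population(lib[sample.int(length(lib), N)], task, capacity = N)
    rows <- list(cbind(trial = t, summarize_generation(pop, task, 0L,
                                                       cfg$fp_kind, cfg$nbits),
                       p_a = NA_real_, n_fallback = NA_integer_))
    for (g in seq_len(cfg$generations)) {
      off <- make_offspring(pop, N, task,
                            crossover_fraction = cfg$crossover_fraction,
                            p_bare = cfg$p_bare,
                            max_attempts = cfg$max_attempts)
      pop <- update_population(pop, off, g, mode = cfg$mode,
                               fp_kind = cfg$fp_kind, nbits = cfg$nbits,
                               beta = cfg$beta)
      s <- summarize_generation(pop, task, g, cfg$fp_kind, cfg$nbits)
      p_a <- if (cfg$mode == "mogata") acceptance_probability(g, cfg$beta) else 1
      rows[[length(rows) + 1L]] <- cbind(trial = t, s, p_a = p_a,
                                         n_fallback = attr(off, "n_fallback"))
      if (verbose)
        message(sprintf("trial %d gen %d: hv=%.3f sr=%.3f gm=%.3f sim=%.3f",
                        t, g, s$hv, s$success_rate, s$max_gm,
                        s$internal_similarity))
    }
    traces[[t]] <- do.call(rbind, rows)
    finals[[t]] <- .final_population_frame(pop, task)
  }
  structure(list(config = cfg, task_name = task$name,
                 trace = do.call(rbind, traces), final = finals),
            class = "molega_result")
}

.final_population_frame <- function(pop, task) {
  sc <- pop$scores
  colnames(sc) <- vapply(task$objectives, `[[`, "", "name")
  data.frame(
    smiles = vapply(pop$molecules, function(m)
      if (is_valid(m)) mol_smiles(m) else NA_character_, ""),
    sc,
    fitness = pop$fitness,
    rank = pop$rank,
    crowding = pop$crowding,
    success = vapply(pop$molecules, function(m)
      as.logical(check_success(m, task)), TRUE),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.molega_result <- function(x, ...) {
  last <- x$trace[x$trace$generation == max(x$trace$generation), , drop = FALSE]
  cat("<molega_result> task", x$task_name, "-", length(x$final), "trial(s),",
      max(x$trace$generation), "generations\n")
  cat(sprintf("  final means: hv=%.3f sr=%.3f max_gm=%.3f internal_sim=%.3f\n",
              mean(last$hv), mean(last$success_rate), mean(last$max_gm),
              mean(last$internal_similarity)))
  invisible(x)
}

# ---- SMILES / results I/O ---------------------------------------------------

#' Read a SMILES library
#'
#' One record per line: SMILES, optionally followed by a whitespace-separated
#' name. Blank lines and lines starting with `#` are skipped. Invalid SMILES
#' are skipped with one summary warning; order is preserved.
#'
#' @param path Path to a `.smi` file.
#' @return List of valid `molecule`s; attributes `"n_invalid"` and
#'   `"names"` carry the skip count and the record names.
#' @export
read_smiles_library <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(structure(list(), n_invalid = 0L))
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, "", 1L)
  nms <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  mols <- parse_molecules(smiles)
  ok <- vapply(mols, is_valid, TRUE)
  if (any(!ok))
    warning(sum(!ok), " invalid SMILES record(s) skipped", call. = FALSE)
  structure(mols[ok], n_invalid = sum(!ok), names_smi = nms[ok])
}

#' Write molecules to a .smi file
#'
#' @param molecules List of `molecule`s (invalid ones are dropped).
#' @param path Output path.
#' @param names Optional record names.
#' @return Invisibly, `path`.
#' @export
write_smiles <- function(molecules, path, names = NULL) {
  ok <- vapply(molecules, is_valid, TRUE)
  smi <- vapply(molecules[ok], mol_smiles, "")
  lines <- if (is.null(names)) smi else paste(smi, names[ok])
  writeLines(lines, path)
  invisible(path)
}

#' Write run results to a directory
#'
#' Emits `config.json` (configuration echo), `trace.csv` (per-generation
#' metrics for all trials), `final_population.csv` (all trials, with scores,
#' rank, crowding and success flags) and one `final_population_trial<t>.smi`
#' per trial.
#'
#' @param result A `molega_result`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "molega_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  cfg <- result$config
  cfg$task <- if (inherits(cfg$task, "mol_task")) cfg$task$name else cfg$task
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$trace, file.path(outdir, "trace.csv"),
                   row.names = FALSE)
  fin <- do.call(rbind, lapply(seq_along(result$final), function(t)
    cbind(trial = t, result$final[[t]])))
  utils::write.csv(fin, file.path(outdir, "final_population.csv"),
                   row.names = FALSE)
  for (t in seq_along(result$final)) {
    writeLines(result$final[[t]]$smiles,
               file.path(outdir, sprintf("final_population_trial%d.smi", t)))
  }
  invisible(outdir)
}
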