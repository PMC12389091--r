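# Multi-property objective (MPO) tasks: an ordered list of objectives, each
# a scoring function (descriptor, similarity-to-target, or plugin) plus a
# modifier mapping the raw value to [0, 1] and a success window on the RAW
# value. The five built-in benchmarks mirror the GuacaMol-style MPO tasks.

#' Define an objective
#'
#' @param name Label for reports.
#' @param scorer A scorer specification: `descriptor_scorer(kind)`,
#'   `similarity_scorer(target_smiles, fp_kind)`, or `plugin_scorer(fun)`.
#' @param mod A `modifier`, or `NULL` for scorers already in \eqn{[0,1]}.
#' @param success Optional success window on the raw score, a list with
#'   fields `lo`, `hi`, `lo_open`, `hi_open`. If omitted it is derived from
#'   the modifier: \eqn{[\mu - \sigma, \mu + \sigma]} (closed) for the
#'   Gaussian family; raw value strictly below \eqn{\mu} for
#'   `ThresholdedLinear` (a novelty constraint: the benchmark counts
#'   similarity *below* the threshold as success).
#' @return A `mol_objective`.
#' @export
mol_objective <- function(name, scorer, mod = NULL, success = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(scorer, "molega_scorer")) stop("scorer must be a scorer spec", call. = FALSE)
  if (!is.null(mod) && !inherits(mod, "modifier")) stop("mod must be a modifier", call. = FALSE)
  if (is.null(success)) success <- .derive_success(mod)
  success <- .validate_success(success)
  structure(list(name = name, scorer = scorer, modifier = mod,
                 success = success),
            class = "mol_objective")
}

success_window <- function(lo = -Inf, hi = Inf, lo_open = FALSE, hi_open = FALSE) {
  list(lo = lo, hi = hi, lo_open = lo_open, hi_open = hi_open)
}

.validate_success <- function(s) {
  stopifnot(is.list(s), all(c("lo", "hi") %in% names(s)))
  if (is.null(s$lo_open)) s$lo_open <- FALSE
  if (is.null(s$hi_open)) s$hi_open <- FALSE
  if (s$lo > s$hi) stop("success window has lo > hi", call. = FALSE)
  s
}

.derive_success <- function(mod) {
  if (is.null(mod)) return(success_window(0.5, Inf))        # plain [0,1] scorers: >= 0.5
  switch(mod$kind,
    Gaussian = ,
    MinGaussian = ,
    MaxGaussian = success_window(mod$mu - mod$sigma, mod$mu + mod$sigma),
    ThresholdedLinear = success_window(-Inf, mod$mu, hi_open = TRUE))
}

.in_window <- function(x, s) {
  lo_ok <- if (s$lo_open) x > s$lo else x >= s$lo
  hi_ok <- if (s$hi_open) x < s$hi else x <= s$hi
  lo_ok & hi_ok
}

# ---- scorer specifications ----------------------------------------------

#' Scorer specifications
#'
#' `descriptor_scorer()` scores a molecular descriptor,
#' `similarity_scorer()` the Tanimoto similarity to a fixed target
#' structure, and `plugin_scorer()` wraps any `function(mol) -> numeric`
#' (the extension point for externally-trained activity models).
#'
#' @param kind Descriptor kind (see [compute_descriptor()]).
#' @param target_smiles SMILES of the reference structure.
#' @param fp_kind Fingerprint kind for the similarity.
#' @param nbits Fingerprint folded length.
#' @param fun Scoring function taking a `molecule`.
#' @param label Plugin label for reports.
#' @return A `molega_scorer` specification.
#' @export
descriptor_scorer <- function(kind) {
  kind <- match.arg(kind, .DESCRIPTOR_KINDS)
  structure(list(type = "descriptor", kind = kind), class = "molega_scorer")
}

#' @rdname descriptor_scorer
#' @export
similarity_scorer <- function(target_smiles, fp_kind = "ECFP4", nbits = 2048L) {
  fp_kind <- match.arg(fp_kind, .FP_KINDS)
  target <- parse_molecule(target_smiles)
  if (!is_valid(target)) stop("target SMILES does not parse", call. = FALSE)
  structure(list(type = "similarity", fp_kind = fp_kind, nbits = as.integer(nbits),
                 target = target),
            class = "molega_scorer")
}

#' @rdname descriptor_scorer
#' @export
plugin_scorer <- function(fun, label = "plugin") {
  stopifnot(is.function(fun))
  structure(list(type = "plugin", fun = fun, label = label),
            class = "molega_scorer")
}

.raw_score <- function(scorer, mol) {
  switch(scorer$type,
    descriptor = compute_descriptor(mol, scorer$kind),
    similarity = mol_similarity(mol, scorer$target, scorer$fp_kind, scorer$nbits),
    plugin = as.numeric(scorer$fun(mol)))
}

# ---- tasks ---------------------------------------------------------------

#' Define a multi-property optimization task
#'
#' @param name Task label.
#' @param objectives List of [mol_objective()]s (at least 2).
#' @return A `mol_task`.
#' @export
mol_task <- function(name, objectives) {
  stopifnot(is.character(name), length(objectives) >= 2L,
            all(vapply(objectives, inherits, TRUE, "mol_objective")))
  structure(list(name = name, objectives = objectives), class = "mol_task")
}

#' @export
print.mol_task <- function(x, ...) {
  cat("<mol_task>", x$name, "-", length(x$objectives), "objectives\n")
  for (o in x$objectives) {
    m <- if (is.null(o$modifier)) "none"
         else sprintf("%s(%s)", o$modifier$kind,
                      if (o$modifier$kind == "ThresholdedLinear") format(o$modifier$mu)
                      else paste(format(o$modifier$mu), format(o$modifier$sigma), sep = ", "))
    cat("  -", o$name, "| modifier:", m, "\n")
  }
  invisible(x)
}

#' Built-in benchmark target structures
#'
#' Reads the packaged SMILES of the five benchmark reference drugs
#' (fexofenadine, pioglitazone, osimertinib, ranolazine, cobimetinib).
#'
#' @return Named character vector of SMILES.
#' @export
benchmark_targets <- function() {
  path <- system.file("extdata", "benchmark_targets.smi", package = "molega")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  stats::setNames(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Built-in benchmark tasks
#'
#' The five multi-property objective benchmarks, parameter-for-parameter:
#' \itemize{
#' \item Fexofenadine: Tanimoto(AP) Thresholded(0.8); TPSA MaxGaussian(90, 10);
#'   logP MinGaussian(4, 2).
#' \item Pioglitazone: Tanimoto(ECFP4) Gaussian(0, 0.1); molecular weight
#'   Gaussian(356, 10); rotatable bonds Gaussian(2, 0.5).
#' \item Osimertinib: Tanimoto(FCFP4) Thresholded(0.8); Tanimoto(ECFP6)
#'   MinGaussian(0.85, 2); TPSA MaxGaussian(95, 20); logP MinGaussian(1, 2).
#' \item Ranolazine: Tanimoto(AP) Thresholded(0.7); TPSA MaxGaussian(95, 20);
#'   logP MaxGaussian(7, 1); fluorine count Gaussian(1, 1).
#' \item Cobimetinib: Tanimoto(FCFP4) Thresholded(0.7); Tanimoto(ECFP6)
#'   MinGaussian(0.75, 0.1); rotatable bonds MinGaussian(3, 1); aromatic
#'   rings MaxGaussian(3, 1); CNS desirability (success at \eqn{\ge 0.5}).
#' }
#' All similarities are to the task's namesake drug. Success windows derive
#' from the modifiers (see [mol_objective()]); `thresholded_success = "above"`
#' flips the thresholded-similarity success rule to reward high similarity
#' instead of novelty.
#'
#' @param name Benchmark name (case-insensitive).
#' @param thresholded_success `"below"` (default; similarity under the
#'   threshold counts as success) or `"above"`.
#' @return A `mol_task`.
#' @export
benchmark_task <- function(name = c("fexofenadine", "pioglitazone", "osimertinib",
                                    "ranolazine", "cobimetinib"),
                           thresholded_success = c("below", "above")) {
  name <- match.arg(tolower(name), c("fexofenadine", "pioglitazone",
                                     "osimertinib", "ranolazine", "cobimetinib"))
  thresholded_success <- match.arg(thresholded_success)
  tg <- benchmark_targets()
  thr_success <- function(mu) {
    if (thresholded_success == "below") success_window(-Inf, mu, hi_open = TRUE)
    else success_window(mu, Inf)
  }
  sim <- function(drug, fp, mod, succ = NULL)
    mol_objective(paste0("similarity_", fp), similarity_scorer(tg[[drug]], fp),
                  mod, success = succ)
  desc <- function(kind, mod, nm = kind)
    mol_objective(nm, descriptor_scorer(kind), mod)
  objs <- switch(name,
    fexofenadine = list(
      sim("fexofenadine", "AP", modifier("ThresholdedLinear", 0.8), thr_success(0.8)),
      desc("TPSA", modifier("MaxGaussian", 90, 10)),
      desc("logP", modifier("MinGaussian", 4, 2))),
    pioglitazone = list(
      sim("pioglitazone", "ECFP4", modifier("Gaussian", 0, 0.1)),
      desc("molecular_weight", modifier("Gaussian", 356, 10)),
      desc("n_rotatable_bonds", modifier("Gaussian", 2, 0.5))),
    osimertinib = list(
      sim("osimertinib", "FCFP4", modifier("ThresholdedLinear", 0.8), thr_success(0.8)),
      sim("osimertinib", "ECFP6", modifier("MinGaussian", 0.85, 2)),
      desc("TPSA", modifier("MaxGaussian", 95, 20)),
      desc("logP", modifier("MinGaussian", 1, 2))),
    ranolazine = list(
      sim("ranolazine", "AP", modifier("ThresholdedLinear", 0.7), thr_success(0.7)),
      desc("TPSA", modifier("MaxGaussian", 95, 20)),
      desc("logP", modifier("MaxGaussian", 7, 1)),
      desc("n_fluorine", modifier("Gaussian", 1, 1))),
    cobimetinib = list(
      sim("cobimetinib", "FCFP4", modifier("ThresholdedLinear", 0.7), thr_success(0.7)),
      sim("cobimetinib", "ECFP6", modifier("MinGaussian", 0.75, 0.1)),
      desc("n_rotatable_bonds", modifier("MinGaussian", 3, 1)),
      desc("n_aromatic_rings", modifier("MaxGaussian", 3, 1)),
      mol_objective("CNS", descriptor_scorer("CNS"), NULL,
                    success = success_window(0.5, Inf))))
  mol_task(name, objs)
}

#' List the built-in benchmark tasks
#'
#' @return A data.frame with one row per objective of each built-in task:
#'   task, objective, scorer, fingerprint, modifier, mu, sigma.
#' @export
list_benchmarks <- function() {
  rows <- list()
  for (nm in c("fexofenadine", "pioglitazone", "osimertinib", "ranolazine",
               "cobimetinib")) {
    t <- benchmark_task(nm)
    for (o in t$objectives) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = nm, objective = o$name,
        scorer = o$scorer$type,
        fingerprint = if (o$scorer$type == "similarity") o$scorer$fp_kind else NA,
        modifier = if (is.null(o$modifier)) NA else o$modifier$kind,
        mu = if (is.null(o$modifier)) NA else o$modifier$mu,
        sigma = if (is.null(o$modifier)) NA else o$modifier$sigma,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- scoring against a task ---------------------------------------------

#' Score a molecule against a task
#'
#' Computes each objective's raw score, applies its modifier, and returns
#' the ordered vector of modified scores in \eqn{[0,1]^n}. Invalid molecules
#' score 0 on every objective.
#'
#' @param mol A `molecule`.
#' @param task A `mol_task`.
#' @param raw If `TRUE`, also return the raw (pre-modifier) values.
#' @return Numeric vector of modified scores (with attribute `"raw"` when
#'   `raw = TRUE`).
#' @export
score_molecule <- function(mol, task, raw = FALSE) {
  stopifnot(inherits(task, "mol_task"))
  n <- length(task$objectives)
  if (!is_valid(mol)) {
    out <- rep(0, n)
    if (raw) attr(out, "raw") <- rep(NA_real_, n)
    return(out)
  }
  rawv <- vapply(task$objectives, function(o) .raw_score(o$scorer, mol), 0)
  mod <- vapply(seq_len(n), function(i) {
    o <- task$objectives[[i]]
    if (is.null(o$modifier)) min(max(rawv[i], 0), 1)
    else apply_modifier(o$modifier, rawv[i])
  }, 0)
  names(mod) <- vapply(task$objectives, `[[`, "", "name")
  if (raw) attr(mod, "raw") <- rawv
  mod
}

#' Check whether a molecule satisfies all task success windows
#'
#' Success is defined on the RAW objective values: every raw value must lie
#' inside its objective's success window. Invalid molecules never succeed.
#'
#' @inheritParams score_molecule
#' @return Logical scalar with attribute `"per_objective"` (named logical
#'   vector).
#' @export
check_success <- function(mol, task) {
  stopifnot(inherits(task, "mol_task"))
  n <- length(task$objectives)
  nms <- vapply(task$objectives, `[[`, "", "name")
  if (!is_valid(mol)) {
    out <- FALSE
    attr(out, "per_objective") <- stats::setNames(rep(FALSE, n), nms)
    return(out)
  }
  per <- vapply(seq_len(n), function(i) {
    o <- task$objectives[[i]]
    .in_window(.raw_score(o$scorer, mol), o$success)
  }, TRUE)
  out <- all(per)
  attr(out, "per_objective") <- stats::setNames(per, nms)
  out
}

# ---- task (de)serialization ----------------------------------------------

#' Serialize / deserialize a task to JSON
#'
#' Plugin scorers are not serializable and raise an error.
#'
#' @param task A `mol_task`.
#' @param path File path.
#' @return `write_task()` invisibly returns `path`; `read_task()` a `mol_task`.
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "mol_task"))
  objs <- lapply(task$objectives, function(o) {
    if (o$scorer$type == "plugin")
      stop("plugin scorers cannot be serialized", call. = FALSE)
    list(name = o$name,
         scorer = if (o$scorer$type == "descriptor")
           list(type = "descriptor", kind = o$scorer$kind)
         else list(type = "similarity", fp_kind = o$scorer$fp_kind,
                   nbits = o$scorer$nbits, target = mol_smiles(o$scorer$target)),
         modifier = if (is.null(o$modifier)) NULL
           else list(kind = o$modifier$kind, mu = o$modifier$mu,
                     sigma = if (is.na(o$modifier$sigma)) NULL
                             else o$modifier$sigma),
         success = o$success)
  })
  jsonlite::write_json(list(name = task$name, objectives = objs), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_task
#' @export
read_task <- function(path) {
  x <- jsonlite::read_json(path)
  objs <- lapply(x$objectives, function(o) {
    scorer <- if (o$scorer$type == "descriptor") descriptor_scorer(o$scorer$kind)
      else similarity_scorer(o$scorer$target, o$scorer$fp_kind,
                             as.integer(o$scorer$nbits))
    mod <- if (is.null(o$modifier)) NULL
      else modifier(o$modifier$kind, o$modifier$mu,
                    if (is.null(o$modifier$sigma)) NA_real_ else o$modifier$sigma)
    succ <- success_window(
      lo = if (is.null(o$success$lo)) -Inf else as.numeric(o$success$lo),
      hi = if (is.null(o$success$hi)) Inf else as.numeric(o$success$hi),
      lo_open = isTRUE(o$success$lo_open), hi_open = isTRUE(o$success$hi_open))
    mol_objective(o$name, scorer, mod, success = succ)
  })
  mol_task(x$name, objs)
}
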