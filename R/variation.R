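# Decoupled crossover and mutation in chemical space.
#
# Molecules are decomposed into a core (ring systems, linkers between them,
# and exocyclic multiply-bonded atoms) and acyclic side chains with recorded
# attachment points. Crossover recombines one parent's core with side chains
# drawn from both parents; mutation adds, replaces or deletes side chains.
# Every product is rebuilt as a V2000 block, canonicalized and re-parsed
# through OpenBabel; candidates that fail sanitization are retried and the
# operators fall back to a parent copy, so the output is always valid.

# ---- fragments -------------------------------------------------------------

.frag <- function(elem, bonds = NULL, charge = NULL, root = 1L) {
  atoms <- data.frame(elem = elem,
                      charge = if (is.null(charge)) rep(0L, length(elem)) else charge,
                      stringsAsFactors = FALSE)
  bonds <- if (is.null(bonds)) data.frame(a1 = integer(0), a2 = integer(0),
                                          order = integer(0))
           else data.frame(a1 = bonds[, 1L], a2 = bonds[, 2L], order = bonds[, 3L])
  list(graph = list(atoms = atoms, bonds = bonds), root = as.integer(root))
}

# Built-in single-attachment-point fragments: small alkyl, hydroxyl,
# halogens, amino, methoxy, carboxyl, trifluoromethyl, sulfonamide.
.builtin_fragments <- function() {
  list(
    methyl = .frag("C"),
    ethyl = .frag(c("C", "C"), rbind(c(1, 2, 1))),
    propyl = .frag(c("C", "C", "C"), rbind(c(1, 2, 1), c(2, 3, 1))),
    isopropyl = .frag(c("C", "C", "C"), rbind(c(1, 2, 1), c(1, 3, 1))),
    hydroxyl = .frag("O"),
    amino = .frag("N"),
    fluoro = .frag("F"),
    chloro = .frag("Cl"),
    bromo = .frag("Br"),
    methoxy = .frag(c("O", "C"), rbind(c(1, 2, 1))),
    carboxyl = .frag(c("C", "O", "O"), rbind(c(1, 2, 2), c(1, 3, 1))),
    trifluoromethyl = .frag(c("C", "F", "F", "F"),
                            rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1))),
    sulfonamide = .frag(c("S", "O", "O", "N"),
                        rbind(c(1, 2, 2), c(1, 3, 2), c(1, 4, 1)))
  )
}

#' Build a fragment pool from a set of molecules
#'
#' Harvests all side chains of the given molecules (via [decompose()]) and
#' appends the built-in seed fragments. Every fragment has exactly one open
#' attachment point.
#'
#' @param molecules List of `molecule`s (may be empty).
#' @return A list of fragments (each `list(graph, root)`).
#' @export
fragment_pool <- function(molecules = list()) {
  pool <- list()
  for (m in molecules) {
    if (!is_valid(m)) next
    fr <- tryCatch(decompose(m), error = function(e) NULL)
    if (is.null(fr)) next
    for (ch in fr$chains)
      pool[[length(pool) + 1L]] <- list(graph = ch$graph, root = ch$root)
  }
  c(pool, unname(.builtin_fragments()))
}

# ---- decomposition ---------------------------------------------------------

.subgraph <- function(graph, idx) {
  idx <- sort(idx)
  map <- integer(nrow(graph$atoms)); map[idx] <- seq_along(idx)
  keep <- graph$bonds$a1 %in% idx & graph$bonds$a2 %in% idx
  b <- graph$bonds[keep, , drop = FALSE]
  list(graph = list(atoms = graph$atoms[idx, , drop = FALSE],
                    bonds = data.frame(a1 = map[b$a1], a2 = map[b$a2],
                                       order = b$order)),
       map = map)
}

#' Decompose a molecule into core and side chains
#'
#' The core is the Bemis-Murcko-style scaffold: all ring atoms, acyclic
#' linkers connecting ring systems (with their decorations), and atoms
#' attached to the scaffold by multiple bonds (e.g. exocyclic carbonyl
#' oxygens). Side chains are the remaining acyclic substituents, each with
#' its attachment atom recorded. Ring-free molecules are returned whole as
#' core with no side chains.
#'
#' @param mol A valid `molecule`.
#' @return A `fragmented_molecule`: `list(core, chains, smiles)` where each
#'   chain is `list(attach, graph, root)` (`attach` indexes the core atoms).
#' @export
decompose <- function(mol) {
  if (!is_valid(mol)) stop("invalid molecule", call. = FALSE)
  memo <- .mol_data(mol)
  if (!is.null(memo$frag)) return(memo$frag)
  g <- .mol_graph(mol)
  ringinfo <- .mol_rings(mol)
  n <- nrow(g$atoms)
  in_ring <- ringinfo$atom_in_ring
  out <- list(smiles = mol_smiles(mol))
  if (!any(in_ring)) {
    out$core <- g
    out$chains <- list()
    class(out) <- "fragmented_molecule"
    memo$frag <- out
    return(out)
  }
  adj <- .adjacency(g)
  nonring <- which(!in_ring)
  comp <- rep(0L, n); cur <- 0L
  for (s in nonring) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nxt <- adj[[v]]
      stack <- c(stack, nxt[!in_ring[nxt] & comp[nxt] == 0L])
    }
  }
  core_atoms <- which(in_ring)
  chains <- list()
  for (cc in seq_len(cur)) {
    atoms_cc <- which(comp == cc)
    # bonds from this component to ring atoms
    att <- g$bonds[(g$bonds$a1 %in% atoms_cc & in_ring[g$bonds$a2]) |
                   (g$bonds$a2 %in% atoms_cc & in_ring[g$bonds$a1]), , drop = FALSE]
    ring_side <- ifelse(in_ring[att$a1], att$a1, att$a2)
    comp_side <- ifelse(in_ring[att$a1], att$a2, att$a1)
    if (nrow(att) != 1L || att$order[1L] > 1L) {
      # linker between ring systems, multiply-bonded decoration, or a
      # detached fragment: keep with the core
      core_atoms <- c(core_atoms, atoms_cc)
    } else {
      chains[[length(chains) + 1L]] <-
        list(ring_atom = ring_side[1L], atoms = atoms_cc, root = comp_side[1L])
    }
  }
  sg <- .subgraph(g, core_atoms)
  out$core <- sg$graph
  out$chains <- lapply(chains, function(ch) {
    fs <- .subgraph(g, ch$atoms)
    list(attach = sg$map[ch$ring_atom],
         graph = fs$graph,
         root = fs$map[ch$root])
  })
  class(out) <- "fragmented_molecule"
  memo$frag <- out
  out
}

#' Reassemble a decomposed molecule
#'
#' Attaches every side chain back to its attachment atom and returns the
#' resulting `molecule`. For an unmodified [decompose()] result this
#' round-trips to the original canonical SMILES.
#'
#' @param frag A `fragmented_molecule`.
#' @return A `molecule`.
#' @export
reassemble <- function(frag) {
  stopifnot(inherits(frag, "fragmented_molecule"))
  g <- .assemble_graph(frag$core, frag$chains)
  .graph_to_molecule(g)
}

.assemble_graph <- function(core, chains) {
  atoms <- core$atoms; bonds <- core$bonds
  for (ch in chains) {
    off <- nrow(atoms)
    atoms <- rbind(atoms, ch$graph$atoms)
    if (nrow(ch$graph$bonds))
      bonds <- rbind(bonds, data.frame(a1 = ch$graph$bonds$a1 + off,
                                       a2 = ch$graph$bonds$a2 + off,
                                       order = ch$graph$bonds$order))
    bonds <- rbind(bonds, data.frame(a1 = ch$attach, a2 = ch$root + off,
                                     order = 1L))
  }
  rownames(atoms) <- NULL
  list(atoms = atoms, bonds = bonds)
}

.graph_to_molecule <- function(graph) {
  can <- .ob_sdf_to_canonical(.graph_to_sdf_text(graph))
  if (is.na(can)) return(.invalid_molecule("<graph>"))
  parse_molecule(can)
}

# Batch-sanitize candidate graphs: one OB call for the whole round.
# Returns a list of molecules (invalid where sanitization failed).
.graphs_to_molecules <- function(graphs) {
  if (!length(graphs)) return(list())
  ids <- paste0("g", seq_along(graphs))
  txt <- paste(vapply(seq_along(graphs), function(i)
    .graph_to_sdf_text(graphs[[i]], title = ids[i]), ""), collapse = "\n")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt)),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  can <- rep(NA_character_, length(graphs))
  for (ln in lines) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(p) >= 2L) {
      i <- match(trimws(p[2L]), ids)
      smi <- trimws(p[1L])
      if (!is.na(i) && nzchar(smi)) can[i] <- smi
    }
  }
  mols <- vector("list", length(graphs))
  ok <- which(!is.na(can))
  if (length(ok)) {
    parsed <- parse_molecules(can[ok])
    for (j in seq_along(ok)) mols[[ok[j]]] <- parsed[[j]]
  }
  for (i in which(is.na(can))) mols[[i]] <- .invalid_molecule("<graph>")
  mols
}

# ---- crossover / mutation --------------------------------------------------

# Candidate offspring graph from two decomposed parents; NULL if no product
# can be formed. Consumes RNG.
.crossover_graph <- function(fa, fb, p_bare = 0.2) {
  f <- if (stats::runif(1) < 0.5) fa else fb
  pool <- c(lapply(fa$chains, function(ch) list(graph = ch$graph, root = ch$root)),
            lapply(fb$chains, function(ch) list(graph = ch$graph, root = ch$root)))
  chains <- list()
  for (ch in f$chains) {
    if (stats::runif(1) < p_bare) next
    pick <- pool[[sample.int(length(pool), 1L)]]
    chains[[length(chains) + 1L]] <-
      list(attach = ch$attach, graph = pick$graph, root = pick$root)
  }
  .assemble_graph(f$core, chains)
}

# Candidate mutated graph; NULL when no operation applies. Consumes RNG.
.mutate_graph <- function(mol, pool) {
  fr <- decompose(mol)
  op <- sample(c("add", "replace", "delete"), 1L)
  if (op != "add" && !length(fr$chains)) op <- "add"
  if (op == "delete") {
    keep <- fr$chains[-sample.int(length(fr$chains), 1L)]
    return(.assemble_graph(fr$core, keep))
  }
  if (op == "replace") {
    i <- sample.int(length(fr$chains), 1L)
    pick <- pool[[sample.int(length(pool), 1L)]]
    fr$chains[[i]] <- list(attach = fr$chains[[i]]$attach,
                           graph = pick$graph, root = pick$root)
    return(.assemble_graph(fr$core, fr$chains))
  }
  # add: attach a pool fragment at a random atom with a free valence
  g <- .mol_graph(mol)
  imph <- .mol_imph(mol)
  cand <- which(imph >= 1L)
  if (!length(cand)) return(NULL)
  at <- cand[sample.int(length(cand), 1L)]
  pick <- pool[[sample.int(length(pool), 1L)]]
  .assemble_graph(g, list(list(attach = at, graph = pick$graph, root = pick$root)))
}

#' Core/side-chain crossover
#'
#' Picks one parent's core uniformly at random, then at each of that core's
#' attachment points attaches a side chain sampled uniformly from the union
#' of both parents' side chains (or leaves the point bare with probability
#' `p_bare`). The product is sanitized; after `max_attempts` failures a copy
#' of a random parent is returned, so the result is always a valid molecule.
#'
#' @param a,b Valid parent `molecule`s.
#' @param max_attempts Sanitization retries (default 10).
#' @param p_bare Probability of leaving an attachment point bare.
#' @return A valid `molecule`.
#' @export
crossover <- function(a, b, max_attempts = 10L, p_bare = 0.2) {
  stopifnot(is_valid(a), is_valid(b))
  fa <- decompose(a); fb <- decompose(b)
  for (i in seq_len(max_attempts)) {
    g <- .crossover_graph(fa, fb, p_bare)
    m <- .graph_to_molecule(g)
    if (is_valid(m)) return(m)
  }
  if (stats::runif(1) < 0.5) a else b
}

#' Side-chain mutation
#'
#' Chooses uniformly among adding, replacing and deleting a side chain
#' (falling back to `add` when the molecule has no side chain), sanitizes
#' the product, and returns the unmodified parent after `max_attempts`
#' failed attempts.
#'
#' @param a A valid `molecule`.
#' @param pool Fragment pool from [fragment_pool()].
#' @param max_attempts Sanitization retries (default 10).
#' @return A valid `molecule`.
#' @export
mutate <- function(a, pool = fragment_pool(), max_attempts = 10L) {
  stopifnot(is_valid(a))
  for (i in seq_len(max_attempts)) {
    g <- .mutate_graph(a, pool)
    if (is.null(g)) break
    m <- .graph_to_molecule(g)
    if (is_valid(m)) return(m)
  }
  a
}

#' Generate and score offspring
#'
#' Produces `n_offspring` new scored individuals: a configured fraction via
#' core/side-chain crossover, the rest via side-chain mutation, with parents
#' drawn by fitness-proportional sampling. Candidates failing sanitization
#' are retried up to `max_attempts` rounds and then replaced by parent
#' copies, so the offspring are always valid.
#'
#' @param pop A scored `molega_pop`.
#' @param n_offspring Number of offspring (> 0); defaults to the capacity.
#' @param task The `mol_task` used for scoring.
#' @param crossover_fraction Fraction of offspring from crossover (default 0.5).
#' @param p_bare Bare-attachment probability for crossover.
#' @param max_attempts Sanitization retries per offspring.
#' @return A `molega_pop` of offspring (capacity `n_offspring`); the
#'   attribute `"n_fallback"` counts parent-copy fallbacks.
#' @export
make_offspring <- function(pop, n_offspring = pop$capacity, task,
                           crossover_fraction = 0.5, p_bare = 0.2,
                           max_attempts = 10L) {
  stopifnot(inherits(pop, "molega_pop"), inherits(task, "mol_task"))
  if (n_offspring <= 0L) stop("n_offspring must be positive", call. = FALSE)
  pool <- fragment_pool(pop$molecules)
  n_x <- round(n_offspring * crossover_fraction)
  is_x <- seq_len(n_offspring) <= n_x
  # plan parents up front (RNG order: one block of draws per offspring)
  plan <- vector("list", n_offspring)
  for (i in seq_len(n_offspring)) {
    if (is_x[i]) {
      ij <- select_parents(pop, 2L)
      plan[[i]] <- list(op = "x",
                        a = pop$molecules[[ij[1L]]],
                        b = pop$molecules[[ij[2L]]],
                        fa = NULL, fb = NULL)
    } else {
      j <- select_parents(pop, 1L)
      plan[[i]] <- list(op = "m", a = pop$molecules[[j]])
    }
  }
  for (i in which(is_x)) {
    plan[[i]]$fa <- decompose(plan[[i]]$a)
    plan[[i]]$fb <- decompose(plan[[i]]$b)
  }
  result <- vector("list", n_offspring)
  unresolved <- seq_len(n_offspring)
  for (round in seq_len(max_attempts)) {
    if (!length(unresolved)) break
    graphs <- vector("list", length(unresolved))
    for (k in seq_along(unresolved)) {
      i <- unresolved[k]
      graphs[[k]] <- if (plan[[i]]$op == "x")
        .crossover_graph(plan[[i]]$fa, plan[[i]]$fb, p_bare)
      else .mutate_graph(plan[[i]]$a, pool)
    }
    usable <- !vapply(graphs, is.null, TRUE)
    mols <- vector("list", length(graphs))
    mols[usable] <- .graphs_to_molecules(graphs[usable])
    ok <- vapply(mols, function(m) !is.null(m) && is_valid(m), TRUE)
    for (k in which(ok)) result[[unresolved[k]]] <- mols[[k]]
    unresolved <- unresolved[!ok]
  }
  n_fallback <- length(unresolved)
  for (i in unresolved) {
    result[[i]] <- if (plan[[i]]$op == "x") {
      if (stats::runif(1) < 0.5) plan[[i]]$a else plan[[i]]$b
    } else plan[[i]]$a
  }
  off <- score_population(result, task, capacity = n_offspring)
  attr(off, "n_fallback") <- n_fallback
  off
}
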