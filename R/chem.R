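# Molecule handling on top of ChemmineR / ChemmineOB (OpenBabel).
#
# A `molecule` is a lightweight handle: canonical SMILES + a shared
# environment holding the parsed structure (SDF), cached descriptors,
# ring/aromaticity perception and fingerprints. Molecules with the same
# canonical SMILES share one environment (package-level cache), so
# fingerprints and descriptors are computed once per distinct structure.

.molega <- new.env(parent = emptyenv())

.cache_reset <- function() {
  .molega$mol <- new.env(parent = emptyenv())       # canonical SMILES -> molecule
  .molega$input2can <- new.env(parent = emptyenv()) # raw SMILES -> canonical (or NA)
}

#' Clear the package-level molecule cache
#'
#' Drops all cached parsed structures, descriptors and fingerprints.
#' Mainly useful in long sessions or tests; results are unaffected because
#' every cached quantity is a pure function of the canonical SMILES.
#' @return Invisibly, `NULL`.
#' @export
clear_molecule_cache <- function() {
  .cache_reset()
  invisible(NULL)
}

# ---- OpenBabel bridges -------------------------------------------------

.strip_ob <- function(x) {
  # convertFormat output lines look like "SMILES\ttitle"; keep first token
  x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x <- x[nzchar(trimws(x))]
  vapply(strsplit(x, "[ \t]+"), `[`, "", 1L)
}

.ob_smiles_to_canonical <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  tok <- .strip_ob(out)
  if (length(tok) != 1L || !nzchar(tok)) NA_character_ else tok
}

.ob_sdf_to_canonical <- function(sdftext) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", sdftext)),
    error = function(e) ""
  )
  tok <- .strip_ob(out)
  if (length(tok) != 1L || !nzchar(tok)) NA_character_ else tok
}

# Aromatic bonds from OpenBabel MOL2 output (atom order is preserved).
# Returns an integer matrix with columns a1, a2 for aromatic bonds.
.ob_aromatic_bonds <- function(sdftext) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "MOL2", sdftext)),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  i <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  if (length(i) == 0L) return(matrix(integer(0), ncol = 2L))
  lines <- lines[-seq_len(i[1L])]
  nxt <- grep("^@<TRIPOS>", lines)
  if (length(nxt)) lines <- lines[seq_len(nxt[1L] - 1L)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(matrix(integer(0), ncol = 2L))
  parts <- strsplit(lines, "[ \t]+")
  ar <- vapply(parts, function(p) length(p) >= 4L && p[4L] == "ar", TRUE)
  a1 <- as.integer(vapply(parts, `[`, "", 2L))
  a2 <- as.integer(vapply(parts, `[`, "", 3L))
  cbind(a1 = a1[ar], a2 = a2[ar])
}

# ---- molecular graph ----------------------------------------------------

# graph: list(atoms = data.frame(elem, charge), bonds = data.frame(a1, a2, order))
.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  chg_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- ifelse(chg_code == 0 | chg_code == 4, 0L, 4L - as.integer(chg_code))
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, "C1"]), a2 = as.integer(bb[, "C2"]),
               order = as.integer(bb[, "C3"]))
  }
  list(atoms = data.frame(elem = elem, charge = as.integer(charge),
                          stringsAsFactors = FALSE),
       bonds = bonds)
}

.graph_to_sdf_text <- function(graph, title = "molega") {
  na <- nrow(graph$atoms); nb <- nrow(graph$bonds)
  head <- c(title, " molega 2D", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  chg_code <- ifelse(graph$atoms$charge == 0, 0L, 4L - graph$atoms$charge)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, graph$atoms$elem, 0L, chg_code)
  bonds <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                           graph$bonds$a1, graph$bonds$a2, graph$bonds$order)
           else character(0)
  chg_idx <- which(graph$atoms$charge != 0L)
  chg <- if (length(chg_idx)) {
    vapply(chg_idx, function(i)
      sprintf("M  CHG  1 %3d %3d", i, graph$atoms$charge[i]), "")
  } else character(0)
  paste(c(head, atoms, bonds, chg, "M  END", "$$$$"), collapse = "\n")
}

.heavy_degree <- function(graph) {
  deg <- integer(nrow(graph$atoms))
  if (nrow(graph$bonds)) {
    t1 <- tabulate(graph$bonds$a1, nbins = nrow(graph$atoms))
    t2 <- tabulate(graph$bonds$a2, nbins = nrow(graph$atoms))
    deg <- t1 + t2
  }
  deg
}

.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)
.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

# Implicit hydrogen counts from a kekulized graph: smallest standard valence
# at or above the bond-order sum, shifted by formal charge for N/O-type atoms.
.implicit_h <- function(graph) {
  n <- nrow(graph$atoms)
  bosum <- numeric(n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      b <- graph$bonds[k, ]
      bosum[b$a1] <- bosum[b$a1] + b$order
      bosum[b$a2] <- bosum[b$a2] + b$order
    }
  }
  imph <- integer(n)
  for (i in seq_len(n)) {
    el <- graph$atoms$elem[i]
    val <- .DEFAULT_VALENCE[[el]]
    if (is.null(val) || is.na(val)) { imph[i] <- 0L; next }
    val <- val + graph$atoms$charge[i]
    # hypervalent S / P expand to the next standard valence
    if (el == "S") while (val < bosum[i] && val < 6) val <- val + 2
    if (el == "P" && val < bosum[i]) val <- 5
    imph[i] <- max(0L, as.integer(round(val - bosum[i])))
  }
  imph
}

# Ring perception: SSSR-style minimal cycle basis from ChemmineR's exhaustive
# ring search, pruned greedily (smallest rings first, keep a ring only if it
# covers a new bond) down to the cyclomatic number per molecule.
.perceive_rings <- function(sdf, graph) {
  n_cyc <- nrow(graph$bonds) - nrow(graph$atoms) + .n_components(graph)
  empty <- list(rings = list(), atom_in_ring = logical(nrow(graph$atoms)),
                ring_bonds = matrix(integer(0), ncol = 2L))
  if (n_cyc <= 0L) return(empty)
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 20, type = "all", arom = FALSE)),
    error = function(e) NULL
  )
  if (is.null(rr) || !length(rr)) return(empty)
  rlist <- lapply(rr, function(at) as.integer(sub("^.*_", "", at)))
  rlist <- rlist[order(lengths(rlist))]
  kept <- list(); covered <- character(0)
  for (ring in rlist) {
    bkeys <- .ring_bond_keys(ring)
    if (any(!(bkeys %in% covered))) {
      kept[[length(kept) + 1L]] <- ring
      covered <- union(covered, bkeys)
      if (length(kept) >= n_cyc) break
    }
  }
  atom_in_ring <- logical(nrow(graph$atoms))
  atom_in_ring[unique(unlist(kept))] <- TRUE
  rb <- do.call(rbind, lapply(kept, function(r) {
    m <- cbind(r, c(r[-1L], r[1L]))
    t(apply(m, 1L, sort))
  }))
  if (is.null(rb)) rb <- matrix(integer(0), ncol = 2L)
  list(rings = kept, atom_in_ring = atom_in_ring,
       ring_bonds = unique(rb))
}

.ring_bond_keys <- function(ring) {
  nxt <- c(ring[-1L], ring[1L])
  paste(pmin(ring, nxt), pmax(ring, nxt), sep = "-")
}

.n_components <- function(graph) {
  n <- nrow(graph$atoms)
  if (n == 0L) return(0L)
  comp <- integer(n); cur <- 0L
  adj <- .adjacency(graph)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  cur
}

.adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- rep(list(integer(0)), n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds$a1[k]; b <- graph$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# ---- molecule constructor ----------------------------------------------

.new_molecule <- function(canonical, input, data = NULL) {
  structure(list(smiles = canonical,
                 valid = !is.na(canonical),
                 input = input,
                 data = data),
            class = "molecule")
}

.invalid_molecule <- function(input) .new_molecule(NA_character_, input)

#' Parse SMILES strings into molecules
#'
#' Parses and sanitizes SMILES through OpenBabel, canonicalizes them, and
#' returns `molecule` handles. Unparsable strings yield invalid molecules
#' (`is_valid()` is `FALSE`) rather than errors, so the evolutionary loop is
#' never interrupted by a bad structure.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of `molecule` objects, one per input.
#' @examples
#' \donttest{
#' mols <- parse_molecules(c("c1ccccc1", "CCO", "C1CC"))
#' vapply(mols, is_valid, TRUE)
#' }
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  canon <- character(length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) { canon[i] <- NA_character_; next }
    hit <- get0(s, envir = .molega$input2can, ifnotfound = NULL)
    if (is.null(hit)) {
      hit <- .ob_smiles_to_canonical(s)
      assign(s, hit, envir = .molega$input2can)
    }
    canon[i] <- hit
  }
  need <- unique(canon[!is.na(canon)])
  need <- need[!vapply(need, exists, TRUE, envir = .molega$mol)]
  if (length(need)) .materialize_molecules(need)
  for (i in seq_along(smiles)) {
    out[[i]] <- if (is.na(canon[i])) .invalid_molecule(smiles[i])
                else {
                  m <- get(canon[i], envir = .molega$mol)
                  m$input <- smiles[i]
                  m
                }
  }
  out
}

#' @rdname parse_molecules
#' @export
parse_molecule <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  parse_molecules(smiles)[[1L]]
}

# Parse a batch of canonical SMILES into cached molecule environments.
# Single-heavy-atom structures break ChemmineR's SDF container and take a
# dedicated path (.register_single_atom).
.materialize_molecules <- function(canon) {
  ids <- paste0("m", seq_along(canon))
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(canon, ids))),
    error = function(e) NULL
  )
  if (is.null(sdfset)) {
    for (i in seq_along(canon)) .materialize_molecules_single(canon[i])
    return(invisible(NULL))
  }
  ok <- suppressWarnings(ChemmineR::validSDF(sdfset))
  props <- if (any(ok)) tryCatch(
    suppressWarnings(ChemmineR::propOB(sdfset[ok])),
    error = function(e) NULL
  ) else NULL
  row <- 0L
  for (i in seq_along(canon)) {
    if (ok[i]) {
      row <- row + 1L
      p <- if (!is.null(props)) props[row, , drop = FALSE] else NULL
      .register_molecule(canon[i], sdfset[[i]], p)
    } else {
      .register_single_atom(canon[i])
    }
  }
  invisible(NULL)
}

.materialize_molecules_single <- function(can) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(can, "m1"))),
    error = function(e) NULL
  )
  if (is.null(sdfset) || !suppressWarnings(ChemmineR::validSDF(sdfset))[1L]) {
    .register_single_atom(can)
    return(invisible(NULL))
  }
  props <- tryCatch(suppressWarnings(ChemmineR::propOB(sdfset)),
                    error = function(e) NULL)
  .register_molecule(can, sdfset[[1L]], props)
  invisible(NULL)
}

# One-heavy-atom SMILES ("C", "[NH4+]", "Cl", ...): interpret the single
# atom spec directly, fetch properties through OpenBabel from the SMILES.
.register_single_atom <- function(can) {
  m <- regmatches(can, regexec(
    "^\\[?([A-Z][a-z]?)(H\\d*)?(([+-])(\\d)?)?\\]?$", can))[[1L]]
  if (length(m) == 0L || !(m[2L] %in% names(.DEFAULT_VALENCE))) {
    assign(can, .new_molecule(NA_character_, can), envir = .molega$mol)
    return(invisible(NULL))
  }
  charge <- if (nzchar(m[4L])) {
    sgn <- if (m[5L] == "-") -1L else 1L
    sgn * (if (nzchar(m[6L])) as.integer(m[6L]) else 1L)
  } else 0L
  graph <- list(atoms = data.frame(elem = m[2L], charge = charge,
                                   stringsAsFactors = FALSE),
                bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                   order = integer(0)))
  p <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", can, ChemmineOB::prop_OB))[[1L]],
    error = function(e) NULL
  )
  e <- new.env(parent = emptyenv())
  e$sdf <- NULL
  e$graph <- graph
  e$sdftext <- .graph_to_sdf_text(graph)
  e$props <- if (!is.null(p)) {
    c(TPSA = as.numeric(p$TPSA), logP = as.numeric(p$logP),
      MW = as.numeric(p$MW), nF = as.numeric(p$nF),
      HBD = as.numeric(p$HBD), HBA = as.numeric(p$HBA1))
  } else NULL
  e$fps <- list()
  assign(can, .new_molecule(can, can, data = e), envir = .molega$mol)
  invisible(NULL)
}

.register_molecule <- function(can, sdf, props) {
  e <- new.env(parent = emptyenv())
  e$sdf <- sdf
  e$sdftext <- paste(methods::as(sdf, "character"), collapse = "\n")
  e$props <- if (!is.null(props)) {
    c(TPSA = as.numeric(props$TPSA), logP = as.numeric(props$logP),
      MW = as.numeric(props$MW), nF = as.numeric(props$nF),
      HBD = as.numeric(props$HBD), HBA = as.numeric(props$HBA1))
  } else NULL
  e$fps <- list()
  assign(can, .new_molecule(can, can, data = e), envir = .molega$mol)
}

#' @export
print.molecule <- function(x, ...) {
  if (x$valid) cat("<molecule> ", x$smiles, "\n", sep = "")
  else cat("<molecule> INVALID (input: ", x$input, ")\n", sep = "")
  invisible(x)
}

#' Molecule validity and canonical SMILES
#'
#' @param mol A `molecule` object.
#' @return `is_valid()` returns a logical; `mol_smiles()` the canonical
#'   SMILES (`NA` for invalid molecules).
#' @export
is_valid <- function(mol) isTRUE(mol$valid)

#' @rdname is_valid
#' @export
mol_smiles <- function(mol) mol$smiles

# lazy accessors ----------------------------------------------------------

.mol_data <- function(mol) {
  if (!is_valid(mol)) stop("invalid molecule", call. = FALSE)
  mol$data
}

.mol_graph <- function(mol) {
  e <- .mol_data(mol)
  if (is.null(e$graph)) e$graph <- .graph_from_sdf(e$sdf)
  e$graph
}

.mol_imph <- function(mol) {
  e <- .mol_data(mol)
  if (is.null(e$imph)) e$imph <- .implicit_h(.mol_graph(mol))
  e$imph
}

.mol_rings <- function(mol) {
  e <- .mol_data(mol)
  if (is.null(e$ring)) e$ring <- .perceive_rings(e$sdf, .mol_graph(mol))
  e$ring
}

.mol_aromatic <- function(mol) {
  e <- .mol_data(mol)
  if (is.null(e$arom)) {
    g <- .mol_graph(mol)
    ar <- .ob_aromatic_bonds(e$sdftext)
    atom_ar <- logical(nrow(g$atoms))
    if (nrow(ar)) atom_ar[unique(c(ar[, 1L], ar[, 2L]))] <- TRUE
    key <- paste(pmin(ar[, 1L], ar[, 2L]), pmax(ar[, 1L], ar[, 2L]), sep = "-")
    bond_ar <- paste(pmin(g$bonds$a1, g$bonds$a2),
                     pmax(g$bonds$a1, g$bonds$a2), sep = "-") %in% key
    e$arom <- list(atom = atom_ar, bond = bond_ar)
  }
  e$arom
}

.mol_props <- function(mol) {
  e <- .mol_data(mol)
  if (is.null(e$props)) stop("descriptors unavailable for this molecule", call. = FALSE)
  e$props
}
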