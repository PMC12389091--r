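# Fingerprints: circular (ECFP/FCFP, Morgan-style iterative neighborhood
# hashing over the molecular graph) and atom-pair (via ChemmineR::sdf2ap),
# folded to a fixed power-of-two length. Bit assignments are deterministic
# functions of the canonical SMILES; they are internally consistent but not
# numerically identical to other toolkits' implementations (a different
# hash), which is immaterial for Tanimoto-based comparisons.

.FP_KINDS <- c("ECFP4", "ECFP6", "FCFP4", "FCFP6", "AP")

.HASH_MOD <- 67108859  # prime below 2^26; 127 * MOD stays exact in doubles

.hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 127 + (x %% .HASH_MOD) + 1) %% .HASH_MOD
  h
}

#' Construct a fingerprint from explicit on-bits
#'
#' Mostly useful for testing and for working with fingerprints as plain
#' bit sets. `compute_fingerprint()` is the usual entry point.
#'
#' @param bits Integer vector of on-bit indices (0-based, `< nbits`).
#' @param kind Fingerprint kind, one of `"ECFP4"`, `"ECFP6"`, `"FCFP4"`,
#'   `"FCFP6"`, `"AP"`.
#' @param nbits Folded length; a power of two.
#' @return A `fingerprint` object.
#' @export
fingerprint <- function(bits, kind = "ECFP4", nbits = 2048L) {
  kind <- match.arg(kind, .FP_KINDS)
  nbits <- as.integer(nbits)
  if (nbits <= 0L || bitwAnd(nbits, nbits - 1L) != 0L)
    stop("nbits must be a power of two", call. = FALSE)
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= nbits))
    stop("bit indices must lie in [0, nbits)", call. = FALSE)
  structure(list(kind = kind, nbits = nbits, bits = bits),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint ", x$kind, "/", x$nbits, "> ",
      length(x$bits), " on-bits\n", sep = "")
  invisible(x)
}

#' Compute a molecular fingerprint
#'
#' ECFP4/FCFP4 use circular radius 2, ECFP6/FCFP6 radius 3. ECFP initial
#' atom invariants encode element, heavy degree, implicit hydrogens, formal
#' charge and ring membership; FCFP uses pharmacophoric feature invariants
#' (donor, acceptor, basic, acidic, aromatic, halogen). AP is the ChemmineR
#' atom-pair descriptor set folded to `nbits`.
#'
#' @param mol A valid `molecule`.
#' @param kind One of `"ECFP4"`, `"ECFP6"`, `"FCFP4"`, `"FCFP6"`, `"AP"`.
#' @param nbits Folded length (power of two, default 2048).
#' @return A `fingerprint`.
#' @export
compute_fingerprint <- function(mol, kind = "ECFP4", nbits = 2048L) {
  kind <- match.arg(kind, .FP_KINDS)
  nbits <- as.integer(nbits)
  if (!is_valid(mol)) stop("cannot fingerprint an invalid molecule", call. = FALSE)
  e <- .mol_data(mol)
  key <- paste0(kind, "_", nbits)
  hit <- e$fps[[key]]
  if (!is.null(hit)) return(hit)
  fp <- if (kind == "AP") .ap_fingerprint(mol, nbits)
        else .morgan_fingerprint(mol, kind, nbits)
  e$fps[[key]] <- fp
  fp
}

.ap_fingerprint <- function(mol, nbits) {
  e <- .mol_data(mol)
  if (is.null(e$sdf))   # single-atom molecule: no atom pairs
    return(fingerprint(integer(0), kind = "AP", nbits = nbits))
  codes <- tryCatch(
    suppressWarnings(ChemmineR::ap(ChemmineR::sdf2ap(e$sdf))),
    error = function(e) numeric(0)
  )
  if (length(codes) == 1L && is.character(codes)) codes <- numeric(0)
  fingerprint(as.integer(codes %% nbits), kind = "AP", nbits = nbits)
}

.morgan_fingerprint <- function(mol, kind, nbits) {
  radius <- if (kind %in% c("ECFP4", "FCFP4")) 2L else 3L
  feat <- substr(kind, 1L, 1L) == "F"
  g <- .mol_graph(mol)
  n <- nrow(g$atoms)
  if (n == 0L) return(fingerprint(integer(0), kind = kind, nbits = nbits))
  imph <- .mol_imph(mol)
  ringinfo <- .mol_rings(mol)
  arom <- .mol_aromatic(mol)
  adj <- .adjacency(g)
  # bond code per bond: aromatic bonds get their own class
  bcode <- ifelse(arom$bond, 4L, g$bonds$order)
  bond_of <- rep(list(integer(0)), n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
      bond_of[[a]] <- c(bond_of[[a]], k)
      bond_of[[b]] <- c(bond_of[[b]], k)
    }
  }
  inv <- if (feat) .fcfp_invariants(g, imph, arom, ringinfo)
         else .ecfp_invariants(g, imph, ringinfo)
  feats <- inv
  for (r in seq_len(radius)) {
    newinv <- numeric(n)
    for (i in seq_len(n)) {
      ks <- bond_of[[i]]
      if (length(ks)) {
        nb <- ifelse(g$bonds$a1[ks] == i, g$bonds$a2[ks], g$bonds$a1[ks])
        o <- order(bcode[ks], inv[nb])
        msg <- c(r, inv[i], rbind(bcode[ks][o], inv[nb][o]))
      } else msg <- c(r, inv[i])
      newinv[i] <- .hash_ints(msg)
    }
    inv <- newinv
    feats <- c(feats, inv)
  }
  fingerprint(as.integer(unique(feats) %% nbits), kind = kind, nbits = nbits)
}

.ecfp_invariants <- function(g, imph, ringinfo) {
  z <- .ATOMIC_NUMBER[g$atoms$elem]
  z[is.na(z)] <- 99
  deg <- .heavy_degree(g)
  vapply(seq_len(nrow(g$atoms)), function(i)
    .hash_ints(c(z[i], deg[i], imph[i], g$atoms$charge[i] + 8,
                 as.integer(ringinfo$atom_in_ring[i]))), 0)
}

# FCFP feature code: 6 bits (donor, acceptor, basic, acidic, aromatic, halogen)
.fcfp_invariants <- function(g, imph, arom, ringinfo) {
  n <- nrow(g$atoms)
  el <- g$atoms$elem
  adj <- .adjacency(g)
  has_double_to_O <- logical(n) # atom carries =O (or =S) — carbonyl-like
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      if (g$bonds$order[k] == 2L) {
        a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
        if (el[b] %in% c("O", "S")) has_double_to_O[a] <- TRUE
        if (el[a] %in% c("O", "S")) has_double_to_O[b] <- TRUE
      }
    }
  }
  max_order <- numeric(n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
      max_order[a] <- max(max_order[a], g$bonds$order[k])
      max_order[b] <- max(max_order[b], g$bonds$order[k])
    }
  }
  codes <- numeric(n)
  for (i in seq_len(n)) {
    donor <- el[i] %in% c("N", "O") && imph[i] >= 1L
    acceptor <- el[i] == "O" || (el[i] == "N" && !(arom$atom[i] && imph[i] >= 1L))
    acidic <- el[i] == "O" && imph[i] >= 1L &&
      any(has_double_to_O[adj[[i]]])
    basic <- el[i] == "N" && !arom$atom[i] && max_order[i] <= 1 &&
      !any(has_double_to_O[adj[[i]]])
    halogen <- el[i] %in% c("F", "Cl", "Br", "I")
    codes[i] <- as.integer(donor) + 2L * as.integer(acceptor) +
      4L * as.integer(basic) + 8L * as.integer(acidic) +
      16L * as.integer(arom$atom[i]) + 32L * as.integer(halogen)
  }
  codes
}

.check_fp_pair <- function(a, b) {
  if (!inherits(a, "fingerprint") || !inherits(b, "fingerprint"))
    stop("expected fingerprint objects", call. = FALSE)
  if (a$kind != b$kind) stop("fingerprint kinds differ", call. = FALSE)
  if (a$nbits != b$nbits) stop("fingerprint lengths differ", call. = FALSE)
}

#' Tanimoto similarity and distance between fingerprints
#'
#' Similarity is the Jaccard coefficient on on-bit sets,
#' \eqn{|A \cap B| / |A \cup B|}; distance is its complement, so
#' `tanimoto_similarity(a, b) + tanimoto_distance(a, b) == 1` always.
#' Two empty fingerprints are identical objects: similarity 1, distance 0.
#'
#' @param a,b Fingerprints of the same kind and folded length.
#' @return A number in \eqn{[0, 1]}.
#' @export
tanimoto_similarity <- function(a, b) {
  .check_fp_pair(a, b)
  na <- length(a$bits); nb <- length(b$bits)
  if (na == 0L && nb == 0L) return(1)
  inter <- length(intersect(a$bits, b$bits))
  inter / (na + nb - inter)
}

#' @rdname tanimoto_similarity
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto_similarity(a, b)

#' Tanimoto similarity between two molecules
#'
#' Convenience wrapper computing fingerprints of the requested kind first.
#'
#' @param mol1,mol2 Valid molecules.
#' @inheritParams compute_fingerprint
#' @return Tanimoto similarity in \eqn{[0, 1]}.
#' @export
mol_similarity <- function(mol1, mol2, kind = "ECFP4", nbits = 2048L) {
  tanimoto_similarity(compute_fingerprint(mol1, kind, nbits),
                      compute_fingerprint(mol2, kind, nbits))
}

# Dense logical matrix of fingerprints (rows = molecules) for fast pairwise
# Tanimoto computations.
.fp_matrix <- function(fps) {
  nbits <- fps[[1L]]$nbits
  M <- matrix(FALSE, nrow = length(fps), ncol = nbits)
  for (i in seq_along(fps)) M[i, fps[[i]]$bits + 1L] <- TRUE
  M
}

# Pairwise Tanimoto similarity matrix from a list of fingerprints.
.pairwise_tanimoto <- function(fps) {
  n <- length(fps)
  M <- .fp_matrix(fps)
  storage.mode(M) <- "numeric"
  inter <- tcrossprod(M)
  sizes <- rowSums(M)
  uni <- outer(sizes, sizes, "+") - inter
  S <- ifelse(uni == 0, 1, inter / pmax(uni, .Machine$double.eps))
  diag(S) <- 1
  S
}
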