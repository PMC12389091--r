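# Descriptor computation and score modifiers.
#
# Raw descriptors come from OpenBabel (TPSA, Crippen-type logP, average
# molecular weight, fluorine count, H-bond donors/acceptors) or from the
# molecular graph (rotatable bonds, aromatic rings). Modifiers map raw
# values to desirabilities in [0, 1] following the GuacaMol conventions:
# Gaussian peak, one-sided Gaussian plateaus, and a capped linear threshold.

.DESCRIPTOR_KINDS <- c("TPSA", "logP", "molecular_weight", "n_rotatable_bonds",
                       "n_aromatic_rings", "n_fluorine", "QED", "CNS")

#' Compute a molecular descriptor
#'
#' @param mol A valid `molecule`.
#' @param kind One of `"TPSA"`, `"logP"`, `"molecular_weight"`,
#'   `"n_rotatable_bonds"`, `"n_aromatic_rings"`, `"n_fluorine"`, `"QED"`,
#'   `"CNS"`. `CNS` delegates to the pluggable scorer registered under
#'   `options(molega.cns_scorer = )` (a CNS-MPO-style desirability average by
#'   default).
#' @return A numeric scalar. Counts are returned as non-negative reals.
#' @export
compute_descriptor <- function(mol, kind) {
  kind <- match.arg(kind, .DESCRIPTOR_KINDS)
  if (!is_valid(mol)) stop("invalid molecule", call. = FALSE)
  switch(kind,
    TPSA = unname(.mol_props(mol)[["TPSA"]]),
    logP = unname(.mol_props(mol)[["logP"]]),
    molecular_weight = unname(.mol_props(mol)[["MW"]]),
    n_fluorine = unname(.mol_props(mol)[["nF"]]),
    n_rotatable_bonds = .n_rotatable_bonds(mol),
    n_aromatic_rings = .n_aromatic_rings(mol),
    QED = .qed_score(mol),
    CNS = {
      scorer <- getOption("molega.cns_scorer", default_cns_scorer)
      as.numeric(scorer(mol))
    })
}

# Rotatable bonds: single, acyclic, both endpoints non-terminal heavy atoms,
# neither endpoint triple-bonded (the standard toolkit SMARTS, applied to
# the graph directly).
.n_rotatable_bonds <- function(mol) {
  g <- .mol_graph(mol)
  if (!nrow(g$bonds)) return(0)
  deg <- .heavy_degree(g)
  ringinfo <- .mol_rings(mol)
  rb_keys <- if (nrow(ringinfo$ring_bonds))
    paste(ringinfo$ring_bonds[, 1L], ringinfo$ring_bonds[, 2L], sep = "-")
  else character(0)
  tripled <- logical(nrow(g$atoms))
  trip <- g$bonds[g$bonds$order == 3L, , drop = FALSE]
  if (nrow(trip)) tripled[unique(c(trip$a1, trip$a2))] <- TRUE
  keys <- paste(pmin(g$bonds$a1, g$bonds$a2),
                pmax(g$bonds$a1, g$bonds$a2), sep = "-")
  rot <- g$bonds$order == 1L & !(keys %in% rb_keys) &
    deg[g$bonds$a1] > 1L & deg[g$bonds$a2] > 1L &
    !tripled[g$bonds$a1] & !tripled[g$bonds$a2]
  sum(rot)
}

.n_aromatic_rings <- function(mol) {
  ringinfo <- .mol_rings(mol)
  if (!length(ringinfo$rings)) return(0)
  arom <- .mol_aromatic(mol)
  g <- .mol_graph(mol)
  bond_keys <- paste(pmin(g$bonds$a1, g$bonds$a2),
                     pmax(g$bonds$a1, g$bonds$a2), sep = "-")
  ar_keys <- bond_keys[arom$bond]
  sum(vapply(ringinfo$rings, function(r)
    all(.ring_bond_keys(r) %in% ar_keys), TRUE))
}

# Drug-likeness desirability in the QED spirit: geometric mean of smooth
# desirability curves over MW, logP, HBA, HBD, TPSA, rotatable bonds and
# aromatic rings. The curves peak at typical oral-drug values; this is a
# documented approximation, not the published fitted curves (no structural
# alert term). See the methods vignette.
.qed_score <- function(mol) {
  p <- .mol_props(mol)
  d <- c(
    .desir_gauss(p[["MW"]], 300, 150),
    .desir_gauss(p[["logP"]], 2.5, 2.0),
    .desir_ramp(p[["HBA"]], 10, 4),
    .desir_ramp(p[["HBD"]], 5, 2),
    .desir_gauss(p[["TPSA"]], 80, 60),
    .desir_ramp(.n_rotatable_bonds(mol), 10, 4),
    .desir_gauss(.n_aromatic_rings(mol), 2, 1.5)
  )
  exp(mean(log(pmax(d, 1e-6))))
}

.desir_gauss <- function(x, mu, sigma) exp(-((x - mu)^2) / (2 * sigma^2))
# 1 up to `edge`, Gaussian decay beyond
.desir_ramp <- function(x, edge, sigma) ifelse(x <= edge, 1, .desir_gauss(x, edge, sigma))

#' Default CNS desirability scorer
#'
#' A central-nervous-system multi-parameter desirability in the CNS MPO
#' spirit: the average of piecewise-linear desirabilities for logP, molecular
#' weight, TPSA and H-bond donors (the pKa term is omitted because no charge
#' model is available), scaled to \eqn{[0, 1]}. Replace it with
#' `options(molega.cns_scorer = function(mol) ...)`.
#'
#' @param mol A valid `molecule`.
#' @return A number in \eqn{[0, 1]}.
#' @export
default_cns_scorer <- function(mol) {
  p <- .mol_props(mol)
  d_logp <- .lin_down(p[["logP"]], 3, 5)
  d_mw <- .lin_down(p[["MW"]], 360, 500)
  d_tpsa <- .hump(p[["TPSA"]], 20, 40, 90, 120)
  d_hbd <- .lin_down(p[["HBD"]], 0.5, 3.5)
  mean(c(d_logp, d_mw, d_tpsa, d_hbd))
}

.lin_down <- function(x, lo, hi) {
  if (x <= lo) 1 else if (x >= hi) 0 else (hi - x) / (hi - lo)
}
.hump <- function(x, a, b, c, d) {
  if (x <= a || x >= d) 0
  else if (x < b) (x - a) / (b - a)
  else if (x <= c) 1
  else (d - x) / (d - c)
}

# ---- modifiers ----------------------------------------------------------

.MODIFIER_KINDS <- c("Gaussian", "MinGaussian", "MaxGaussian", "ThresholdedLinear")

#' Score modifiers
#'
#' A modifier maps a raw property value to a desirability in \eqn{[0, 1]}:
#' \describe{
#'   \item{Gaussian}{\eqn{\exp(-(x-\mu)^2 / (2\sigma^2))}, peak 1 at \eqn{\mu}.}
#'   \item{MaxGaussian}{1 for \eqn{x \ge \mu}, Gaussian tail below (rewards
#'     large values).}
#'   \item{MinGaussian}{1 for \eqn{x \le \mu}, Gaussian tail above (rewards
#'     small values).}
#'   \item{ThresholdedLinear}{\eqn{\min(x, \mu)/\mu}; requires \eqn{\mu > 0}.}
#' }
#'
#' @param kind Modifier kind.
#' @param mu Target / threshold parameter.
#' @param sigma Width (> 0); unused for `ThresholdedLinear`.
#' @return A `modifier` object.
#' @export
modifier <- function(kind, mu, sigma = NA_real_) {
  kind <- match.arg(kind, .MODIFIER_KINDS)
  if (kind == "ThresholdedLinear") {
    if (!is.finite(mu) || mu <= 0)
      stop("ThresholdedLinear requires mu > 0", call. = FALSE)
  } else if (!is.finite(sigma) || sigma <= 0) {
    stop("Gaussian-family modifiers require sigma > 0", call. = FALSE)
  }
  structure(list(kind = kind, mu = mu, sigma = sigma), class = "modifier")
}

#' Apply a modifier to raw values
#'
#' @param m A `modifier`.
#' @param x Numeric vector of raw values.
#' @return Desirabilities in \eqn{[0, 1]}, same length as `x`.
#' @export
apply_modifier <- function(m, x) {
  stopifnot(inherits(m, "modifier"))
  if (m$kind == "ThresholdedLinear") return(pmin(pmax(pmin(x, m$mu) / m$mu, 0), 1))
  g <- exp(-((x - m$mu)^2) / (2 * m$sigma^2))
  out <- switch(m$kind,
    Gaussian = g,
    MaxGaussian = ifelse(x >= m$mu, 1, g),
    MinGaussian = ifelse(x <= m$mu, 1, g))
  pmin(pmax(out, 0), 1)
}

#' Geometric mean of a score vector
#'
#' Returns 0 if any entry is 0 (the fitness of an individual failing an
#' objective completely).
#'
#' @param scores Numeric vector in \eqn{[0,1]^n}, \eqn{n \ge 1}.
#' @return The geometric mean \eqn{(\prod s_i)^{1/n}}.
#' @export
geometric_mean <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  if (any(scores == 0)) return(0)
  exp(mean(log(scores)))
}
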