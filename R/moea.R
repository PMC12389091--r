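# Evolutionary core: Pareto dominance, fast non-dominated sorting,
# structure-aware (Tanimoto) crowding, the generation-dependent acceptance
# probability, and the population update. Three update modes:
#   mogata - Tanimoto crowding + stochastic acceptance-probability selection
#   mogat  - Tanimoto crowding, deterministic truncation (acceptance = 1)
#   nsga2  - classical objective-space crowding, deterministic truncation

#' Pareto dominance (maximization)
#'
#' `u` dominates `v` iff `u >= v` coordinate-wise with strict improvement in
#' at least one coordinate.
#'
#' @param u,v Numeric score vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v)) stop("score vectors differ in length", call. = FALSE)
  all(u >= v) && any(u > v)
}

#' Fast non-dominated sorting
#'
#' Partitions score vectors (rows of `scores`) into Pareto fronts: front 1 is
#' the non-dominated set, front k+1 the non-dominated set after removing
#' fronts 1..k.
#'
#' @param scores Numeric matrix, one row per individual, maximization on
#'   every column.
#' @return List of integer vectors (row indices), in front order. Empty input
#'   gives an empty list.
#' @export
fast_nondominated_sort <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  n <- nrow(scores)
  if (n == 0L) return(list())
  ge <- matrix(TRUE, n, n); gt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(scores))) {
    cj <- scores[, j]
    d <- outer(cj, cj, "-")
    ge <- ge & (d >= 0)
    gt <- gt | (d > 0)
  }
  dom <- ge & gt            # dom[i, j]: i dominates j
  n_dominators <- colSums(dom)
  fronts <- list()
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    fr <- which(remaining & n_dominators == 0L)
    if (!length(fr)) stop("internal error: cyclic dominance", call. = FALSE)
    fronts[[length(fronts) + 1L]] <- fr
    remaining[fr] <- FALSE
    if (any(remaining)) {
      drop <- colSums(dom[fr, , drop = FALSE])
      n_dominators <- n_dominators - drop
    }
  }
  fronts
}

#' Structure-based crowding: mean Tanimoto distance to front mates
#'
#' For each member of a front, the crowding value is the mean Tanimoto
#' distance between its fingerprint and every other member of the same
#' front. A singleton front gets crowding 1 (maximally isolated). Larger
#' values mark structurally more isolated molecules.
#'
#' @param x A list of `molecule`s or a list of `fingerprint`s (one front).
#' @param fp_kind,nbits Fingerprint parameters used when `x` holds molecules.
#' @return Numeric vector of crowding values in \eqn{[0, 1]}.
#' @export
tanimoto_crowding <- function(x, fp_kind = "ECFP4", nbits = 2048L) {
  if (!length(x)) stop("empty front", call. = FALSE)
  fps <- if (inherits(x[[1L]], "fingerprint")) x
         else lapply(x, compute_fingerprint, kind = fp_kind, nbits = nbits)
  n <- length(fps)
  if (n == 1L) return(1)
  S <- .pairwise_tanimoto(fps)
  D <- 1 - S
  rowSums(D) / (n - 1)
}

#' Classical NSGA-II objective-space crowding distance
#'
#' Per objective, members of a front are sorted; boundary members get
#' infinite crowding and interior members the normalized gap between their
#' neighbors, summed over objectives.
#'
#' @param scores Numeric matrix of the front's score vectors (rows).
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
objective_crowding <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  n <- nrow(scores)
  if (n == 0L) stop("empty front", call. = FALSE)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (j in seq_len(ncol(scores))) {
    o <- order(scores[, j])
    rng <- scores[o[n], j] - scores[o[1L], j]
    cd[o[c(1L, n)]] <- Inf
    if (rng > 0) {
      gaps <- (scores[o[3:n], j] - scores[o[1:(n - 2L)], j]) / rng
      cd[o[2:(n - 1L)]] <- cd[o[2:(n - 1L)]] + gaps
    }
  }
  cd
}

#' Generation-dependent acceptance probability
#'
#' \eqn{p_a = \exp(-(1/g)^\beta)} for a 1-based generation counter `g`.
#' Strictly increasing in `g`, equal to \eqn{e^{-1}} at `g = 1` for any
#' \eqn{\beta}, and tending to 1.
#'
#' @param g Generation index (integer, \eqn{\ge 1}).
#' @param beta Decay-rate parameter (> 0), default 0.45.
#' @return Acceptance probability in \eqn{(0, 1]}.
#' @export
acceptance_probability <- function(g, beta = 0.45) {
  if (any(g < 1)) stop("generation counter is 1-based", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  exp(-(1 / g)^beta)
}

# ---- population container -------------------------------------------------

#' Create a population
#'
#' A population couples molecules with their objective-score matrix, fitness
#' (geometric mean of scores), Pareto rank and crowding values, plus a fixed
#' capacity used by [update_population()].
#'
#' @param molecules List of `molecule`s.
#' @param scores Numeric matrix (rows = molecules) in \eqn{[0,1]}.
#' @param capacity Target population size N (default: number of molecules).
#' @return A `molega_pop`.
#' @export
new_population <- function(molecules, scores, capacity = length(molecules)) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = length(molecules))
  stopifnot(length(molecules) == nrow(scores))
  structure(list(molecules = molecules,
                 scores = scores,
                 fitness = apply(scores, 1L, geometric_mean),
                 rank = rep(NA_integer_, length(molecules)),
                 crowding = rep(NA_real_, length(molecules)),
                 capacity = as.integer(capacity)),
            class = "molega_pop")
}

#' @export
length.molega_pop <- function(x) length(x$molecules)

#' @export
print.molega_pop <- function(x, ...) {
  cat("<population> ", length(x), " members, ",
      ncol(x$scores), " objectives, capacity ", x$capacity, "\n", sep = "")
  invisible(x)
}

#' Score molecules into a population
#'
#' @param molecules List of `molecule`s.
#' @param task A `mol_task`.
#' @param capacity Population capacity (defaults to the number of molecules).
#' @return A `molega_pop` with ranks assigned (crowding left `NA`).
#' @export
score_population <- function(molecules, task, capacity = length(molecules)) {
  scores <- do.call(rbind, lapply(molecules, score_molecule, task = task))
  pop <- new_population(molecules, scores, capacity)
  fronts <- fast_nondominated_sort(pop$scores)
  for (k in seq_along(fronts)) pop$rank[fronts[[k]]] <- k - 1L
  pop
}

#' Fitness-proportional parent selection
#'
#' Draws `k` parents with replacement, with probability proportional to
#' fitness (geometric-mean score), floored at `eps` so an all-zero
#' population still yields a valid (uniform) wheel.
#'
#' @param pop A `molega_pop`.
#' @param k Number of draws (> 0).
#' @param eps Fitness floor (default 1e-6).
#' @return Integer vector of selected member indices.
#' @export
select_parents <- function(pop, k, eps = 1e-6) {
  stopifnot(inherits(pop, "molega_pop"))
  if (length(pop) == 0L) stop("empty population", call. = FALSE)
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  w <- pmax(pop$fitness, eps)
  sample.int(length(pop), size = k, replace = TRUE, prob = w)
}

# ---- population update -----------------------------------------------------

#' Merge parents and offspring and select the next generation
#'
#' Implements the elitist population update: parents and offspring are
#' merged, non-dominated sorted, and whole fronts are carried over while
#' they fit. The first front that would overflow ("splitting front") is
#' sorted by crowding in descending order; in `mogata` mode the remaining
#' slots are filled by one Bernoulli pass with the generation-dependent
#' acceptance probability over that order, topped up deterministically from
#' the rejected members (again in crowding order) if the pass leaves slots
#' unfilled. `mogat` uses the same Tanimoto crowding with acceptance
#' probability 1 (deterministic truncation); `nsga2` uses classical
#' objective-space crowding with deterministic truncation. Crowding ties are
#' broken by higher fitness, then stable input order.
#'
#' @param parents A `molega_pop` at capacity N.
#' @param offspring A `molega_pop` (or list with `molecules` and `scores`).
#' @param g Generation counter (1-based) for the acceptance probability.
#' @param mode `"mogata"`, `"mogat"`, or `"nsga2"`.
#' @param fp_kind,nbits Fingerprint parameters for Tanimoto crowding.
#' @param beta Acceptance-probability decay parameter.
#' @return A `molega_pop` with exactly N members, ranks and crowding set.
#' @export
update_population <- function(parents, offspring, g,
                              mode = c("mogata", "mogat", "nsga2"),
                              fp_kind = "ECFP4", nbits = 2048L, beta = 0.45) {
  mode <- match.arg(mode)
  stopifnot(inherits(parents, "molega_pop"))
  N <- parents$capacity
  mols <- c(parents$molecules, offspring$molecules)
  scores <- rbind(parents$scores, offspring$scores)
  if (length(mols) < N) stop("merged pool smaller than capacity", call. = FALSE)
  fitness <- apply(scores, 1L, geometric_mean)
  fronts <- fast_nondominated_sort(scores)
  rank_all <- integer(length(mols))
  crowd_all <- numeric(length(mols))
  sel <- integer(0)
  for (k in seq_along(fronts)) {
    f <- fronts[[k]]
    rank_all[f] <- k - 1L
    crowd <- if (mode == "nsga2") objective_crowding(scores[f, , drop = FALSE])
             else tanimoto_crowding(mols[f], fp_kind = fp_kind, nbits = nbits)
    crowd_all[f] <- crowd
    if (length(sel) + length(f) <= N) {
      sel <- c(sel, f)
      if (length(sel) == N) break
    } else {
      slots <- N - length(sel)
      ord <- f[order(-crowd, -fitness[f], seq_along(f))]
      p_a <- if (mode == "mogata") acceptance_probability(g, beta) else 1
      take <- if (p_a >= 1) {
        ord[seq_len(slots)]
      } else {
        accepted <- ord[stats::runif(length(ord)) < p_a]
        if (length(accepted) >= slots) accepted[seq_len(slots)]
        else c(accepted, setdiff(ord, accepted)[seq_len(slots - length(accepted))])
      }
      sel <- c(sel, take)
      break
    }
  }
  out <- new_population(mols[sel], scores[sel, , drop = FALSE], capacity = N)
  out$fitness <- fitness[sel]
  out$rank <- rank_all[sel]
  out$crowding <- crowd_all[sel]
  out
}
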