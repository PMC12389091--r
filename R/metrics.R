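# Run-level evaluation metrics: hypervolume against the origin, success
# rate, geometric-mean summary and internal similarity of a population.

# Keep only non-dominated rows (maximization); used to prune HV recursion.
.pareto_filter <- function(P) {
  n <- nrow(P)
  if (n <= 1L) return(P)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (all(P[j, ] >= P[i, ]) && any(P[j, ] > P[i, ])) { keep[i] <- FALSE; break }
    }
  }
  P[keep, , drop = FALSE]
}

#' Hypervolume dominated by a point set (origin reference)
#'
#' Lebesgue measure of the union of axis-aligned boxes \eqn{[0, p]} over the
#' given points, i.e. the volume of objective space dominated by the set
#' relative to the origin. With all objectives in \eqn{[0,1]} the value lies
#' in \eqn{[0,1]}. Exact recursive dimension-sweep for up to 5 objectives;
#' Monte Carlo estimation above (1e6 samples). Dominated points are allowed
#' and contribute nothing.
#'
#' @param points Numeric matrix of score vectors (rows), all in \eqn{[0,1]};
#'   a vector is taken as a single point.
#' @return The hypervolume (0 for an empty set).
#' @export
hypervolume <- function(points) {
  if (is.null(points) || length(points) == 0L) return(0)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (any(points < 0) || any(points > 1))
    stop("points must lie in [0,1] for the origin reference", call. = FALSE)
  if (nrow(points) == 0L) return(0)
  points <- unique(points)
  if (ncol(points) > 5L) return(.hv_montecarlo(points))
  .hv_exact(.pareto_filter(points))
}

.hv_exact <- function(P) {
  m <- ncol(P)
  if (nrow(P) == 0L) return(0)
  if (m == 1L) return(max(P[, 1L]))
  if (m == 2L) {
    o <- order(P[, 2L], decreasing = TRUE)
    ys <- c(P[o, 2L], 0)
    xmax <- cummax(P[o, 1L])
    return(sum((ys[-length(ys)] - ys[-1L]) * xmax))
  }
  o <- order(P[, m], decreasing = TRUE)
  P <- P[o, , drop = FALSE]
  z <- c(P[, m], 0)
  vol <- 0
  for (k in seq_len(nrow(P))) {
    depth <- z[k] - z[k + 1L]
    if (depth > 0) {
      proj <- .pareto_filter(P[seq_len(k), -m, drop = FALSE])
      vol <- vol + depth * .hv_exact(proj)
    }
  }
  vol
}

.hv_montecarlo <- function(P, n_samples = 1e6) {
  m <- ncol(P)
  X <- matrix(stats::runif(n_samples * m), ncol = m)
  hit <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(P))) {
    dom <- rep(TRUE, n_samples)
    for (j in seq_len(m)) dom <- dom & (X[, j] <= P[i, j])
    hit <- hit | dom
  }
  mean(hit)
}

#' Success rate of a population
#'
#' Fraction of members whose raw objective values satisfy every success
#' window of the task (see [check_success()]).
#'
#' @param pop A `molega_pop`.
#' @param task A `mol_task`.
#' @return A number in \eqn{[0, 1]}.
#' @export
success_rate <- function(pop, task) {
  stopifnot(inherits(pop, "molega_pop"))
  if (length(pop) == 0L) stop("empty population", call. = FALSE)
  mean(vapply(pop$molecules, function(m) as.logical(check_success(m, task)), TRUE))
}

#' Internal similarity of a population
#'
#' Default: mean pairwise Tanimoto similarity over all unordered pairs.
#' `method = "extended"` instead uses an n-ary coincidence index computed
#' column-wise on the fingerprint matrix: for each bit, the fraction of the
#' larger side of the population that agrees (on or off), linearly rescaled
#' from \eqn{[1/2, 1]} to \eqn{[0, 1]} and averaged over bits that are on in
#' at least one molecule.
#'
#' @param pop A `molega_pop`, a list of molecules, or a list of
#'   fingerprints; at least 2 members.
#' @param fp_kind,nbits Fingerprint parameters (default ECFP4/2048), used
#'   when fingerprints must be computed.
#' @param method `"pairwise"` (default) or `"extended"`.
#' @return A number in \eqn{[0, 1]}.
#' @export
internal_similarity <- function(pop, fp_kind = "ECFP4", nbits = 2048L,
                                method = c("pairwise", "extended")) {
  method <- match.arg(method)
  mols <- if (inherits(pop, "molega_pop")) pop$molecules else pop
  if (length(mols) < 2L) stop("need at least 2 members", call. = FALSE)
  fps <- if (inherits(mols[[1L]], "fingerprint")) mols
         else lapply(mols, compute_fingerprint, kind = fp_kind, nbits = nbits)
  if (method == "pairwise") {
    S <- .pairwise_tanimoto(fps)
    return(mean(S[upper.tri(S)]))
  }
  M <- .fp_matrix(fps)
  n <- nrow(M)
  on <- colSums(M)
  used <- on > 0L
  if (!any(used)) return(1)
  agree <- pmax(on[used], n - on[used]) / n
  mean(2 * agree - 1)
}

#' Summarize a generation
#'
#' Hypervolume of the rank-0 (Pareto) front, success rate and internal
#' similarity of the whole population, and the maximum geometric-mean
#' fitness.
#'
#' @param pop A scored and ranked `molega_pop`.
#' @param task The `mol_task`.
#' @param g Generation index to record.
#' @param fp_kind,nbits Fingerprint parameters for internal similarity.
#' @return A one-row `data.frame`: generation, hv, success_rate, max_gm,
#'   internal_similarity, n_valid, n_unique.
#' @export
summarize_generation <- function(pop, task, g, fp_kind = "ECFP4", nbits = 2048L) {
  stopifnot(inherits(pop, "molega_pop"))
  front0 <- which(pop$rank == 0L)
  hv <- hypervolume(pop$scores[front0, , drop = FALSE])
  smi <- vapply(pop$molecules, function(m) if (is_valid(m)) mol_smiles(m) else NA, "")
  data.frame(
    generation = as.integer(g),
    hv = hv,
    success_rate = success_rate(pop, task),
    max_gm = max(pop$fitness),
    internal_similarity = if (length(pop) >= 2L)
      internal_similarity(pop, fp_kind, nbits) else 1,
    n_valid = sum(!is.na(smi)),
    n_unique = length(unique(smi[!is.na(smi)]))
  )
}
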