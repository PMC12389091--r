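test_that("Pareto dominance definition", {
  expect_true(dominates(c(0.9, 0.9), c(0.5, 0.5)))
  expect_false(dominates(c(0.5, 0.5), c(0.5, 0.5)))   # no strict improvement
  expect_false(dominates(c(0.9, 0.4), c(0.5, 0.5)))   # incomparable ...
  expect_false(dominates(c(0.5, 0.5), c(0.9, 0.4)))   # ... both ways
  expect_true(dominates(c(1, 0.5), c(1, 0.4)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)))
})

test_that("fast non-dominated sorting: structure and oracle agreement", {
  # mutually non-dominated set -> one front
  s <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  expect_length(fast_nondominated_sort(s), 1L)
  # dominance chain -> singleton fronts in order
  s <- rbind(c(0.9, 0.9), c(0.5, 0.5), c(0.1, 0.1))
  fr <- fast_nondominated_sort(s)
  expect_identical(fr, list(1L, 2L, 3L))
  expect_identical(fast_nondominated_sort(matrix(0, 0, 3)), list())
  # random instances vs the brute-force oracle
  set.seed(2024)
  for (rep in 1:20) {
    n <- sample(5:30, 1L); m <- sample(2:4, 1L)
    sc <- matrix(stats::runif(n * m), ncol = m)
    got <- fast_nondominated_sort(sc)
    want <- bruteforce_fronts(sc)
    expect_identical(lapply(got, sort), lapply(want, sort))
    # partition property
    expect_identical(sort(unlist(got)), seq_len(n))
  }
})

test_that("Tanimoto crowding equals the mean distance to front mates", {
  # pairwise distances d(A,B)=0.5, d(A,C)=1, d(B,C)=0.5 by construction
  A <- fingerprint(c(1, 2)); B <- fingerprint(c(1, 2, 3, 4)); C <- fingerprint(c(3, 4))
  expect_equal(tanimoto_distance(A, B), 0.5)
  expect_equal(tanimoto_distance(A, C), 1.0)
  expect_equal(tanimoto_distance(B, C), 0.5)
  expect_equal(tanimoto_crowding(list(A, B, C)), c(0.75, 0.5, 0.75))
  # identical fingerprints crowd each other completely
  expect_equal(tanimoto_crowding(list(A, A)), c(0, 0))
  # singleton front is maximally isolated by convention
  expect_equal(tanimoto_crowding(list(A)), 1)
  expect_error(tanimoto_crowding(list()))
  # random fronts agree with the double-loop oracle
  set.seed(31)
  for (rep in 1:10) {
    fps <- replicate(sample(2:12, 1L), random_fingerprint(), simplify = FALSE)
    expect_equal(tanimoto_crowding(fps), bruteforce_crowding(fps),
                 tolerance = 1e-12)
  }
})

test_that("acceptance probability: closed form, monotonicity, bounds", {
  for (beta in c(0.1, 0.45, 2)) {
    expect_equal(acceptance_probability(1, beta), exp(-1), tolerance = 1e-12)
  }
  p <- acceptance_probability(1:200, 0.45)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > exp(-1) - 1e-12 & p < 1))
  expect_gt(acceptance_probability(10), acceptance_probability(2))
  expect_error(acceptance_probability(0))
  expect_error(acceptance_probability(5, beta = -1))
})

test_that("fitness-proportional parent selection", {
  expect_error(select_parents(mini_population(c(0.5, 0.5)), 0))
  set.seed(7)
  # equal fitness -> uniform within Monte Carlo error
  idx <- select_parents(mini_population(rep(0.4, 4)), 2e4)
  expect_true(all(abs(tabulate(idx, 4) / 2e4 - 0.25) < 0.02))
  # 0.2 : 0.8 -> 1 : 4 within 3 sigma of the binomial error
  idx <- select_parents(mini_population(c(0.2, 0.8)), 1e5)
  phat <- mean(idx == 2L)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 1e5))
  # the epsilon floor keeps zero-fitness individuals selectable but rare
  idx <- select_parents(mini_population(c(0.9, 0, 0)), 1e4)
  expect_gt(mean(idx == 1L), 0.999)
})

test_that("population update: capacity, whole-front elitism, modes", {
  set.seed(123)
  n_obj <- 3L
  mk <- function(n) {
    fps <- replicate(n, random_fingerprint(), simplify = FALSE)
    mols <- lapply(fps, function(fp) {
      e <- new.env(parent = emptyenv()); e$fps <- list(ECFP4_256 = fp)
      structure(list(smiles = paste(fp$bits, collapse = ","), valid = TRUE,
                     input = "", data = e), class = "molecule")
    })
    new_population(mols, matrix(stats::runif(n * n_obj), ncol = n_obj),
                   capacity = n)
  }
  parents <- mk(20); offspring <- mk(20)
  parents$capacity <- 20L
  for (mode in c("mogata", "mogat", "nsga2")) {
    set.seed(55)
    nxt <- update_population(parents, offspring, g = 3, mode = mode,
                             nbits = 256L)
    expect_length(nxt, 20L)
    expect_false(any(is.na(nxt$rank)))
    expect_false(any(is.na(nxt$crowding)))
    # whole fronts that fit are always carried: every selected rank-k member
    # implies no unselected member of a lower front
    merged_scores <- rbind(parents$scores, offspring$scores)
    fronts <- fast_nondominated_sort(merged_scores)
    sel_smiles <- vapply(nxt$molecules, `[[`, "", "smiles")
    all_smiles <- vapply(c(parents$molecules, offspring$molecules), `[[`, "", "smiles")
    picked <- which(all_smiles %in% sel_smiles)
    cum <- 0L
    for (f in fronts) {
      if (cum + length(f) <= 20L) {
        expect_true(all(f %in% picked))
        cum <- cum + length(f)
      } else break
    }
  }
  # pool <= capacity keeps everything
  small <- mk(8); small$capacity <- 20L
  kept <- update_population(small, mk(12), g = 1, mode = "mogat", nbits = 256L)
  expect_length(kept, 20L)
  # capacity above merged pool errors
  small2 <- mk(5); small2$capacity <- 50L
  expect_error(update_population(small2, mk(5), g = 1, nbits = 256L))
})

test_that("mogat equals deterministic truncation; mogata converges to it", {
  set.seed(9)
  mkfp <- function() random_fingerprint()
  n <- 15L
  fps <- replicate(2L * n, mkfp(), simplify = FALSE)
  mols <- lapply(fps, function(fp) {
    e <- new.env(parent = emptyenv()); e$fps <- list(ECFP4_256 = fp)
    structure(list(smiles = paste(fp$bits, collapse = ","), valid = TRUE,
                   input = "", data = e), class = "molecule")
  })
  scores <- matrix(stats::runif(2L * n * 2L), ncol = 2L)
  parents <- new_population(mols[1:n], scores[1:n, ], capacity = n)
  offspring <- new_population(mols[(n + 1L):(2L * n)], scores[(n + 1L):(2L * n), ])
  # at huge g the acceptance probability is ~1: mogata == mogat, same seed
  set.seed(77)
  a <- update_population(parents, offspring, g = 1e9, mode = "mogata", nbits = 256L)
  set.seed(77)
  b <- update_population(parents, offspring, g = 1e9, mode = "mogat", nbits = 256L)
  expect_identical(vapply(a$molecules, `[[`, "", "smiles"),
                   vapply(b$molecules, `[[`, "", "smiles"))
  # mogat output equals classical rank + crowding truncation (multiset)
  fronts <- fast_nondominated_sort(scores)
  fitness <- apply(scores, 1L, geometric_mean)
  want <- integer(0)
  for (f in fronts) {
    if (length(want) + length(f) <= n) want <- c(want, f)
    else {
      cr <- tanimoto_crowding(mols[f], nbits = 256L)
      ord <- f[order(-cr, -fitness[f], seq_along(f))]
      want <- c(want, ord[seq_len(n - length(want))])
      break
    }
  }
  expect_setequal(vapply(b$molecules, `[[`, "", "smiles"),
                  vapply(mols[want], `[[`, "", "smiles"))
})
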