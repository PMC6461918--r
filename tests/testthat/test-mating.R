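# Cross-level objectives, plan evaluation, and the mating-plan search.

make_inbred_fixture <- function(m = 4, n = 10, seed = 1, n_chrom = 2) {
  set.seed(seed)
  map <- uniform_map(n / n_chrom, n_chrom)
  G <- rand_genotypes(m, n, inbred = TRUE, map = map)
  E <- marker_effects(cbind(rnorm(n), rnorm(n)))
  list(G = G, E = E, A = compute_relationship(G))
}

test_that("cross gain is the mid-parent value", {
  fx <- make_inbred_fixture(seed = 2)
  v <- genetic_values(fx$G, fx$E)$values
  expect_equal(cross_gain(fx$G, fx$E, 1, 2, 1), (v[1, 1] + v[2, 1]) / 2)
  expect_equal(cross_gain(fx$G, fx$E, 3, 3, 2), v[3, 2])  # selfing
  expect_error(cross_gain(fx$G, fx$E, 1, 99), "invalid")
})

test_that("closed-form cross variance matches exhaustive progeny enumeration", {
  set.seed(3)
  n <- 10
  di <- sample(c(0, 2), n, TRUE)
  dj <- sample(c(0, 2), n, TRUE)
  dj[1] <- di[1]  # guarantee at least one shared locus
  G <- genotype_matrix(rbind(di, dj), map = uniform_map(n))
  beta <- rnorm(n)
  E <- marker_effects(matrix(beta))
  got <- cross_variance(G, E, 1, 2, 1)
  # enumerate all 2^s fixed progeny at the segregating loci
  seg <- which(di != dj)
  combos <- as.matrix(expand.grid(rep(list(0:1), length(seg))))
  vals <- apply(combos, 1, function(pick) {
    d <- di
    d[seg] <- ifelse(pick == 1, dj[seg], di[seg])
    sum(d * beta)
  })
  expect_equal(got, mean(vals^2) - mean(vals)^2, tolerance = 1e-10)
  # trivial cases
  expect_equal(cross_variance(G, E, 1, 1, 1), 0)
  G1 <- genotype_matrix(rbind(c(0, 2), c(2, 2)), map = uniform_map(2))
  E1 <- marker_effects(matrix(c(0.5, 1), 2))
  expect_equal(cross_variance(G1, E1, 1, 2, 1), 0.25)
  Ghet <- genotype_matrix(rbind(c(1, 0), c(0, 2)), map = uniform_map(2))
  expect_error(cross_variance(Ghet, E1, 1, 2, 1), "inbred")
})

test_that("simulated cross variance agrees with the unlinked closed form in the limit", {
  set.seed(4)
  n <- 10
  # each locus on its own chromosome: effectively unlinked
  map <- uniform_map(1, n_chrom = n)
  map$pos <- rep(0.5, n)
  di <- sample(c(0, 2), n, TRUE); dj <- sample(c(0, 2), n, TRUE)
  G <- genotype_matrix(rbind(di, dj), map = map)
  E <- marker_effects(matrix(rnorm(n)))
  closed <- cross_variance(G, E, 1, 2, 1)
  est <- simulated_cross_variance(G, E, 1, 2, 1, n_progeny = 4000, seed = 9)
  se <- closed * sqrt(2 / (4000 - 1))   # normal-approx SE of a sample variance
  expect_lt(abs(est - closed), 3 * se + 1e-12)
  expect_equal(simulated_cross_variance(G, E, 1, 1, 1, n_progeny = 50, seed = 1), 0)
})

test_that("complete linkage in repulsion shrinks the progeny variance", {
  # two coincident loci, parents in repulsion phase
  map <- data.frame(marker = c("a", "b"), chrom = 1, pos = c(0.5, 0.5))
  G <- genotype_matrix(rbind(c(2, 0), c(0, 2)), map = map)
  E <- marker_effects(matrix(c(1, 0.8)))
  closed <- cross_variance(G, E, 1, 2, 1)       # unlinked assumption
  est <- simulated_cross_variance(G, E, 1, 2, 1, n_progeny = 2000, seed = 5)
  expect_lt(est, closed)
  expect_equal(est, (2 * 1 - 2 * 0.8)^2 / 4, tolerance = 0.05)  # parental-only progeny
})

test_that("cross inbreeding equals parental kinship under the A scaling", {
  A <- matrix(c(2, 0.4, 0.4, 2), 2)
  expect_equal(cross_inbreeding(A, 1, 1), 1)    # selfing a fully inbred line
  expect_equal(cross_inbreeding(A, 1, 2), 0.2)
  expect_equal(cross_inbreeding(diag(2), 1, 2), 0)
  expect_error(cross_inbreeding(A, 1, 3), "invalid")
})

test_that("plan evaluation is a multiplicity-weighted mean, invariant to duplication", {
  fx <- make_inbred_fixture(m = 5, seed = 6)
  P1 <- mating_plan(rbind(c(1, 2)))
  o1 <- evaluate_plan(P1, fx$G, fx$E, fx$A)
  expect_equal(o1$gain[1], cross_gain(fx$G, fx$E, 1, 2, 1))
  expect_equal(o1$cross_variance[2], cross_variance(fx$G, fx$E, 1, 2, 2))
  expect_equal(o1$inbreeding, cross_inbreeding(fx$A$A, 1, 2))
  # duplication invariance and symmetry to cross/parent order
  P <- mating_plan(rbind(c(1, 2), c(4, 3), c(5, 5)))
  Pdup <- mating_plan(rbind(c(2, 1), c(2, 1), c(3, 4), c(3, 4), c(5, 5), c(5, 5)))
  o <- evaluate_plan(P, fx$G, fx$E, fx$A)
  odup <- evaluate_plan(Pdup, fx$G, fx$E, fx$A)
  expect_equal(o$gain, odup$gain)
  expect_equal(o$cross_variance, odup$cross_variance)
  expect_equal(o$inbreeding, odup$inbreeding)
  # loop oracle over crosses
  crosses <- list(c(1, 2), c(3, 4), c(5, 5))
  g1 <- mean(vapply(crosses, function(cr) cross_gain(fx$G, fx$E, cr[1], cr[2], 1), 0))
  expect_equal(o$gain[1], g1, tolerance = 1e-12)
  expect_true(all(o$cross_variance >= 0))
})

test_that("mating search recovers the exhaustive non-dominated plan set", {
  fx <- make_inbred_fixture(m = 3, n = 12, seed = 7)
  F <- search_mating_frontier(fx$G, fx$E, fx$A, n_crosses = 1,
                              search_opts = list(pop_size = 30, generations = 30),
                              seed = 11)
  # exhaustive oracle over all 6 unordered pairs (selfing included)
  pairs <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  objs <- t(apply(pairs, 1, function(pr) {
    o <- evaluate_plan(mating_plan(rbind(pr)), fx$G, fx$E, fx$A)
    c(o$gain, o$cross_variance, o$inbreeding)
  }))
  lev <- nondominated_sort(objs, maximize = c(rep(TRUE, 4), FALSE))$levels
  expected <- objs[lev == 1L, , drop = FALSE]
  got <- as.matrix(F)
  expect_equal(nrow(got), nrow(expected))
  # same objective vectors up to row order
  ord <- function(M) M[do.call(order, as.data.frame(M)), , drop = FALSE]
  expect_equal(ord(got), ord(expected), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("plan search handles clones and returns a mutually non-dominated archive", {
  set.seed(8)
  n <- 12
  row <- sample(c(0, 2), n, TRUE)
  Gc <- genotype_matrix(matrix(rep(row, 4), 4, n, byrow = TRUE),
                        map = uniform_map(n))
  E <- marker_effects(cbind(rnorm(n), rnorm(n)))
  Ac <- relationship_matrix(matrix(2, 4, 4))
  Fc <- search_mating_frontier(Gc, E, Ac, n_crosses = 2,
                               search_opts = list(pop_size = 20, generations = 10),
                               seed = 2)
  expect_equal(nrow(unique(round(as.matrix(Fc), 9))), 1L)
  fx <- make_inbred_fixture(m = 6, n = 14, seed = 9)
  F2 <- search_mating_frontier(fx$G, fx$E, fx$A, n_crosses = 2,
                               search_opts = list(pop_size = 40, generations = 25),
                               seed = 3)
  V <- as.matrix(F2)
  lev <- nondominated_sort(V, maximize = c(rep(TRUE, 4), FALSE))$levels
  expect_true(all(lev == 1L))
  # determinism given the seed
  F3 <- search_mating_frontier(fx$G, fx$E, fx$A, n_crosses = 2,
                               search_opts = list(pop_size = 40, generations = 25),
                               seed = 3)
  expect_identical(as.matrix(F2), as.matrix(F3))
})
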