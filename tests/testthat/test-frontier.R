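# Contribution-vector objectives, the scalarized QP, frontier tracing, and
# the legacy rho-constrained formulation.

test_that("gain and coancestry match naive loop oracles and closed forms", {
  set.seed(21)
  m <- 8
  bv <- breeding_values(matrix(rnorm(m * 2), m, 2))
  A <- compute_relationship(rand_genotypes(m, 50))$A
  cv <- random_simplex(1, m)[1, ]
  g_loop <- 0; for (i in 1:m) g_loop <- g_loop + cv[i] * bv$values[i, 2]
  expect_equal(gain(cv, bv, 2), g_loop, tolerance = 1e-12)
  r_loop <- 0
  for (i in 1:m) for (j in 1:m) r_loop <- r_loop + cv[i] * A[i, j] * cv[j]
  expect_equal(coancestry(cv, A), r_loop / 2, tolerance = 1e-12)
  # point mass and uniform closed forms
  e3 <- numeric(m); e3[3] <- 1
  expect_equal(gain(e3, bv, 1), bv$values[3, 1])
  expect_equal(coancestry(e3, A), A[3, 3] / 2)
  expect_equal(gain(rep(1 / m, m), bv, 1), mean(bv$values[, 1]))
  expect_equal(coancestry(rep(1 / m, m), diag(m)), 1 / (2 * m))
})

test_that("correlation-penalized matrix evaluates the scaling factor correctly", {
  A <- diag(3) + 0.1
  psi0 <- diag(2)
  expect_equal(unclass(penalized_quadratic_matrix(A, psi0)), 2 * A,
               ignore_attr = TRUE)
  psi_neg <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(unclass(penalized_quadratic_matrix(A, psi_neg)), 3 * A,
               ignore_attr = TRUE)
  psi3 <- matrix(-0.2, 3, 3); diag(psi3) <- 1
  out <- penalized_quadratic_matrix(A, psi3)
  expect_equal(attr(out, "factor"), 3 - 2 * (-0.6))
  # strongly positive correlations can push the factor non-positive (k = 3,
  # all pairwise 0.6: factor = 3 - 2 * 1.8 < 0)
  psi_pos <- matrix(0.6, 3, 3); diag(psi_pos) <- 1
  expect_error(penalized_quadratic_matrix(A, psi_pos), "fall back")
})

test_that("scalarized QP attains closed-form solutions at the weight extremes", {
  set.seed(31)
  m <- 6
  bv <- breeding_values(matrix(rnorm(m * 2), m, 2))
  # all weight on co-ancestry with Q = I: minimum-norm point is uniform
  s <- solve_scalarized_qp(bv, diag(m), c(0, 0, 1))
  expect_equal(s$contribution$c, rep(1 / m, m), tolerance = 1e-8)
  # all weight on trait 1: vertex at the arg-max individual
  s2 <- solve_scalarized_qp(bv, diag(m), c(1, 0, 0))
  expect_equal(which(s2$contribution$c == 1), unname(which.max(bv$values[, 1])))
  expect_error(solve_scalarized_qp(bv, diag(m), c(0, 0)), "weights")
  expect_error(solve_scalarized_qp(bv, diag(m), c(0, 0, 0)), "not all zero")
})

test_that("scalarized QP matches a dense simplex-grid oracle on small instances", {
  set.seed(41)
  for (rep in 1:4) {
    m <- 4
    bv <- breeding_values(matrix(rnorm(m * 2), m, 2))
    A <- compute_relationship(rand_genotypes(m, 60))$A
    w <- c(runif(2), runif(1, 0.2, 1))
    s <- solve_scalarized_qp(bv, A, w)
    val <- sum(w[1:2] * s$objectives$values[1:2]) - w[3] * s$objectives$values[3]
    oracle <- grid_qp_oracle(bv$values, A, w, resolution = 100L)
    expect_gte(val, oracle$value - 1e-4)   # solver at least as good as the grid
    expect_lte(oracle$value, val + 1e-8)   # grid can never beat the true optimum
    expect_lt(s$kkt, 1e-6)
  }
})

test_that("scalarized QP agrees with an independent QP solver", {
  skip_if_not_installed("pracma")
  set.seed(51)
  for (rep in 1:5) {
    m <- sample(5:15, 1)
    bv <- breeding_values(matrix(rnorm(m * 2), m, 2))
    A <- compute_relationship(rand_genotypes(m, 80))$A + diag(1e-6, m)
    w <- c(runif(2), runif(1, 0.3, 1))
    s <- solve_scalarized_qp(bv, A, w)
    ref <- pracma::quadprog(w[3] * A, -as.numeric(bv$values %*% w[1:2]),
                            Aeq = matrix(1, 1, m), beq = 1, lb = rep(0, m))
    obj <- function(x) sum(w[1:2] * (t(bv$values) %*% x)) - w[3] * sum(x * (A %*% x)) / 2
    expect_equal(obj(s$contribution$c), obj(ref$xmin), tolerance = 1e-6)
  }
})

test_that("traced frontiers are internally non-dominated and deterministic", {
  set.seed(61)
  m <- 10
  bv <- standardize(breeding_values(matrix(rnorm(m * 2), m, 2)))
  A <- compute_relationship(rand_genotypes(m, 100))
  F1 <- trace_frontier(bv, A, resolution = 11)
  F2 <- trace_frontier(bv, A, resolution = 11)
  expect_identical(as.matrix(F1), as.matrix(F2))   # bit-for-bit determinism
  V <- as.matrix(F1)
  dirs <- c(TRUE, TRUE, FALSE)
  for (i in seq_len(nrow(V))) for (j in seq_len(nrow(V))) {
    if (i != j)
      expect_false(dominates(objective_vector(V[i, ], dirs),
                             objective_vector(V[j, ], dirs)) &&
                   dominates(objective_vector(V[j, ], dirs),
                             objective_vector(V[i, ], dirs)))
  }
  lev <- nondominated_sort(V, maximize = dirs)$levels
  expect_true(all(lev == 1L))
  # objectives recomputable from the stored contributions
  for (s in F1$solutions) {
    expect_equal(s$objectives$values[1], gain(s$contribution, bv, 1), tolerance = 1e-8)
    expect_equal(s$objectives$values[3], coancestry(s$contribution, A$A), tolerance = 1e-8)
  }
})

test_that("frontier solutions survive a Monte-Carlo dominance challenge", {
  set.seed(71)
  m <- 5
  bv <- breeding_values(matrix(rnorm(m * 2), m, 2))
  A <- compute_relationship(rand_genotypes(m, 60))
  F <- trace_frontier(bv, A, resolution = 11)
  C <- random_simplex(10000, m)
  gains <- C %*% bv$values
  co <- rowSums((C %*% A$A) * C) / 2
  V <- as.matrix(F)
  for (i in seq_len(nrow(V))) {
    dominated <- gains[, 1] >= V[i, 1] & gains[, 2] >= V[i, 2] & co <= V[i, 3] &
      (gains[, 1] > V[i, 1] + 1e-9 | gains[, 2] > V[i, 2] + 1e-9 |
         co < V[i, 3] - 1e-9)
    expect_equal(sum(dominated), 0)
  }
})

test_that("k = 1 frontier endpoints and trade-off monotonicity hold", {
  set.seed(81)
  m <- 7
  b <- rnorm(m)
  bv <- breeding_values(matrix(b, m, 1))
  F <- trace_frontier(bv, diag(m), resolution = 21)
  V <- as.matrix(F)
  ord <- order(V[, 1])
  # ordered by gain, co-ancestry must also be non-decreasing (trade-off)
  expect_true(all(diff(V[ord, 2]) >= -1e-9))
  expect_equal(min(V[, 2]), 1 / (2 * m), tolerance = 1e-6)  # uniform endpoint
  expect_equal(max(V[, 1]), max(b), tolerance = 1e-8)       # best-individual endpoint
})

test_that("rho-constrained legacy QP agrees with the k = 1 frontier sweep", {
  set.seed(91)
  m <- 8
  b <- rnorm(m)
  bv <- breeding_values(matrix(b, m, 1))
  A <- compute_relationship(rand_genotypes(m, 80))
  # point-mass and uniform closed forms
  cv_max <- constrained_min_coancestry(b, A, max(b))
  expect_equal(which(cv_max$c > 1e-8), which.max(b))
  cv_mean <- constrained_min_coancestry(b, diag(m), mean(b))
  expect_equal(cv_mean$c, rep(1 / m, m), tolerance = 1e-7)
  expect_error(constrained_min_coancestry(b, A, max(b) + 1), "infeasible")
  # sweep rho; solutions must satisfy the gain constraint and be mutually
  # non-dominating with the traced frontier
  F <- trace_frontier(bv, A, resolution = 41)
  VF <- as.matrix(F)
  rhos <- seq(mean(b), max(b) - 1e-6, length.out = 9)
  for (rho in rhos) {
    cv <- constrained_min_coancestry(b, A, rho)
    expect_equal(sum(cv$c * b), rho, tolerance = 1e-6)
    pt <- c(sum(cv$c * b), coancestry(cv, A))
    strictly_better <- VF[, 1] > pt[1] + 1e-6 & VF[, 2] < pt[2] - 1e-6
    expect_equal(sum(strictly_better), 0)
  }
})

test_that("rescaling one trait rescales its gain axis and preserves the front", {
  set.seed(101)
  m <- 6
  X <- matrix(rnorm(m * 2), m, 2)
  A <- compute_relationship(rand_genotypes(m, 60))
  F1 <- trace_frontier(breeding_values(X), A, resolution = 11)
  X2 <- X; X2[, 1] <- 3 * X2[, 1]
  F2 <- trace_frontier(breeding_values(X2), A, resolution = 11)
  V1 <- as.matrix(F1); V2 <- as.matrix(F2)
  V2[, 1] <- V2[, 1] / 3
  # no solution of either front strictly dominates one of the other beyond
  # solver tolerance
  eps <- 1e-6
  strictly_dominates <- function(a, b)
    a[1] > b[1] + eps & a[2] > b[2] + eps & a[3] < b[3] - eps
  for (i in seq_len(nrow(V1))) for (j in seq_len(nrow(V2))) {
    expect_false(strictly_dominates(V1[i, ], V2[j, ]))
    expect_false(strictly_dominates(V2[j, ], V1[i, ]))
  }
})
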