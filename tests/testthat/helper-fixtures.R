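# Shared fixtures and independent oracles. All oracles here are deliberately
# naive (loops, enumeration, peeling) so they stay independent of the package
# implementation they check.

rand_genotypes <- function(m, n, inbred = FALSE, seed = NULL, map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- if (inbred) c(0, 2) else 0:2
  repeat {  # ensure at least one polymorphic marker
    M <- matrix(sample(vals, m * n, replace = TRUE), m, n)
    if (any(apply(M, 2, function(x) length(unique(x)) > 1))) break
  }
  genotype_matrix(M, map = map)
}

uniform_map <- function(n_per_chrom, n_chrom = 1, length_m = 1) {
  data.frame(marker = paste0("m", seq_len(n_per_chrom * n_chrom)),
             chrom = rep(seq_len(n_chrom), each = n_per_chrom),
             pos = rep(seq(0, length_m, length.out = n_per_chrom), n_chrom))
}

# O(n^2) repeated-peeling non-dominated sort (maximization orientation)
peel_sort_oracle <- function(V) {
  n <- nrow(V)
  lev <- rep(NA_integer_, n)
  current <- 1L
  remaining <- seq_len(n)
  dominates_pt <- function(a, b) all(a >= b) && any(a > b)
  while (length(remaining)) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && dominates_pt(V[j, ], V[i, ]), TRUE))
    }, TRUE)
    lev[remaining[nd]] <- current
    remaining <- remaining[!nd]
    current <- current + 1L
  }
  lev
}

# dense simplex-grid maximizer of sum(w_g * c'g) - w_q * c'Qc/2, m variables
grid_qp_oracle <- function(Gv, Q, weights, resolution = 100L) {
  m <- nrow(Gv)
  comp <- function(n, p) {
    if (p == 1L) return(matrix(n, 1, 1))
    out <- NULL
    for (i in 0:n) out <- cbind(out, rbind(i, comp(n - i, p - 1L)))
    out
  }
  C <- t(comp(resolution, m)) / resolution   # points x m
  k <- ncol(Gv)
  lin <- C %*% (Gv %*% weights[seq_len(k)])
  quad <- rowSums((C %*% Q) * C) / 2
  obj <- lin - weights[k + 1] * quad
  list(value = max(obj), c = C[which.max(obj), ])
}

# random points on the simplex (uniform Dirichlet(1,...,1))
random_simplex <- function(n, m) {
  X <- matrix(stats::rexp(n * m), n, m)
  X / rowSums(X)
}

# a small random ParetoFrontier object made directly from points
frontier_from_points <- function(V, maximize) {
  sols <- lapply(seq_len(nrow(V)), function(i)
    structure(list(contribution = contribution_vector(rep(1 / 3, 3)),
                   objectives = objective_vector(V[i, ], maximize),
                   scalarization_weights = rep(1 / ncol(V), ncol(V))),
              class = "FrontierSolution"))
  pareto_frontier(sols)
}

small_sim_config <- function(...) {
  args <- modifyList(list(pop_size = 40, n_markers_per_chrom = 80, n_chrom = 3,
                          n_qtl_per_chrom = 20, n_opposite_sign = 10,
                          burnin_random_mating = 25), list(...))
  do.call(sim_config, args)
}
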