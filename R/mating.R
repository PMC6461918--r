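#' Mating plan
#'
#' A multiset of parent pairs (selfing allowed). Pairs are unordered: the plan
#' is stored in canonical form with parent_i <= parent_j and crosses sorted,
#' so evaluation is invariant to cross order and to parent order within a
#' cross.
#'
#' @param crosses two-column integer matrix (or data frame) of parent indices,
#'   one row per cross occurrence; a third column, if present, gives
#'   multiplicities.
#' @param n_parents number of candidate parents (for index validation).
#' @return Object of class \code{MatingPlan}: data frame \code{crosses} with
#'   columns \code{parent_i}, \code{parent_j}, \code{n}, plus \code{n_crosses}
#'   (total multiplicity).
#' @export
mating_plan <- function(crosses, n_parents = NULL) {
  crosses <- as.matrix(crosses)
  if (ncol(crosses) == 2) crosses <- cbind(crosses, 1)
  if (any(crosses[, 3] < 1)) .stopf("cross multiplicities must be >= 1")
  idx <- crosses[, 1:2]
  if (any(idx != round(idx)) || any(idx < 1))
    .stopf("parent indices must be positive integers")
  if (!is.null(n_parents) && any(idx > n_parents))
    .stopf("parent index exceeds candidate count %d", n_parents)
  lo <- pmin(crosses[, 1], crosses[, 2])
  hi <- pmax(crosses[, 1], crosses[, 2])
  agg <- stats::aggregate(n ~ parent_i + parent_j,
                          data = data.frame(parent_i = lo, parent_j = hi,
                                            n = crosses[, 3]),
                          FUN = sum)
  agg <- agg[order(agg$parent_i, agg$parent_j), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(crosses = agg, n_crosses = sum(agg$n)), class = "MatingPlan")
}

#' @export
print.MatingPlan <- function(x, ...) {
  cat(sprintf("MatingPlan: %d cross(es) over %d distinct pair(s)\n",
              x$n_crosses, nrow(x$crosses)))
  invisible(x)
}

#' Expected progeny mean of a cross (mid-parent value)
#'
#' @param G a [genotype_matrix()].
#' @param E a [marker_effects()].
#' @param i,j parent row indices.
#' @param trait trait index or name.
#' @return Scalar mid-parent genetic value.
#' @export
cross_gain <- function(G, E, i, j, trait = 1L) {
  vals <- genetic_values(G, E)$values
  if (any(c(i, j) < 1) || any(c(i, j) > nrow(vals))) .stopf("invalid parent index")
  (vals[i, trait] + vals[j, trait]) / 2
}

#' Expected within-cross progeny variance (unlinked, inbred parents)
#'
#' Closed-form genetic variance among fully inbred progeny lines
#' (doubled-haploid / RIL-at-fixation model) of a cross between two fully
#' inbred parents, assuming unlinked markers: each locus where the parents
#' differ segregates independently and is fixed for either parental allele
#' with probability 1/2, contributing beta_l^2 (dosage spread 2, variance 1 in
#' dosage units). Loci where the parents agree contribute nothing. The value
#' equals the population variance of the genetic values over all 2^s equally
#' likely fixed progeny genotypes (s = number of segregating loci).
#'
#' @inheritParams cross_gain
#' @return Scalar variance (>= 0).
#' @export
cross_variance <- function(G, E, i, j, trait = 1L) {
  stopifnot(inherits(G, "GenotypeMatrix"), inherits(E, "MarkerEffects"))
  di <- G$dosages[i, ]; dj <- G$dosages[j, ]
  if (any(di == 1) || any(dj == 1))
    .stopf(paste("closed-form cross variance requires fully inbred parents;",
                 "use simulated_cross_variance() for heterozygous parents"))
  beta <- E$beta[, trait]
  seg <- di != dj
  sum(beta[seg]^2)
}

#' Simulated within-cross progeny variance honoring linkage
#'
#' Monte-Carlo estimate of the genetic variance among inbred progeny lines of
#' a cross: the two parental haplotypes (recovered from the inbred parents'
#' dosages) form the F1, gametes are simulated through the meiosis model
#' (Poisson crossovers on the genetic map, no interference), and each gamete
#' is doubled into a fixed progeny line. With unlinked loci the estimate
#' converges to [cross_variance()]; linkage disequilibrium between the
#' parental alleles moves it above (coupling) or below (repulsion) the
#' unlinked value.
#'
#' @inheritParams cross_gain
#' @param n_progeny number of simulated progeny lines (>= 2).
#' @param seed optional integer seed.
#' @return Scalar empirical variance.
#' @export
simulated_cross_variance <- function(G, E, i, j, trait = 1L, n_progeny = 500,
                                     seed = NULL) {
  stopifnot(inherits(G, "GenotypeMatrix"), inherits(E, "MarkerEffects"))
  if (n_progeny < 2) .stopf("need at least 2 simulated progeny")
  if (is.null(G$map)) .stopf("a genetic map is required to simulate meiosis")
  di <- G$dosages[i, ]; dj <- G$dosages[j, ]
  if (any(di == 1) || any(dj == 1))
    .stopf("parents must be fully inbred so haplotypes equal dosage/2")
  if (!is.null(seed)) set.seed(seed)
  h1 <- di / 2; h2 <- dj / 2
  geo <- .map_geometry(G$map)
  beta <- E$beta[, trait]
  vals <- vapply(seq_len(n_progeny), function(p) {
    gam <- .make_gamete(h1, h2, geo)
    sum(2 * gam * beta)
  }, 0)
  var(vals)
}

#' Expected progeny inbreeding of a cross
#'
#' The expected inbreeding coefficient of progeny of parents i and j equals
#' the parents' kinship, A[i, j] / 2 under the additive-relationship scaling
#' (so selfing a fully inbred parent with A[i, i] = 2 gives 1).
#'
#' @param A a [relationship_matrix()] or matrix.
#' @param i,j parent indices.
#' @return Scalar expected inbreeding.
#' @export
cross_inbreeding <- function(A, i, j) {
  Am <- if (inherits(A, "RelationshipMatrix")) A$A else as.matrix(A)
  if (any(c(i, j) < 1) || any(c(i, j) > nrow(Am))) .stopf("invalid parent index")
  Am[i, j] / 2
}

# per-pair objective tables used by plan evaluation and the plan search
.pair_tables <- function(G, E, A, haplotypes = NULL, n_sim = NULL, seed = NULL) {
  vals <- genetic_values(G, E)$values
  m <- nrow(vals); k <- ncol(vals)
  Am <- if (inherits(A, "RelationshipMatrix")) A$A else as.matrix(A)
  gain_t <- lapply(seq_len(k), function(t)
    (outer(vals[, t], rep(1, m)) + outer(rep(1, m), vals[, t])) / 2)
  var_t <- vector("list", k)
  if (is.null(haplotypes)) {
    if (any(G$dosages == 1))
      .stopf(paste("closed-form cross variances require fully inbred candidates;",
                   "supply phased haplotypes for heterozygous parents"))
    D <- G$dosages
    for (t in seq_len(k)) {
      b2 <- E$beta[, t]^2
      # (d_i - d_j)^2 / 4 = 1 at differing inbred loci, 0 otherwise
      S <- D %*% diag(b2, ncol(D)) %*% t(D)
      q <- as.numeric(D^2 %*% b2)
      var_t[[t]] <- (outer(q, rep(1, m)) + outer(rep(1, m), q) - 2 * S) / 4
    }
  } else {
    # heterozygous parents: Monte-Carlo per pair on phased haplotypes
    geo <- .map_geometry(G$map)
    if (!is.null(seed)) set.seed(seed)
    n_sim <- n_sim %||% 60
    for (t in seq_len(k)) var_t[[t]] <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in i:m) {
      prog <- matrix(0, n_sim, k)
      for (p in seq_len(n_sim)) {
        g1 <- .make_gamete(haplotypes$h1[i, ], haplotypes$h2[i, ], geo)
        g2 <- .make_gamete(haplotypes$h1[j, ], haplotypes$h2[j, ], geo)
        prog[p, ] <- (g1 + g2) %*% E$beta
      }
      v <- apply(prog, 2, var)
      for (t in seq_len(k)) { var_t[[t]][i, j] <- v[t]; var_t[[t]][j, i] <- v[t] }
    }
  }
  list(gain = gain_t, variance = var_t, inbreeding = Am / 2, k = k, m = m)
}

.plan_objectives_from_tables <- function(plan, tb) {
  cr <- plan$crosses
  w <- cr$n / sum(cr$n)
  ii <- cbind(cr$parent_i, cr$parent_j)
  gain <- vapply(tb$gain, function(M) sum(w * M[ii]), 0)
  cv <- vapply(tb$variance, function(M) sum(w * M[ii]), 0)
  inb <- sum(w * tb$inbreeding[ii])
  structure(list(gain = gain, cross_variance = cv, inbreeding = inb),
            class = "MatingObjectives")
}

#' @export
print.MatingObjectives <- function(x, ...) {
  cat(sprintf("MatingObjectives: gain (%s), cross variance (%s), inbreeding %.4f\n",
              paste(sprintf("%.4g", x$gain), collapse = ", "),
              paste(sprintf("%.4g", x$cross_variance), collapse = ", "),
              x$inbreeding))
  invisible(x)
}

#' Evaluate a mating plan
#'
#' Multiplicity-weighted means over the plan's crosses of the per-trait
#' mid-parent gains, per-trait expected within-cross variances, and expected
#' progeny inbreeding (2k + 1 components). Aggregation by mean keeps the
#' objectives comparable across plan sizes.
#'
#' @param P a [mating_plan()].
#' @param G a [genotype_matrix()] of the candidate parents.
#' @param E a [marker_effects()].
#' @param A a [relationship_matrix()] or matrix.
#' @return A \code{MatingObjectives} object: \code{gain} (k-vector),
#'   \code{cross_variance} (k-vector), \code{inbreeding} (scalar).
#' @export
evaluate_plan <- function(P, G, E, A) {
  stopifnot(inherits(P, "MatingPlan"))
  if (any(P$crosses$parent_j > nrow(G$dosages))) .stopf("invalid parent index in plan")
  tb <- .pair_tables(G, E, A)
  .plan_objectives_from_tables(P, tb)
}

# objective vector for dominance comparisons: maximize gains and variances,
# minimize inbreeding
.mating_objective_vector <- function(obj) {
  objective_vector(c(obj$gain, obj$cross_variance, obj$inbreeding),
                   c(rep(TRUE, 2 * length(obj$gain)), FALSE))
}

# crowding distance per NSGA-II, larger = less crowded
.crowding <- function(V) {
  n <- nrow(V); cd <- numeric(n)
  for (j in seq_len(ncol(V))) {
    o <- order(V[, j])
    rng <- V[o[n], j] - V[o[1], j]
    cd[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (V[o[3:n], j] - V[o[1:(n - 2)], j]) / rng
  }
  cd
}

#' Search the Pareto frontier of mating plans
#'
#' Multi-objective evolutionary search (non-dominated-sorting genetic
#' algorithm) over fixed-size mating plans, balancing per-trait gain,
#' per-trait within-cross variance (both maximized) and progeny inbreeding
#' (minimized). Plan crossover recombines the parents' cross lists; mutation
#' replaces one endpoint of a random cross. An elitist archive of all
#' non-dominated, objective-distinct plans encountered is returned.
#'
#' @param candidates a [genotype_matrix()] of candidate parents (>= 2). The
#'   closed-form cross variance requires fully inbred candidates; for
#'   heterozygous candidates supply phased haplotypes via
#'   \code{search_opts$haplotypes} (list with matrices \code{h1}, \code{h2})
#'   and the variance table is estimated by progeny simulation.
#' @param E a [marker_effects()].
#' @param A a [relationship_matrix()] or matrix.
#' @param n_crosses number of crosses per plan (>= 1).
#' @param search_opts list: \code{pop_size} (default 100), \code{generations}
#'   (default 200), \code{mutation_rate} per cross (default 0.1),
#'   \code{allow_selfing} (default TRUE), \code{haplotypes}, \code{n_sim}.
#' @param seed integer seed; the search is deterministic given the seed.
#' @return A [pareto_frontier()] whose solutions carry \code{plan}
#'   (a \code{MatingPlan}) and \code{objectives}.
#' @export
search_mating_frontier <- function(candidates, E, A, n_crosses,
                                   search_opts = list(), seed = 1L) {
  stopifnot(inherits(candidates, "GenotypeMatrix"))
  m <- nrow(candidates$dosages)
  if (m < 2) .stopf("need at least 2 candidate parents")
  if (n_crosses < 1) .stopf("n_crosses must be >= 1")
  opts <- modifyList(list(pop_size = 100L, generations = 200L,
                          mutation_rate = 0.1, allow_selfing = TRUE,
                          haplotypes = NULL, n_sim = 60L), search_opts)
  set.seed(seed)
  tb <- .pair_tables(candidates, E, A, haplotypes = opts$haplotypes,
                     n_sim = opts$n_sim)
  # enumerate allowed pairs once; a plan is a multiset of pair indices
  pairs <- which(upper.tri(diag(m), diag = opts$allow_selfing), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  eval_pair_rows <- cbind(pairs[, 1], pairs[, 2])
  pair_obj <- cbind(
    do.call(cbind, lapply(tb$gain, function(M) M[eval_pair_rows])),
    do.call(cbind, lapply(tb$variance, function(M) M[eval_pair_rows])),
    tb$inbreeding[eval_pair_rows])
  n_obj <- ncol(pair_obj)
  plan_obj <- function(p) colMeans(pair_obj[p, , drop = FALSE])
  canon <- function(p) sort(p)
  {
    pop <- lapply(seq_len(opts$pop_size), function(i)
      canon(sample.int(np, n_crosses, replace = TRUE)))
    V <- t(vapply(pop, plan_obj, numeric(n_obj)))
    arch_p <- pop; arch_v <- V
    orient <- c(rep(1, n_obj - 1), -1)  # maximize all but inbreeding
    for (gen in seq_len(opts$generations)) {
      Vm <- sweep(V, 2, orient, "*")
      lev <- .nds_levels(Vm)
      cd <- .crowding(Vm)
      tourn <- function() {
        ij <- sample.int(length(pop), 2)
        a <- ij[1]; b <- ij[2]
        if (lev[a] < lev[b] || (lev[a] == lev[b] && cd[a] > cd[b])) a else b
      }
      children <- vector("list", opts$pop_size)
      for (i in seq_len(opts$pop_size)) {
        pa <- pop[[tourn()]]; pb <- pop[[tourn()]]
        child <- sample(c(pa, pb), n_crosses)
        # mutation: re-draw one endpoint of a random cross
        for (cx in seq_len(n_crosses)) if (runif(1) < opts$mutation_rate) {
          pr <- pairs[child[cx], ]
          pr[sample(1:2, 1)] <- sample.int(m, 1)
          if (!opts$allow_selfing && pr[1] == pr[2]) pr[2] <- (pr[2] %% m) + 1
          lo <- min(pr); hi <- max(pr)
          child[cx] <- which(pairs[, 1] == lo & pairs[, 2] == hi)
        }
        children[[i]] <- canon(child)
      }
      Vc <- t(vapply(children, plan_obj, numeric(n_obj)))
      allp <- c(pop, children); allv <- rbind(V, Vc)
      Vm <- sweep(allv, 2, orient, "*")
      lev <- .nds_levels(Vm); cd <- .crowding(Vm)
      keep <- order(lev, -cd)[seq_len(opts$pop_size)]
      pop <- allp[keep]; V <- allv[keep, , drop = FALSE]
      arch_p <- c(arch_p, children); arch_v <- rbind(arch_v, Vc)
      # compress the archive to its non-dominated, distinct members
      if (gen %% 20 == 0 || gen == opts$generations) {
        lv <- .nds_levels(sweep(arch_v, 2, orient, "*"))
        sel <- which(lv == 1L)
        dup <- duplicated(round(arch_v[sel, , drop = FALSE], 10))
        sel <- sel[!dup]
        arch_p <- arch_p[sel]; arch_v <- arch_v[sel, , drop = FALSE]
      }
    }
    P <- arch_p; V <- arch_v
  }
  orient <- c(rep(1, n_obj - 1), -1)
  lv <- .nds_levels(sweep(V, 2, orient, "*"))
  sel <- which(lv == 1L)
  dup <- duplicated(round(V[sel, , drop = FALSE], 10))
  sel <- sel[!dup]
  sols <- lapply(sel, function(i) {
    pidx <- P[[i]]
    plan <- mating_plan(cbind(pairs[pidx, 1], pairs[pidx, 2]), n_parents = m)
    list(plan = plan,
         objectives = objective_vector(V[i, ], c(rep(TRUE, n_obj - 1), FALSE)),
         scalarization_weights = NULL)
  })
  pareto_frontier(sols, deduplicated = TRUE)
}
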