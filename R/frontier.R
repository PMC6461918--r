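#' Parental contribution vector
#'
#' Non-negative proportional contributions of candidate parents to the next
#' generation, summing to one. Tiny negative entries (above -1e-9, as produced
#' by numerical optimizers) are clipped to zero.
#'
#' @param c numeric vector of proportions.
#' @param ids optional individual ids.
#' @return Object of class \code{ContributionVector}.
#' @export
contribution_vector <- function(c, ids = NULL) {
  c <- as.numeric(c)
  if (any(c < -.moob_tol$nonneg))
    .stopf("contribution entries must be non-negative (min %.3g)", min(c))
  c <- pmax(c, 0)
  if (abs(sum(c) - 1) > .moob_tol$sum_one)
    .stopf("contributions must sum to 1 (got %.10f)", sum(c))
  structure(list(c = c, ids = ids %||% names(c) %||% paste0("ind", seq_along(c))),
            class = "ContributionVector")
}

#' @export
print.ContributionVector <- function(x, ...) {
  nz <- sum(x$c > 1e-8)
  cat(sprintf("ContributionVector: %d candidates, %d with non-zero contribution\n",
              length(x$c), nz))
  invisible(x)
}

.as_contrib <- function(c, m) {
  if (inherits(c, "ContributionVector")) c$c
  else { stopifnot(length(c) == m); as.numeric(c) }
}

#' Expected gain of a contribution vector for one trait
#'
#' The expected genetic gain g(c) = c'b, the contribution-weighted mean
#' breeding value of the selected parents for the given trait.
#'
#' @param c a [contribution_vector()] or numeric vector.
#' @param g a [breeding_values()] object (or numeric vector for one trait).
#' @param trait trait index or name.
#' @return Scalar expected gain.
#' @export
gain <- function(c, g, trait = 1L) {
  b <- if (inherits(g, "BreedingValues")) g$values[, trait] else as.numeric(g)
  cc <- .as_contrib(c, length(b))
  sum(cc * b)
}

#' Group co-ancestry of a contribution vector
#'
#' The expected average inbreeding/co-ancestry of the next generation,
#' r(c) = c'Ac / 2, given the additive relationship matrix A of the candidates.
#'
#' @param c a [contribution_vector()] or numeric vector.
#' @param A a [relationship_matrix()] or plain symmetric matrix.
#' @return Scalar co-ancestry.
#' @export
coancestry <- function(c, A) {
  Am <- if (inherits(A, "RelationshipMatrix")) A$A else as.matrix(A)
  cc <- .as_contrib(c, nrow(Am))
  as.numeric(cc %*% Am %*% cc) / 2
}

#' Correlation-penalized co-ancestry matrix
#'
#' For k traits with genetic correlation matrix Psi, the penalized variant of
#' the co-ancestry objective replaces A by (k - 2 * sum_{i<j} Psi_ij) * A,
#' increasing the diversity penalty when trait pairs are negatively
#' correlated. The scaling factor must be positive; with strongly positive
#' correlations it can be non-positive, in which case an error directs the
#' caller to fall back to the unpenalized objective.
#'
#' @param A a [relationship_matrix()] or plain matrix.
#' @param psi k x k genetic correlation matrix.
#' @param k number of traits (defaults to \code{nrow(psi)}).
#' @return The scaled matrix, with the factor attached as attribute
#'   \code{"factor"}.
#' @export
penalized_quadratic_matrix <- function(A, psi, k = nrow(psi)) {
  psi <- as.matrix(psi)
  if (k < 2) .stopf("penalized objective requires at least 2 traits")
  if (max(abs(psi - t(psi))) > 1e-8 || any(abs(diag(psi) - 1) > 1e-8))
    .stopf("psi must be symmetric with unit diagonal")
  fac <- k - 2 * sum(psi[upper.tri(psi)])
  if (fac <= 0)
    .stopf(paste("penalization factor k - 2*sum(Psi_ij) = %.4f is not positive;",
                 "fall back to the unpenalized (eq1) co-ancestry objective"), fac)
  Am <- if (inherits(A, "RelationshipMatrix")) A$A else as.matrix(A)
  structure(fac * Am, factor = fac)
}

# ensure strict convexity of the quadratic term
.jitter_psd <- function(Q) {
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) Q + diag(.moob_tol$jitter, nrow(Q)) else Q
}

#' Solve one scalarization of the contribution frontier problem
#'
#' Maximizes \code{sum_l w_l c'g_l - w_{k+1} * 0.5 * c'Qc} over the simplex of
#' contribution vectors. With zero weight on the quadratic term the problem is
#' linear and attains a vertex: the arg-max individual of the weighted gain is
#' returned directly instead of solving a degenerate QP.
#'
#' @param g_all a [breeding_values()] object (m individuals x k traits).
#' @param Q m x m quadratic (co-ancestry) matrix, possibly penalized.
#' @param weights non-negative scalarization weights, length k + 1 (k gain
#'   weights, then the co-ancestry weight); not all zero.
#' @param A relationship matrix used to report the co-ancestry objective
#'   (defaults to \code{Q}).
#' @param solver_opts list; supports \code{tol} (KKT tolerance) and
#'   \code{start} (warm-start vector).
#' @return Object of class \code{FrontierSolution}: \code{contribution},
#'   \code{objectives} (k gains then co-ancestry r(c), with co-ancestry
#'   minimized), \code{scalarization_weights}, \code{kkt}.
#' @export
solve_scalarized_qp <- function(g_all, Q, weights, A = Q, solver_opts = list()) {
  stopifnot(inherits(g_all, "BreedingValues"))
  Gm <- .orient_max(g_all$values, g_all$maximize)
  m <- nrow(Gm); k <- ncol(Gm)
  if (length(weights) != k + 1) .stopf("expected %d weights, got %d", k + 1, length(weights))
  if (any(weights < 0) || all(weights == 0)) .stopf("weights must be non-negative, not all zero")
  wq <- weights[k + 1]
  if (wq == 0) {
    score <- as.numeric(Gm %*% weights[seq_len(k)])
    cvec <- numeric(m); cvec[which.max(score)] <- 1
    kkt <- 0
  } else {
    d <- as.numeric(Gm %*% weights[seq_len(k)])
    Qw <- .jitter_psd(as.matrix(Q)) * wq
    fit <- solve_qp(Qw, d, matrix(1, 1, m), 1,
                    start = solver_opts$start %||% NULL,
                    tol = solver_opts$tol %||% 1e-9)
    if (!fit$converged) .stopf("QP solver did not converge (kkt %.3g)", fit$kkt)
    cvec <- fit$x / sum(fit$x)
    kkt <- fit$kkt
  }
  contrib <- contribution_vector(cvec, ids = rownames(g_all$values))
  obj <- c(vapply(seq_len(k), function(t) gain(contrib, g_all, t), 0),
           coancestry(contrib, A))
  structure(list(contribution = contrib,
                 objectives = objective_vector(obj, c(g_all$maximize, FALSE)),
                 scalarization_weights = weights, kkt = kkt),
            class = "FrontierSolution")
}

#' @export
print.FrontierSolution <- function(x, ...) {
  cat("FrontierSolution:", paste(sprintf("%.4g", x$objectives$values), collapse = ", "),
      sprintf("(weights %s)\n", paste(sprintf("%.3g", x$scalarization_weights), collapse = "/")))
  invisible(x)
}

# all non-negative integer compositions of n into p parts (columns)
.compositions <- function(n, p) {
  if (p == 1L) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    sub <- .compositions(n - i, p - 1L)
    out <- cbind(out, rbind(rep(i, ncol(sub)), sub))
  }
  out
}

#' Construct a Pareto frontier object
#'
#' @param solutions list of [solve_scalarized_qp()] solutions (or, for mating
#'   frontiers, plan solutions carrying an \code{objectives} element).
#' @param deduplicated logical flag: dominated and duplicate solutions removed.
#' @return Object of class \code{ParetoFrontier}.
#' @export
pareto_frontier <- function(solutions, deduplicated = FALSE) {
  if (!length(solutions)) .stopf("empty frontier")
  structure(list(solutions = solutions, deduplicated = isTRUE(deduplicated)),
            class = "ParetoFrontier")
}

#' @export
print.ParetoFrontier <- function(x, ...) {
  cat(sprintf("ParetoFrontier: %d solution(s), %d objective(s)%s\n",
              length(x$solutions), length(x$solutions[[1]]$objectives$values),
              if (x$deduplicated) ", pruned" else ""))
  invisible(x)
}

#' Objective matrix of a frontier
#'
#' @param x a [pareto_frontier()].
#' @param ... unused.
#' @return Numeric matrix, one row per solution.
#' @export
as.matrix.ParetoFrontier <- function(x, ...) {
  do.call(rbind, lapply(x$solutions, function(s) s$objectives$values))
}

.frontier_dirs <- function(F) F$solutions[[1L]]$objectives$maximize

# prune duplicates (sup-norm) and dominated solutions
.prune_frontier <- function(solutions) {
  V <- do.call(rbind, lapply(solutions, function(s) s$objectives$values))
  dirs <- solutions[[1L]]$objectives$maximize
  keep <- rep(TRUE, nrow(V))
  for (i in seq_len(nrow(V))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(V))) {
      if (i == j || !keep[j]) next
      if (max(abs(V[i, ] - V[j, ])) < .moob_tol$dedupe) { keep[j] <- FALSE; next }
    }
  }
  idx <- which(keep)
  Vm <- .orient_max(V[idx, , drop = FALSE], dirs)
  lev <- .nds_levels(Vm)
  pareto_frontier(solutions[idx[lev == 1L]], deduplicated = TRUE)
}

#' Trace the Pareto frontier of parental contributions
#'
#' Solves the multi-objective parental contribution problem — maximize the k
#' per-trait expected gains c'g_l and minimize group co-ancestry c'Ac/2 over
#' the simplex — by sweeping weighted-sum scalarizations over a uniform
#' simplex lattice of weight vectors. Because the gains are linear and the
#' co-ancestry objective is convex, weighted sums recover the whole Pareto
#' front. The \code{"eq2"} variant replaces A by the correlation-penalized
#' matrix from [penalized_quadratic_matrix()].
#'
#' @param g_all a [breeding_values()] object.
#' @param A a [relationship_matrix()] (or matrix) for the candidates.
#' @param variant \code{"eq1"} (plain co-ancestry) or \code{"eq2"}
#'   (correlation-penalized).
#' @param resolution number of lattice points per weight axis (default 21,
#'   i.e. weight steps of 1/20).
#' @param psi genetic correlation matrix for \code{"eq2"}; estimated from
#'   \code{g_all} when \code{NULL}.
#' @param solver_opts passed to [solve_scalarized_qp()].
#' @return A [pareto_frontier()] of [solve_scalarized_qp()] solutions, with
#'   dominated and duplicate solutions removed. Reported co-ancestry
#'   objectives always use the unpenalized A.
#' @export
trace_frontier <- function(g_all, A, variant = c("eq1", "eq2"), resolution = 21,
                           psi = NULL, solver_opts = list()) {
  variant <- match.arg(variant)
  stopifnot(inherits(g_all, "BreedingValues"))
  if (resolution < 2) .stopf("resolution must be at least 2")
  Am <- if (inherits(A, "RelationshipMatrix")) A$A else as.matrix(A)
  if (nrow(Am) != nrow(g_all$values))
    .stopf("relationship matrix and breeding values disagree on m")
  k <- ncol(g_all$values)
  Q <- if (variant == "eq2") {
    psi <- psi %||% estimate_genetic_correlations(g_all)
    unclass(penalized_quadratic_matrix(Am, psi, k))
  } else Am
  steps <- resolution - 1L
  W <- .compositions(steps, k + 1L) / steps
  sols <- vector("list", ncol(W))
  warm <- NULL
  for (i in seq_len(ncol(W))) {
    opts <- solver_opts
    if (W[k + 1L, i] > 0) opts$start <- warm
    s <- solve_scalarized_qp(g_all, Q, W[, i], A = Am, solver_opts = opts)
    if (W[k + 1L, i] > 0) warm <- s$contribution$c
    sols[[i]] <- s
  }
  .prune_frontier(sols)
}

#' Minimum co-ancestry at a fixed single-trait gain (legacy formulation)
#'
#' Solves the classical optimal-contribution problem: minimize
#' r(c) = c'Ac/2 subject to c'b = rho, sum(c) = 1, c >= 0 — the single-trait
#' precursor of the multi-objective frontier. Sweeping rho reproduces the
#' k = 1 frontier and is used to cross-check [trace_frontier()].
#'
#' @param g single-trait [breeding_values()] or numeric vector b.
#' @param A a [relationship_matrix()] or matrix.
#' @param rho desired gain level, within [min(b), max(b)].
#' @return A [contribution_vector()].
#' @export
constrained_min_coancestry <- function(g, A, rho) {
  b <- if (inherits(g, "BreedingValues")) g$values[, 1L] else as.numeric(g)
  Am <- if (inherits(A, "RelationshipMatrix")) A$A else as.matrix(A)
  if (rho < min(b) - 1e-12 || rho > max(b) + 1e-12)
    .stopf("rho = %.4g is infeasible: attainable gains are [%.4g, %.4g]",
           rho, min(b), max(b))
  rho <- min(max(rho, min(b)), max(b))
  m <- length(b)
  Q <- .jitter_psd(Am)
  ids <- if (inherits(g, "BreedingValues")) rownames(g$values) else NULL
  if (max(b) == min(b)) return(contribution_vector(rep(1 / m, m), ids = ids))
  # at a boundary rho the gain constraint pins the support to the extreme
  # individuals; minimize co-ancestry within that set directly
  for (side in c(1, -1)) {
    bnd <- if (side == 1) max(b) else min(b)
    if (abs(rho - bnd) < 1e-10) {
      S <- which(abs(b - bnd) < 1e-12)
      cvec <- numeric(m)
      if (length(S) == 1L) cvec[S] <- 1
      else {
        sub <- solve_qp(Q[S, S, drop = FALSE], rep(0, length(S)),
                        matrix(1, 1, length(S)), 1)
        cvec[S] <- sub$x
      }
      return(contribution_vector(cvec / sum(cvec), ids = ids))
    }
  }
  # feasible start: mix of the extreme-gain vertices
  alpha <- (rho - min(b)) / (max(b) - min(b))
  x0 <- numeric(m)
  x0[which.max(b)] <- alpha
  x0[which.min(b)] <- x0[which.min(b)] + (1 - alpha)
  fit <- solve_qp(Q, rep(0, m), rbind(rep(1, m), b), c(1, rho), start = x0)
  if (!fit$converged) .stopf("QP solver did not converge")
  cvec <- pmax(fit$x, 0)
  # c'b = rho holds through the equality constraint; only normalize rounding
  # error on the sum
  contribution_vector(cvec / sum(cvec), ids = ids)
}
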