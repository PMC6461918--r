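# Decision support: picking a preferred solution on a Pareto frontier.

# orient frontier objectives to minimization and minmax/zscore-normalize;
# returns list(X = normalized matrix, degenerate = zero-range axes)
.normalize_objectives <- function(V, maximize,
                                  normalization = c("minmax", "zscore", "none")) {
  normalization <- match.arg(normalization)
  X <- .orient_max(V, maximize) * -1  # smaller = better on every axis
  degenerate <- rep(FALSE, ncol(X))
  if (normalization == "minmax") {
    for (j in seq_len(ncol(X))) {
      rng <- range(X[, j])
      if (diff(rng) < 1e-300) { X[, j] <- 0; degenerate[j] <- TRUE }
      else X[, j] <- (X[, j] - rng[1]) / diff(rng)
    }
  } else if (normalization == "zscore") {
    for (j in seq_len(ncol(X))) {
      s <- sd(X[, j])
      if (s == 0) { X[, j] <- 0; degenerate[j] <- TRUE }
      else X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  list(X = X, degenerate = degenerate)
}

#' Ideal point of a Pareto frontier
#'
#' The componentwise best value of each objective over all frontier solutions
#' (direction-aware). The ideal point is usually infeasible; it anchors the
#' global-criterion distance.
#'
#' @param F a [pareto_frontier()].
#' @return An [objective_vector()].
#' @export
ideal_point <- function(F) {
  stopifnot(inherits(F, "ParetoFrontier"))
  V <- as.matrix(F)
  dirs <- .frontier_dirs(F)
  vals <- vapply(seq_len(ncol(V)), function(j)
    if (dirs[j]) max(V[, j]) else min(V[, j]), 0)
  objective_vector(vals, dirs)
}

#' Select a frontier solution by weighted distance to the ideal point
#'
#' Implements the global-criterion rule: each objective axis is normalized
#' (default min-max over the frontier), and the solution minimizing the
#' weighted p-norm distance to the normalized ideal point is returned. An axis
#' with zero range under min-max normalization contributes zero distance.
#' Ties are broken by lowest co-ancestry (the designated axis), then by input
#' order.
#'
#' @param F a [pareto_frontier()].
#' @param weights non-negative importance weights over the objectives, summing
#'   to one (they are renormalized if not).
#' @param normalization \code{"minmax"} (default), \code{"zscore"} or
#'   \code{"none"}.
#' @param p norm exponent (default 2, Euclidean).
#' @param coancestry_axis index of the co-ancestry objective used for tie
#'   breaking; defaults to the last axis.
#' @return The selected \code{FrontierSolution}, with the attribute
#'   \code{"index"} giving its position in the frontier.
#' @export
select_by_global_criterion <- function(F, weights,
                                       normalization = c("minmax", "zscore", "none"),
                                       p = 2, coancestry_axis = NULL) {
  stopifnot(inherits(F, "ParetoFrontier"))
  V <- as.matrix(F)
  k1 <- ncol(V)
  if (length(weights) != k1) .stopf("expected %d weights, got %d", k1, length(weights))
  if (any(weights < 0)) .stopf("weights must be non-negative")
  if (sum(weights) <= 0) .stopf("weights must not all be zero")
  weights <- weights / sum(weights)
  coancestry_axis <- coancestry_axis %||% k1
  nz <- .normalize_objectives(V, .frontier_dirs(F), normalization)
  # ideal point in normalized space is the componentwise minimum
  ideal <- apply(nz$X, 2, min)
  D <- sweep(nz$X, 2, ideal, "-")
  dist <- (abs(D)^p %*% weights)^(1 / p)
  best <- min(dist)
  cand <- which(dist <= best + 1e-12)
  if (length(cand) > 1L) {
    co <- V[cand, coancestry_axis]
    co <- if (.frontier_dirs(F)[coancestry_axis]) -co else co
    cand <- cand[order(co, cand)]
  }
  sol <- F$solutions[[cand[1L]]]
  attr(sol, "index") <- cand[1L]
  sol
}

#' Find the knee of a two-objective frontier
#'
#' A knee is a frontier region where a small improvement in one objective
#' costs a large deterioration in the other. This implementation uses the
#' chord rule: after min-max normalization of the two chosen axes, it returns
#' the solution with maximum perpendicular distance to the straight line
#' joining the two frontier endpoints. For frontiers with more than two
#' objectives the caller selects the two axes to project on.
#'
#' @param F a [pareto_frontier()] with at least 3 solutions.
#' @param axes length-2 integer vector of objective axes (default
#'   \code{c(1, 2)}; required explicitly when there are more than 2
#'   objectives).
#' @return The knee \code{FrontierSolution} with attributes \code{"index"},
#'   \code{"chord_distance"}, and logical \code{"no_knee"} set when all points
#'   are collinear (distance ~ 0, first solution returned by the tie rule).
#' @export
find_knee <- function(F, axes = NULL) {
  stopifnot(inherits(F, "ParetoFrontier"))
  V <- as.matrix(F)
  if (nrow(V) < 3)
    .stopf("knee detection needs at least 3 solutions; use select_by_global_criterion()")
  if (is.null(axes)) {
    if (ncol(V) != 2)
      .stopf("frontier has %d objectives; pass the two axes to project on", ncol(V))
    axes <- c(1L, 2L)
  }
  dirs <- .frontier_dirs(F)[axes]
  X <- .normalize_objectives(V[, axes, drop = FALSE], dirs, "minmax")$X
  ord <- order(X[, 1L], X[, 2L])
  a <- X[ord[1L], ]; b <- X[ord[length(ord)], ]
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  d <- if (nrm < 1e-12) rep(0, nrow(X)) else
    abs(ab[2] * (X[, 1] - a[1]) - ab[1] * (X[, 2] - a[2])) / nrm
  no_knee <- max(d) < 1e-9
  idx <- which.max(d)
  if (no_knee) idx <- 1L
  sol <- F$solutions[[idx]]
  attr(sol, "index") <- idx
  attr(sol, "chord_distance") <- d[idx]
  attr(sol, "no_knee") <- no_knee
  sol
}

#' Self-organizing map of frontier solutions
#'
#' Fits a batch Kohonen self-organizing map to the (min-max normalized)
#' objective vectors of a frontier: a u x v grid of prototype vectors is
#' trained with a Gaussian neighborhood whose radius decays linearly from
#' max(u, v)/2 to 0.5 over the epochs. The codebook is initialized on the
#' first two principal axes of the normalized objectives, making the fit
#' deterministic. Intended as a topology-preserving 2-D visual summary of
#' high-dimensional frontiers.
#'
#' @param F a [pareto_frontier()] with at least 2 solutions.
#' @param grid integer (u, v) grid dimensions; default \code{c(6, 6)}.
#' @param epochs training epochs (default 50).
#' @param seed optional integer seed (the batch algorithm itself is
#'   deterministic; the seed is set for forward compatibility).
#' @return Object of class \code{SomGrid}: \code{codebook} ((u*v) x k matrix),
#'   \code{grid} dims, \code{units} (grid coordinates per unit),
#'   \code{assignments} (best-matching unit per solution),
#'   \code{quantization_error}, \code{quantization_error_init}, and the
#'   normalized data matrix \code{X}.
#' @export
som_fit <- function(F, grid = c(6, 6), epochs = 50, seed = NULL) {
  stopifnot(inherits(F, "ParetoFrontier"))
  u <- grid[1]; v <- grid[2]
  if (u * v < 2) .stopf("SOM grid must have at least 2 units")
  if (epochs < 1) .stopf("epochs must be >= 1")
  V <- as.matrix(F)
  if (nrow(V) < 2) .stopf("need at least 2 solutions to fit a SOM")
  if (!is.null(seed)) set.seed(seed)
  X <- .normalize_objectives(V, .frontier_dirs(F), "minmax")$X
  n <- nrow(X); k <- ncol(X)
  units <- as.matrix(expand.grid(gx = seq_len(u), gy = seq_len(v)))
  # PCA-plane initialization
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ax1 <- pc$rotation[, 1] * pc$sdev[1]
  ax2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2] * pc$sdev[2] else rep(0, k)
  gx <- if (u > 1) (units[, 1] - (u + 1) / 2) / ((u - 1) / 2) else rep(0, nrow(units))
  gy <- if (v > 1) (units[, 2] - (v + 1) / 2) / ((v - 1) / 2) else rep(0, nrow(units))
  codebook <- matrix(colMeans(X), u * v, k, byrow = TRUE) +
    outer(gx, ax1) + outer(gy, ax2)
  bmu_of <- function(cb) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(cb))) - 2 * X %*% t(cb) +
      outer(rep(1, n), rowSums(cb^2))
    max.col(-d2, ties.method = "first")
  }
  qe_of <- function(cb, bmu) mean(sqrt(rowSums((X - cb[bmu, , drop = FALSE])^2)))
  grid_d2 <- as.matrix(dist(units))^2
  bmu <- bmu_of(codebook)
  qe_init <- qe_of(codebook, bmu)
  r0 <- max(u, v) / 2; r1 <- 0.5
  for (e in seq_len(epochs)) {
    r <- if (epochs == 1) r1 else r0 + (r1 - r0) * (e - 1) / (epochs - 1)
    bmu <- bmu_of(codebook)
    H <- exp(-grid_d2 / (2 * r^2))   # units x units neighborhood
    W <- H[, bmu, drop = FALSE]      # units x n influence of each point
    denom <- rowSums(W)
    num <- W %*% X
    upd <- denom > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  bmu <- bmu_of(codebook)
  structure(list(codebook = codebook, grid = c(u = u, v = v), units = units,
                 assignments = bmu, quantization_error = qe_of(codebook, bmu),
                 quantization_error_init = qe_init, X = X),
            class = "SomGrid")
}

#' @export
print.SomGrid <- function(x, ...) {
  cat(sprintf("SomGrid: %dx%d units, %d solutions, quantization error %.4f\n",
              x$grid[1], x$grid[2], length(x$assignments), x$quantization_error))
  invisible(x)
}
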