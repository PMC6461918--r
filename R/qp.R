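# Quadratic programming over the nonnegative orthant with linear equality
# constraints:  minimize 1/2 x'Qx - d'x  s.t.  E x = f, x >= 0.
# Primal active-set method on the bound constraints; the equality constraints
# stay in the working set throughout. Q must be positive definite on the
# feasible subspace (callers jitter near-singular matrices).

.qp_kkt_solve <- function(Q, d, E, f, S) {
  p <- nrow(E)
  Es <- E[, S, drop = FALSE]
  M <- rbind(cbind(Q[S, S, drop = FALSE], -t(Es)),
             cbind(Es, matrix(0, p, p)))
  rhs <- c(d[S], f)
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    M[seq_along(S), seq_along(S)] <- M[seq_along(S), seq_along(S)] +
      diag(1e-10 * (1 + max(abs(diag(Q)))), length(S))
    sol <- solve(M, rhs)
  }
  list(x = sol[seq_along(S)], mu = sol[length(S) + seq_len(p)])
}

# Euclidean projection onto the probability simplex (Held et al. algorithm)
.proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

# accelerated projected gradient fallback, valid only for the simplex case
.qp_fista_simplex <- function(Q, d, x0, iters = 5000, tol = 1e-12) {
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
  x <- y <- x0
  t_k <- 1
  for (it in seq_len(iters)) {
    g <- as.numeric(Q %*% y) - d
    x_new <- .proj_simplex(y - g / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- x_new + ((t_k - 1) / t_new) * (x_new - x)
    if (max(abs(x_new - x)) < tol && it > 10) { x <- x_new; break }
    x <- x_new; t_k <- t_new
  }
  x
}

#' Solve an equality-constrained nonnegative quadratic program
#'
#' Minimizes \code{0.5 * x'Qx - d'x} subject to \code{E x = f} and
#' \code{x >= 0}, by a primal active-set method on the bounds. Used internally
#' for all parental-contribution optimizations; exported for cross-checking.
#'
#' @param Q symmetric positive-definite matrix (m x m).
#' @param d linear term (length m).
#' @param E equality constraint matrix (p x m), rows linearly independent.
#' @param f equality right-hand side (length p).
#' @param start feasible starting point (x >= 0, E x = f). Defaults to the
#'   uniform vector when \code{E} is the single sum-to-one constraint.
#' @param tol stationarity tolerance for the KKT check.
#' @return List with \code{x}, multipliers \code{mu}, \code{kkt} (max
#'   stationarity residual over the free set), \code{iterations},
#'   \code{converged}.
#' @export
solve_qp <- function(Q, d, E, f, start = NULL, tol = 1e-9) {
  m <- length(d)
  Q <- (Q + t(Q)) / 2
  E <- matrix(E, ncol = m)
  simplex_case <- nrow(E) == 1L && all(abs(E - 1) < 1e-12) && abs(f - 1) < 1e-12
  if (is.null(start)) {
    if (!simplex_case) .stopf("a feasible starting point is required")
    start <- rep(1 / m, m)
  }
  x <- pmax(start, 0)
  S <- which(x > 1e-12)
  if (!length(S)) S <- seq_len(m)
  scale <- max(abs(d), max(abs(Q)), 1)
  max_iter <- 6L * m + 100L
  mu <- rep(0, nrow(E))
  for (it in seq_len(max_iter)) {
    sol <- .qp_kkt_solve(Q, d, E, f, S)
    xs <- sol$x
    if (min(xs) >= -1e-11) {
      x[] <- 0; x[S] <- pmax(xs, 0); mu <- sol$mu
      # dual feasibility of the clamped variables
      nu <- as.numeric(Q %*% x) - d - as.numeric(t(E) %*% mu)
      out <- setdiff(seq_len(m), S)
      viol <- out[nu[out] < -tol * scale]
      if (!length(viol)) {
        kkt <- if (length(S)) max(abs(nu[S])) else 0
        return(list(x = x, mu = mu, kkt = kkt, iterations = it, converged = TRUE))
      }
      S <- sort(c(S, viol[which.min(nu[viol])]))
    } else {
      cur <- x[S]
      delta <- xs - cur
      block <- which(xs < -1e-11 & delta < 0)
      alpha <- (cur[block]) / (cur[block] - xs[block])
      jstar <- block[which.min(alpha)]
      astar <- max(min(alpha), 0)
      x[S] <- cur + astar * delta
      x[x < 0] <- 0
      S <- S[-jstar]
      if (!length(S)) S <- which.max(d)  # degenerate guard
    }
  }
  if (simplex_case) {
    x <- .qp_fista_simplex(Q, d, rep(1 / m, m))
    nu <- as.numeric(Q %*% x) - d
    mu_hat <- min(nu[x > 1e-9])
    kkt <- max(abs(nu[x > 1e-9] - mu_hat))
    return(list(x = x, mu = mu_hat, kkt = kkt, iterations = max_iter,
                converged = kkt < 1e-6))
  }
  .stopf("QP active-set method did not converge in %d iterations", max_iter)
}
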