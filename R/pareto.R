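#' Objective vector
#'
#' A point in objective space together with the direction of improvement of
#' each axis.
#'
#' @param values finite numeric vector.
#' @param maximize logical vector (recycled) per objective.
#' @return Object of class \code{ObjectiveVector}.
#' @export
objective_vector <- function(values, maximize = TRUE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) .stopf("objective values must be finite")
  structure(list(values = values,
                 maximize = rep_len(as.logical(maximize), length(values))),
            class = "ObjectiveVector")
}

#' @export
print.ObjectiveVector <- function(x, ...) {
  cat("(", paste(sprintf("%s%.4g", ifelse(x$maximize, "+", "-"), x$values),
                 collapse = ", "), ")\n")
  invisible(x)
}

#' Pareto dominance between two objective vectors
#'
#' \code{a} dominates \code{b} when, after orienting every axis towards
#' improvement, \code{a} is no worse in every objective and strictly better in
#' at least one. The relation is irreflexive: a point never dominates itself.
#'
#' @param a,b [objective_vector()]s of equal length and identical directions.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  stopifnot(inherits(a, "ObjectiveVector"), inherits(b, "ObjectiveVector"))
  if (length(a$values) != length(b$values) || !identical(a$maximize, b$maximize))
    .stopf("objective vectors differ in length or direction flags")
  av <- ifelse(a$maximize, a$values, -a$values)
  bv <- ifelse(b$maximize, b$values, -b$values)
  all(av >= bv) && any(av > bv)
}

# orient a points matrix (rows = solutions) so larger is always better
.orient_max <- function(values, maximize) {
  sweep(values, 2, ifelse(maximize, 1, -1), "*")
}

# fast non-dominated sort on an n x k matrix already oriented to maximization;
# returns integer frontier levels (1 = non-dominated)
.nds_levels <- function(V) {
  n <- nrow(V)
  if (n == 1L) return(1L)
  dom_count <- integer(n)          # number of points dominating i
  dominated_by <- vector("list", n) # points that i dominates
  for (i in seq_len(n - 1L)) {
    vi <- V[i, ]
    for (j in (i + 1L):n) {
      vj <- V[j, ]
      if (all(vi >= vj) && any(vi > vj)) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
        dom_count[j] <- dom_count[j] + 1L
      } else if (all(vj >= vi) && any(vj > vi)) {
        dominated_by[[j]] <- c(dominated_by[[j]], i)
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  levels <- integer(n)
  current <- which(dom_count == 0L)
  lev <- 1L
  while (length(current)) {
    levels[current] <- lev
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
    lev <- lev + 1L
  }
  levels
}

#' Non-dominated sorting into dominance frontiers
#'
#' Classifies a set of points in objective space into successive frontiers:
#' level 1 is the non-dominated set; level l is the non-dominated set after
#' removing all points of levels below l. Points identical in every objective
#' share a level (neither dominates the other).
#'
#' @param points a list of [objective_vector()]s with identical direction
#'   flags, or a numeric matrix (rows = points) combined with \code{maximize}.
#' @param maximize direction flags used when \code{points} is a matrix.
#' @return Object of class \code{DominanceSort}: list with integer vector
#'   \code{levels} (one per point, 1 = non-dominated) and \code{n_levels}.
#' @export
nondominated_sort <- function(points, maximize = TRUE) {
  if (is.list(points) && !is.data.frame(points)) {
    if (!length(points)) .stopf("empty point set")
    stopifnot(all(vapply(points, inherits, TRUE, "ObjectiveVector")))
    dirs <- points[[1L]]$maximize
    for (p in points)
      if (!identical(p$maximize, dirs)) .stopf("direction flags differ across points")
    V <- do.call(rbind, lapply(points, `[[`, "values"))
    maximize <- dirs
  } else {
    V <- as.matrix(points)
    if (!nrow(V)) .stopf("empty point set")
    maximize <- rep_len(as.logical(maximize), ncol(V))
  }
  levels <- .nds_levels(.orient_max(V, maximize))
  structure(list(levels = levels, n_levels = max(levels)),
            class = "DominanceSort")
}

#' @export
print.DominanceSort <- function(x, ...) {
  cat(sprintf("DominanceSort: %d points in %d frontier level(s)\n",
              length(x$levels), x$n_levels))
  invisible(x)
}

#' Parental weights from dominance levels (non-dominated selection)
#'
#' Turns a dominance sort of candidates into a parental contribution vector,
#' assigning higher weights to individuals on lower (better) frontier levels.
#' The selected quota (a fraction of the population) is filled frontier by
#' frontier from level 1 upward. With the default \code{"linear"} scheme an
#' included individual on level l receives raw weight (L - l + 1), where L is
#' the deepest included level; a level only partially covered by the quota
#' has its remaining allocation spread equally over all its members. Weights
#' are normalized to sum to one; excluded individuals receive zero.
#'
#' @param sort a [nondominated_sort()] result.
#' @param selected_fraction fraction of the population to select, in (0, 1].
#' @param scheme \code{"linear"} (raw weight L - l + 1, default) or
#'   \code{"inverse"} (raw weight 1/l).
#' @param ids optional individual ids.
#' @return A [contribution_vector()].
#' @export
dominance_weights <- function(sort, selected_fraction,
                              scheme = c("linear", "inverse"), ids = NULL) {
  stopifnot(inherits(sort, "DominanceSort"))
  scheme <- match.arg(scheme)
  if (!(selected_fraction > 0 && selected_fraction <= 1))
    .stopf("selected_fraction must be in (0, 1]")
  m <- length(sort$levels)
  quota <- floor(m * selected_fraction + 1e-9)
  if (quota < 1) .stopf("selection quota below one individual")
  sizes <- tabulate(sort$levels, nbins = sort$n_levels)
  cum <- cumsum(sizes)
  Lstar <- which(cum >= quota)[1L]
  raw_of <- function(l) if (scheme == "linear") (Lstar - l + 1) else 1 / l
  w <- numeric(m)
  for (l in seq_len(Lstar)) {
    members <- which(sort$levels == l)
    if (l < Lstar || cum[Lstar] == quota) {
      w[members] <- raw_of(l)
    } else {
      used <- quota - (if (Lstar > 1) cum[Lstar - 1] else 0)
      w[members] <- raw_of(Lstar) * used / sizes[Lstar]
    }
  }
  contribution_vector(w / sum(w), ids = ids)
}
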