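#' Multi-trait breeding values
#'
#' Individuals-by-traits matrix of (estimated) breeding values, with a
#' direction-of-improvement flag per trait.
#'
#' @param values numeric matrix or data frame, individuals in rows, traits in
#'   columns; no missing entries.
#' @param maximize logical vector (recycled) indicating, per trait, whether
#'   larger values are better. Default \code{TRUE}.
#' @param standardized logical; whether columns are centered/scaled z-scores.
#' @return Object of class \code{BreedingValues}: list with \code{values},
#'   \code{trait_names}, \code{maximize}, \code{standardized}.
#' @export
breeding_values <- function(values, maximize = TRUE, standardized = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) .stopf("breeding values contain missing entries")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("trait", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("ind", seq_len(nrow(values)))
  maximize <- rep_len(as.logical(maximize), ncol(values))
  if (isTRUE(standardized)) {
    mu <- colMeans(values)
    s2 <- apply(values, 2, var)
    if (any(abs(mu) > 1e-6) || any(abs(s2 - 1) > 1e-6))
      .stopf("standardized = TRUE but columns are not z-scores")
  }
  structure(list(values = values, trait_names = colnames(values),
                 maximize = maximize, standardized = isTRUE(standardized)),
            class = "BreedingValues")
}

#' @export
print.BreedingValues <- function(x, ...) {
  cat(sprintf("BreedingValues: %d individuals x %d trait(s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @export
dim.BreedingValues <- function(x) dim(x$values)

#' Center and scale breeding values trait-wise
#'
#' Brings all traits to a common scale (mean 0, unit variance), as done before
#' multi-trait frontier optimization so that gains are comparable across
#' traits. Direction-of-improvement flags are preserved.
#'
#' @param BV a [breeding_values()] object.
#' @return A standardized \code{BreedingValues} object.
#' @export
standardize <- function(BV) {
  stopifnot(inherits(BV, "BreedingValues"))
  s <- apply(BV$values, 2, sd)
  if (any(s == 0))
    .stopf("trait '%s' has zero variance; cannot standardize",
           BV$trait_names[which(s == 0)[1L]])
  z <- scale(BV$values)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  breeding_values(z, maximize = BV$maximize, standardized = TRUE)
}

#' Genetic correlations between traits
#'
#' Pairwise Pearson correlation of breeding-value columns; used as the
#' estimate of the genetic correlation matrix that feeds the
#' correlation-penalized co-ancestry objective.
#'
#' @param BV a [breeding_values()] object with at least 3 individuals.
#' @return A k x k symmetric correlation matrix with unit diagonal.
#' @export
estimate_genetic_correlations <- function(BV) {
  stopifnot(inherits(BV, "BreedingValues"))
  if (nrow(BV$values) < 3) .stopf("need at least 3 individuals")
  s <- apply(BV$values, 2, sd)
  if (any(s == 0))
    .stopf("trait '%s' is constant; correlation undefined",
           BV$trait_names[which(s == 0)[1L]])
  psi <- cor(BV$values)
  dimnames(psi) <- list(BV$trait_names, BV$trait_names)
  psi
}
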