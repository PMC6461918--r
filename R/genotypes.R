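#' Genotype matrix of biallelic marker dosages
#'
#' Container for an individuals-by-markers matrix of allele dosages in
#' \{0, 1, 2\} (counts of the arbitrarily designated alternate allele), with an
#' optional genetic map. Fully inbred lines carry only dosages 0 and 2.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns;
#'   entries must be 0, 1 or 2 with no missing values. Row names are taken as
#'   individual ids (generated if absent), column names as marker ids.
#' @param map optional data frame with columns \code{marker}, \code{chrom},
#'   \code{pos} (genetic position in Morgans, non-decreasing within
#'   chromosome), one row per marker in column order.
#' @param inbred logical; if \code{NULL} (default), detected from the data
#'   (no dosage equal to 1).
#' @return An object of class \code{GenotypeMatrix} with elements
#'   \code{dosages}, \code{map}, \code{ids}, \code{inbred}.
#' @export
genotype_matrix <- function(dosages, map = NULL, inbred = NULL) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages))
    .stopf("missing genotypes are not supported; impute or filter before import")
  if (!all(dosages %in% c(0, 1, 2))) {
    bad <- which(!(dosages %in% c(0, 1, 2)))[1L]
    rc <- arrayInd(bad, dim(dosages))
    .stopf("dosage outside {0,1,2} at individual %d, marker %d (value %s)",
           rc[1], rc[2], format(dosages[bad]))
  }
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages)))
    .stopf("individual ids must be unique")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  if (!is.null(map)) {
    map <- as.data.frame(map)
    need <- c("marker", "chrom", "pos")
    if (!all(need %in% names(map)))
      .stopf("map must have columns marker, chrom, pos")
    if (nrow(map) != ncol(dosages))
      .stopf("map has %d rows but there are %d markers", nrow(map), ncol(dosages))
    for (ch in unique(map$chrom)) {
      p <- map$pos[map$chrom == ch]
      if (is.unsorted(p)) .stopf("map positions decrease within chromosome %s", ch)
    }
  }
  detected_inbred <- !any(dosages == 1)
  if (is.null(inbred)) inbred <- detected_inbred
  if (inbred && !detected_inbred)
    .stopf("inbred flag set but heterozygous dosages present")
  structure(list(dosages = dosages, map = map,
                 ids = rownames(dosages), inbred = inbred),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers%s%s\n",
              nrow(x$dosages), ncol(x$dosages),
              if (x$inbred) " (fully inbred)" else "",
              if (!is.null(x$map)) sprintf(", %d chromosome(s)",
                                           length(unique(x$map$chrom))) else ""))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

#' Additive genomic relationship matrix from marker dosages
#'
#' Computes the realized additive relationship matrix A from marker data.
#' The default is the centered cross-product scaled by the expected marker
#' variance, A = ZZ'/(2 * sum p_l (1 - p_l)) with Z the column-centered
#' dosage matrix and p_l allele frequencies computed from the candidate set
#' itself (VanRaden method 1). Monomorphic markers contribute zero to both
#' numerator and denominator. The alternative \code{"standardized"} method
#' scales each centered marker by its own standard deviation
#' sqrt(2 p_l (1 - p_l)) and averages across polymorphic markers (VanRaden
#' method 2).
#'
#' Because markers are centered, the result is invariant to swapping the
#' allele labelling (dosage d -> 2 - d) at any subset of markers.
#'
#' @param G a [genotype_matrix()].
#' @param method one of \code{"vanraden"} (default) or \code{"standardized"}.
#' @return An object of class \code{RelationshipMatrix}: list with the m x m
#'   symmetric matrix \code{A} and \code{ids}.
#' @export
compute_relationship <- function(G, method = c("vanraden", "standardized")) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  method <- match.arg(method)
  M <- G$dosages
  if (nrow(M) < 2) .stopf("need at least 2 individuals")
  p <- colMeans(M) / 2
  pq <- p * (1 - p)
  poly <- pq > 0
  if (!any(poly)) .stopf("zero scaling denominator: all markers are monomorphic")
  Z <- sweep(M, 2, 2 * p, "-")
  if (method == "vanraden") {
    A <- tcrossprod(Z) / (2 * sum(pq))
  } else {
    Zs <- sweep(Z[, poly, drop = FALSE], 2, sqrt(2 * pq[poly]), "/")
    A <- tcrossprod(Zs) / sum(poly)
  }
  A <- (A + t(A)) / 2
  dimnames(A) <- list(G$ids, G$ids)
  relationship_matrix(A)
}

#' Construct a relationship matrix object
#'
#' @param A symmetric m x m matrix of additive relationships (row/column names
#'   used as individual ids when present).
#' @param ids optional character vector of m individual ids.
#' @return Object of class \code{RelationshipMatrix}.
#' @export
relationship_matrix <- function(A, ids = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) .stopf("relationship matrix must be square")
  if (max(abs(A - t(A))) > 1e-8) .stopf("relationship matrix is not symmetric")
  if (any(diag(A) < 0)) .stopf("negative diagonal entries in relationship matrix")
  ids <- ids %||% rownames(A) %||% paste0("ind", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, ids = ids), class = "RelationshipMatrix")
}

#' @export
print.RelationshipMatrix <- function(x, ...) {
  cat(sprintf("RelationshipMatrix: %d individuals, mean diagonal %.3f\n",
              nrow(x$A), mean(diag(x$A))))
  invisible(x)
}

#' Additive marker effects for one or more traits
#'
#' @param beta numeric matrix (or vector) of allele-substitution effects,
#'   markers in rows, traits in columns.
#' @param trait_names optional trait labels.
#' @return Object of class \code{MarkerEffects}.
#' @export
marker_effects <- function(beta, trait_names = NULL) {
  beta <- as.matrix(beta)
  if (anyNA(beta)) .stopf("marker effects contain missing values")
  if (is.null(colnames(beta)))
    colnames(beta) <- trait_names %||% paste0("trait", seq_len(ncol(beta)))
  structure(list(beta = beta, trait_names = colnames(beta)),
            class = "MarkerEffects")
}

#' Genetic values from marker effects
#'
#' Genotypic value of each individual for each trait as the sum over loci of
#' dosage times allele-substitution effect: values = dosages %*% beta.
#'
#' @param G a [genotype_matrix()].
#' @param E a [marker_effects()] with one row per marker of \code{G}.
#' @return A [breeding_values()] object (unstandardized).
#' @export
genetic_values <- function(G, E) {
  stopifnot(inherits(G, "GenotypeMatrix"), inherits(E, "MarkerEffects"))
  if (nrow(E$beta) != ncol(G$dosages))
    .stopf("effect table has %d rows but genotypes have %d markers",
           nrow(E$beta), ncol(G$dosages))
  v <- G$dosages %*% E$beta
  breeding_values(v, standardized = FALSE)
}
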