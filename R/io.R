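# Delimited-text readers and writers. Outputs are tab-separated with a
# commented header documenting columns and units (positions in Morgans in
# machine-readable files); input delimiters (comma/tab) are autodetected.
# Indices are 1-based in all files.

.detect_sep <- function(path) {
  line <- readLines(path, n = 50)
  line <- line[!startsWith(line, "#")][1]
  if (grepl("\t", line)) "\t" else ","
}

.read_table <- function(path, sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- sep %||% .detect_sep(path)
  read.table(path, header = TRUE, sep = sep, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

.write_table <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.num <- function(x) format(x, digits = 17, trim = TRUE)

#' Read a genotype matrix from delimited text or VCF
#'
#' Delimited files have one row per individual: first column the individual
#' id, remaining columns marker dosages in \{0,1,2\} with marker ids in the
#' header. VCF input (requires the vcfR package) is restricted to biallelic
#' SNPs with a GT field; dosage is the ALT allele count and missing genotypes
#' are rejected.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"csv"} (any delimited
#'   text) or \code{"vcf"}.
#' @param map optional path to a map file with columns \code{marker},
#'   \code{chrom}, \code{pos} (Morgans).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "csv"
  map_df <- if (!is.null(map)) .read_table(map) else NULL
  if (format == "csv") {
    df <- .read_table(path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      .stopf("duplicate individual id '%s'", ids[anyDuplicated(ids)])
    M <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(M)) .stopf("non-numeric dosage values in %s", path)
    bad <- which(!(M %in% c(0, 1, 2)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(M))
      .stopf("invalid dosage %s at data row %d, column '%s' of %s",
             format(M[bad[1]]), rc[1], colnames(M)[rc[2]], path)
    }
    rownames(M) <- ids
    return(genotype_matrix(M, map = map_df))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stopf("VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  bi <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  if (!all(bi)) .stopf("non-biallelic or non-SNP record at VCF row %s",
                       paste(which(!bi), collapse = ","))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt) || any(gt %in% c(".", "./.", ".|.")))
    .stopf("missing GT entries are not supported")
  dos <- matrix(vapply(strsplit(gsub("\\|", "/", gt), "/"),
                       function(a) sum(a == "1"), 0L),
                nrow = nrow(gt), dimnames = dimnames(gt))
  M <- t(dos)
  colnames(M) <- fix[, "ID"]
  if (is.null(map_df) && !anyNA(fix[, "POS"]))
    map_df <- data.frame(marker = colnames(M), chrom = fix[, "CHROM"],
                         pos = as.numeric(fix[, "POS"]) / 1e8)  # placeholder scale
  genotype_matrix(M, map = map_df)
}

#' Write a genotype matrix (and optionally its map) to delimited text
#'
#' @param G a [genotype_matrix()].
#' @param path output file (tab-separated, id column first).
#' @param map_path optional output path for the map file.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(G, path, map_path = NULL) {
  df <- data.frame(id = G$ids, G$dosages, check.names = FALSE)
  .write_table(df, path,
               c("genotype dosages: count of alternate allele in {0,1,2}",
                 "columns: id, then one column per marker"))
  if (!is.null(map_path) && !is.null(G$map))
    .write_table(G$map, map_path,
                 c("marker map; pos in Morgans",
                   "columns: marker, chrom, pos"))
  invisible(path)
}

#' Read a breeding-value (GEBV) table
#'
#' First column individual id, remaining columns one per trait.
#'
#' @param path input file.
#' @param maximize per-trait direction flags (recycled).
#' @return A [breeding_values()] object.
#' @export
read_breeding_values <- function(path, maximize = TRUE) {
  df <- .read_table(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  breeding_values(M, maximize = maximize)
}

#' Write a breeding-value table
#' @param BV a [breeding_values()] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_breeding_values <- function(BV, path) {
  df <- data.frame(id = rownames(BV$values), BV$values, check.names = FALSE)
  .write_table(df, path, c("breeding values; columns: id, then one per trait",
                           sprintf("maximize: %s",
                                   paste(BV$maximize, collapse = ","))))
  invisible(path)
}

#' Read a marker-effect table (marker id column plus one column per trait)
#' @param path input file.
#' @return A [marker_effects()] object.
#' @export
read_marker_effects <- function(path) {
  df <- .read_table(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  marker_effects(M)
}

#' Write a marker-effect table
#' @param E a [marker_effects()] object.
#' @param path output file.
#' @param marker_ids optional marker ids.
#' @return \code{path}, invisibly.
#' @export
write_marker_effects <- function(E, path, marker_ids = NULL) {
  ids <- marker_ids %||% rownames(E$beta) %||% paste0("m", seq_len(nrow(E$beta)))
  df <- data.frame(marker = ids, E$beta, check.names = FALSE)
  .write_table(df, path, "additive allele-substitution effects per trait")
  invisible(path)
}

#' Read / write a relationship matrix (square, ids on both axes)
#' @param path file path.
#' @return A [relationship_matrix()].
#' @export
read_grm <- function(path) {
  df <- .read_table(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  relationship_matrix(M)
}

#' @rdname read_grm
#' @param A a [relationship_matrix()].
#' @export
write_grm <- function(A, path) {
  df <- data.frame(id = A$ids, A$A, check.names = FALSE)
  .write_table(df, path, "additive genomic relationship matrix (VanRaden scaling)")
  invisible(path)
}

#' Write a contribution frontier to tab-separated text
#'
#' One row per solution: scalarization weights, objective values, and the
#' sparse non-zero contributions as \code{id=value} pairs. The direction flags
#' are stored in the header so the file round-trips through
#' [read_frontier()].
#'
#' @param F a [pareto_frontier()] of contribution solutions.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_frontier <- function(F, path) {
  stopifnot(inherits(F, "ParetoFrontier"))
  dirs <- .frontier_dirs(F)
  rows <- lapply(seq_along(F$solutions), function(i) {
    s <- F$solutions[[i]]
    ct <- s$contribution
    nz <- which(ct$c > 0)
    data.frame(
      solution = i,
      weights = paste(.num(s$scalarization_weights), collapse = "/"),
      t(setNames(s$objectives$values, paste0("obj", seq_along(s$objectives$values)))),
      contributions = paste(sprintf("%s=%s", ct$ids[nz], .num(ct$c[nz])),
                            collapse = ";"),
      check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  .write_table(df, path,
               c("Pareto frontier of parental contributions",
                 "columns: solution, scalarization weights (w1/w2/...),",
                 "objectives obj1..objK (gains then group co-ancestry),",
                 "non-zero contributions as id=value;...",
                 sprintf("maximize: %s", paste(dirs, collapse = ",")),
                 sprintf("ids: %s", paste(F$solutions[[1]]$contribution$ids,
                                          collapse = ","))))
  invisible(path)
}

#' Read a contribution frontier written by [write_frontier()]
#' @param path input file.
#' @return A [pareto_frontier()].
#' @export
read_frontier <- function(path) {
  hdr <- grep("^# ", readLines(path, n = 20), value = TRUE)
  dirline <- sub("^# maximize: ", "", grep("^# maximize:", hdr, value = TRUE))
  idline <- sub("^# ids: ", "", grep("^# ids:", hdr, value = TRUE))
  dirs <- as.logical(strsplit(dirline, ",")[[1]])
  all_ids <- strsplit(idline, ",")[[1]]
  df <- .read_table(path, sep = "\t")
  objcols <- grep("^obj", names(df))
  sols <- lapply(seq_len(nrow(df)), function(i) {
    cv <- numeric(length(all_ids)); names(cv) <- all_ids
    for (tok in strsplit(df$contributions[i], ";")[[1]]) {
      kv <- strsplit(tok, "=")[[1]]
      cv[kv[1]] <- as.numeric(kv[2])
    }
    structure(list(
      contribution = contribution_vector(cv / sum(cv), ids = all_ids),
      objectives = objective_vector(as.numeric(df[i, objcols]), dirs),
      scalarization_weights = as.numeric(strsplit(df$weights[i], "/")[[1]])),
      class = "FrontierSolution")
  })
  pareto_frontier(sols, deduplicated = TRUE)
}

#' Write / read a mating plan (TSV: parent_i, parent_j, n)
#' @param P a [mating_plan()].
#' @param path file path.
#' @return \code{path} (writer) or a [mating_plan()] (reader).
#' @export
write_plan <- function(P, path) {
  .write_table(P$crosses, path,
               c("mating plan; columns: parent_i, parent_j (1-based indices),",
                 "n = number of times the cross is made"))
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  df <- .read_table(path, sep = "\t")
  mating_plan(as.matrix(df[, c("parent_i", "parent_j", "n")]))
}

#' Write a breeding trajectory
#'
#' Columns: cycle, inbreeding, then per trait the mean true breeding value,
#' genetic variance, and cumulative standardized gain relative to cycle 0
#' (2 + 3k columns).
#'
#' @param traj a [run_breeding()] trajectory data frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  k <- sum(grepl("^mean_trait", names(traj)))
  out <- data.frame(cycle = traj$cycle, inbreeding = traj$inbreeding)
  for (t in seq_len(k)) {
    mu <- traj[[paste0("mean_trait", t)]]
    v <- traj[[paste0("var_trait", t)]]
    sd0 <- sqrt(v[1])
    out[[paste0("mean_trait", t)]] <- mu
    out[[paste0("var_trait", t)]] <- v
    out[[paste0("gain_trait", t)]] <- if (sd0 > 0) (mu - mu[1]) / sd0 else mu - mu[1]
  }
  .write_table(out, path,
               c("breeding trajectory; one row per cycle (0 = base population)",
                 "columns: cycle, mean inbreeding, then per trait:",
                 "mean true breeding value, genetic variance,",
                 "cumulative gain in base-population genetic SD units"))
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line invocation records its command, resolved configuration,
#' seed, input file digests, output paths and wall time as JSON, making runs
#' reconstructible.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config resolved configuration list.
#' @param seed integer seed used.
#' @param inputs,outputs character vectors of file paths.
#' @param wall_time elapsed seconds.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, inputs, outputs,
                           wall_time) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         input_digests = digests, outputs = as.list(outputs),
         wall_time_sec = wall_time),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
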