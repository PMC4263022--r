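# Input tables and result serialization.
#
# All tables are tab-separated UTF-8 with a header row.  The presence
# matrix has taxa as rows (first column = taxon identifier) and samples as
# columns; cells must be exactly 0 or 1.  Missing lineage ranks are encoded
# as empty strings and treated as unknown (never equal to each other).

#' Construct and validate a presence-absence matrix
#'
#' Wraps a binary taxa-by-samples matrix together with its identifiers and
#' per-taxon prevalence (row sums).  Every cell must be exactly 0 or 1 and
#' identifiers must be unique.
#'
#' @param X numeric or integer matrix with taxa as rows and samples as
#'   columns; must carry row and column names unless `taxa` / `samples`
#'   are given.
#' @param taxa,samples optional character vectors of identifiers.
#' @return An object of class `presence_matrix`: a list with elements
#'   `X` (integer matrix), `taxa`, `samples` and `prevalence`.
#' @export
presence_matrix <- function(X, taxa = rownames(X), samples = colnames(X)) {
  if (!is.matrix(X)) stop("X must be a matrix")
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(X)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(X)))
  if (length(taxa) != nrow(X)) stop("taxa length does not match nrow(X)")
  if (length(samples) != ncol(X)) stop("samples length does not match ncol(X)")
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(samples)) stop("duplicate sample identifiers: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  bad <- which(is.na(X) | !(X == 0 | X == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary cell at taxon '%s', sample '%s' (value %s)",
                 taxa[bad[1, 1]], samples[bad[1, 2]],
                 format(X[bad[1, , drop = FALSE]])))
  }
  Xi <- matrix(as.integer(X), nrow(X), ncol(X),
               dimnames = list(taxa, samples))
  structure(list(X = Xi, taxa = taxa, samples = samples,
                 prevalence = rowSums(Xi)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  n <- length(x$taxa); m <- length(x$samples)
  cat(sprintf("presence_matrix: %d taxa x %d samples (%d taxon pairs)\n",
              n, m, n * (n - 1) / 2))
  cat(sprintf("  fill: %.1f%%; prevalence range %d..%d\n",
              100 * mean(x$X), min(x$prevalence), max(x$prevalence)))
  invisible(x)
}

#' Validate a sample environment hierarchy table
#'
#' Each sample is labelled at three nested levels: subtype, type,
#' supertype.  The mapping subtype -> type -> supertype must be a function
#' (no subtype may map to two types, no type to two supertypes).
#'
#' @param df data.frame with columns `sample`, `subtype`, `type`,
#'   `supertype`.
#' @return `df` with class `env_hierarchy` prepended.
#' @export
environment_hierarchy <- function(df) {
  need <- c("sample", "subtype", "type", "supertype")
  if (!all(need %in% names(df)))
    stop("environment table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (v in need) df[[v]] <- as.character(df[[v]])
  if (anyDuplicated(df$sample))
    stop("duplicate sample identifiers in environment table")
  if (any(is.na(df)) || any(df == ""))
    stop("environment labels must be non-empty at every level")
  for (pair in list(c("subtype", "type"), c("type", "supertype"))) {
    map <- unique(df[pair])
    dup <- map[[1]][duplicated(map[[1]])]
    if (length(dup) > 0)
      stop(sprintf("inconsistent hierarchy: %s '%s' maps to multiple %ss",
                   pair[1], dup[1], pair[2]))
  }
  class(df) <- c("env_hierarchy", "data.frame")
  df
}

#' Validate a taxonomy lineage table
#'
#' Lineages at ranks phylum, class, order, family (input taxa are genera;
#' the root is implicit).  Unknown ranks are empty strings and never
#' compare equal to each other.  Ranks must be consistent: taxa sharing a
#' named family share order, class and phylum, and so on up.
#'
#' @param df data.frame with columns `taxon`, `phylum`, `class`, `order`,
#'   `family`.
#' @return `df` with class `taxonomy_table` prepended.
#' @export
taxonomy_table <- function(df) {
  need <- c("taxon", "phylum", "class", "order", "family")
  if (!all(need %in% names(df)))
    stop("taxonomy table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (v in need) {
    df[[v]] <- as.character(df[[v]])
    df[[v]][is.na(df[[v]])] <- ""
  }
  if (anyDuplicated(df$taxon)) stop("duplicate taxon identifiers in taxonomy")
  ranks <- c("phylum", "class", "order", "family")
  for (k in seq(2, 4)) {     # each named rank determines all coarser ranks
    child <- ranks[k]
    keep <- df[[child]] != ""
    map <- unique(df[keep, ranks[seq_len(k)], drop = FALSE])
    dup <- map[[child]][duplicated(map[[child]])]
    if (length(dup) > 0)
      stop(sprintf("inconsistent taxonomy: %s '%s' has multiple parent lineages",
                   child, dup[1]))
  }
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, colClasses = "character",
             quote = "", comment.char = "")
}

#' Read a presence-absence matrix from TSV
#'
#' Rows are taxa (first column holds the taxon identifier), columns are
#' samples.  Any cell other than `0` or `1` is a validation error naming
#' the offending row and column.
#'
#' @param path path to the TSV file.
#' @return A [presence_matrix()].
#' @export
read_presence_matrix <- function(path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2) stop("matrix file must have a taxon column plus samples")
  taxa <- tab[[1]]
  samples <- colnames(tab)[-1]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  ok <- matrix(cells %in% c("0", "1"), nrow(cells), ncol(cells))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary cell '%s' at taxon '%s', sample '%s' in %s",
                 cells[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]],
                 samples[bad[1, 2]], path))
  X <- matrix(as.integer(cells), nrow(cells), ncol(cells))
  presence_matrix(X, taxa = taxa, samples = samples)
}

#' Read and cross-validate the three input tables
#'
#' Reads the presence matrix, the sample environment hierarchy and the
#' taxonomy table, and cross-references them.  Samples in the matrix that
#' lack an environment label abort by default (the stratified null model
#' is undefined for them); set `drop_unlabelled = TRUE` to drop them
#' instead.  Taxa lacking a lineage are kept with unknown ranks unless
#' `drop_unknown_taxa = TRUE`.
#'
#' @param matrix_path,env_path,taxonomy_path paths to the three TSV files.
#' @param drop_unlabelled drop unlabelled samples instead of aborting.
#' @param drop_unknown_taxa drop taxa without a taxonomy row.
#' @return list with elements `presence`, `env`, `taxonomy`.
#' @export
read_dataset <- function(matrix_path, env_path, taxonomy_path,
                         drop_unlabelled = FALSE, drop_unknown_taxa = FALSE) {
  pm <- read_presence_matrix(matrix_path)
  env <- environment_hierarchy(read_tsv(env_path))
  tax <- taxonomy_table(read_tsv(taxonomy_path))

  missing_env <- setdiff(pm$samples, env$sample)
  if (length(missing_env) > 0) {
    if (!drop_unlabelled)
      stop(length(missing_env), " sample(s) lack an environment label ",
           "(first: '", missing_env[1], "'); use drop_unlabelled = TRUE to drop")
    warning("dropping ", length(missing_env), " unlabelled sample(s)")
    keep <- pm$samples %in% env$sample
    pm <- presence_matrix(pm$X[, keep, drop = FALSE])
  }
  env <- env[match(pm$samples, env$sample), , drop = FALSE]
  rownames(env) <- NULL
  class(env) <- c("env_hierarchy", "data.frame")

  missing_tax <- setdiff(pm$taxa, tax$taxon)
  if (length(missing_tax) > 0) {
    if (drop_unknown_taxa) {
      warning("dropping ", length(missing_tax), " taxa without lineage")
      keep <- pm$taxa %in% tax$taxon
      pm <- presence_matrix(pm$X[keep, , drop = FALSE])
    } else {
      warning(length(missing_tax), " taxa lack a lineage; kept with unknown ranks")
      add <- data.frame(taxon = missing_tax, phylum = "", class = "",
                        order = "", family = "", stringsAsFactors = FALSE)
      tax <- rbind(as.data.frame(tax), add)
    }
  }
  tax <- tax[match(pm$taxa, tax$taxon), , drop = FALSE]
  rownames(tax) <- NULL
  class(tax) <- c("taxonomy_table", "data.frame")

  list(presence = pm, env = env, taxonomy = tax)
}

#' Write the three input tables of a dataset
#'
#' Inverse of [read_dataset()]; used to persist synthetic datasets.
#'
#' @param dataset list with `presence`, `env`, `taxonomy` (as returned by
#'   [read_dataset()] or [generate_dataset()]).
#' @param matrix_path,env_path,taxonomy_path output paths.
#' @return invisibly, the three paths.
#' @export
write_dataset <- function(dataset, matrix_path, env_path, taxonomy_path) {
  pm <- dataset$presence
  out <- data.frame(taxon = pm$taxa, pm$X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("taxon", pm$samples)
  write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(dataset$env), env_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(dataset$taxonomy), taxonomy_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, env_path, taxonomy_path))
}

#' Write significant associations to TSV
#'
#' One row per network edge with the pair, the association type, the
#' observed co-occurrence count, the raw score of the edge's type, its Z
#' score and the evaluability flags.  Rows are ordered lexicographically
#' by taxon pair, so the output is deterministic.
#'
#' @param network an `assoc_network` (see [build_network()]).
#' @param scores the calibrated `score_table` the network was built from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(network, scores, path) {
  stopifnot(inherits(network, "assoc_network"),
            inherits(scores, "score_table"))
  ed <- network$edges
  cols <- c("taxon_i", "taxon_j", "association_type", "n_ij",
            "raw_score", "Z", "evaluable_agg", "evaluable_seg")
  if (nrow(ed) == 0) {
    empty <- setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    write.table(empty, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  key_net <- paste(ed$taxon_i, ed$taxon_j, sep = "\r")
  key_sc <- paste(scores$taxon_i, scores$taxon_j, sep = "\r")
  idx <- match(key_net, key_sc)
  if (anyNA(idx)) stop("network and score table refer to different pairs")
  out <- data.frame(
    taxon_i = ed$taxon_i, taxon_j = ed$taxon_j,
    association_type = ed$type,
    n_ij = scores$n_ij[idx],
    raw_score = ifelse(ed$type == "aggregation",
                       scores$S_agg[idx], scores$S_seg[idx]),
    Z = ed$Z,
    evaluable_agg = scores$evaluable_agg[idx],
    evaluable_seg = scores$evaluable_seg[idx],
    stringsAsFactors = FALSE)
  out <- out[order(out$taxon_i, out$taxon_j, method = "radix"), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an associations TSV written by [write_associations()]
#'
#' @param path path to the file.
#' @return data.frame with typed columns.
#' @export
read_associations <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) > 0) {
    tab$n_ij <- as.integer(tab$n_ij)
    tab$raw_score <- as.numeric(tab$raw_score)
    tab$Z <- as.numeric(tab$Z)
    tab$evaluable_agg <- as.logical(tab$evaluable_agg)
    tab$evaluable_seg <- as.logical(tab$evaluable_seg)
  }
  tab
}
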