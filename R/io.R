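#' Construct a survival cohort
#'
#' Bundles a genes-by-samples expression matrix with per-sample follow-up
#' time and event indicator.  This is the unit every signature is tested
#' against: stratify the samples by the signature's PC1 median, then test the
#' two groups for a survival difference.
#'
#' @param expression numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param time per-sample non-negative follow-up time, same unit throughout.
#' @param event per-sample event indicator, 1 = event observed, 0 = censored.
#' @return an object of class `survival_cohort` with fields `expression`,
#'   `gene_ids`, `sample_ids`, `time`, `event`.
#' @export
survival_cohort <- function(expression, time = NULL, event = NULL) {
  stopifnot(is.matrix(expression), is.numeric(expression))
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expression)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expression)))
    stop("duplicate sample ids in expression matrix")
  ns <- ncol(expression)
  if (!is.null(time)) {
    stopifnot(length(time) == ns, length(event) == ns)
    if (anyNA(time) || anyNA(event)) stop("missing survival entries")
    if (any(time < 0)) stop("negative survival time")
    if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  }
  structure(
    list(expression = expression,
         gene_ids = rownames(expression),
         sample_ids = colnames(expression),
         time = if (is.null(time)) NULL else as.numeric(time),
         event = if (is.null(event)) NULL else as.integer(event)),
    class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d genes x %d samples", nrow(x$expression),
              ncol(x$expression)))
  if (!is.null(x$time))
    cat(sprintf("; %d events / %d samples", sum(x$event), length(x$event)))
  cat("\n")
  invisible(x)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Duplicate gene rows are collapsed by their mean (logged); duplicate sample
#' IDs are an error.
#'
#' @param path TSV file path.
#' @param dialect currently only `"genes_in_rows"`.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, dialect = "genes_in_rows") {
  dialect <- match.arg(dialect, "genes_in_rows")
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character"),
    error = function(e) stop("empty or malformed expression file: ", path))
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or malformed expression file: ", path)
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ID in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- raw[[1L]]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !(raw[[j + 1L]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric expression value at gene row '%s', sample column '%s'",
                   genes[bad[1L]], samples[j]))
    mat[, j] <- v
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    mat <- rowsum(mat, group = genes, reorder = FALSE) /
      as.vector(table(genes)[unique(genes)])
    rownames(mat) <- unique(genes)
    rs_log("read_expression: collapsed %d duplicate gene rows by mean", n_dup)
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Write an expression matrix as TSV (genes in rows)
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample survival table
#'
#' TSV with columns `sample_id`, `time`, `event`.  Samples absent from
#' `sample_ids` (when given) are dropped with a logged count.
#'
#' @param path TSV path.
#' @param sample_ids optional character vector restricting (and ordering) the
#'   returned records, e.g. the cohort's expression columns.
#' @return data.frame with columns sample_id, time, event.
#' @export
read_survival <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival file must have columns sample_id, time, event")
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  if (anyNA(df$time) || anyNA(df$event)) stop("missing survival entries")
  if (any(df$time < 0)) stop("negative survival time for sample ",
                             df$sample_id[which(df$time < 0)[1L]])
  if (!all(df$event %in% c(0, 1))) stop("event indicator outside {0,1}")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in survival file")
  if (!is.null(sample_ids)) {
    extra <- setdiff(df$sample_id, sample_ids)
    if (length(extra)) {
      warning(sprintf("dropping %d survival samples absent from expression", length(extra)))
      df <- df[df$sample_id %in% sample_ids, , drop = FALSE]
    }
    missing <- setdiff(sample_ids, df$sample_id)
    if (length(missing))
      stop("no survival record for samples: ", paste(utils::head(missing, 5), collapse = ", "))
    df <- df[match(sample_ids, df$sample_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Construct a gene set collection
#' @param sets named list of character vectors (gene symbols).
#' @param descriptions optional character vector, one per set.
#' @return object of class `gene_set_collection` (a named list with a
#'   `descriptions` attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene set")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  attr(sets, "descriptions") <- stats::setNames(descriptions, names(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `name TAB description TAB gene1 TAB gene2 ...`, one set per
#' line.  Duplicate genes within a line are deduplicated; a duplicated set
#' name or a line with fewer than three fields is an error.
#'
#' @param path GMT path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate set name in GMT: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write gene sets to a GMT file
#' @param sets a [gene_set_collection()] or named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a weighted (undirected) network
#'
#' Gene-labelled nodes with symmetric, non-negative edge weights in `[0, 1]`
#' (STRING-style confidence scores rescaled to the unit interval).  Self
#' loops are forbidden; parallel/reciprocal duplicates are merged keeping the
#' maximum weight.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param nodes optional character vector of node names (isolated nodes are
#'   allowed); defaults to the union of the edge endpoints.
#' @return object of class `weighted_network` with fields `nodes`, `edges`.
#' @export
weighted_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% colnames(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$weight < 0 | edges$weight > 1))
    stop("edge weights must lie in [0, 1]")
  if (any(edges$from == edges$to)) stop("self loops are not allowed")
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, max)
    ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(from = ab[, 1L], to = ab[, 2L], weight = as.numeric(w),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = a, to = b, weight = edges$weight,
                        stringsAsFactors = FALSE)
  }
  nodes <- union(nodes, union(edges$from, edges$to))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-style weighted edge list
#'
#' TSV with two protein/gene columns and one or more integer confidence
#' columns on the STRING 0-1000 scale.  The chosen score column is divided by
#' `scale` to give weights in `[0, 1]`; edges below `min_score` (on the raw
#' scale) are dropped; reciprocal duplicate rows collapse to one undirected
#' edge; self edges are dropped with a warning.
#'
#' @param path TSV path; first two columns are the endpoints.
#' @param score_column name of the confidence column; default the
#'   `combined_score` column if present, else the last column.
#' @param min_score minimum raw confidence retained (default 0).
#' @param scale raw-scale maximum (default 1000).
#' @return a [weighted_network()].
#' @export
read_string_edges <- function(path, score_column = NULL, min_score = 0,
                              scale = 1000) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 3L) stop("edge file needs two endpoint columns and a score column")
  if (is.null(score_column))
    score_column <- if ("combined_score" %in% colnames(df))
      "combined_score" else colnames(df)[ncol(df)]
  if (!score_column %in% colnames(df)) stop("no such score column: ", score_column)
  w <- as.numeric(df[[score_column]])
  if (anyNA(w)) stop("non-numeric score in column ", score_column)
  if (any(w < 0 | w > scale))
    stop(sprintf("score outside [0, %g] in column %s", scale, score_column))
  from <- as.character(df[[1L]])
  to <- as.character(df[[2L]])
  keep <- w >= min_score
  self <- from == to
  if (any(self)) {
    warning(sprintf("dropped %d self edges", sum(self & keep)))
    keep <- keep & !self
  }
  weighted_network(data.frame(from = from[keep], to = to[keep],
                              weight = w[keep] / scale))
}

#' Write a network as a STRING-style TSV
#' @param network a [weighted_network()].
#' @param path output path.
#' @param scale raw-scale maximum used for the integer score column.
#' @export
write_string_edges <- function(network, path, scale = 1000) {
  df <- data.frame(protein1 = network$edges$from,
                   protein2 = network$edges$to,
                   combined_score = as.integer(round(network$edges$weight * scale)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize gene identifiers across cohort, gene sets and network
#'
#' Maps every object onto one shared symbol namespace via a two-column
#' mapping (source identifier, gene symbol), e.g. Entrez or Ensembl protein
#' IDs to HUGO symbols.  Unmapped identifiers are dropped from the object
#' they appear in (never imputed), with per-object logged counts.  A source
#' ID mapping to two different symbols is an error.
#'
#' @param cohort a [survival_cohort()] or NULL.
#' @param sets a [gene_set_collection()] or NULL.
#' @param network a [weighted_network()] or NULL.
#' @param mapping data.frame with columns `source_id`, `gene_symbol`.
#' @return list with elements `cohort`, `sets`, `network` (those supplied,
#'   re-keyed by symbol).
#' @export
harmonize_ids <- function(cohort = NULL, sets = NULL, network = NULL, mapping) {
  stopifnot(all(c("source_id", "gene_symbol") %in% colnames(mapping)))
  mapping$source_id <- as.character(mapping$source_id)
  mapping$gene_symbol <- as.character(mapping$gene_symbol)
  mapping <- unique(mapping[c("source_id", "gene_symbol")])
  if (anyDuplicated(mapping$source_id))
    stop("ambiguous mapping: source id ",
         mapping$source_id[duplicated(mapping$source_id)][1L],
         " maps to multiple symbols")
  lut <- stats::setNames(mapping$gene_symbol, mapping$source_id)

  out <- list(cohort = NULL, sets = NULL, network = NULL)
  if (!is.null(cohort)) {
    sym <- lut[cohort$gene_ids]
    drop <- is.na(sym)
    if (any(drop)) rs_log("harmonize_ids: dropped %d unmapped cohort genes", sum(drop))
    mat <- cohort$expression[!drop, , drop = FALSE]
    rownames(mat) <- sym[!drop]
    if (anyDuplicated(rownames(mat))) {
      g <- rownames(mat)
      mat <- rowsum(mat, g, reorder = FALSE) / as.vector(table(g)[unique(g)])
      rownames(mat) <- unique(g)
      rs_log("harmonize_ids: collapsed duplicate symbols by mean")
    }
    out$cohort <- survival_cohort(mat, cohort$time, cohort$event)
  }
  if (!is.null(sets)) {
    n_drop <- 0L
    mapped <- lapply(unclass(sets), function(g) {
      sym <- lut[g]
      n_drop <<- n_drop + sum(is.na(sym))
      unique(sym[!is.na(sym)])
    })
    if (n_drop) rs_log("harmonize_ids: dropped %d unmapped set genes", n_drop)
    mapped <- mapped[lengths(mapped) > 0L]
    out$sets <- gene_set_collection(mapped)
  }
  if (!is.null(network)) {
    e <- network$edges
    f <- lut[e$from]; t2 <- lut[e$to]
    keep <- !is.na(f) & !is.na(t2) & f != t2
    n_nodes_drop <- sum(is.na(lut[network$nodes]))
    if (n_nodes_drop) rs_log("harmonize_ids: dropped %d unmapped network nodes", n_nodes_drop)
    nodes <- unname(lut[network$nodes])
    nodes <- unique(nodes[!is.na(nodes)])
    out$network <- weighted_network(
      data.frame(from = f[keep], to = t2[keep], weight = e$weight[keep]),
      nodes = nodes)
  }
  out
}
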