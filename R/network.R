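#' Occurrence scores of genes over selected signatures
#'
#' The raw score of a gene is the number of selected signatures that contain
#' it; a gene occurring in 20 selected signatures scores 20.
#'
#' @param selected_signatures list of gene vectors (the selected signatures).
#' @param gene_ids ordered gene universe defining the score vector's index.
#' @return named numeric vector of counts over `gene_ids`.
#' @export
occurrence_scores <- function(selected_signatures, gene_ids) {
  s <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  if (length(selected_signatures)) {
    tab <- table(unlist(lapply(selected_signatures, unique), use.names = FALSE))
    hit <- intersect(names(tab), gene_ids)
    s[hit] <- as.numeric(tab[hit])
  }
  s
}

#' Weighted graph Laplacian over a gene universe
#'
#' `H = D - A` with `A` the symmetric weighted adjacency matrix of the
#' network restricted to `gene_ids` and `D` the diagonal of its row sums.
#' Genes absent from the network become isolated (all-zero) rows/columns, so
#' they stay eligible downstream.
#'
#' @param network a [weighted_network()] whose nodes are a subset of
#'   `gene_ids`.
#' @param gene_ids ordered gene universe.
#' @return sparse symmetric `Matrix` with zero row sums.
#' @export
build_laplacian <- function(network, gene_ids) {
  if (!all(network$nodes %in% gene_ids))
    stop("network contains nodes outside the gene universe")
  e <- network$edges
  if (any(e$weight < 0)) stop("negative edge weight")
  n <- length(gene_ids)
  i <- match(e$from, gene_ids)
  j <- match(e$to, gene_ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = c(e$weight, e$weight), dims = c(n, n),
                            dimnames = list(gene_ids, gene_ids))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

#' Heat diffusion kernel of the weighted Laplacian
#'
#' The diffusion kernel of Kondor and Lafferty: `k_beta = exp(-beta * H)`
#' with `H = D - A`.  (The exponential of +H amplifies instead of smoothing
#' and is unbounded in the graph size; the heat kernel uses the negative
#' Laplacian.)  Realized by eigendecomposition of the symmetric Laplacian,
#' suitable for graphs up to a few thousand nodes.  The kernel is symmetric,
#' entrywise non-negative (up to roundoff) and doubly stochastic: each
#' row/column sums to 1, so diffusion conserves total score mass.
#'
#' @param H Laplacian from [build_laplacian()] (dense or sparse).
#' @param beta diffusion strength (>= 0); 0.3 is the pipeline default.
#' @return object of class `diffusion_operator` with fields `gene_ids`,
#'   `beta`, `kernel` (dense matrix).
#' @export
diffusion_kernel <- function(H, beta = 0.3) {
  if (beta < 0) stop("beta must be >= 0")
  Hd <- as.matrix(H)
  if (is.null(rownames(Hd))) stop("Laplacian must carry gene dimnames")
  if (max(abs(Hd - t(Hd))) > 1e-10) stop("Laplacian must be symmetric")
  if (max(abs(rowSums(Hd))) > 1e-8) stop("Laplacian rows must sum to 0")
  eig <- eigen(Hd, symmetric = TRUE)
  K <- eig$vectors %*% (exp(-beta * eig$values) * t(eig$vectors))
  dimnames(K) <- dimnames(Hd)
  structure(list(gene_ids = rownames(Hd), beta = beta, kernel = K),
            class = "diffusion_operator")
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat(sprintf("diffusion_operator: %d genes, beta = %g\n",
              length(x$gene_ids), x$beta))
  invisible(x)
}

#' Diffuse a score vector through the kernel
#'
#' `S_beta = k_beta %*% S`: each gene's diffusion score blends its own raw
#' score with those of its network neighbours (and, for larger beta, more
#' distant nodes).  Total mass is conserved.
#'
#' @param operator a [diffusion_kernel()].
#' @param scores named numeric vector in the operator's gene order.
#' @return named numeric vector of diffusion scores.
#' @export
diffuse <- function(operator, scores) {
  if (!identical(names(scores), operator$gene_ids))
    stop("score vector ordering does not match operator gene_ids")
  stats::setNames(as.numeric(operator$kernel %*% scores), operator$gene_ids)
}

# All permutations of 1..n (n <= 8), in lexicographic-ish recursive order.
#' @keywords internal
#' @noRd
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[p])
    }
  }
  out
}

#' Permutation scores for diffusion scores
#'
#' For each of `n_perm` uniform random permutations the score vector is
#' permuted across genes, re-diffused through the kernel, and gene `j`'s
#' permutation score is the fraction of permuted diffusion scores at
#' position `j` that are greater than or equal to the observed diffusion
#' score (non-strict, as small as 0).  By default the *diffused* vector
#' `S_beta` is permuted and diffused again (the printed formulation);
#' `null_mode = "raw-scores"` instead permutes the raw occurrence vector.
#'
#' @param operator a [diffusion_kernel()].
#' @param scores named raw score vector (operator gene order).
#' @param n_perm number of permutations (>= 1); ignored when `exhaustive`.
#' @param seed RNG seed.
#' @param null_mode `"as-printed"` (permute S_beta) or `"raw-scores"`.
#' @param exhaustive enumerate all `n!` permutations instead of sampling
#'   (only for small gene universes, n <= 8).
#' @return named numeric vector of permutation scores in `[0, 1]`.
#' @export
permutation_scores <- function(operator, scores, n_perm = 1000L, seed = NULL,
                               null_mode = c("as-printed", "raw-scores"),
                               exhaustive = FALSE) {
  null_mode <- match.arg(null_mode)
  observed <- diffuse(operator, scores)
  base <- if (null_mode == "as-printed") observed else scores
  n <- length(scores)
  if (exhaustive) {
    perms <- all_permutations(n)
    P <- vapply(perms, function(p) unname(base)[p], numeric(n))
    n_perm <- length(perms)
  } else {
    if (is.null(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
    if (is.null(seed)) stop("seed is required for Monte-Carlo permutation scores")
    set.seed(seed)
    P <- vapply(seq_len(n_perm), function(r) unname(base)[sample.int(n)],
                numeric(n))
  }
  D <- operator$kernel %*% P              # each column: one permuted diffusion
  counts <- rowSums(D >= observed)
  stats::setNames(counts / n_perm, operator$gene_ids)
}

#' Call and rank significant genes
#'
#' Genes with permutation score strictly below `alpha` are called
#' significant and sorted by permutation score ascending, then diffusion
#' score descending, then gene id ascending; ranks run 1..k.
#'
#' @param gene_ids gene universe (aligned with the score vectors).
#' @param raw_scores raw occurrence scores.
#' @param diffusion_scores diffusion scores.
#' @param perm_scores permutation scores.
#' @param alpha calling threshold (default 0.05, strict).
#' @return data.frame: gene, raw_score, diffusion_score, permutation_score,
#'   rank (called genes only, in rank order).
#' @export
call_significant_genes <- function(gene_ids, raw_scores, diffusion_scores,
                                   perm_scores, alpha = 0.05) {
  stopifnot(length(gene_ids) == length(raw_scores),
            length(gene_ids) == length(diffusion_scores),
            length(gene_ids) == length(perm_scores))
  keep <- which(perm_scores < alpha)
  o <- keep[order(perm_scores[keep], -diffusion_scores[keep], gene_ids[keep])]
  data.frame(gene = gene_ids[o], raw_score = raw_scores[o],
             diffusion_score = diffusion_scores[o],
             permutation_score = perm_scores[o],
             rank = seq_along(o), row.names = NULL, stringsAsFactors = FALSE)
}

#' Network-diffusion prioritization of genes from selected signatures
#'
#' End-to-end wrapper: occurrence scores over the selected signatures,
#' Laplacian and heat kernel of the weighted network (genes missing from the
#' network are isolated nodes and keep their raw score), permutation scores,
#' and the significant-gene call.
#'
#' @param selected_signatures list of gene vectors.
#' @param network a [weighted_network()].
#' @param gene_ids ordered gene universe; default: union of network nodes and
#'   signature genes.
#' @param beta diffusion strength (default 0.3).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param alpha calling threshold (default 0.05).
#' @param null_mode forwarded to [permutation_scores()].
#' @return list with `table` (all genes, sorted by the ranking key, with a
#'   `significant` flag) and `calls` (the called subset with ranks).
#' @export
prioritize_genes <- function(selected_signatures, network, gene_ids = NULL,
                             beta = 0.3, n_perm = 1000L, seed, alpha = 0.05,
                             null_mode = c("as-printed", "raw-scores")) {
  null_mode <- match.arg(null_mode)
  if (is.null(gene_ids))
    gene_ids <- sort(union(network$nodes,
                           unlist(selected_signatures, use.names = FALSE)))
  S <- occurrence_scores(selected_signatures, gene_ids)
  H <- build_laplacian(network, gene_ids)
  op <- diffusion_kernel(H, beta = beta)
  Sb <- diffuse(op, S)
  perm <- permutation_scores(op, S, n_perm = n_perm, seed = seed,
                             null_mode = null_mode)
  o <- order(perm, -Sb, gene_ids)
  table <- data.frame(gene = gene_ids[o], raw_score = S[o],
                      diffusion_score = Sb[o], permutation_score = perm[o],
                      significant = perm[o] < alpha, row.names = NULL,
                      stringsAsFactors = FALSE)
  calls <- call_significant_genes(gene_ids, S, Sb, perm, alpha = alpha)
  rs_log("prioritize: %d of %d genes called significant at alpha = %g",
         nrow(calls), length(gene_ids), alpha)
  list(table = table, calls = calls)
}
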