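#' Per-gene phenotype means
#'
#' Arithmetic mean expression of each gene within each phenotype group
#' (`N` = good prognosis, `notN` = poor prognosis).
#'
#' @param cohort a [survival_cohort()].
#' @param phenotype per-sample labels, values `"N"` / `"notN"` (character or
#'   factor), aligned with the cohort samples.
#' @param genes genes to compute means for (must be in the cohort).
#' @return list with numeric vectors `mu_N` and `mu_notN`, named by gene.
#' @export
phenotype_means <- function(cohort, phenotype, genes) {
  phenotype <- as.character(phenotype)
  stopifnot(length(phenotype) == length(cohort$sample_ids),
            all(phenotype %in% c("N", "notN")))
  if (!any(phenotype == "N") || !any(phenotype == "notN"))
    stop("both phenotypes must be non-empty")
  missing <- setdiff(genes, cohort$gene_ids)
  if (length(missing)) stop("genes absent from cohort: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  x <- cohort$expression[genes, , drop = FALSE]
  list(mu_N = rowMeans(x[, phenotype == "N", drop = FALSE]),
       mu_notN = rowMeans(x[, phenotype == "notN", drop = FALSE]))
}

#' Per-patient weighted pathway scores
#'
#' For each patient of phenotype `notN`, two scores are computed over
#' `P_SG` = pathway genes that are also significant genes:
#' `score_N = sum_g e * (e - mu_N(g))^2` and
#' `score_notN = sum_g e * (e - mu_notN(g))^2`, i.e. expression-weighted
#' squared deviations from the phenotype mean.  The weights are the
#' expression values themselves, so a non-negative expression scale is
#' required; when negatives are present the whole matrix is shifted by its
#' global minimum (logged).
#'
#' @param cohort a [survival_cohort()].
#' @param phenotype per-sample `"N"`/`"notN"` labels.
#' @param significant_genes the called significant gene set SG.
#' @param pathway gene vector for one pathway P.
#' @param pathway_name label for error messages and the output.
#' @return object of class `pathway_score_table`: list with `pathway_name`,
#'   `patient_ids` (the notN patients), `score_N`, `score_notN`, `genes`
#'   (P_SG), `p_value` (NA until tested).
#' @export
patient_pathway_scores <- function(cohort, phenotype, significant_genes,
                                   pathway, pathway_name = "pathway") {
  phenotype <- as.character(phenotype)
  p_sg <- intersect(intersect(pathway, significant_genes), cohort$gene_ids)
  if (!length(p_sg))
    stop("pathway '", pathway_name, "' shares no genes with the significant set")
  expr <- cohort$expression
  if (min(expr) < 0) {
    rs_log("patient_pathway_scores: shifting expression by %.4g to enforce non-negative weights",
           -min(expr))
    expr <- expr - min(expr)
  }
  mu <- phenotype_means(survival_cohort(expr, cohort$time, cohort$event),
                        phenotype, p_sg)
  idx <- which(phenotype == "notN")
  e <- expr[p_sg, idx, drop = FALSE]
  score_N <- colSums(e * (e - mu$mu_N)^2)
  score_notN <- colSums(e * (e - mu$mu_notN)^2)
  structure(list(pathway_name = pathway_name,
                 patient_ids = cohort$sample_ids[idx],
                 score_N = unname(score_N), score_notN = unname(score_notN),
                 genes = p_sg, p_value = NA_real_),
            class = "pathway_score_table")
}

#' Phenotype-separation test for one pathway score table
#'
#' Tests whether score_N and score_notN differ for the notN patients.  The
#' two score arrays are defined on the same patients, so the default is a
#' paired two-sided t-test on the per-patient differences; `method =
#' "welch"` exposes the unpaired Welch alternative.  If every difference is
#' exactly zero the p-value is 1; a nonzero constant difference (zero
#' variance) is degenerate and reported as strongly significant (p = 0) with
#' a warning.
#'
#' @param table a [patient_pathway_scores()] result.
#' @param method `"paired"` (default) or `"welch"`.
#' @return the p-value (also stored in the returned table's attribute);
#'   numeric scalar in `[0, 1]`.
#' @export
pathway_separation_test <- function(table, method = c("paired", "welch")) {
  method <- match.arg(method)
  x <- table$score_N
  y <- table$score_notN
  if (length(x) < 2L) stop("need at least 2 patients")
  if (method == "paired") {
    d <- x - y
    if (all(d == 0)) return(1)
    if (stats::sd(d) == 0) {
      warning("zero variance of nonzero differences; reporting p = 0")
      return(0)
    }
    stats::t.test(x, y, paired = TRUE)$p.value
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (all(x == y)) 1 else {
        warning("zero variance in both groups; reporting p = 0"); 0
      })
    stats::t.test(x, y, paired = FALSE, var.equal = FALSE)$p.value
  }
}

#' Score a collection of pathways against the significant gene set
#'
#' Wrapper over [patient_pathway_scores()] and
#' [pathway_separation_test()]; pathways sharing no genes with SG are
#' skipped with a log line.
#'
#' @inheritParams patient_pathway_scores
#' @param pathways a [gene_set_collection()].
#' @param method forwarded to [pathway_separation_test()].
#' @return data.frame: pathway, n_genes_in_SG, p_value.
#' @export
score_pathways <- function(cohort, phenotype, significant_genes, pathways,
                           method = "paired") {
  rows <- lapply(names(pathways), function(nm) {
    tab <- tryCatch(
      patient_pathway_scores(cohort, phenotype, significant_genes,
                             pathways[[nm]], pathway_name = nm),
      error = function(e) NULL)
    if (is.null(tab)) {
      rs_log("score_pathways: skipping %s (no overlap with SG)", nm)
      return(NULL)
    }
    p <- pathway_separation_test(tab, method = method)
    data.frame(pathway = nm, n_genes_in_SG = length(tab$genes), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), n_genes_in_SG = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
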