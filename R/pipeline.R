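#' Pipeline configuration
#'
#' All defaults are the published pipeline settings: 1000 permutations per
#' signature, 1000 random signatures per template, selection thresholds 0
#' (empirical p) and -10 (log10 nominal p), diffusion strength beta = 0.3,
#' 1000 score permutations, and a calling threshold of 0.05.  One master
#' seed is fanned out deterministically to every randomized stage.
#'
#' @param expression,survival,templates,network paths to the pipeline
#'   inputs (TSV / GMT; see the reader functions).
#' @param pathways optional pathway GMT; when NULL the pathway-score stage
#'   is skipped.
#' @param outdir output directory.
#' @param mapping optional two-column identifier mapping TSV
#'   (source_id, gene_symbol) applied to all inputs before analysis.
#' @param n_perm_signature permutations per signature (empirical p-value).
#' @param n_random_per_template random signatures per template.
#' @param empirical_threshold,log10_nominal_threshold selection thresholds.
#' @param beta diffusion strength.
#' @param n_perm_diffusion score permutations.
#' @param alpha significant-gene calling threshold.
#' @param null_mode `"as-printed"` or `"raw-scores"` (see
#'   [permutation_scores()]).
#' @param seed master seed.
#' @return object of class `pipeline_config` (a validated list; round-trips
#'   through [yaml::as.yaml()]).
#' @export
pipeline_config <- function(expression, survival, templates, network,
                            pathways = NULL, outdir = "randsig_out",
                            mapping = NULL,
                            n_perm_signature = 1000L,
                            n_random_per_template = 1000L,
                            empirical_threshold = 0,
                            log10_nominal_threshold = -10,
                            beta = 0.3, n_perm_diffusion = 1000L,
                            alpha = 0.05,
                            null_mode = c("as-printed", "raw-scores"),
                            seed) {
  null_mode <- match.arg(null_mode)
  for (field in c("expression", "survival", "templates", "network")) {
    val <- get(field)
    if (is.null(val) || !nzchar(val))
      stop("pipeline_config: missing required path field '", field, "'")
  }
  stopifnot(n_perm_signature >= 1, n_random_per_template >= 1, beta >= 0,
            n_perm_diffusion >= 1, alpha > 0, alpha <= 1)
  structure(list(expression = expression, survival = survival,
                 templates = templates, network = network,
                 pathways = pathways, outdir = outdir, mapping = mapping,
                 n_perm_signature = as.integer(n_perm_signature),
                 n_random_per_template = as.integer(n_random_per_template),
                 empirical_threshold = empirical_threshold,
                 log10_nominal_threshold = log10_nominal_threshold,
                 beta = beta, n_perm_diffusion = as.integer(n_perm_diffusion),
                 alpha = alpha, null_mode = null_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full mining / prioritization / pathway-score pipeline
#'
#' Stages, in order: load and (optionally) harmonize the inputs; mine random
#' signatures against the cohort and select the significant ones; score and
#' diffuse gene occurrences over the network and call significant genes;
#' compute pathway scores and their phenotype-separation p-values (phenotype
#' `notN` = samples with an observed event, `N` = censored).  Artifacts
#' written to `config$outdir`: `selected_signatures.gmt`,
#' `signature_records.tsv`, `gene_calls.tsv` (all genes, ranked),
#' `pathway_scores.tsv` (when a pathway GMT was given) and `manifest.yaml`.
#'
#' @param config a [pipeline_config()].
#' @return list with `selected`, `records`, `prioritization` (table +
#'   calls), `pathway_scores` (or NULL), `paths` (written artifacts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  result <- tryCatch({
    expr <- read_expression(config$expression)
    surv <- read_survival(config$survival, sample_ids = colnames(expr))
    cohort <- survival_cohort(expr, surv$time, surv$event)
    templates <- read_gmt(config$templates)
    network <- read_string_edges(config$network)
    pathways <- if (!is.null(config$pathways)) read_gmt(config$pathways)
    if (!is.null(config$mapping)) {
      map <- utils::read.delim(config$mapping, header = TRUE, sep = "\t")
      colnames(map)[1:2] <- c("source_id", "gene_symbol")
      h <- harmonize_ids(cohort, templates, network, map)
      cohort <- h$cohort; templates <- h$sets; network <- h$network
      if (!is.null(pathways))
        pathways <- harmonize_ids(sets = pathways, mapping = map)$sets
    }
    net_only <- setdiff(network$nodes, cohort$gene_ids)
    if (length(net_only)) {
      rs_log("run_pipeline: restricting network to the %d cohort genes (%d nodes dropped)",
             length(cohort$gene_ids), length(net_only))
      e <- network$edges
      keep <- e$from %in% cohort$gene_ids & e$to %in% cohort$gene_ids
      network <- weighted_network(e[keep, , drop = FALSE],
                                  nodes = intersect(network$nodes, cohort$gene_ids))
    }

    stage <- "mine"
    rs_log("stage mine: %d templates, %d random signatures each",
           length(templates), config$n_random_per_template)
    mined <- mine_random_signatures(
      cohort, templates,
      n_per_template = config$n_random_per_template,
      n_perm = config$n_perm_signature,
      seed = derive_seed(config$seed, 101L),
      empirical_threshold = config$empirical_threshold,
      log10_nominal_threshold = config$log10_nominal_threshold)

    stage <- "prioritize"
    prio <- prioritize_genes(mined$selected, network,
                             gene_ids = cohort$gene_ids,
                             beta = config$beta,
                             n_perm = config$n_perm_diffusion,
                             seed = derive_seed(config$seed, 202L),
                             alpha = config$alpha,
                             null_mode = config$null_mode)

    stage <- "pathway-score"
    pw <- NULL
    if (!is.null(config$pathways)) {
      phenotype <- ifelse(cohort$event == 1L, "notN", "N")
      pw <- score_pathways(cohort, phenotype, prio$calls$gene, pathways)
    }
    list(cohort = cohort, mined = mined, prio = prio, pw = pw)
  }, error = function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  paths <- list(
    selected = file.path(config$outdir, "selected_signatures.gmt"),
    records = file.path(config$outdir, "signature_records.tsv"),
    gene_calls = file.path(config$outdir, "gene_calls.tsv"),
    pathway_scores = file.path(config$outdir, "pathway_scores.tsv"),
    manifest = file.path(config$outdir, "manifest.yaml"))
  if (length(result$mined$selected)) {
    write_gmt(gene_set_collection(result$mined$selected,
                                  rep("selected random signature",
                                      length(result$mined$selected))),
              paths$selected)
  } else {
    writeLines(character(), paths$selected)
  }
  utils::write.table(result$mined$records, paths$records, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$prio$table, paths$gene_calls, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$pw))
    utils::write.table(result$pw, paths$pathway_scores, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  else paths$pathway_scores <- NULL

  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  manifest <- list(
    config = cfg,
    config_hash = sum(utf8ToInt(yaml::as.yaml(cfg))) %% 1000000007,
    n_selected_signatures = length(result$mined$selected),
    n_significant_genes = nrow(result$prio$calls),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    input_bytes = vapply(
      c(expression = config$expression, survival = config$survival,
        templates = config$templates, network = config$network),
      function(p) file.info(p)$size, numeric(1L)))
  yaml::write_yaml(manifest, paths$manifest)
  rs_log("run_pipeline: done in %.1f s (%d selected signatures, %d significant genes)",
         manifest$elapsed_sec, manifest$n_selected_signatures,
         manifest$n_significant_genes)
  list(selected = result$mined$selected, records = result$mined$records,
       prioritization = result$prio, pathway_scores = result$pw,
       paths = paths)
}
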