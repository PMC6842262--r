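#' Generate size-matched random signatures
#'
#' Each signature is a uniform sample without replacement from the gene
#' universe, size-matched to a template (published-style) signature.
#'
#' @param universe character vector of candidate gene symbols.
#' @param size signature size (<= length(universe)).
#' @param n number of signatures.
#' @param seed RNG seed.
#' @param template_name label carried into signature names.
#' @return object of class `random_signature_batch`: list with `members`
#'   (named list of gene vectors), `size`, `seed`, `template_name`,
#'   `records` (NULL until evaluated).
#' @export
generate_random_signatures <- function(universe, size, n, seed,
                                       template_name = "template") {
  if (size > length(universe)) stop("signature size exceeds universe size")
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  members <- lapply(seq_len(n), function(i) sample(universe, size))
  names(members) <- sprintf("%s_rand%04d", template_name, seq_len(n))
  structure(list(members = members, size = as.integer(size),
                 seed = as.integer(seed), template_name = template_name,
                 records = NULL),
            class = "random_signature_batch")
}

#' Evaluate a batch of random signatures against a cohort
#'
#' Fills one significance record per member (nominal, BH-adjusted and
#' empirical p-value).  Per-signature permutation seeds are derived
#' deterministically from `(seed, member index)` so reruns are bitwise
#' stable.  A member whose genes are all absent from the cohort is recorded
#' as failed (NA p-values), not fatal.
#'
#' @param batch a [generate_random_signatures()] batch (or any object with a
#'   `members` list).
#' @param cohort a [survival_cohort()] with survival fields.
#' @param n_perm permutations per signature.
#' @param seed master seed for the batch.
#' @param progress_every log progress every this many members (0 = silent).
#' @return the batch with `records` filled (data.frame, one row per member).
#' @export
evaluate_batch <- function(batch, cohort, n_perm = 1000L, seed,
                           progress_every = 0L) {
  members <- batch$members
  prep <- logrank_prep(cohort$time, cohort$event)
  n <- length(members)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- names(members)[i]
    rows[[i]] <- tryCatch({
      labels <- pc1_stratify(cohort, members[[i]])
      nominal <- as.numeric(logrank_p_many(prep, matrix(labels, ncol = 1L)))
      set.seed(derive_seed(seed, i))
      L <- vapply(seq_len(n_perm), function(r) labels[sample.int(length(labels))],
                  numeric(length(labels)))
      emp <- empirical_pvalue(nominal, as.numeric(logrank_p_many(prep, L)))
      data.frame(signature_name = nm, size = length(members[[i]]),
                 nominal_p = nominal, adjusted_p = emp$adjusted_p,
                 empirical_p = emp$empirical_p, n_perm = as.integer(n_perm),
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(signature_name = nm, size = length(members[[i]]),
                 nominal_p = NA_real_, adjusted_p = NA_real_,
                 empirical_p = NA_real_, n_perm = as.integer(n_perm),
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    if (progress_every > 0L && i %% progress_every == 0L)
      rs_log("evaluate_batch: %d/%d signatures done", i, n)
  }
  batch$records <- do.call(rbind, rows)
  batch
}

#' Select the significant random signatures by the dual thresholds
#'
#' Keeps members with `empirical_p <= empirical_threshold` AND
#' `log10(nominal_p) <= log10_nominal_threshold` (defaults 0 and -10, i.e.
#' empirical p exactly 0 and nominal p <= 1e-10).  Both comparisons are
#' non-strict.  Failed records never pass.
#'
#' @param records data.frame of significance records (as from
#'   [evaluate_batch()]).
#' @param members named list of gene vectors aligned with `records`.
#' @param empirical_threshold maximum empirical p-value (default 0).
#' @param log10_nominal_threshold maximum log10 nominal p-value (default -10).
#' @return list with `members` (the selected signatures, named list) and
#'   `records` (their record rows).
#' @export
select_significant <- function(records, members, empirical_threshold = 0,
                               log10_nominal_threshold = -10) {
  stopifnot(nrow(records) == length(members))
  ok <- !is.na(records$nominal_p) & !is.na(records$empirical_p) &
    records$empirical_p <= empirical_threshold &
    log10(records$nominal_p) <= log10_nominal_threshold
  list(members = members[ok], records = records[ok, , drop = FALSE])
}

#' Mine significant random signatures across a set of templates
#'
#' For each template gene set, generates `n_per_template` random signatures
#' of the template's size from the cohort gene universe, evaluates them, and
#' pools the selections across templates.
#'
#' @param cohort a [survival_cohort()].
#' @param templates a [gene_set_collection()] whose set sizes define the
#'   random-signature sizes.
#' @param n_per_template random signatures per template.
#' @param n_perm permutations per signature.
#' @param seed master seed.
#' @param empirical_threshold,log10_nominal_threshold selection thresholds.
#' @param progress_every forwarded to [evaluate_batch()].
#' @return list with `selected` (named list of selected gene vectors),
#'   `records` (all records, with a `template` column), and
#'   `selected_records`.
#' @export
mine_random_signatures <- function(cohort, templates, n_per_template = 1000L,
                                   n_perm = 1000L, seed,
                                   empirical_threshold = 0,
                                   log10_nominal_threshold = -10,
                                   progress_every = 0L) {
  universe <- cohort$gene_ids
  all_records <- list()
  all_members <- list()
  for (k in seq_along(templates)) {
    tname <- names(templates)[k]
    size <- length(templates[[k]])
    batch <- generate_random_signatures(universe, size, n_per_template,
                                        seed = derive_seed(seed, 1000L + k),
                                        template_name = tname)
    batch <- evaluate_batch(batch, cohort, n_perm = n_perm,
                            seed = derive_seed(seed, 2000L + k),
                            progress_every = progress_every)
    rec <- batch$records
    rec$template <- tname
    all_records[[k]] <- rec
    all_members <- c(all_members, batch$members)
    rs_log("mine: template %s (size %d): %d/%d signatures evaluated", tname,
           size, sum(!rec$failed), nrow(rec))
  }
  records <- do.call(rbind, all_records)
  sel <- select_significant(records, all_members,
                            empirical_threshold = empirical_threshold,
                            log10_nominal_threshold = log10_nominal_threshold)
  rs_log("mine: selected %d of %d random signatures", length(sel$members),
         length(all_members))
  list(selected = sel$members, records = records,
       selected_records = sel$records)
}
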