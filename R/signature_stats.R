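#' Stratify a cohort by the median of a signature's first principal component
#'
#' The signature submatrix (genes present in the cohort) is gene-wise
#' mean-centered (no variance scaling) and its first principal component is
#' taken by SVD; each sample's PC1 score is compared to the median score.
#' Samples strictly above the median form the "high" group (label 1), the
#' rest the "low" group (label 0).  The split is invariant to the sign of the
#' principal component because the median split is sign-symmetric.
#'
#' @param cohort a [survival_cohort()].
#' @param signature character vector of gene symbols; genes absent from the
#'   cohort are ignored (logged).
#' @return integer 0/1 vector named by sample, both groups non-empty.
#' @export
pc1_stratify <- function(cohort, signature) {
  present <- intersect(signature, cohort$gene_ids)
  if (!length(present)) stop("no signature gene present in cohort")
  n_miss <- length(setdiff(signature, present))
  if (n_miss) rs_log("pc1_stratify: %d signature genes absent from cohort", n_miss)
  if (ncol(cohort$expression) < 4L) stop("need at least 4 samples")
  x <- cohort$expression[present, , drop = FALSE]
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) stop("degenerate PC1: all samples identical on signature genes")
  sv <- svd(xc, nu = 0L, nv = 1L)
  scores <- sv$d[1L] * sv$v[, 1L]
  # SVD determines PC1 only up to sign; canonicalize so the split does not
  # depend on the implementation's (or the data's) sign convention: the
  # sample deviating most from the median score gets a positive deviation.
  med <- stats::median(scores)
  far <- which.max(abs(scores - med))
  if (scores[far] < med) {
    scores <- -scores
    med <- -med
  }
  labels <- as.integer(scores > med)
  if (all(labels == 0L) || all(labels == 1L))
    stop("degenerate PC1 median split: one group empty")
  stats::setNames(labels, cohort$sample_ids)
}

# Precompute the per-event-time risk/event indicator matrices for the
# log-rank score test so that many label vectors can be tested with two
# matrix multiplications.  Depends only on (time, event).
#' @keywords internal
#' @noRd
logrank_prep <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  if (sum(event) < 1L) stop("no events observed")
  et <- sort(unique(time[event == 1]))
  at_risk <- outer(et, time, function(t, s) as.numeric(s >= t))
  ev_at <- outer(et, time, function(t, s) as.numeric(s == t)) *
    rep(event, each = length(et))
  d <- rowSums(ev_at)       # events at each event time
  nr <- rowSums(at_risk)    # at risk at each event time
  list(at_risk = at_risk, ev_at = ev_at, d = d, nr = nr)
}

# Two-sided log-rank (Cox score test for a binary covariate) p-values for a
# matrix of 0/1 label vectors (samples x k).
#' @keywords internal
#' @noRd
logrank_p_many <- function(prep, label_mat) {
  label_mat <- as.matrix(label_mat)
  n1 <- prep$at_risk %*% label_mat          # group-1 at risk per event time
  d1 <- prep$ev_at %*% label_mat            # group-1 events per event time
  frac <- n1 / prep$nr
  O <- colSums(d1)
  E <- colSums(prep$d * frac)
  vfac <- ifelse(prep$nr > 1, prep$d * (prep$nr - prep$d) / (prep$nr - 1), 0)
  V <- colSums(vfac * frac * (1 - frac))
  chi <- ifelse(V > 0, (O - E)^2 / V, 0)
  stats::pchisq(chi, df = 1L, lower.tail = FALSE)
}

#' Nominal survival p-value for a binary stratification
#'
#' Two-sided p-value of the group covariate from a proportional-hazards fit,
#' taken as the score test, which for a single binary covariate is the
#' log-rank test.  Deterministic and closed-form, with no convergence
#' concerns on permuted labels.
#'
#' @param labels 0/1 per-sample group labels (both groups non-empty).
#' @param time per-sample follow-up time.
#' @param event per-sample event indicator (>= 1 event overall).
#' @return two-sided p-value in (0, 1].
#' @export
cox_nominal_pvalue <- function(labels, time, event) {
  labels <- as.integer(labels)
  if (all(labels == 0L) || all(labels == 1L)) stop("one label group is empty")
  prep <- logrank_prep(time, event)
  as.numeric(logrank_p_many(prep, matrix(labels, ncol = 1L)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Ordered p-values are adjusted by `p_(i) * m / i` and then enforced
#' monotone from the largest down (`adj_(i) = min(p_(i) m / i, adj_(i+1))`),
#' capped at 1; the result is returned in the input order.
#'
#' @param p_values numeric vector with entries in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Permutation null of nominal p-values for a signature
#'
#' The PC1-median labels are held fixed in composition while their assignment
#' to samples is shuffled uniformly at random relative to the fixed
#' (time, event) records; the nominal log-rank p-value is recomputed for each
#' shuffle.  This realizes the exchangeability null: outcome independent of
#' the signature stratification.
#'
#' @param cohort a [survival_cohort()].
#' @param signature gene symbols.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return numeric vector of `n_perm` nominal p-values.
#' @export
permutation_null <- function(cohort, signature, n_perm = 1000L, seed) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- pc1_stratify(cohort, signature)
  prep <- logrank_prep(cohort$time, cohort$event)
  set.seed(seed)
  n <- length(labels)
  L <- vapply(seq_len(n_perm), function(r) labels[sample.int(n)],
              numeric(n))
  as.numeric(logrank_p_many(prep, L))
}

#' Empirical p-value of an observed nominal p-value against a permutation null
#'
#' The observed p joins the permutation family (family size m = n_perm + 1)
#' and the whole family is BH-adjusted together; the empirical p-value is the
#' fraction of the n_perm permutation adjusted p-values that are less than or
#' equal to the observed adjusted p-value.
#'
#' @param observed_p observed nominal p-value.
#' @param perm_ps non-empty vector of permutation nominal p-values.
#' @return list with `adjusted_p` (BH-adjusted observed), `empirical_p`, and
#'   `perm_adjusted_p` (the adjusted permutation family).
#' @export
empirical_pvalue <- function(observed_p, perm_ps) {
  if (!length(perm_ps)) stop("empty permutation family")
  fam <- bh_adjust(c(observed_p, perm_ps))
  obs_adj <- fam[1L]
  perm_adj <- fam[-1L]
  list(adjusted_p = obs_adj,
       empirical_p = sum(perm_adj <= obs_adj) / length(perm_ps),
       perm_adjusted_p = perm_adj)
}

#' Full significance record for one signature
#'
#' Convenience wrapper: PC1-median stratification, nominal log-rank p,
#' permutation null, and the joint-family empirical p-value.
#'
#' @inheritParams permutation_null
#' @param name signature name for the output record.
#' @return one-row data.frame: signature_name, size, nominal_p, adjusted_p,
#'   empirical_p, n_perm.
#' @export
signature_significance <- function(cohort, signature, n_perm = 1000L, seed,
                                   name = "signature") {
  labels <- pc1_stratify(cohort, signature)
  nominal <- cox_nominal_pvalue(labels, cohort$time, cohort$event)
  perm <- permutation_null(cohort, signature, n_perm = n_perm, seed = seed)
  emp <- empirical_pvalue(nominal, perm)
  data.frame(signature_name = name, size = length(signature),
             nominal_p = nominal, adjusted_p = emp$adjusted_p,
             empirical_p = emp$empirical_p, n_perm = as.integer(n_perm),
             stringsAsFactors = FALSE)
}
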