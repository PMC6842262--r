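#' Derive a stage- or item-specific RNG seed from a master seed
#'
#' A single master seed is fanned out deterministically to every randomized
#' stage (and to every signature inside a batch) so that one integer controls
#' full reproducibility while sub-streams stay distinct.  The derivation is a
#' Lehmer step modulo the Mersenne prime 2^31 - 1, so results always fit an R
#' integer.
#'
#' @param seed master seed (integer).
#' @param offset non-negative integer distinguishing the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(offset) + 1) %% m
  if (s == 0) s <- 1
  as.integer(s)
}

#' @keywords internal
#' @noRd
rs_log <- function(fmt, ...) {
  message(sprintf(paste0("[randsig] ", fmt), ...))
}

#' Area under the ROC curve for a gene ranking
#'
#' Rank-based AUROC (equivalent to the Mann-Whitney statistic) of a numeric
#' ranking score against binary truth labels; used to quantify how well a
#' prioritization recovers a planted driver module.  Higher scores must mean
#' "more likely positive".  Ties receive midranks.
#'
#' @param score numeric vector, larger = ranked higher.
#' @param truth logical (or 0/1) vector of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
ranking_auroc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), any(truth), any(!truth))
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
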