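#' Exact null distribution of the Mann-Whitney rank-sum statistic
#'
#' Probability mass of the Mann-Whitney count statistic
#' `W = #{(x_i, y_j) : x_i > y_j}` under the null that all
#' `choose(n + m, n)` orderings are equally likely (no ties), computed by
#' the standard generating-function recurrence
#' `c(u; i, j) = c(u - j; i - 1, j) + c(u; i, j - 1)` (dynamic programming
#' over bounded partitions).  The distribution is symmetric about `n m / 2`.
#'
#' @param n,m the two sample sizes (>= 1).
#' @return numeric vector of probabilities over `W = 0..n*m` (names = W),
#'   summing to 1.
#' @export
ranksum_null_distribution <- function(n, m) {
  if (n < 1L || m < 1L) stop("n and m must be >= 1")
  n <- as.integer(n); m <- as.integer(m)
  # prev[[j + 1]] = counts over u = 0..(i-1)*j for row i-1
  prev <- lapply(0:m, function(j) 1)
  for (i in seq_len(n)) {
    cur <- vector("list", m + 1L)
    cur[[1L]] <- 1
    for (j in seq_len(m)) {
      a <- prev[[j + 1L]]              # c(.; i-1, j), length (i-1)*j + 1
      b <- cur[[j]]                    # c(.; i,  j-1), length i*(j-1) + 1
      u_max <- i * j
      av <- c(numeric(j), a, numeric(u_max - j - length(a) + 1L))[1:(u_max + 1L)]
      bv <- c(b, numeric(u_max + 1L - length(b)))
      cur[[j + 1L]] <- av + bv
    }
    prev <- cur
  }
  counts <- prev[[m + 1L]]
  stats::setNames(counts / sum(counts), 0:(n * m))
}

#' One- or two-sided exact Wilcoxon rank-sum test
#'
#' The statistic is reported on the Mann-Whitney count scale
#' (`W = #{(x_i, y_j) : x_i > y_j}`, range `0..n*m`); `alternative =
#' "greater"` tests whether `x` is shifted to the right of `y` (upper tail
#' of W).  With no ties the p-value comes from the exact null distribution;
#' with ties the test falls back to midranks and the normal approximation
#' with tie correction and continuity correction (logged via a warning).
#'
#' @param x,y numeric samples (non-empty, no missing values).
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return object of class `ranksum_result`: list with `W`, `n`, `m`,
#'   `alternative`, `p_value`, `exact` (logical).
#' @export
ranksum_test <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x); m <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties) {
    W <- sum(outer(x, y, ">"))
    pmf <- ranksum_null_distribution(n, m)
    lower <- sum(pmf[1:(W + 1L)])            # P(W' <= W)
    upper <- sum(pmf[(W + 1L):(n * m + 1L)]) # P(W' >= W)
    p <- switch(alternative,
                greater = upper,
                less = lower,
                two.sided = min(1, 2 * min(lower, upper)))
    exact <- TRUE
  } else {
    warning("ties present; using midrank normal approximation with tie correction")
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # midrank Mann-Whitney count
    N <- n + m
    tie_tab <- table(r)
    sigma2 <- n * m / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    mu <- n * m / 2
    z <- W - mu
    cc <- switch(alternative, greater = 0.5, less = -0.5, two.sided = sign(z) * 0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
    exact <- FALSE
  }
  structure(list(W = W, n = n, m = m, alternative = alternative,
                 p_value = as.numeric(p), exact = exact),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g (n = %d, m = %d), %s p = %.5g%s\n",
              x$W, x$n, x$m, x$alternative, x$p_value,
              if (x$exact) " (exact)" else " (normal approx.)"))
  invisible(x)
}

#' Bootstrap of the Wilcoxon rank-sum p-value
#'
#' Each replicate resamples `x` and `y` with replacement (keeping the
#' original sizes) and recomputes the rank-sum p-value; resampling
#' introduces ties, so the tie-tolerant normal-approximation variant is
#' used throughout.  Returns all replicate p-values and their median (the
#' bootstrap point estimate).
#'
#' @param x,y numeric samples.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param alternative forwarded to [ranksum_test()].
#' @return list with `p_values` (length `n_boot`) and `median_p`.
#' @export
bootstrap_wilcoxon <- function(x, y, n_boot = 1000L, seed,
                               alternative = "greater") {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  set.seed(seed)
  ps <- vapply(seq_len(n_boot), function(b) {
    xb <- sample(x, length(x), replace = TRUE)
    yb <- sample(y, length(y), replace = TRUE)
    suppressWarnings(ranksum_test(xb, yb, alternative = alternative)$p_value)
  }, numeric(1L))
  list(p_values = ps, median_p = stats::median(ps))
}
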