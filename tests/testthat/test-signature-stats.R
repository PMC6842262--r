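test_that("single-gene and rank-1 signatures reduce PC1 to a median split on the gene", {
  expr <- rbind(gA = c(1, 2, 3, 4))
  colnames(expr) <- paste0("s", 1:4)
  cohort <- survival_cohort(expr)
  labels <- pc1_stratify(cohort, "gA")
  # the partition is the median split on the gene: {s1,s2} vs {s3,s4}
  expect_equal(labels[["s1"]], labels[["s2"]])
  expect_equal(labels[["s3"]], labels[["s4"]])
  expect_false(labels[["s1"]] == labels[["s3"]])

  # two perfectly correlated genes give the same split as either alone
  expr2 <- rbind(gA = c(1, 2, 3, 4, 0, 5), gB = 2 * c(1, 2, 3, 4, 0, 5) + 1)
  colnames(expr2) <- paste0("s", 1:6)
  cohort2 <- survival_cohort(expr2)
  expect_equal(pc1_stratify(cohort2, c("gA", "gB")),
               pc1_stratify(cohort2, "gA"))
})

test_that("PC1 split matches an independent eigendecomposition oracle", {
  cohort <- make_cohort(3, 6, seed = 11)
  labels <- pc1_stratify(cohort, cohort$gene_ids)
  # oracle: eigenvector of the gene-gene covariance, projected scores
  x <- cohort$expression - rowMeans(cohort$expression)
  ev <- eigen(tcrossprod(x), symmetric = TRUE)$vectors[, 1]
  scores <- as.numeric(ev %*% x)
  oracle <- as.integer(scores > median(scores))
  # the oracle's eigenvector sign is arbitrary: the partition must agree
  same <- identical(unname(labels), oracle) ||
    identical(unname(labels), 1L - oracle)
  expect_true(same)
})

test_that("PC1 stratification is invariant to the sign of the component", {
  for (seed in 1:5) {
    cohort <- make_cohort(5, 10, seed = seed)
    neg <- survival_cohort(-cohort$expression, cohort$time, cohort$event)
    sig <- sample(cohort$gene_ids, 3)
    expect_equal(pc1_stratify(cohort, sig), pc1_stratify(neg, sig))
  }
})

test_that("PC1 stratification rejects degenerate inputs", {
  cohort <- make_cohort(4, 6)
  expect_error(pc1_stratify(cohort, c("nope1", "nope2")), "no signature gene")
  flat <- survival_cohort(matrix(1, 2, 6, dimnames = list(c("a", "b"),
                                                          paste0("s", 1:6))))
  expect_error(pc1_stratify(flat, c("a", "b")), "degenerate")
})

test_that("nominal p-value equals the log-rank test (survdiff oracle)", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 24
    time <- rexp(n)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1
    labels <- rep(c(0L, 1L), n / 2)
    p <- cox_nominal_pvalue(labels, time, event)
    sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
    expect_equal(p, pchisq(sd$chisq, 1, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("identical survival multisets in both groups give p = 1", {
  time <- rep(c(1, 2, 3, 4), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  labels <- rep(c(0L, 1L), each = 4)
  expect_equal(cox_nominal_pvalue(labels, time, event), 1, tolerance = 1e-9)
})

test_that("early events concentrated in one group are detected", {
  # all events early in group 1, group 0 censored late
  time <- c(1:5, 96:100)
  event <- c(rep(1, 5), rep(0, 5))
  labels <- c(rep(1L, 5), rep(0L, 5))
  expect_lt(cox_nominal_pvalue(labels, time, event), 0.05)
  expect_error(cox_nominal_pvalue(rep(1L, 10), time, event), "empty")
  expect_error(cox_nominal_pvalue(labels, time, rep(0, 10)), "no events")
})

test_that("bh_adjust follows the step-up recursion and matches p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(42)
  for (len in c(1, 2, 17, 1001)) {
    p <- runif(len)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    # order preserved and adjusted >= nominal
    expect_true(all(rank(bh_adjust(p)) == rank(p) |
                      duplicated(bh_adjust(p)) |
                      duplicated(bh_adjust(p), fromLast = TRUE)))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("permutation null is seed-reproducible and propagates errors", {
  cohort <- make_cohort(6, 12, seed = 3)
  sig <- cohort$gene_ids[1:3]
  a <- permutation_null(cohort, sig, n_perm = 5, seed = 9)
  b <- permutation_null(cohort, sig, n_perm = 5, seed = 9)
  expect_identical(a, b)
  expect_length(a, 5)
  expect_error(permutation_null(cohort, sig, n_perm = 0, seed = 1), "n_perm")
})

test_that("empirical p-value counts the joint BH family as specified", {
  # hand BH of the 5-value family {0.01, 0.2, 0.4, 0.6, 0.8}:
  # adjusted = (0.05, 0.5, 2/3, 0.75, 0.8); observed below all -> 0
  res <- empirical_pvalue(0.01, c(0.2, 0.4, 0.6, 0.8))
  expect_equal(res$adjusted_p, 0.05)
  expect_equal(res$perm_adjusted_p, c(0.5, 2 / 3, 0.75, 0.8))
  expect_equal(res$empirical_p, 0)

  # observed above every permutation value -> 1
  expect_equal(empirical_pvalue(0.9, c(0.1, 0.2, 0.3))$empirical_p, 1)
  # empirical_p * n_perm is an integer count
  set.seed(1)
  perm <- runif(50)
  e <- empirical_pvalue(0.3, perm)$empirical_p
  expect_equal(e * 50, round(e * 50))
})

test_that("empirical p is conservative under an exchangeable null", {
  # BH plateaus tie large blocks of adjusted values; the tie-inclusive
  # "equal or less" count therefore pushes null empirical p-values toward 1
  # and keeps the 0.05 tail below its nominal level.
  set.seed(12)
  emp <- replicate(800, {
    fam <- runif(101)
    empirical_pvalue(fam[1], fam[-1])$empirical_p
  })
  expect_lt(mean(emp <= 0.05), 0.06)
  expect_gt(median(emp), 0.5)
})

test_that("empirical p-value is monotone in the observed p-value", {
  set.seed(7)
  perm <- runif(100)
  obs <- sort(runif(20))
  emp <- vapply(obs, function(p) empirical_pvalue(p, perm)$empirical_p, 1)
  expect_true(all(diff(emp) >= 0))
})
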