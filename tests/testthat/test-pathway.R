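make_pheno_cohort <- function(n_genes = 4, n_samples = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples)) + 0.1, nrow = n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  list(cohort = survival_cohort(m),
       pheno = rep(c("N", "notN"), length.out = n_samples))
}

test_that("phenotype means are plain arithmetic means per group", {
  m <- rbind(gA = c(1, 3, 10, 20), gB = rep(5, 4))
  colnames(m) <- paste0("s", 1:4)
  cohort <- survival_cohort(m)
  pheno <- c("N", "N", "notN", "notN")
  mu <- phenotype_means(cohort, pheno, c("gA", "gB"))
  expect_equal(unname(mu$mu_N), c(2, 5))
  expect_equal(unname(mu$mu_notN), c(15, 5))
  expect_error(phenotype_means(cohort, rep("N", 4), "gA"), "non-empty")

  fx <- make_pheno_cohort(4, 12, seed = 3)
  mu2 <- phenotype_means(fx$cohort, fx$pheno, fx$cohort$gene_ids)
  expect_equal(mu2$mu_N,
               rowMeans(fx$cohort$expression[, fx$pheno == "N"]))
})

test_that("patient pathway scores follow the weighted squared-deviation form", {
  # single gene, e = 2 with mu_N = 2 -> contribution 0; e = 3, mu = 2 -> 3
  m <- rbind(gA = c(2, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  cohort <- survival_cohort(m)
  pheno <- c("N", "N", "notN")          # mu_N = 2
  tab <- patient_pathway_scores(cohort, pheno, "gA", "gA", "pw")
  expect_equal(tab$score_N, 3 * (3 - 2)^2)

  # additivity over genes of P_SG; genes outside P_SG are ignored
  fx <- make_pheno_cohort(4, 8, seed = 5)
  sg <- c("g01", "g02", "g03")
  tab2 <- patient_pathway_scores(fx$cohort, fx$pheno, sg, c("g01", "g02"))
  t_a <- patient_pathway_scores(fx$cohort, fx$pheno, sg, "g01")
  t_b <- patient_pathway_scores(fx$cohort, fx$pheno, sg, "g02")
  expect_equal(tab2$score_N, t_a$score_N + t_b$score_N)
  with_extra <- patient_pathway_scores(fx$cohort, fx$pheno, sg,
                                       c("g01", "g02", "not_a_gene", "g04"))
  expect_equal(with_extra$score_N, tab2$score_N)   # g04 not in SG, ignored
  # gene order inside the pathway is irrelevant
  expect_equal(patient_pathway_scores(fx$cohort, fx$pheno, sg,
                                      c("g02", "g01"))$score_notN,
               tab2$score_notN)

  expect_error(patient_pathway_scores(fx$cohort, fx$pheno, "g01", "g02",
                                      pathway_name = "pwX"), "pwX")
})

test_that("label swap exchanges the two score arrays", {
  fx <- make_pheno_cohort(5, 12, seed = 9)
  sg <- fx$cohort$gene_ids[1:3]
  tab <- patient_pathway_scores(fx$cohort, fx$pheno, sg, sg)
  swapped <- ifelse(fx$pheno == "N", "notN", "N")
  tab_sw <- patient_pathway_scores(fx$cohort, swapped, sg, sg)
  # the notN patients change, but for a patient in both tables the roles of
  # mu_N and mu_notN are exchanged: compute on a cohort where groups align
  expect_equal(sort(c(tab$patient_ids, tab_sw$patient_ids)),
               sort(fx$cohort$sample_ids))
  mu <- phenotype_means(fx$cohort, fx$pheno, sg)
  mu_sw <- phenotype_means(fx$cohort, swapped, sg)
  expect_equal(mu$mu_N, mu_sw$mu_notN)
  expect_equal(mu$mu_notN, mu_sw$mu_N)
})

test_that("negative expression triggers the logged non-negativity shift", {
  m <- rbind(gA = c(-1, 0, 2, 3))
  colnames(m) <- paste0("s", 1:4)
  cohort <- survival_cohort(m)
  pheno <- c("N", "N", "notN", "notN")
  expect_message(tab <- patient_pathway_scores(cohort, pheno, "gA", "gA"),
                 "shifting")
  # shifted values: 0,1,3,4; mu_N = 0.5
  expect_equal(tab$score_N, c(3 * 2.5^2, 4 * 3.5^2))
})

test_that("separation test matches the closed-form paired t oracle", {
  fx <- make_pheno_cohort(4, 40, seed = 13)
  sg <- fx$cohort$gene_ids
  tab <- patient_pathway_scores(fx$cohort, fx$pheno, sg, sg[1:3])
  p <- pathway_separation_test(tab)
  d <- tab$score_N - tab$score_notN
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(p, 2 * pt(abs(tstat), df = length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical arrays -> p = 1; constant nonzero differences -> degenerate
  tab$score_notN <- tab$score_N
  expect_equal(pathway_separation_test(tab), 1)
  tab$score_notN <- tab$score_N - 1
  expect_warning(p0 <- pathway_separation_test(tab), "zero variance")
  expect_equal(p0, 0)

  tab$score_N <- tab$score_N[1]
  tab$score_notN <- tab$score_notN[1]
  expect_error(pathway_separation_test(tab), "2 patients")
})

test_that("the null carries the own-group shrinkage offset of the score pair", {
  # The scored (notN) patients contribute to mu_notN but not mu_N, so even
  # with no phenotype effect score_N stochastically exceeds score_notN by an
  # offset ~ sigma^2 (1/|N| + 1/|notN|); the separation test is therefore
  # anti-conservative under the null.  Assert the offset's direction.
  set.seed(31)
  mean_diffs <- replicate(40, {
    fx <- make_pheno_cohort(6, 30, seed = sample.int(1e6, 1))
    sg <- fx$cohort$gene_ids
    tab <- patient_pathway_scores(fx$cohort, fx$pheno, sg, sample(sg, 3))
    mean(tab$score_N - tab$score_notN)
  })
  expect_gt(mean(mean_diffs), 0)
  expect_lt(t.test(mean_diffs, alternative = "greater")$p.value, 0.01)
})

test_that("score_pathways summarizes a collection and skips empty overlaps", {
  fx <- make_pheno_cohort(6, 20, seed = 17)
  sg <- fx$cohort$gene_ids[1:4]
  pw <- gene_set_collection(list(hit = fx$cohort$gene_ids[1:3],
                                 miss = "unrelated_gene"))
  out <- suppressMessages(score_pathways(fx$cohort, fx$pheno, sg, pw))
  expect_equal(out$pathway, "hit")
  expect_equal(out$n_genes_in_SG, 3L)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
})
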