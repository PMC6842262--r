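# Shared fixtures built in code: tiny cohorts, networks and files.

make_expr <- function(n_genes = 6, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

make_cohort <- function(n_genes = 6, n_samples = 8, seed = 1) {
  set.seed(seed + 100)
  survival_cohort(make_expr(n_genes, n_samples, seed),
                  time = rexp(n_samples), event = rbinom(n_samples, 1, 0.7))
}

# a small connected weighted network over given node names
make_net <- function(nodes, p = 0.3, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  # guarantee connectivity via a chain
  chain <- cbind(nodes[-length(nodes)], nodes[-1])
  e <- unique(rbind(pairs[keep, , drop = FALSE], chain))
  weighted_network(data.frame(from = e[, 1], to = e[, 2],
                              weight = runif(nrow(e), 0.2, 1)),
                   nodes = nodes)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
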