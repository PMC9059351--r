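# Independent oracles and shared fixtures for the test suite.

# Spearman via the tie-free closed form 1 - 6*sum(d^2)/(n(n^2-1));
# valid only when neither vector has ties.
spearman_closed_form <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force association indices from explicit set operations
brute_index <- function(na, nb, method, n_y = NULL) {
  i <- length(intersect(na, nb))
  a <- length(na); b <- length(nb)
  switch(method,
    jaccard = i / length(union(na, nb)),
    simpson = i / min(a, b),
    geometric = i^2 / (a * b),
    cosine = i / sqrt(a * b),
    pcc = (i * n_y - a * b) / sqrt(a * b * (n_y - a) * (n_y - b)))
}

# hypergeometric upper-tail by exhaustive enumeration over subsets
enum_hyper_p <- function(k, K, N, m) {
  sum(vapply(k:min(K, m), function(j) {
    choose(K, j) * choose(N - K, m - j)
  }, numeric(1))) / choose(N, m)
}

# tiny deterministic z-table for network-construction tests
toy_z_table <- function() {
  set.seed(7)
  x <- matrix(rnorm(6 * 30), nrow = 6,
              dimnames = list(paste0("L", 1:6), paste0("S", 1:30)))
  y <- matrix(rnorm(8 * 30), nrow = 8,
              dimnames = list(paste0("M", 1:8), paste0("S", 1:30)))
  pairwise_z_table(expr_matrix(2^x, "lncRNA", "fpkm"),
                   expr_matrix(2^y, "mRNA", "fpkm"))
}

# default study cohort, generated once per test run
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(synthetic_config())
    cache
  }
})

# a reduced cohort for fast pipeline round-trips
small_config <- function(seed = 11) {
  synthetic_config(
    n_subtypes = 2, samples_per_subtype = 60,
    n_mrna = 120, n_lncrna = 60, n_mirna = 30, n_groups = 3,
    group_sizes = list(mrna = c(14, 10, 7), lncrna = c(9, 6, 4),
                       mirna = c(5, 4, 3)),
    seed = seed)
}

# preprocessing chain for one subtype of a cohort, mirroring the
# pipeline's per-subtype path
preprocess_subtype <- function(cohort, st = "subtype1") {
  lapply(cohort$matrices, function(m) {
    norm <- upper_quartile_normalize(filter_nonzero_features(m))
    per_st <- subtype_expression_filter(
      norm, cohort$labels,
      median_filter = m$rna_class != "miRNA")[[st]]
    remove_outlier_samples(log2_shift_transform(per_st))
  })
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a), as.character(b))
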