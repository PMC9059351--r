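test_that("the five indices match their set-arithmetic definitions", {
  na <- c("m1", "m2", "m3"); nb <- c("m2", "m3", "m4")
  expect_equal(association_index(na, nb, "jaccard"), 0.5)
  expect_equal(association_index(na, nb, "simpson"), 2 / 3)
  expect_equal(association_index(na, nb, "geometric"), 4 / 9)
  expect_equal(association_index(na, nb, "cosine"), 2 / 3)
  # identical neighborhoods: all set indices 1; pcc 1 when 0 < |N| < n_y
  for (m in c("jaccard", "simpson", "geometric", "cosine")) {
    expect_equal(association_index(na, na, m), 1)
  }
  expect_equal(association_index(na, na, "pcc", n_y = 5), 1)
  # profile-PCC equals the Pearson correlation of incidence vectors
  expect_equal(association_index(c("y1", "y2"), c("y2", "y3"), "pcc", n_y = 4), 0)
  expect_equal(cor(c(1, 1, 0, 0), c(0, 1, 1, 0)), 0)
})

test_that("undefined index combinations are signaled", {
  expect_error(association_index(character(0), character(0), "jaccard"),
               class = "undefined_index")
  expect_error(association_index(character(0), "y1", "simpson"),
               class = "undefined_index")
  expect_error(association_index(c("y1", "y2"), c("y1", "y2"), "pcc", n_y = 2),
               class = "undefined_index")
  expect_error(association_index("y1", "y2", "pcc"), "n_y")
  # jaccard of one empty set against a non-empty one is 0, not undefined
  expect_equal(association_index(character(0), "y1", "jaccard"), 0)
})

test_that("index inequalities hold over neighborhoods of a 6-element Y set", {
  universe <- paste0("y", 1:6)
  set.seed(31)
  for (i in 1:300) {
    na <- universe[runif(6) < 0.5]
    nb <- universe[runif(6) < 0.5]
    if (length(na) == 0 || length(nb) == 0) next
    g <- association_index(na, nb, "geometric")
    c_ <- association_index(na, nb, "cosine")
    s <- association_index(na, nb, "simpson")
    j <- association_index(na, nb, "jaccard")
    expect_lte(g, c_ + 1e-12)
    expect_lte(c_, s + 1e-12)
    expect_lte(j, c_ + 1e-12)
  }
})

test_that("pairwise similarities equal the scalar computation and are symmetric", {
  zt <- toy_z_table()
  net <- build_bipartite(zt, sort(abs(zt$z), decreasing = TRUE)[20])
  sim <- pairwise_profile_similarity(net, "x")
  expect_equal(nrow(sim), choose(length(net$x_nodes), 2))
  for (r in seq_len(nrow(sim))) {
    na <- neighborhood(net, sim$node_a[r], "x")
    nb <- neighborhood(net, sim$node_b[r], "x")
    for (m in c("jaccard", "simpson", "geometric", "cosine", "pcc")) {
      expected <- tryCatch(association_index(na, nb, m, n_y = net$n_y),
                           undefined_index = function(e) NA_real_)
      expect_equal(sim[[m]][r], expected, tolerance = 1e-12)
      # symmetry: swapping the pair changes nothing
      swapped <- tryCatch(association_index(nb, na, m, n_y = net$n_y),
                          undefined_index = function(e) NA_real_)
      expect_equal(expected, swapped, tolerance = 1e-12)
    }
  }
  expect_error(pairwise_profile_similarity(
    build_bipartite(zt, max(abs(zt$z))), "x"), "at least 2")
})

test_that("area labels partition the records with quantile boundaries", {
  set.seed(32)
  recs <- data.frame(
    node_a = paste0("a", 1:10), node_b = paste0("b", 1:10),
    index = "jaccard",
    value_1 = sample(seq(0.1, 1, 0.1)), value_2 = sample(seq(0.1, 1, 0.1)))
  out <- assign_areas(recs, area_quantile = 0.5)
  expect_false(any(is.na(out$area)))
  # with 10 distinct values and the median boundary, exactly the top 5
  # of each axis are high
  hi1 <- out$value_1 %in% sort(out$value_1, decreasing = TRUE)[1:5]
  hi2 <- out$value_2 %in% sort(out$value_2, decreasing = TRUE)[1:5]
  expect_equal(out$area, ifelse(hi1 & hi2, "D", ifelse(hi1, "B",
                                ifelse(hi2, "C", "A"))))
  # degenerate axis errors
  recs$value_1 <- 0.5
  expect_error(assign_areas(recs), "degenerate")
  # missing values stay unlabeled
  recs2 <- data.frame(node_a = "a", node_b = "b", index = "cosine",
                      value_1 = c(0.1, NA, 0.9), value_2 = c(0.1, 0.5, 0.9))
  expect_true(is.na(assign_areas(recs2, 0.5)$area[2]))
})

test_that("coherent pairs need area D, extreme rank, and enough supporting indices", {
  # 50 pairs per index; p1 tops jaccard/cosine/simpson, p2 only
  # jaccard/cosine, p3 only simpson/pcc (it holds their bulk maxima)
  mk <- function(idx, v) {
    data.frame(node_a = paste0("p", seq_along(v)), node_b = "q",
               index = idx, value_1 = v, value_2 = v)
  }
  base1 <- seq(0.01, 0.45, length.out = 48)
  recs <- rbind(
    mk("jaccard", c(0.99, 0.98, base1)),
    mk("cosine", c(0.99, 0.98, base1)),
    mk("simpson", c(0.99, 0.10, rev(base1))),
    mk("geometric", c(0.02, 0.01, base1)),
    mk("pcc", c(0.02, 0.01, rev(base1))))
  recs <- assign_areas(recs, area_quantile = 0.9)
  out <- select_coherent_pairs(
    recs, coherence_config(min_indices = 3, top_frac = 0.04))
  expect_equal(out$node_a, "p1")
  expect_equal(out$n_support, 3L)
  out2 <- select_coherent_pairs(
    recs, coherence_config(min_indices = 2, top_frac = 0.04))
  expect_setequal(out2$node_a, c("p1", "p2", "p3"))
  # coherent pairs are always a subset of area-D pairs
  d_pairs <- unique(recs$node_a[!is.na(recs$area) & recs$area == "D"])
  expect_true(all(out2$node_a %in% d_pairs))
  # empty result is allowed
  out3 <- select_coherent_pairs(
    recs, coherence_config(min_indices = 5, top_frac = 0.001))
  expect_equal(nrow(out3), 0)
})

test_that("planted lncRNA pairs concentrate in area D and contexts agree", {
  co <- default_cohort()
  mats <- preprocess_subtype(co)
  net1 <- {
    zt <- pairwise_z_table(mats$lncRNA, mats$mRNA, clip = TRUE)
    build_bipartite(zt, select_cutoff(zt)$cutoff)
  }
  net2 <- {
    zt <- pairwise_z_table(mats$lncRNA, mats$miRNA, clip = TRUE)
    build_bipartite(zt, select_cutoff(zt)$cutoff)
  }
  recs <- assign_areas(similarity_records(
    pairwise_profile_similarity(net1, "x"),
    pairwise_profile_similarity(net2, "x")))
  g <- co$truth$group_of$lncrna
  planted <- g[recs$node_a] > 0 & g[recs$node_a] == g[recs$node_b]
  frac <- tapply(planted, recs$area, mean)
  expect_gt(frac[["D"]], frac[["A"]])
  # pairs similar in the shared-mRNA context tend to be similar in the
  # shared-miRNA context
  j <- recs[recs$index == "jaccard", ]
  expect_gt(cor(j$value_1, j$value_2, method = "spearman",
                use = "complete.obs"), 0)
})
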